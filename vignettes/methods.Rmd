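---
title: "Models and methods: nascent-chain compaction in the exit tunnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: nascent-chain compaction in the exit tunnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribotunnel)
```

This vignette is the package's own account of its models: what is computed,
which parameters matter and why their defaults are what they are, what the
synthetic-data generators do and do not emulate, and where the design was
genuinely open. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## 1. Conformer construction

Peptides are built from internal coordinates by natural-extension-of-
reference-frame (NeRF) placement: each atom is placed from the previous
three by bond length, bond angle and torsion (`place_next_atom`), with the
torsion measured in the IUPAC convention so that building and re-measuring
a dihedral round-trips exactly. Backbone bond lengths and angles are
standard peptide values; ω is fixed at 180°.

Two conformational states are supported:

* **helical** — canonical α-helix dihedrals φ = −57°, ψ = −47°, applied
  inside the sequence's annotated helical region (the rest of the chain
  stays extended). The built helix has ~3.6 residues per turn and an axial
  rise of ~1.56 Å per residue, within the conventional "~1.5 Å" figure.
* **extended** — φ = −130°, ψ = +135° by default. These are *calibrated*
  values, not a β-strand convention: the sources that motivate this package
  quote an extended nascent chain at ~3.4 Å per residue, and fully extended
  (180°, 180°) dihedrals would give ~3.6–3.8 Å. The default reproduces a
  measured rise of ~3.43 Å per residue. The dihedrals are tunable through
  `backbone_geometry()`.

Rise is measured as the end-to-end Cα displacement projected onto the
best-fit chain axis (first principal component of the Cα cloud), divided by
n − 1; it is rigid-motion invariant by construction.

Side chains are represented by a single pseudo-atom per residue ("CB"),
placed 2.0 Å from Cα along the Cα→Cβ direction (L-configuration improper
dihedral), with a per-residue radius calibrated to the side-chain volume
(Gly smallest, Trp largest). This is a deliberate desk-scale choice: it
gives surface-area calculations the right relative footprint per residue
without rotamer libraries or force fields, which are out of scope.

## 2. SASA and the burial statistics

`sasa()` implements Shrake–Rupley point sampling with a deterministic
golden-section spiral lattice (default 960 points/atom, probe 1.4 Å).
A deterministic lattice makes results reproducible without a seed; the
price is that the lattice is fixed in the atom frame, so totals are
translation-invariant exactly but rotation-stable only to ~0.1–0.5%. The
test suite verifies the isolated sphere against 4π(r+probe)² and
two-sphere configurations against the analytic spherical-cap formula
within 1%.

`delta_sasa()` computes the burial ΔSASA = SASA(selection | complex) −
SASA(selection | peptide alone). The default selection is the hydrophobic
atoms of the annotated helical region (`burial_selection`). Because context
atoms can only occlude lattice points, ΔSASA ≤ 0 holds exactly, not just
statistically. Occlusion by *all* context atoms is counted, following the
operational definition of burial; the alternative reading in which only
hydrophobic contacts count is exposed separately through
`occluder_attribution()`, which attributes every lost lattice point to the
context atom whose expanded sphere it penetrates most deeply and splits the
totals by wall-atom hydrophobicity. The attribution totals equal |ΔSASA|
exactly because the same lattice is reused.

`dd_sasa()` contrasts two state ensembles sharing a context:
ΔΔSASA = mean ΔSASA(helical) − mean ΔSASA(extended), with means optionally
restricted to the trailing fraction of frames (default window 0.5,
mirroring the practice of scoring the equilibrated tail of a trajectory;
for the package's i.i.d. synthetic frames the window only trades precision).
`burial_energy()` converts areas with the empirical hydrophobic-burial
coefficient 0.015 kcal·mol⁻¹·Å⁻², negative = stabilizing.

## 3. The synthetic tunnel and ensembles

`make_tunnel()` builds a rotationally symmetric channel along z (P-site at
z = 0): length 100 Å, lumen diameter 20 Å at the ends narrowing to 10 Å at
a constriction 30 Å from the P-site — the textbook dimensions of the exit
tunnel. The radius profile interpolates these control points with smooth
cosine ramps (monotone on each side, exact at the knots; an earlier
monotone-spline implementation undershot the V-shaped minimum). Wall
pseudo-atom centres (radius 1.8 Å) sit on the *offset* surface
r(z) + 1.8 Å so that the wall's van der Waals surface, not its centre line,
delimits the stated lumen. Hydrophobicity flags are Bernoulli draws
(default fraction 0.3), or three localized rings (two at the constriction,
one near the exit) as a closer cartoon of the known hydrophobic patches.
This is deliberately a cartoon: no nucleic-acid chemistry, no
electrostatics, no aspherical vestibule.

`jitter_ensemble()` stands in for the out-of-scope molecular-dynamics
ensembles: each frame is a rigid placement draw (uniform axial offset ±2 Å,
small Gaussian tilt) plus independent per-atom Gaussian jitter (σ = 0.3 Å),
rejection-resampled until no peptide atom centre comes within 1.2 Å of a
wall atom centre. Frames are i.i.d. given the seed — they emulate the
*magnitude* of thermal positional spread, not correlated dynamics,
conformational exchange, or solvent structure. A green ensemble test
therefore establishes that the geometry-driven burial contrast has the
expected sign and magnitude ordering, nothing about kinetics or sampling.

**Anchoring (a load-bearing choice).** The C-terminal Cα is anchored at
z = 27 Å, not at the P-site itself. The assayed test segments begin 7–9
residues from the P-site, and those linker residues are extended in either
state: 8 × 3.4 Å ≈ 27 Å. This matters: anchored directly at the P-site, a
22-residue extended conformer stays entirely inside the tunnel and out-buries
the helix (ΔΔSASA > 0); anchored at 27 Å, the extended chain protrudes past
the exit pore into solvent while the helix remains packed against the
constriction, and ΔΔSASA < 0 for hydrophobic sequences — which is precisely
the physical mechanism the burial statistic is meant to capture. The anchor
is a parameter (`anchor_z`) and the choice is recorded here rather than
hidden in a default.

**Test sequences.** `make_test_sequences()` draws TM-like segments
(20–22 residues from a hydrophobic alphabet), soluble-like segments (a
strictly polar, helix-favouring alphabet — by construction their burial
selection is empty and the burial contrast is exactly zero, a degenerate
but faithful rendering of "close to zero"; real hydrophilic helices carry
a few nonpolar residues, and users can supply their own sequences),
half-TM segments (~11 hydrophobic residues padded with polar flanks), and
central-pair mutants.

## 4. The gel simulator

`simulate_gel()` draws glycosylated/non-glycosylated band intensities as
total·G(d)/100 and total·(1 − G(d)/100), each multiplied by independent
lognormal noise (σ = 0.15 on the log scale). Multiplicative noise is the
natural model for densitometry; σ = 0.15 is a free default — the sources
give no quantitative gel-noise characterization. Ground-truth logistic
parameters default to the two profile families the assay contrasts:
extended d50 = 64, compacted d50 = 70, slope 1.2 residues,
G_min = 5%, G_max = 95%.

## 5. Quantification, fitting, and the compaction call

* `percent_glyc` = 100·glyc/(glyc + nonglyc), scale-invariant.
* `build_profile` summarizes per distance with mean, sample SD (n − 1
  denominator) and n, warning below the n ≥ 3 floor.
* `pnst_distance` uses the exclusive-of-Asn convention: d = truncation
  length − Asn position, i.e. residues strictly C-terminal of the acceptor
  Asn. The inclusive/exclusive choice is not fixed by the assay description;
  it is fixed here once and used everywhere.

**`fit_sigmoid` operates on the logit scale.** Since
logit(percent) = log(glyc/nonglyc), the lognormal band noise is additive,
homoscedastic and Gaussian on that scale, so least squares there is the
maximum-likelihood fit under the gel noise model; on the raw percent scale
the same fit is visibly less efficient. Optimization is bounded L-BFGS-B
from several data-driven starts, with a restart polish if the line search
stops early; flat profiles are flagged non-identifiable instead of fitted.

One estimator assumption deserves emphasis: the background floor g_min is
bounded above by `max_background` (default 15%). When the assayed
distances do not reach the lower plateau — exactly the situation for an
extended-law profile sampled at d ∈ 63..73 — g_min is unidentified, and an
unbounded fit lets a single noisy low-d point lift the floor and drag d50
upward by up to a residue. The bound encodes an assay fact (acceptor sites
out of reach of the glycosylation machinery show only a small residual
background; observed floors are ~5%), not a fitted constant, and it can be
disabled with `max_background = 100`.

* `critical_stat` is G(d = 73) − G(d = 67): the distance long enough for
  full glycosylation in every construct versus the critical distance that
  maximally separates compact from extended chains. Compact profiles show a
  large positive gap; extended ones sit near the ceiling at both distances.
* `infer_folded` converts a midpoint shift into folded residues:
  n = 3.4·Δd50/(3.4 − 1.5). For the canonical Δd50 ≈ 6 this gives 10.7;
  the prose figure usually quoted is "more than 12", which does not follow
  from these constants — the function returns the closed form and the
  discrepancy is documented rather than reconciled.
* `call_compaction` classifies: *compact* if Δd50 ≥ 3 residues or gap ≥ 25
  points; *extended* if Δd50 ≤ 1 and gap ≤ 10; *intermediate* otherwise.
  The thresholds were chosen once to separate the two default simulation
  families cleanly and are exposed as arguments.
* `compare_conditions` is a Welch (unequal-variance) two-sample t-test on
  replicate percent values with stars at 0.01/0.001; the variance model of
  the original comparisons is not stated, and Welch is the safe default.
* `gel_mass_model`: each N-glycan adds ~2.5 kDa of apparent mass.

## 6. Folding-propensity scoring

`propensity_score` is an explicitly labeled heuristic:

score = L_run − w_P·#Pro − w_G·#Gly − w_q·#charged + w_h·Σ KD(core)/22,

where L_run is the longest contiguous hydrophobic run
(set {A, C, F, I, L, M, V, W}), the core is the full hydrophobic span
(first to last hydrophobic residue; polar flanks never enter), KD is
Kyte–Doolittle hydropathy, and the class is *folds-in-tunnel* iff
L_run ≥ 14 and score ≥ 16. The 14-residue floor comes from the observation
that roughly 14 hydrophobic residues are needed for a glycosylation pattern
compatible with helix formation; it need not coincide with the membrane-
*insertion* threshold (a half-TM with 12 hydrophobic residues can still
insert), which is why no stronger insertion predictor is offered.

The weights are a calibration, not a derivation: w_P = 3 > w_G = 1.15 >
w_q = 1.0, w_h = 1. Their only contract is to reproduce the qualitative
mutant ordering (II ≈ LL) > AA > DD > GG > KK > PP and the full-TM versus
half-TM contrast. Two structural facts fall out of the algebra: (i) a
weight ordering with w_q > w_G cannot produce DD > GG, because Asp and Lys
share the charge penalty and Gly's hydropathy penalty is milder — so the
helix-breaker Gly must out-penalize charge directly; (ii) dividing the
hydropathy sum by a fixed reference length (22) rather than the core length
guarantees that extending a hydrophobic run never lowers the score, which
is tested as a property.

## 7. Numerical and engineering choices

* Degenerate inputs: collinear NeRF frames, sub-4-residue rise
  measurements, non-physical tunnel dimensions, oversized conformers,
  zero-intensity lanes and motif-less constructs all raise typed errors;
  flat profiles and non-converged fits are flagged, never thrown.
* Determinism: every generator is a pure function of (parameters, seed);
  the pipeline derives a named sub-stream seed per stage
  (`substream_seed`), so adding draws to one stage never shifts another.
  RNG state of the caller is always restored.
* I/O: PDB ATOM records (fixed columns, chain A, pseudo-side-chains as CB,
  wall atoms as residue TUN, radius stored in the B-factor column so files
  round-trip without an external radius table; multi-frame as
  MODEL/ENDMDL); tidy CSV for gel data; JSON for configs and reports
  (YAML was the original intent but no YAML reader is available in the
  supported dependency set, and JSON loses nothing here).

## 8. Known limitations

* The tunnel is a smooth rotationally symmetric cartoon; real tunnels have
  aspherical vestibules, RNA walls and specific protein loops at the
  constriction. ΔΔSASA magnitudes are therefore not comparable to all-atom
  values — only signs and orderings are meaningful, and the acceptance
  battery asserts exactly that.
* Ensemble frames are i.i.d. positional jitter; no conformational exchange
  between helical and extended states, no partial helicity.
* The soluble test family is strictly polar, making its burial contrast
  exactly zero rather than "small".
* The propensity score is a calibrated heuristic; its numerical values have
  no thermodynamic meaning.
* Percent-glycosylation means under multiplicative band noise are slightly
  biased off the logistic law away from the midpoint (the logit means are
  exact); the fitting works on the logit scale partly for this reason.
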