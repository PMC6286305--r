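# ribotunnel

Desk-scale analysis of whether a nascent peptide chain folds into an
α-helix while it is still inside the ribosome exit tunnel.

## The problem

The exit tunnel of the ribosome is a ~100 Å channel, 10–20 Å wide, with its
narrowest constriction ~30 Å from the P-site. Transmembrane (TM) segments —
stretches of ~20 mostly hydrophobic residues — appear to compact into
helices inside this tunnel, while hydrophilic helices of soluble proteins
do not. Two independent rulers can detect this:

1. **Hydrophobic burial (structural ruler).** For a peptide conformer inside
   a tunnel, ΔSASA is the solvent-accessible surface area of the hydrophobic
   residues of its helical region in the peptide–tunnel complex minus the
   same selection for the peptide alone (always ≤ 0; the magnitude is the
   hydrophobic surface concealed by the tunnel). Comparing conformational
   states over ensembles,

   ΔΔSASA = mean ΔSASA(helical) − mean ΔSASA(extended),

   a negative value means the tunnel preferentially stabilizes the helix;
   the burial free energy is ΔG ≈ 0.015 kcal·mol⁻¹·Å⁻² × ΔSASA.

2. **Glycosylation mapping (biochemical ruler).** In stalled, truncated
   constructs, the distance *d* (residues between the acceptor Asn of an
   N-S-T sequon and the C-terminus held at the P-site) is titrated, and
   percent glycosylation versus *d* is fitted with a logistic
   G(d) = G_min + (G_max − G_min)/(1 + exp(−(d − d50)/s)).
   An extended chain reaches the glycosylation machinery at d50 ≈ 64
   residues; a chain compacted to a helix needs d50 ≈ 70. Converting rise
   per residue (3.4 Å extended, 1.5 Å helical), a shift of Δd50 residues
   implies n = 3.4·Δd50/(3.4 − 1.5) residues folded.

The package implements both rulers plus a synthetic-data module (reduced
tunnel geometries, seeded conformer ensembles, designed test sequences, and
replicate gel datasets with multiplicative noise) so the whole analysis is
testable without wet-lab or molecular-dynamics input, and a sequence-level
heuristic scoring of in-tunnel folding propensity (hydrophobic run length,
helix-breaker and charge penalties).

## Worked example

```r
library(ribotunnel)
res <- run_pipeline(system.file("extdata", "demo_config.json",
                                package = "ribotunnel"))
print(res$sasa$ddsasa)
print(res$gel$tm_like$call)
print(res$gel$extended_like$call)
```

Output (seed 1, shipped demo configuration):

```
ddSASA = -770.49 +/- 33.4 A^2 (helical -1535.3 , extended -764.78 , window 0.5 )
CompactionCall: compact (d50 69.91 vs ref 64.0 => shift 5.91 res; gap 76.2 pts; ~10.6 residues folded)
CompactionCall: extended (d50 63.88 vs ref 64.0 => shift -0.12 res; gap 6.9 pts; ~0.0 residues folded)
```

Reading this: for a 22-residue TM-like peptide in the default synthetic
tunnel, the helical ensemble buries ~770 Å² more hydrophobic surface than
the extended ensemble (ΔΔSASA < 0: the tunnel favours the helix). The
simulated TM-like gel dataset fits with d50 ≈ 69.9 — a +5.9-residue shift
from the extended reference of 64, a 76-point glycosylation gap between
d = 73 and the critical distance d = 67, and an implied ~10.6 folded
residues — so the chain is called *compact*; the extended-law dataset stays
at d50 ≈ 63.9 and is called *extended*.

Sequence-level scoring:

```r
base <- make_test_sequences("tm", seed = 3)
rank_mutants(base)
#>   label replacement     score rank near_wt
#> 1    WT (wild type) 25.709091    1    TRUE
#> 2    LL           L 25.672727    2    TRUE
#> 3    AA           A 25.490909    3   FALSE
#> 4    DD           D 11.009091    4   FALSE
#> 5    GG           G 10.990909    5   FALSE
#> 6    KK           K 10.972727    6   FALSE
#> 7    PP           P  7.181818    7   FALSE
```

The central-pair mutant series ranks Leu ≈ wild type at the top and the
helix-breaking Pro pair last, mirroring the experimentally observed order
of glycosylation increase (Pro-Pro > Lys-Lys > Gly-Gly > Asp-Asp > Ala-Ala).

## Command line

A thin CLI wraps the pipeline (see `?ribotunnel_cli`):

```sh
Rscript inst/exec/ribotunnel demo seed=1 out=demo_out
Rscript inst/exec/ribotunnel simulate-gel d50=70 seed=2 out=gel.csv
Rscript inst/exec/ribotunnel fit gel=gel.csv
```
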