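# Synthetic data: reduced exit-tunnel geometry, conformational ensembles,
# designed test sequences, and simulated glycosylation gels.

# Run expr with a locally seeded RNG, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a named sub-stream seed from a global seed
#'
#' Deterministic hash of (global seed, stream name) onto [0, 2^31 - 2], so
#' that each pipeline stage draws from its own stream and adding draws to one
#' stage never shifts another.
#'
#' @param seed integer global seed
#' @param name stream name
#' @return Integer seed.
#' @export
substream_seed <- function(seed, name) {
  h <- as.double(seed %% 2147483647L)
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

#' Synthetic reduced exit-tunnel geometry
#'
#' A rotationally symmetric channel of wall pseudo-atoms along the z axis
#' (the P-site at z = 0): ~100 Angstrom long, 20 Angstrom in diameter at the
#' ends and narrowing to 10 Angstrom at a constriction ~30 Angstrom from the
#' P-site. The lumen radius profile r(z) interpolates the three control
#' points with smooth cosine ramps (monotone on each side of the
#' constriction); wall atom centres sit in rings on the offset surface
#' r(z) + wall_radius, so the wall's van der Waals surface
#' delimits the stated lumen diameter, with seeded positional jitter.
#' Hydrophobic wall flags are either Bernoulli draws at
#' `hydrophobic_fraction`, or, with `hydrophobic_rings = TRUE`, three
#' localized rings (two at the constriction, one near the exit) as a closer
#' cartoon of the L4/L17 and L39 patches.
#'
#' @param length tunnel length, Angstrom
#' @param d_max,d_min maximal / minimal diameter, Angstrom
#' @param constriction_at axial position of the narrowest point, Angstrom
#' @param wall_spacing ring spacing and in-ring atom spacing, Angstrom
#' @param hydrophobic_fraction Bernoulli probability of a hydrophobic wall
#'   atom
#' @param hydrophobic_rings place localized hydrophobic rings instead of
#'   random flags
#' @param wall_radius wall pseudo-atom radius, Angstrom
#' @param jitter_sd positional jitter SD, Angstrom
#' @param seed RNG seed
#' @return An object of class `TunnelModel`.
#' @examples
#' tun <- make_tunnel(seed = 1)
#' min(2 * tun$radius_profile(seq(0, 100, 0.5))) # ~10
#' @export
make_tunnel <- function(length = 100, d_max = 20, d_min = 10,
                        constriction_at = 30, wall_spacing = 2.2,
                        hydrophobic_fraction = 0.3, hydrophobic_rings = FALSE,
                        wall_radius = 1.8, jitter_sd = 0.25, seed = 1L) {
  if (d_min > d_max || d_min <= 0 || length <= 0 ||
      constriction_at <= 0 || constriction_at >= length) {
    stop("input error: non-physical tunnel dimensions")
  }
  # smooth cosine ramps on either side of the constriction: monotone on each
  # side, derivative zero at the ends and at the minimum, exact at the knots
  r_lo <- d_min / 2
  r_hi <- d_max / 2
  rfun <- function(z) {
    z <- pmin(pmax(z, 0), length)
    t <- ifelse(z <= constriction_at,
                (constriction_at - z) / constriction_at,
                (z - constriction_at) / (length - constriction_at))
    r_lo + (r_hi - r_lo) * (1 - cos(pi * t)) / 2
  }
  atoms <- with_seed(seed, {
    zs <- seq(0, length, by = wall_spacing)
    rows <- lapply(zs, function(z) {
      # centres offset outward by the wall-atom radius so the van der Waals
      # surface of the wall delimits the stated lumen diameter
      r <- rfun(z) + wall_radius
      m <- max(6L, round(2 * pi * r / wall_spacing))
      ang <- 2 * pi * (seq_len(m) - 1) / m + stats::runif(1, 0, 2 * pi / m)
      data.frame(x = r * cos(ang), y = r * sin(ang), z = z, ring_r = r)
    })
    df <- do.call(rbind, rows)
    n <- nrow(df)
    df$x <- df$x + stats::rnorm(n, 0, jitter_sd)
    df$y <- df$y + stats::rnorm(n, 0, jitter_sd)
    df$z <- df$z + stats::rnorm(n, 0, jitter_sd)
    if (hydrophobic_rings) {
      # two rings at the constriction, one near the exit pore
      centres <- c(constriction_at - 2, constriction_at + 2, 0.85 * length)
      df$hydrophobic <- Reduce(`|`, lapply(centres, function(c0)
        abs(df$z - c0) < 2.5))
    } else {
      df$hydrophobic <- stats::runif(n) < hydrophobic_fraction
    }
    df
  })
  tun <- list(
    atoms = sphere_set(as.matrix(atoms[, c("x", "y", "z")]),
                       radius = wall_radius, owner = "context",
                       hydrophobic = atoms$hydrophobic, role = "W"),
    ring_r = atoms$ring_r,
    radius_profile = rfun,
    length = length, d_max = d_max, d_min = d_min,
    constriction_at = constriction_at,
    hydrophobic_fraction = hydrophobic_fraction, seed = seed
  )
  class(tun) <- "TunnelModel"
  tun
}

#' @export
print.TunnelModel <- function(x, ...) {
  cat("TunnelModel: length", x$length, "A, diameter", x$d_min, "-", x$d_max,
      "A, constriction at", x$constriction_at,
      "A;", nrow(x$atoms), "wall atoms (",
      round(100 * mean(x$atoms$hydrophobic)), "% hydrophobic )\n")
  invisible(x)
}

#' @rdname as_sphere_set
#' @export
as_sphere_set.TunnelModel <- function(x, ...) x$atoms

#' Ensemble sampling parameters
#'
#' @param n_frames number of frames (>= 1)
#' @param jitter_sd per-atom Gaussian jitter SD, Angstrom
#' @param axial_range range of the uniform rigid axial offset, Angstrom
#' @param tilt_sd_deg SD of the rigid tilt angle, degrees
#' @param clash_dist centre-centre peptide-wall distance under which a frame
#'   is rejected, Angstrom
#' @param seed RNG seed
#' @return List of class `EnsembleSpec`.
#' @export
ensemble_spec <- function(n_frames = 50, jitter_sd = 0.3,
                          axial_range = c(-2, 2), tilt_sd_deg = 2,
                          clash_dist = 1.2, seed = 1L) {
  stopifnot(n_frames >= 1, jitter_sd >= 0, clash_dist >= 0)
  structure(list(n_frames = as.integer(n_frames), jitter_sd = jitter_sd,
                 axial_range = axial_range, tilt_sd_deg = tilt_sd_deg,
                 clash_dist = clash_dist, seed = seed),
            class = "EnsembleSpec")
}

rotation_about <- function(axis, angle) {
  u <- unit3(axis)
  c0 <- cos(angle); s0 <- sin(angle)
  u %o% u * (1 - c0) + diag(3) * c0 +
    matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3) * s0
}

#' Place a conformer inside a tunnel
#'
#' Rotates the conformer so its best-fit chain axis lies along +z with the
#' C-terminus toward the P-site (low z, where the nascent chain is tethered)
#' and the N-terminus pointing toward the exit, centres it on the tunnel
#' axis, and anchors the C-terminal CA at `anchor_z`.
#'
#' @param conf a `Conformer`
#' @param anchor_z axial coordinate of the C-terminal CA, Angstrom
#' @return A peptide `SphereSet`.
#' @export
place_in_tunnel <- function(conf, anchor_z = 27) {
  ss <- as_sphere_set(conf)
  xyz <- as.matrix(ss[, c("x", "y", "z")])
  ca <- ca_coords(conf)
  axis <- chain_axis(ca)        # oriented N -> C
  target <- c(0, 0, -1)         # C-terminus at low z
  v <- cross3(axis, target)
  s <- sqrt(sum(v^2)); cth <- sum(axis * target)
  R <- if (s < 1e-12) {
    if (cth > 0) diag(3) else rotation_about(c(1, 0, 0), pi)
  } else rotation_about(v / s, atan2(s, cth))
  xyz <- xyz %*% t(R)
  ca_r <- ca %*% t(R)
  # centre the CA centroid on the tunnel axis, anchor last CA axially
  shift <- c(-mean(ca_r[, 1]), -mean(ca_r[, 2]), anchor_z - ca_r[nrow(ca_r), 3])
  xyz <- sweep(xyz, 2, shift, "+")
  ss$x <- xyz[, 1]; ss$y <- xyz[, 2]; ss$z <- xyz[, 3]
  ss
}

min_wall_distance <- function(pep, wall) {
  P <- as.matrix(pep[, c("x", "y", "z")])
  W <- as.matrix(wall[, c("x", "y", "z")])
  d2 <- outer(rowSums(P^2), rowSums(W^2), "+") - 2 * P %*% t(W)
  sqrt(max(0, min(d2)))
}

#' Seeded conformational ensemble of a peptide inside a tunnel
#'
#' A cartoon stand-in for an equilibrium trajectory: each frame applies a
#' rigid placement draw (uniform axial offset, small random tilt about the
#' anchor point) followed by independent per-atom Gaussian jitter, and is
#' rejection-resampled until no peptide atom centre comes closer than
#' `clash_dist` to a wall atom centre. Frames are independent given the seed
#' stream.
#'
#' @param conf a `Conformer`
#' @param tunnel a `TunnelModel`
#' @param spec an `EnsembleSpec`
#' @param anchor_z see \code{\link{place_in_tunnel}}
#' @return List of peptide `SphereSet` frames.
#' @export
jitter_ensemble <- function(conf, tunnel, spec = ensemble_spec(),
                            anchor_z = 27) {
  base <- place_in_tunnel(conf, anchor_z = anchor_z)
  wall <- as_sphere_set(tunnel)
  if (min_wall_distance(base, wall) < spec$clash_dist) {
    stop("placement error: conformer clashes with the tunnel wall at zero ",
         "jitter (min centre distance ",
         format(min_wall_distance(base, wall), digits = 3), " A < clash ",
         spec$clash_dist, " A)")
  }
  xyz0 <- as.matrix(base[, c("x", "y", "z")])
  anchor <- c(0, 0, anchor_z)
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_frames), function(f) {
      for (try in seq_len(100L)) {
        dz <- stats::runif(1, spec$axial_range[1], spec$axial_range[2])
        tilt <- deg2rad(stats::rnorm(1, 0, spec$tilt_sd_deg))
        phi0 <- stats::runif(1, 0, 2 * pi)
        R <- rotation_about(c(cos(phi0), sin(phi0), 0), tilt)
        xyz <- sweep(sweep(xyz0, 2, anchor) %*% t(R), 2, anchor, "+")
        xyz[, 3] <- xyz[, 3] + dz
        xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, spec$jitter_sd),
                            ncol = 3)
        fr <- base
        fr$x <- xyz[, 1]; fr$y <- xyz[, 2]; fr$z <- xyz[, 3]
        if (spec$jitter_sd == 0 && all(spec$axial_range == 0) &&
            spec$tilt_sd_deg == 0) return(base)
        if (min_wall_distance(fr, wall) >= spec$clash_dist) return(fr)
      }
      stop("placement error: could not draw a clash-free frame in 100 tries")
    })
  })
}

#' Designed test sequences
#'
#' Seeded generators for the sequence families the tunnel assay contrasts:
#' \describe{
#'   \item{tm}{20-22 residues drawn from a hydrophobic alphabet (a
#'     transmembrane-like segment).}
#'   \item{soluble}{a strictly polar, helix-favouring alphabet emulating a
#'     hydrophilic helix from a soluble protein; its burial selection is
#'     empty by construction.}
#'   \item{half_tm}{the N- or C-terminal half (~10-12 residues) of a tm
#'     segment, padded back to full length with polar flanks.}
#'   \item{mutant_pair}{a tm segment whose central residue pair is replaced.}
#' }
#'
#' @param kind one of `"tm"`, `"soluble"`, `"half_tm"`, `"mutant_pair"`
#' @param length sequence length (tm / soluble)
#' @param base `PeptideSequence` to mutate or halve (defaults to a seeded tm)
#' @param replacement single residue for `mutant_pair`, one of
#'   L, A, K, D, G, P (or I for the wild type)
#' @param half `"N"` or `"C"` for `half_tm`
#' @param seed RNG seed
#' @return A `PeptideSequence`.
#' @export
make_test_sequences <- function(kind = c("tm", "soluble", "half_tm",
                                         "mutant_pair"),
                                length = 22, base = NULL, replacement = "L",
                                half = "N", seed = 1L) {
  kind <- match.arg(kind)
  tm_alphabet <- c("I", "L", "V", "F", "A", "M", "W")
  tm_weights <- c(4, 4, 3, 2, 1.5, 1, 0.5)
  polar_alphabet <- c("E", "K", "Q", "R", "S", "N", "D", "T", "H")
  polar_weights <- c(3, 3, 2.5, 2, 2, 2, 1.5, 1.5, 1)
  draw <- function(alphabet, w, n) {
    sample(alphabet, n, replace = TRUE, prob = w / sum(w))
  }
  with_seed(seed, switch(kind,
    tm = peptide_sequence(
      paste(draw(tm_alphabet, tm_weights, length), collapse = ""),
      id = sprintf("tm_%d", seed)),
    soluble = peptide_sequence(
      paste(draw(polar_alphabet, polar_weights, length), collapse = ""),
      id = sprintf("soluble_%d", seed)),
    half_tm = {
      if (is.null(base)) base <- make_test_sequences("tm", length = length,
                                                     seed = seed)
      n <- length(base$residues)
      keep <- floor(n / 2)
      core <- if (half == "N") base$residues[seq_len(keep)]
              else base$residues[(n - keep + 1L):n]
      pad <- draw(polar_alphabet, rep(1, 9), n - keep)
      res <- if (half == "N") c(core, pad) else c(pad, core)
      peptide_sequence(paste(res, collapse = ""),
                       id = paste0(base$id, "_half", half))
    },
    mutant_pair = {
      if (is.null(base)) base <- make_test_sequences("tm", length = length,
                                                     seed = seed)
      if (!replacement %in% c("I", "L", "A", "K", "D", "G", "P")) {
        stop("input error: replacement must be one of I, L, A, K, D, G, P")
      }
      res <- base$residues
      n <- length(res)
      centre <- floor(n / 2)            # replaces positions centre, centre+1
      res[c(centre, centre + 1L)] <- replacement
      peptide_sequence(paste(res, collapse = ""),
                       id = paste0(base$id, "_", replacement, replacement))
    }
  ))
}

#' Gel simulation parameters
#'
#' Ground-truth logistic law for percent glycosylation versus the P-NST
#' distance d, plus the replicate structure and multiplicative (lognormal)
#' band noise of a radiolabel gel. Defaults anchor the two profile families:
#' an extended nascent chain reaches the glycosylation machinery at
#' d50 ~ 64 residues, a compacted (helical) one at d50 ~ 70.
#'
#' @param d P-NST distances assayed (residues)
#' @param replicates lanes per distance (>= 3 for summary statistics)
#' @param d50 distance of half-maximal glycosylation (residues)
#' @param slope logistic width parameter (residues)
#' @param g_min,g_max lower/upper glycosylation asymptotes (percent)
#' @param total total lane intensity (arbitrary units)
#' @param sigma lognormal noise SD (log scale) per band
#' @param construct label carried into the dataset
#' @param seed RNG seed
#' @return List of class `GelSimSpec`.
#' @export
gel_sim_spec <- function(d = 63:73, replicates = 3, d50 = 64, slope = 1.2,
                         g_min = 5, g_max = 95, total = 1000, sigma = 0.15,
                         construct = "sim", seed = 1L) {
  stopifnot(g_min >= 0, g_min < g_max, g_max <= 100, slope > 0,
            replicates >= 1)
  structure(list(d = d, replicates = as.integer(replicates), d50 = d50,
                 slope = slope, g_min = g_min, g_max = g_max, total = total,
                 sigma = sigma, construct = construct, seed = seed),
            class = "GelSimSpec")
}

#' Logistic glycosylation law
#'
#' G(d) = g_min + (g_max - g_min) / (1 + exp(-(d - d50)/slope)), percent.
#'
#' @param d P-NST distance (residues)
#' @param d50,slope,g_min,g_max logistic parameters
#' @return Percent glycosylation.
#' @export
glyc_law <- function(d, d50, slope, g_min = 5, g_max = 95) {
  g_min + (g_max - g_min) / (1 + exp(-(d - d50) / slope))
}

#' Simulate a glycosylation-mapping gel dataset
#'
#' For each distance and replicate, the glycosylated and non-glycosylated
#' band intensities are `total * G(d)/100` and `total * (1 - G(d)/100)`, each
#' multiplied by independent lognormal noise (multiplicative, as appropriate
#' for densitometry).
#'
#' @param spec a `GelSimSpec`
#' @return A tidy data.frame of class `GelDataset` with columns construct,
#'   d, replicate, band (`"glyc"`/`"nonglyc"`), intensity.
#' @examples
#' gel <- simulate_gel(gel_sim_spec(d50 = 70, seed = 7))
#' head(gel)
#' @export
simulate_gel <- function(spec) {
  stopifnot(inherits(spec, "GelSimSpec"))
  grid <- expand.grid(replicate = seq_len(spec$replicates), d = spec$d)
  g <- glyc_law(grid$d, spec$d50, spec$slope, spec$g_min, spec$g_max)
  with_seed(spec$seed, {
    noise <- function(n) exp(stats::rnorm(n, 0, spec$sigma))
    n <- nrow(grid)
    out <- rbind(
      data.frame(construct = spec$construct, d = grid$d,
                 replicate = grid$replicate, band = "glyc",
                 intensity = spec$total * g / 100 * noise(n)),
      data.frame(construct = spec$construct, d = grid$d,
                 replicate = grid$replicate, band = "nonglyc",
                 intensity = spec$total * (1 - g / 100) * noise(n))
    )
    out <- out[order(out$d, out$replicate, out$band), ]
    rownames(out) <- NULL
    class(out) <- c("GelDataset", "data.frame")
    out
  })
}
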