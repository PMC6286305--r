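# Shrake-Rupley solvent-accessible surface area and burial statistics.

#' Construct a sphere set
#'
#' The common atomic container for surface-area work: each row is one sphere
#' with a centre, radius, owner (`"peptide"` or `"context"`), hydrophobicity
#' flag and residue index (NA for context atoms).
#'
#' @param xyz numeric matrix (n x 3) of centres, Angstrom
#' @param radius numeric vector of radii, Angstrom
#' @param owner `"peptide"` or `"context"`, recycled
#' @param hydrophobic logical vector, recycled
#' @param residue integer residue indices, recycled (NA allowed)
#' @param role atom role labels, recycled
#' @return An object of class `SphereSet` (a data.frame).
#' @export
sphere_set <- function(xyz, radius, owner = "peptide", hydrophobic = FALSE,
                       residue = NA_integer_, role = "X") {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, all(is.finite(xyz)), all(radius > 0))
  n <- nrow(xyz)
  df <- data.frame(
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    radius = rep_len(radius, n), owner = rep_len(owner, n),
    hydrophobic = rep_len(hydrophobic, n),
    residue = rep_len(residue, n), role = rep_len(role, n),
    stringsAsFactors = FALSE
  )
  class(df) <- c("SphereSet", "data.frame")
  df
}

#' Convert an object to a `SphereSet`
#' @param x object to convert
#' @param ... passed to methods
#' @export
as_sphere_set <- function(x, ...) UseMethod("as_sphere_set")

#' @export
as_sphere_set.SphereSet <- function(x, ...) x

#' @rdname as_sphere_set
#' @export
as_sphere_set.Conformer <- function(x, ...) {
  a <- x$atoms
  ss <- sphere_set(as.matrix(a[, c("x", "y", "z")]), a$radius,
                   owner = "peptide", hydrophobic = a$hydrophobic,
                   residue = a$residue, role = a$role)
  ss$code <- a$code
  ss
}

rbind_sphere_sets <- function(a, b) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  for (col in setdiff(names(a), names(b))) b[[col]] <- rep(NA, nrow(b))
  for (col in setdiff(names(b), names(a))) a[[col]] <- rep(NA, nrow(a))
  out <- rbind(a, b[names(a)])
  class(out) <- c("SphereSet", "data.frame")
  out
}

# Deterministic golden-section spiral on the unit sphere. The lattice is
# fixed in the atom frame, so totals are reproducible without a seed at the
# price of a ~0.1% orientation dependence.
.spiral_cache <- new.env(parent = emptyenv())
unit_sphere_points <- function(n) {
  key <- as.character(n)
  if (!is.null(.spiral_cache[[key]])) return(.spiral_cache[[key]])
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (k - 1)
  pts <- cbind(r * cos(phi), r * sin(phi), z)
  .spiral_cache[[key]] <- pts
  pts
}

# Logical accessibility mask (n_points long) for sphere i of `ss` given
# occluders `occ_idx` (row indices into ss, excluding i).
.point_access <- function(ss, i, occ_idx, probe, pts) {
  R <- ss$radius[i] + probe
  P <- pts * R
  P[, 1] <- P[, 1] + ss$x[i]
  P[, 2] <- P[, 2] + ss$y[i]
  P[, 3] <- P[, 3] + ss$z[i]
  if (!length(occ_idx)) return(rep(TRUE, nrow(P)))
  C <- cbind(ss$x[occ_idx], ss$y[occ_idx], ss$z[occ_idx])
  thr <- (ss$radius[occ_idx] + probe)^2
  d2 <- outer(rowSums(P^2), rowSums(C^2), "+") - 2 * P %*% t(C)
  rowSums(sweep(d2, 2, thr, "<")) == 0L
}

.neighbours <- function(ss, i, candidates, probe) {
  dx <- ss$x[candidates] - ss$x[i]
  dy <- ss$y[candidates] - ss$y[i]
  dz <- ss$z[candidates] - ss$z[i]
  cut <- (ss$radius[candidates] + ss$radius[i] + 2 * probe)^2
  candidates[dx * dx + dy * dy + dz * dz < cut & candidates != i]
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Point-sampling SASA: each atom's expanded sphere (radius + probe) is
#' covered with a deterministic golden-section spiral lattice; a point is
#' accessible if it lies outside every neighbouring expanded sphere, and the
#' atom's area is the accessible fraction times 4*pi*(r+probe)^2. Only
#' neighbours within r_i + r_j + 2*probe are tested as occluders.
#'
#' @param spheres a `SphereSet` (or object convertible via
#'   \code{\link{as_sphere_set}})
#' @param probe probe radius, Angstrom (water: 1.4)
#' @param n_points lattice points per atom (>= 32)
#' @param selection logical or integer index of the atoms whose area is
#'   reported; occluders are always drawn from the full set. Default: all.
#' @return A list of class `SASAResult`: `per_atom` (data.frame with the
#'   selected atoms' areas), `per_residue` aggregate, `total`, and the
#'   sampling parameters.
#' @examples
#' s <- sphere_set(matrix(0, 1, 3), 1.7)
#' sasa(s)$total # ~ 4*pi*3.1^2
#' @export
sasa <- function(spheres, probe = 1.4, n_points = 960, selection = NULL) {
  ss <- as_sphere_set(spheres)
  if (probe < 0) stop("input error: probe radius must be >= 0")
  if (n_points < 32) stop("input error: n_points must be >= 32")
  n <- nrow(ss)
  sel <- if (is.null(selection)) seq_len(n) else seq_len(n)[selection]
  params <- list(probe = probe, n_points = n_points)
  if (!length(sel)) {
    out <- list(per_atom = data.frame(atom = integer(), residue = integer(),
                                      area = numeric()),
                per_residue = data.frame(residue = integer(), area = numeric()),
                total = 0, params = params)
    class(out) <- "SASAResult"
    return(out)
  }
  pts <- unit_sphere_points(n_points)
  all_idx <- seq_len(n)
  area <- vapply(sel, function(i) {
    nb <- .neighbours(ss, i, all_idx, probe)
    frac <- mean(.point_access(ss, i, nb, probe, pts))
    frac * 4 * pi * (ss$radius[i] + probe)^2
  }, numeric(1))
  per_atom <- data.frame(atom = sel, residue = ss$residue[sel], area = area)
  agg <- stats::aggregate(area ~ residue, data = per_atom, FUN = sum,
                          na.action = stats::na.pass)
  out <- list(per_atom = per_atom, per_residue = agg,
              total = sum(area), params = params)
  class(out) <- "SASAResult"
  out
}

#' @export
print.SASAResult <- function(x, ...) {
  cat("SASAResult: total", format(x$total, digits = 6), "A^2 over",
      nrow(x$per_atom), "atoms (probe", x$params$probe, "A,",
      x$params$n_points, "points/atom)\n")
  invisible(x)
}

#' Default burial selection: hydrophobic atoms of the helical region
#'
#' Returns the logical selection (over a peptide `SphereSet` or `Conformer`)
#' of atoms belonging to hydrophobic residues inside the sequence's annotated
#' helical region — the selection over which nascent-chain burial is scored.
#'
#' @param conf a `Conformer`
#' @return Logical vector over the conformer's atoms.
#' @export
burial_selection <- function(conf) {
  stopifnot(inherits(conf, "Conformer"))
  span <- conf$sequence$helical_region
  conf$atoms$hydrophobic &
    conf$atoms$residue >= span[1] & conf$atoms$residue <= span[2]
}

#' Hydrophobic burial: selection SASA in complex minus alone
#'
#' Computes the SASA of a selection of peptide atoms twice — once with the
#' peptide embedded in its context (e.g. an exit-tunnel wall) and once for
#' the peptide alone — and reports the difference. Because adding context
#' atoms can only occlude lattice points, the difference is <= 0; its
#' magnitude is the hydrophobic surface concealed by the context.
#'
#' @param peptide peptide `SphereSet` (or `Conformer`)
#' @param context context `SphereSet` (or `TunnelModel`); may have zero rows
#' @param selection logical/integer selection over the *peptide* atoms;
#'   default: hydrophobic atoms
#' @param probe,n_points see \code{\link{sasa}}
#' @return A list of class `DeltaSASAResult` with `delta` (A^2, <= 0),
#'   `sasa_alone`, `sasa_complex` and the parameters.
#' @export
delta_sasa <- function(peptide, context, selection = NULL,
                       probe = 1.4, n_points = 960) {
  pep <- as_sphere_set(peptide)
  ctx <- as_sphere_set(context)
  np <- nrow(pep)
  sel <- if (is.null(selection)) which(pep$hydrophobic) else seq_len(np)[selection]
  if (anyNA(sel) || (length(sel) && max(sel) > np)) {
    stop("input error: selection must address peptide atoms only")
  }
  alone <- sasa(pep, probe, n_points, selection = sel)
  combined <- rbind_sphere_sets(pep, ctx)
  complex <- sasa(combined, probe, n_points, selection = sel)
  out <- list(delta = complex$total - alone$total,
              sasa_alone = alone$total, sasa_complex = complex$total,
              selection = sel, n_context = nrow(ctx),
              params = alone$params)
  class(out) <- "DeltaSASAResult"
  out
}

#' @export
print.DeltaSASAResult <- function(x, ...) {
  cat("DeltaSASA:", format(x$delta, digits = 6), "A^2 (alone",
      format(x$sasa_alone, digits = 6), ", in complex",
      format(x$sasa_complex, digits = 6), ")\n")
  invisible(x)
}

#' Ensemble burial contrast between helical and extended states
#'
#' Computes per-frame \code{\link{delta_sasa}} for two conformational
#' ensembles sharing one context and reports
#' ddsasa = mean(helical) - mean(extended). A negative value means the
#' context buries more hydrophobic surface of the helical state, i.e. the
#' tunnel preferentially stabilizes the helix. Means can be restricted to the
#' trailing fraction of frames (`window`), mirroring the practice of scoring
#' an equilibrated trajectory tail.
#'
#' @param helical_frames,extended_frames lists of peptide `SphereSet` frames
#' @param context context `SphereSet`
#' @param selection_helical,selection_extended atom selections for the two
#'   states (the atoms scored); see \code{\link{delta_sasa}}
#' @param probe,n_points sampling parameters (identical for both states)
#' @param window fraction (0, 1] of trailing frames entering the means
#' @return A list of class `DDSASAResult` with per-frame series, windowed
#'   means, SDs, standard errors, and `ddsasa`.
#' @export
dd_sasa <- function(helical_frames, extended_frames, context,
                    selection_helical = NULL, selection_extended = NULL,
                    probe = 1.4, n_points = 960, window = 0.5) {
  stopifnot(length(helical_frames) >= 1, length(extended_frames) >= 1,
            window > 0, window <= 1)
  per_state <- function(frames, selection) {
    vapply(frames, function(fr) {
      delta_sasa(fr, context, selection = selection,
                 probe = probe, n_points = n_points)$delta
    }, numeric(1))
  }
  dh <- per_state(helical_frames, selection_helical)
  de <- per_state(extended_frames, selection_extended)
  tail_idx <- function(v) seq.int(floor(length(v) * (1 - window)) + 1L, length(v))
  wh <- dh[tail_idx(dh)]
  we <- de[tail_idx(de)]
  se <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
  out <- list(
    delta_helical = dh, delta_extended = de,
    mean_helical = mean(wh), mean_extended = mean(we),
    sd_helical = if (length(wh) > 1) stats::sd(wh) else 0,
    sd_extended = if (length(we) > 1) stats::sd(we) else 0,
    se_helical = se(wh), se_extended = se(we),
    ddsasa = mean(wh) - mean(we),
    se_ddsasa = sqrt(se(wh)^2 + se(we)^2),
    window = window, params = list(probe = probe, n_points = n_points)
  )
  class(out) <- "DDSASAResult"
  out
}

#' @export
print.DDSASAResult <- function(x, ...) {
  cat("ddSASA =", format(x$ddsasa, digits = 5), "+/-",
      format(x$se_ddsasa, digits = 3), "A^2",
      "(helical", format(x$mean_helical, digits = 5),
      ", extended", format(x$mean_extended, digits = 5),
      ", window", x$window, ")\n")
  invisible(x)
}

#' Free-energy estimate from buried hydrophobic area
#'
#' Linear conversion dG = coefficient * dSASA with the empirical
#' hydrophobic-burial coefficient 0.015 kcal/mol/A^2; negative values are
#' stabilizing.
#'
#' @param dsasa a `DeltaSASAResult`, `DDSASAResult`, or a plain area (A^2)
#' @param coefficient kcal/mol/A^2, > 0
#' @return List of class `EnergyEstimate` with `dG` (kcal/mol) and the
#'   coefficient.
#' @export
burial_energy <- function(dsasa, coefficient = 0.015) {
  stopifnot(coefficient > 0)
  area <- if (inherits(dsasa, "DeltaSASAResult")) dsasa$delta
          else if (inherits(dsasa, "DDSASAResult")) dsasa$ddsasa
          else as.numeric(dsasa)
  out <- list(dG = coefficient * area, coefficient = coefficient, area = area)
  class(out) <- "EnergyEstimate"
  out
}

#' @export
print.EnergyEstimate <- function(x, ...) {
  cat("dG =", format(x$dG, digits = 4), "kcal/mol",
      "(", format(x$coefficient, digits = 3), "kcal/mol/A^2 x",
      format(x$area, digits = 5), "A^2 )\n")
  invisible(x)
}

#' Attribute buried surface to context atom classes
#'
#' For each selected peptide atom, lattice points that are accessible with
#' the peptide alone but lost in the complex are attributed to the occluding
#' context atom whose expanded surface the point penetrates most deeply;
#' totals are split by the context atoms' hydrophobicity flag. The class
#' totals sum exactly to |dSASA| (the same lattice is reused), and the
#' surface already occluded peptide-internally is reported separately.
#'
#' @inheritParams delta_sasa
#' @return List of class `OccluderAttribution`: `hydrophobic`, `polar`
#'   (A^2 lost to each context class), `internal` (A^2 occluded by the
#'   peptide itself in the alone state) and `delta` for reference.
#' @export
occluder_attribution <- function(peptide, context, selection = NULL,
                                 probe = 1.4, n_points = 960) {
  pep <- as_sphere_set(peptide)
  ctx <- as_sphere_set(context)
  np <- nrow(pep)
  sel <- if (is.null(selection)) which(pep$hydrophobic) else seq_len(np)[selection]
  comb <- rbind_sphere_sets(pep, ctx)
  ctx_rows <- np + seq_len(nrow(ctx))
  pts <- unit_sphere_points(n_points)
  hydro_area <- polar_area <- internal_area <- 0
  for (i in sel) {
    patch <- 4 * pi * (pep$radius[i] + probe)^2 / n_points
    nb_pep <- .neighbours(pep, i, seq_len(np), probe)
    acc_alone <- .point_access(pep, i, nb_pep, probe, pts)
    internal_area <- internal_area + sum(!acc_alone) * patch
    if (!nrow(ctx)) next
    nb_ctx <- .neighbours(comb, i, ctx_rows, probe)
    if (!length(nb_ctx)) next
    acc_ctx <- .point_access(comb, i, nb_ctx, probe, pts)
    lost <- acc_alone & !acc_ctx
    if (!any(lost)) next
    R <- pep$radius[i] + probe
    P <- pts[lost, , drop = FALSE] * R
    P[, 1] <- P[, 1] + pep$x[i]; P[, 2] <- P[, 2] + pep$y[i]
    P[, 3] <- P[, 3] + pep$z[i]
    C <- cbind(comb$x[nb_ctx], comb$y[nb_ctx], comb$z[nb_ctx])
    d <- sqrt(pmax(outer(rowSums(P^2), rowSums(C^2), "+") - 2 * P %*% t(C), 0))
    # penetration depth below each occluder's expanded surface
    depth <- sweep(-d, 2, comb$radius[nb_ctx] + probe, "+")
    owner <- nb_ctx[apply(depth, 1, which.max)]
    is_hydro <- comb$hydrophobic[owner]
    hydro_area <- hydro_area + sum(is_hydro) * patch
    polar_area <- polar_area + sum(!is_hydro) * patch
  }
  out <- list(hydrophobic = hydro_area, polar = polar_area,
              internal = internal_area,
              delta = -(hydro_area + polar_area))
  class(out) <- "OccluderAttribution"
  out
}

#' @export
print.OccluderAttribution <- function(x, ...) {
  cat("Buried by context: hydrophobic", format(x$hydrophobic, digits = 5),
      "A^2, polar", format(x$polar, digits = 5),
      "A^2; peptide-internal", format(x$internal, digits = 5), "A^2\n")
  invisible(x)
}
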