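# Glycosylation-mapping analysis: P-NST distance accounting, gel
# quantification, profile statistics, sigmoid fitting and the compaction
# call.

#' Truncated nascent-chain construct
#'
#' A stalled, truncated construct carrying a single Asn-Ser-Thr acceptor
#' sequon. The assay's ruler is d, the number of residues strictly
#' C-terminal of the acceptor Asn.
#'
#' @param sequence full construct sequence (one-letter codes)
#' @param asn_pos 1-based position of the acceptor Asn; the sequence must
#'   read N-S-T there
#' @param truncation_length chain length at the stall point (defaults to the
#'   full sequence length)
#' @param id label
#' @return List of class `Construct` with the derived `d`.
#' @export
glyc_construct <- function(sequence, asn_pos,
                           truncation_length = nchar(sequence),
                           id = "construct") {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  stopifnot(asn_pos >= 1, truncation_length <= n)
  if (asn_pos + 2 > n || substr(sequence, asn_pos, asn_pos + 2) != "NST") {
    stop("construct error: no N-S-T acceptor motif at position ", asn_pos)
  }
  if (truncation_length < asn_pos) {
    stop("construct error: truncation removes the acceptor site")
  }
  structure(list(id = id, sequence = sequence, asn_pos = as.integer(asn_pos),
                 truncation_length = as.integer(truncation_length),
                 d = as.integer(truncation_length - asn_pos)),
            class = "Construct")
}

#' P-NST distance of a construct
#'
#' d = truncation length - Asn position: the number of residues strictly
#' C-terminal of the acceptor Asn, i.e. between the Asn and the P-site
#' tether.
#'
#' @param x a `Construct`
#' @return Integer distance in residues.
#' @export
pnst_distance <- function(x) {
  stopifnot(inherits(x, "Construct"))
  x$d
}

#' Percent glycosylation from two band intensities
#'
#' 100 * glyc / (glyc + nonglyc); invariant under a common intensity
#' rescaling, as densitometry ratios must be.
#'
#' @param glyc,nonglyc band intensities (>= 0), vectorized
#' @return Percent glycosylation.
#' @export
percent_glyc <- function(glyc, nonglyc) {
  if (any(glyc < 0 | nonglyc < 0)) stop("input error: negative intensity")
  if (any(glyc + nonglyc == 0)) {
    stop("quantification error: both bands have zero intensity")
  }
  100 * glyc / (glyc + nonglyc)
}

#' Replicate glycosylation profile from a gel dataset
#'
#' Pairs the glycosylated and non-glycosylated band of each (construct, d,
#' replicate) lane, converts to percent glycosylation, and summarizes per
#' distance as mean, sample SD (n - 1 denominator) and n. A warning is
#' issued for distances with fewer than `min_n` replicates; with a single
#' replicate the SD is reported as NA.
#'
#' @param dataset a `GelDataset` (tidy data.frame: construct, d, replicate,
#'   band, intensity)
#' @param min_n replicate floor for summary rows (default 3)
#' @return List of class `GlycProfile`: `summary` (d, mean, sd, n) and
#'   `replicates` (d, replicate, percent).
#' @export
build_profile <- function(dataset, min_n = 3) {
  if (!nrow(dataset)) stop("input error: empty gel dataset")
  wide <- stats::reshape(as.data.frame(dataset), direction = "wide",
                         idvar = c("construct", "d", "replicate"),
                         timevar = "band")
  pct <- data.frame(d = wide$d, replicate = wide$replicate,
                    percent = percent_glyc(wide$intensity.glyc,
                                           wide$intensity.nonglyc))
  pct <- pct[order(pct$d, pct$replicate), ]
  sds <- tapply(pct$percent, pct$d, function(v)
    if (length(v) > 1) stats::sd(v) else NA_real_)
  summ <- data.frame(
    d = as.numeric(names(sds)),
    mean = as.numeric(tapply(pct$percent, pct$d, mean)),
    sd = as.numeric(sds),
    n = as.integer(tapply(pct$percent, pct$d, length))
  )
  if (any(summ$n < min_n)) {
    warning("some distances have fewer than ", min_n, " replicates")
  }
  structure(list(summary = summ, replicates = pct,
                 construct = dataset$construct[1]),
            class = "GlycProfile")
}

#' @export
print.GlycProfile <- function(x, ...) {
  cat("GlycProfile <", x$construct, ">\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Fit a four-parameter logistic to a glycosylation profile
#'
#' Least-squares fit of
#' G(d) = g_min + (g_max - g_min) / (1 + exp(-(d - d50)/slope))
#' on the logit scale: since logit(percent) = log(glyc/nonglyc), the
#' multiplicative (lognormal) band noise of densitometry is additive
#' Gaussian there, so least squares on logit-transformed values is the
#' maximum-likelihood fit under the gel noise model. Replicate-level values
#' are used when available, per-distance means otherwise. Optimization is
#' bounded quasi-Newton (L-BFGS-B) from several data-driven starts;
#' non-convergence or a non-identifiable (flat) profile is flagged rather
#' than raised.
#'
#' When the assayed distances do not reach down to the lower plateau, the
#' background level g_min is unidentified and the midpoint estimate drifts
#' with it. The fitter therefore bounds g_min by `max_background`
#' (default 15 percent): in this assay an acceptor site out of reach of the
#' glycosylation machinery shows only a small residual background, so the
#' floor is constrained a priori rather than extrapolated from noise. Set
#' `max_background = 100` to disable the assumption.
#'
#' @param profile a `GlycProfile`, or a data.frame with columns d and mean
#' @param min_range minimal spread (percentage points) below which the
#'   transition is declared non-identifiable
#' @param max_background upper bound on the fitted g_min (percent)
#' @return List of class `SigmoidFit`: d50, slope, g_min, g_max, rss (on
#'   the logit scale), converged, reason.
#' @export
fit_sigmoid <- function(profile, min_range = 10, max_background = 15) {
  if (inherits(profile, "GlycProfile")) {
    d <- profile$replicates$d
    y <- profile$replicates$percent
    n_d <- length(unique(profile$summary$d))
  } else {
    d <- profile$d
    y <- profile$mean
    n_d <- length(unique(d))
  }
  if (n_d < 4) {
    stop("input error: need >= 4 distinct d values to fit a sigmoid")
  }
  bad_fit <- function(reason) {
    structure(list(d50 = NA_real_, slope = NA_real_, g_min = NA_real_,
                   g_max = NA_real_, rss = NA_real_, converged = FALSE,
                   reason = reason),
              class = "SigmoidFit")
  }
  if (diff(range(y)) < min_range) {
    return(bad_fit("non-identifiable: flat profile"))
  }
  # logit scale; clamp away from the boundaries where logit diverges
  yc <- pmin(pmax(y, 0.05), 99.95)
  ylog <- log(yc / (100 - yc))
  obj <- function(p) {
    g <- glyc_law(d, p[1], p[2], p[3], p[4])
    sum((ylog - log(g / (100 - g)))^2)
  }
  lower <- c(min(d) - 10, 0.05, 0.01, 1)
  upper <- c(max(d) + 10, 20, max_background, 99.99)
  half <- mean(range(ylog))
  d_half <- d[which.min(abs(ylog - half))]
  g0 <- min(max(min(y) / 2, 0.5), max_background)
  starts <- list(
    c(d_half, 1, g0, min((max(y) + 100) / 2, 99.9)),
    c(d_half, 1, min(1, max_background), 99),
    c(mean(range(d)), 2, g0, min(max(y), 99.9))
  )
  best <- NULL
  for (s0 in starts) {
    fit <- try(stats::optim(s0, obj, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(maxit = 500)), silent = TRUE)
    if (!inherits(fit, "try-error") &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) return(bad_fit("optimizer failure"))
  # polish: restart from the optimum if the line search stopped early
  for (k in 1:2) {
    if (best$convergence == 0) break
    again <- try(stats::optim(best$par, obj, method = "L-BFGS-B",
                              lower = lower, upper = upper,
                              control = list(maxit = 500)), silent = TRUE)
    if (inherits(again, "try-error")) break
    if (again$value <= best$value) best <- again
  }
  p <- best$par
  if (p[3] >= p[4]) return(bad_fit("degenerate asymptotes"))
  structure(list(d50 = unname(p[1]), slope = unname(p[2]),
                 g_min = unname(p[3]), g_max = unname(p[4]),
                 rss = best$value, converged = best$convergence == 0,
                 reason = if (best$convergence == 0) "ok" else "no convergence"),
            class = "SigmoidFit")
}

#' @export
print.SigmoidFit <- function(x, ...) {
  if (!x$converged) {
    cat("SigmoidFit: NOT converged (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf(
      "SigmoidFit: d50 = %.2f res, slope = %.2f, G in [%.1f, %.1f]%%, rss = %.3g\n",
      x$d50, x$slope, x$g_min, x$g_max, x$rss))
  }
  invisible(x)
}

#' Predict percent glycosylation from a fit
#' @param object a `SigmoidFit`
#' @param d distances (residues)
#' @param ... ignored
#' @export
predict.SigmoidFit <- function(object, d, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit")
  glyc_law(d, object$d50, object$slope, object$g_min, object$g_max)
}

#' Critical-distance statistic
#'
#' The percentage-point gap G(d_full) - G(d_crit) between the distance long
#' enough for full glycosylation in every construct (default 73) and the
#' critical distance that maximally separates compact from extended chains
#' (default 67). Compact (helical) chains show a large positive gap;
#' extended chains sit near the upper asymptote at both distances and show a
#' gap near zero.
#'
#' @param profile a `GlycProfile`, or NULL if `fit` is given
#' @param d_crit,d_full the two probe distances (residues)
#' @param fit optional `SigmoidFit` used to interpolate missing distances
#' @return Gap in percentage points.
#' @export
critical_stat <- function(profile = NULL, d_crit = 67, d_full = 73,
                          fit = NULL) {
  value_at <- function(d) {
    if (!is.null(profile)) {
      s <- profile$summary
      hit <- which(s$d == d)
      if (length(hit)) return(s$mean[hit[1]])
    }
    if (!is.null(fit) && fit$converged) return(predict(fit, d))
    stop("input error: d = ", d, " absent from profile and no usable fit")
  }
  value_at(d_full) - value_at(d_crit)
}

#' Residues folded from a d50 shift
#'
#' A shift of the glycosylation midpoint by delta_d50 residues (relative to
#' an extended reference) is absorbed by converting n residues from extended
#' rise (~3.4 Angstrom/res) to helical rise (~1.5 Angstrom/res):
#' n = rise_ext * delta_d50 / (rise_ext - rise_helix).
#'
#' @param delta_d50 midpoint shift, residues; negative values are flagged
#'   and reported as 0
#' @param rise_ext,rise_helix axial rise per residue, Angstrom
#' @return Estimated number of folded residues.
#' @export
infer_folded <- function(delta_d50, rise_ext = 3.4, rise_helix = 1.5) {
  stopifnot(rise_ext > rise_helix, rise_helix > 0)
  if (delta_d50 < 0) {
    warning("negative d50 shift: compaction cannot be negative, reporting 0")
    return(0)
  }
  rise_ext * delta_d50 / (rise_ext - rise_helix)
}

#' Residues needed to span a membrane core as a helix
#'
#' thickness / rise: with the canonical helical rise of 1.5 Angstrom per
#' residue, spanning the ~30 Angstrom hydrocarbon core of a typical bilayer
#' takes ~20 consecutive residues.
#'
#' @param thickness core thickness, Angstrom
#' @param rise axial rise per residue, Angstrom
#' @return List with `raw` (thickness/rise) and `residues` (ceiling).
#' @export
helix_span_residues <- function(thickness = 30, rise = 1.5) {
  stopifnot(thickness >= 0, rise > 0)
  raw <- thickness / rise
  list(raw = raw, residues = ceiling(raw))
}

#' Compare replicate glycosylation between two conditions
#'
#' Welch (unequal-variance) two-sample t-test on replicate percent-
#' glycosylation values, with significance stars at 0.01 and 0.001.
#'
#' @param a,b numeric vectors of replicate percent values (>= 3 each), or
#'   `GlycProfile`s with `at` giving the distance to compare
#' @param at distance at which to pull replicates from profiles
#' @return List: statistic, p_value, stars, estimate (mean difference a - b).
#' @export
compare_conditions <- function(a, b, at = NULL) {
  pull <- function(x) {
    if (inherits(x, "GlycProfile")) {
      if (is.null(at)) stop("input error: `at` is required with profiles")
      x$replicates$percent[x$replicates$d == at]
    } else as.numeric(x)
  }
  va <- pull(a); vb <- pull(b)
  if (length(va) < 3 || length(vb) < 3) {
    stop("input error: need >= 3 replicates per condition")
  }
  if (isTRUE(all.equal(va, vb)) && stats::var(va) == 0) {
    return(list(statistic = 0, p_value = 1, stars = "",
                estimate = mean(va) - mean(vb)))
  }
  tt <- stats::t.test(va, vb, var.equal = FALSE)
  stars <- if (tt$p.value < 0.001) "***" else if (tt$p.value < 0.01) "**" else ""
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       stars = stars, estimate = mean(va) - mean(vb))
}

#' Apparent mass of a glycosylated chain on a gel
#'
#' Each attached N-glycan adds ~2.5 kDa of apparent molecular mass; double
#' glycosylation therefore shifts the band by ~5 kDa.
#'
#' @param base_mass unmodified apparent mass (kDa)
#' @param n_glycans 0, 1 or 2 attached glycans
#' @param per_glycan apparent shift per glycan (kDa)
#' @return Apparent mass in kDa.
#' @export
gel_mass_model <- function(base_mass, n_glycans, per_glycan = 2.5) {
  stopifnot(n_glycans %in% 0:2)
  base_mass + n_glycans * per_glycan
}

#' Compaction call from a fitted glycosylation profile
#'
#' Compares the fitted midpoint with the extended-chain reference
#' (d50 ~ 64 residues) and the critical-distance gap, and classifies the
#' nascent chain as compact, extended or intermediate:
#' compact if the midpoint shift >= `compact_shift` residues or the gap >=
#' `compact_gap` points; extended if shift <= `extended_shift` and gap <=
#' `extended_gap`; intermediate otherwise. Also reports the implied number
#' of folded residues.
#'
#' @param fit a `SigmoidFit`
#' @param profile optional `GlycProfile` for the gap statistic (fit-based
#'   interpolation is used otherwise)
#' @param reference_d50 extended-chain reference midpoint (residues)
#' @param d_crit,d_full see \code{\link{critical_stat}}
#' @param compact_shift,compact_gap,extended_shift,extended_gap thresholds
#' @return List of class `CompactionCall`: state, delta_d50, gap, n_folded.
#' @export
call_compaction <- function(fit, profile = NULL, reference_d50 = 64,
                            d_crit = 67, d_full = 73,
                            compact_shift = 3, compact_gap = 25,
                            extended_shift = 1, extended_gap = 10) {
  if (!inherits(fit, "SigmoidFit") || !fit$converged) {
    stop("input error: a converged SigmoidFit is required")
  }
  delta <- fit$d50 - reference_d50
  gap <- critical_stat(profile, d_crit, d_full, fit = fit)
  state <- if (delta >= compact_shift || gap >= compact_gap) "compact"
           else if (delta <= extended_shift && gap <= extended_gap) "extended"
           else "intermediate"
  n_folded <- if (delta > 0) infer_folded(delta) else 0
  structure(list(state = state, delta_d50 = delta, gap = gap,
                 n_folded = n_folded, d50 = fit$d50,
                 reference_d50 = reference_d50),
            class = "CompactionCall")
}

#' @export
print.CompactionCall <- function(x, ...) {
  cat(sprintf(
    "CompactionCall: %s (d50 %.2f vs ref %.1f => shift %.2f res; gap %.1f pts; ~%.1f residues folded)\n",
    x$state, x$d50, x$reference_d50, x$delta_d50, x$gap, x$n_folded))
  invisible(x)
}
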