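# Sequence-level determinants of in-tunnel folding: hydrophobic runs,
# breaker/charge penalties, and a labeled folding-propensity heuristic.

#' Windowed hydropathy profile
#'
#' Kyte-Doolittle values per position plus sliding-window means (defined only
#' for full windows, reported at the window centre).
#'
#' @param seq `PeptideSequence` or residue string
#' @param window odd window length (default 19)
#' @return List of class `HydrophobicityProfile`: `values`, `windowed`
#'   (data.frame centre, mean), `window`.
#' @export
hydropathy_profile <- function(seq, window = 19) {
  if (is.character(seq)) seq <- peptide_sequence(seq)
  v <- kd_values(seq$residues)
  n <- length(v)
  win <- NULL
  if (n >= window) {
    centres <- seq.int((window + 1) %/% 2, n - window %/% 2)
    means <- vapply(centres, function(c0) {
      mean(v[(c0 - window %/% 2):(c0 + window %/% 2)])
    }, numeric(1))
    win <- data.frame(centre = centres, mean = means)
  }
  structure(list(values = v, windowed = win, window = window),
            class = "HydrophobicityProfile")
}

#' Maximal hydrophobic runs in a sequence
#'
#' @param seq `PeptideSequence` or residue string
#' @param hydrophobic_set one-letter codes treated as hydrophobic
#' @return data.frame (start, end, length) of maximal contiguous hydrophobic
#'   runs, N to C order; zero rows if none.
#' @export
hydrophobic_runs <- function(seq, hydrophobic_set = NULL) {
  mask <- hydrophobic_mask(seq, hydrophobic_set)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

#' Scoring parameters for the folding-propensity heuristic
#'
#' @param w_P,w_G,w_q penalties per Pro, Gly and charged (D/E/K/R) residue in
#'   the segment core
#' @param w_h weight of the hydropathy term (summed Kyte-Doolittle over the
#'   core, scaled by `l_ref`)
#' @param l_ref reference length scaling the hydropathy sum
#' @param l_min minimal contiguous hydrophobic run for the folds-in-tunnel
#'   class
#' @param score_min minimal score for the folds-in-tunnel class
#' @param hydrophobic_set residues treated as hydrophobic
#' @return List of class `PropensityParams`.
#' @export
propensity_params <- function(w_P = 3, w_G = 1.15, w_q = 1.0, w_h = 1.0,
                              l_ref = 22, l_min = 14, score_min = 16,
                              hydrophobic_set = default_hydrophobic_set()) {
  structure(list(w_P = w_P, w_G = w_G, w_q = w_q, w_h = w_h, l_ref = l_ref,
                 l_min = l_min, score_min = score_min,
                 hydrophobic_set = hydrophobic_set),
            class = "PropensityParams")
}

# Segment core: the full hydrophobic span, from the first to the last
# hydrophobic residue. Polar flanks outside the span never enter the score,
# and extending a run can only add hydrophobic residues to the core.
.segment_core <- function(runs) {
  c(min(runs$start), max(runs$end))
}

#' Folding-propensity score and class for a sequence segment
#'
#' An explicitly heuristic score whose only contract is to reproduce the
#' qualitative behaviour seen in the tunnel assay: long uninterrupted
#' hydrophobic runs fold, half-length runs do not, and helix breakers hurt
#' more than charges, which hurt more than mere hydrophobicity loss.
#'
#' score = L_run - w_P * #Pro - w_G * #Gly - w_q * #charged
#'         + w_h * sum(KD over core) / l_ref
#'
#' where L_run is the longest contiguous hydrophobic run and the core is the
#' full hydrophobic span (first to last hydrophobic residue). The class
#' is `folds-in-tunnel` iff L_run >= l_min and score >= score_min,
#' `borderline` for very short sequences, `extended` otherwise.
#'
#' @param seq `PeptideSequence` or residue string
#' @param params a `PropensityParams`
#' @return List of class `SegmentCall`: span, run_length, breaker and charge
#'   counts, score, class. The output is labeled `heuristic`.
#' @export
propensity_score <- function(seq, params = propensity_params()) {
  if (is.character(seq)) seq <- peptide_sequence(seq)
  res <- seq$residues
  n <- length(res)
  if (n < 8L) {
    warning("sequence too short for a meaningful propensity call")
    return(structure(list(span = c(NA, NA), run_length = 0, n_pro = NA,
                          n_gly = NA, n_charged = NA, score = NA_real_,
                          class = "borderline", kind = "heuristic"),
                     class = "SegmentCall"))
  }
  runs <- hydrophobic_runs(seq, params$hydrophobic_set)
  if (!nrow(runs)) {
    return(structure(list(span = c(NA, NA), run_length = 0, n_pro = 0,
                          n_gly = 0, n_charged = 0, score = 0,
                          class = "extended", kind = "heuristic"),
                     class = "SegmentCall"))
  }
  core <- .segment_core(runs)
  core_res <- res[core[1]:core[2]]
  l_run <- max(runs$length)
  n_pro <- sum(core_res == "P")
  n_gly <- sum(core_res == "G")
  n_charged <- sum(core_res %in% c("D", "E", "K", "R"))
  score <- l_run - params$w_P * n_pro - params$w_G * n_gly -
    params$w_q * n_charged +
    params$w_h * sum(kd_values(core_res)) / params$l_ref
  cls <- if (l_run >= params$l_min && score >= params$score_min)
    "folds-in-tunnel" else "extended"
  structure(list(span = core, run_length = l_run, n_pro = n_pro,
                 n_gly = n_gly, n_charged = n_charged, score = score,
                 class = cls, kind = "heuristic"),
            class = "SegmentCall")
}

#' @export
print.SegmentCall <- function(x, ...) {
  cat(sprintf(
    "SegmentCall (heuristic): %s | run %d res, core %s-%s, score %.2f (P:%s G:%s q:%s)\n",
    x$class, x$run_length, x$span[1], x$span[2], x$score,
    x$n_pro, x$n_gly, x$n_charged))
  invisible(x)
}

#' Rank central-pair mutants of a transmembrane segment by score
#'
#' Builds the central-pair replacement series of a base segment (wild type
#' plus the given replacements), scores each with
#' \code{\link{propensity_score}}, and ranks by decreasing score. Ties (score
#' difference below `tie_tol`) are reported and broken alphabetically.
#'
#' @param base a `PeptideSequence` (the wild-type segment)
#' @param replacements residues substituted for the central pair
#' @param params a `PropensityParams`
#' @param tie_tol score difference treated as a tie
#' @return data.frame (label, replacement, score, rank, near_wt) ordered by
#'   rank; the wild type carries label `"WT"`.
#' @export
rank_mutants <- function(base, replacements = c("L", "A", "K", "D", "G", "P"),
                         params = propensity_params(), tie_tol = 0.1) {
  stopifnot(inherits(base, "PeptideSequence"))
  bad <- setdiff(replacements, c("L", "A", "K", "D", "G", "P"))
  if (length(bad)) {
    stop("input error: replacements must be from {L, A, K, D, G, P}")
  }
  labels <- c("WT", paste0(replacements, replacements))
  seqs <- c(list(base),
            lapply(replacements, function(r)
              make_test_sequences("mutant_pair", base = base, replacement = r)))
  scores <- vapply(seqs, function(s) propensity_score(s, params)$score,
                   numeric(1))
  out <- data.frame(label = labels,
                    replacement = c("(wild type)", replacements),
                    score = scores, stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$label), ]
  out$rank <- rank(-out$score, ties.method = "min")
  wt_score <- scores[1]
  out$near_wt <- abs(out$score - wt_score) < tie_tol
  rownames(out) <- NULL
  out
}
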