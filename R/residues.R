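# Residue-level reference data and sequence containers.

#' Amino-acid reference table
#'
#' Per-residue constants used throughout the package: one-letter code,
#' three-letter code, monoisotopic-ish residue mass (Da), Kyte-Doolittle
#' hydropathy, the radius (Angstrom) of the single pseudo-atom that stands in
#' for the whole side chain, and membership in the default hydrophobic set.
#'
#' The side-chain pseudo-atom radii are volume-calibrated: each radius is the
#' radius of a sphere of roughly the side-chain van der Waals volume, so that
#' a one-sphere side chain occupies about the right amount of space in
#' surface-area calculations. Glycine carries the smallest radius.
#'
#' @return A data.frame with one row per canonical amino acid.
#' @export
residue_table <- function() {
  df <- data.frame(
    code = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
             "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
    name3 = c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
              "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
              "TYR", "VAL"),
    mass = c(71.08, 156.19, 114.10, 115.09, 103.14, 128.13, 129.12, 57.05,
             137.14, 113.16, 113.16, 128.17, 131.19, 147.18, 97.12, 87.08,
             101.10, 186.21, 163.18, 99.13),
    kd = c(1.8, -4.5, -3.5, -3.5, 2.5, -3.5, -3.5, -0.4, -3.2, 4.5,
           3.8, -3.9, 1.9, 2.8, -1.6, -0.8, -0.7, -0.9, -1.3, 4.2),
    sidechain_radius = c(1.50, 2.20, 1.85, 1.80, 1.70, 2.00, 1.95, 1.00,
                         2.05, 2.00, 2.00, 2.10, 2.05, 2.20, 1.80, 1.60,
                         1.75, 2.40, 2.25, 1.90),
    stringsAsFactors = FALSE
  )
  df$hydrophobic <- df$code %in% default_hydrophobic_set()
  df
}

#' Default hydrophobic residue set
#'
#' The Kyte-Doolittle-positive residues \{A, C, F, I, L, M, V, W\}. Every
#' function that classifies residues as hydrophobic accepts an alternative
#' set, since the classification is a modelling choice rather than a fact.
#'
#' @return Character vector of one-letter codes.
#' @export
default_hydrophobic_set <- function() c("A", "C", "F", "I", "L", "M", "V", "W")

#' Kyte-Doolittle hydropathy values for a sequence
#' @param residues character vector of one-letter codes
#' @keywords internal
kd_values <- function(residues) {
  tab <- residue_table()
  idx <- match(residues, tab$code)
  if (anyNA(idx)) {
    stop("unknown residue code(s): ",
         paste(unique(residues[is.na(idx)]), collapse = ", "))
  }
  tab$kd[idx]
}

#' Construct a peptide sequence object
#'
#' A `PeptideSequence` bundles an identifier, the residue string and the
#' 1-based inclusive span of the segment that is alpha-helical in the mature
#' fold (the segment whose conformational state the tunnel assay probes).
#'
#' @param sequence single string of one-letter residue codes (case
#'   insensitive)
#' @param id identifier string
#' @param helical_region integer vector `c(start, end)`, 1-based inclusive;
#'   defaults to the whole sequence
#' @param hydrophobic_set one-letter codes treated as hydrophobic
#' @return An object of class `PeptideSequence`.
#' @examples
#' peptide_sequence("LLLLLLLLLLLLLLLLLLLLLL", id = "polyLeu")
#' @export
peptide_sequence <- function(sequence, id = "peptide",
                             helical_region = NULL,
                             hydrophobic_set = default_hydrophobic_set()) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) >= 1L)
  residues <- strsplit(toupper(sequence), "")[[1]]
  tab <- residue_table()
  bad <- setdiff(unique(residues), tab$code)
  if (length(bad)) {
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  }
  n <- length(residues)
  if (is.null(helical_region)) helical_region <- c(1L, n)
  helical_region <- as.integer(helical_region)
  if (length(helical_region) != 2L ||
      helical_region[1] < 1L || helical_region[2] > n ||
      helical_region[1] > helical_region[2]) {
    stop("helical_region must be c(start, end) with 1 <= start <= end <= length")
  }
  structure(
    list(id = id, residues = residues, helical_region = helical_region,
         hydrophobic_set = hydrophobic_set),
    class = "PeptideSequence"
  )
}

#' @export
print.PeptideSequence <- function(x, ...) {
  cat("PeptideSequence <", x$id, ">: ", paste(x$residues, collapse = ""),
      "\n  length ", length(x$residues),
      ", helical region ", x$helical_region[1], "-", x$helical_region[2],
      "\n", sep = "")
  invisible(x)
}

#' @export
length.PeptideSequence <- function(x) length(x$residues)

#' Hydrophobicity mask for a sequence
#'
#' @param seq a `PeptideSequence` or a plain residue string
#' @param hydrophobic_set one-letter codes treated as hydrophobic; defaults to
#'   the set stored in the sequence (or the package default)
#' @return Logical vector, one entry per residue, `TRUE` where the residue is
#'   in the hydrophobic set.
#' @export
hydrophobic_mask <- function(seq, hydrophobic_set = NULL) {
  if (is.character(seq)) seq <- peptide_sequence(seq)
  if (is.null(hydrophobic_set)) hydrophobic_set <- seq$hydrophobic_set
  seq$residues %in% hydrophobic_set
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over \code{Biostrings::readAAStringSet}; each record becomes a
#' `PeptideSequence` whose helical region defaults to the full length.
#'
#' @param path FASTA file path
#' @return A list of `PeptideSequence` objects, named by record id.
#' @export
read_fasta_peptides <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  out <- lapply(seq_along(set), function(i) {
    peptide_sequence(as.character(set[[i]]), id = names(set)[i])
  })
  names(out) <- names(set)
  out
}
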