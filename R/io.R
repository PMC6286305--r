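# Structure and table I/O.

.pdb_element <- function(role) {
  ifelse(role == "N", "N",
         ifelse(role == "O", "O", "C"))
}

.pdb_resname <- function(code) {
  tab <- residue_table()
  out <- tab$name3[match(code, tab$code)]
  out[is.na(out)] <- "UNK"
  out
}

format_atom_record <- function(serial, name, resname, chain, resseq,
                               x, y, z, occ, b, element) {
  name_fmt <- ifelse(nchar(name) < 4, sprintf(" %-3s", name),
                     sprintf("%-4s", name))
  sprintf("ATOM  %5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name_fmt, resname, chain, resseq, x, y, z, occ, b, element)
}

frame_to_records <- function(fr) {
  ss <- as_sphere_set(fr)
  n <- nrow(ss)
  resseq <- ifelse(is.na(ss$residue), seq_len(n), ss$residue)
  code <- if (!is.null(ss$code)) ss$code else rep(NA_character_, n)
  resname <- ifelse(ss$owner == "context", "TUN", .pdb_resname(code))
  name <- ifelse(ss$role == "X", "C", ss$role)
  element <- ifelse(ss$owner == "context", "C", .pdb_element(ss$role))
  vapply(seq_len(n), function(i) {
    format_atom_record(i, name[i], resname[i], "A", resseq[i],
                       ss$x[i], ss$y[i], ss$z[i], 1.00, ss$radius[i],
                       element[i])
  }, character(1))
}

#' Write structures as PDB ATOM records
#'
#' Standard fixed-column ATOM records, chain A; side-chain pseudo-atoms are
#' written as atom name CB and tunnel wall atoms as residue TUN. The sphere
#' radius is stored in the B-factor column so that files round-trip without
#' an external radius table. Multiple frames are written as MODEL/ENDMDL
#' blocks.
#'
#' @param frames a `Conformer`/`SphereSet`/`TunnelModel`, or a list of them
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_structure <- function(frames, path) {
  if (!is.list(frames) || inherits(frames, c("Conformer", "SphereSet",
                                             "TunnelModel", "data.frame"))) {
    frames <- list(frames)
  }
  lines <- character(0)
  multi <- length(frames) > 1L
  for (k in seq_along(frames)) {
    rec <- frame_to_records(frames[[k]])
    if (multi) {
      lines <- c(lines, sprintf("MODEL     %4d", k), rec, "ENDMDL")
    } else {
      lines <- c(lines, rec)
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read PDB ATOM records into sphere-set frames
#'
#' Parses fixed-column ATOM/HETATM records; MODEL/ENDMDL blocks delimit
#' frames. Radii are taken from the B-factor column when positive (the
#' package's own convention), otherwise assigned from a small per-element
#' table, with a warning and a default of 1.7 Angstrom for unknown elements.
#'
#' @param path PDB file
#' @return A list of `SphereSet` frames (length 1 for single-model files).
#' @export
read_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("format error: empty file ", path)
  model_starts <- grep("^MODEL", lines)
  blocks <- if (length(model_starts)) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(model_starts)) {
      stop("format error: unbalanced MODEL/ENDMDL in ", path)
    }
    Map(function(s, e) seq.int(s + 1L, e - 1L), model_starts, ends)
  } else list(seq_along(lines))
  elem_radius <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)
  parse_block <- function(idx) {
    sel <- idx[grepl("^(ATOM  |HETATM)", lines[idx])]
    if (!length(sel)) stop("format error: no ATOM records in ", path)
    txt <- lines[sel]
    num <- function(from, to, what) {
      v <- suppressWarnings(as.numeric(substr(txt, from, to)))
      if (anyNA(v)) {
        stop("format error: unparseable ", what, " at line ",
             sel[which(is.na(v))[1]], " of ", path)
      }
      v
    }
    x <- num(31, 38, "x"); y <- num(39, 46, "y"); z <- num(47, 54, "z")
    b <- suppressWarnings(as.numeric(substr(txt, 61, 66)))
    name <- trimws(substr(txt, 13, 16))
    resname <- trimws(substr(txt, 18, 20))
    resseq <- suppressWarnings(as.integer(substr(txt, 23, 26)))
    element <- trimws(substr(txt, 77, 78))
    element[element == ""] <- toupper(substr(name[element == ""], 1, 1))
    radius <- ifelse(!is.na(b) & b > 0, b, elem_radius[element])
    if (anyNA(radius)) {
      warning("unknown element(s) in ", path, "; using default radius 1.7 A")
      radius[is.na(radius)] <- 1.7
    }
    owner <- ifelse(resname == "TUN", "context", "peptide")
    ss <- sphere_set(cbind(x, y, z), radius, owner = owner,
                     residue = resseq, role = name)
    tab <- residue_table()
    ss$code <- tab$code[match(resname, tab$name3)]
    ss$hydrophobic <- !is.na(ss$code) &
      ss$code %in% default_hydrophobic_set()
    ss
  }
  lapply(blocks, parse_block)
}

#' Write a gel dataset as tidy CSV
#' @param dataset a `GelDataset`
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_gel_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

#' Read a tidy gel CSV (columns construct, d, replicate, band, intensity)
#' @param path CSV file
#' @return A `GelDataset`.
#' @export
read_gel_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("construct", "d", "replicate", "band", "intensity")
  if (!all(need %in% names(df))) {
    stop("format error: gel CSV must have columns ",
         paste(need, collapse = ", "))
  }
  class(df) <- c("GelDataset", "data.frame")
  df
}

#' Read a JSON run configuration
#' @param path JSON file
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config error: no such file ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
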