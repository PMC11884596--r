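#' Protein record
#'
#' Container for a single-chain protein: sequence, per-residue C-alpha
#' coordinates, optional sidechain geometric centres and a per-residue
#' confidence score (pLDDT for predicted models; for experimental
#' structures the B-factor column is carried in the same slot).
#'
#' @param accession Character identifier (e.g. a UniProt accession).
#' @param sequence Amino-acid string over the 20-letter alphabet plus `X`.
#' @param ca_coords Numeric L x 3 matrix of C-alpha coordinates (Angstrom).
#' @param plddt Numeric vector of length L with values in `[0, 100]`.
#' @param sidechain_centers Numeric L x 3 matrix of sidechain geometric
#'   centres, with `NA` rows where a residue has no sidechain heavy atoms
#'   (glycine, or missing atoms).
#'
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(accession, sequence, ca_coords, plddt,
                           sidechain_centers = NULL) {
  sequence <- toupper(as.character(sequence))
  L <- nchar(sequence)
  ca_coords <- as.matrix(ca_coords)
  if (nrow(ca_coords) != L || ncol(ca_coords) != 3) {
    stop_pf("sequence length (%d) does not match coordinate rows (%d)",
            "phosfusion_invalid_record", L, nrow(ca_coords))
  }
  plddt <- as.numeric(plddt)
  if (length(plddt) != L) {
    stop_pf("pLDDT length (%d) does not match sequence length (%d)",
            "phosfusion_invalid_record", length(plddt), L)
  }
  if (any(plddt < 0 | plddt > 100, na.rm = TRUE)) {
    stop_pf("pLDDT values must lie in [0, 100]", "phosfusion_invalid_record")
  }
  if (is.null(sidechain_centers)) {
    sidechain_centers <- matrix(NA_real_, L, 3)
  }
  sidechain_centers <- as.matrix(sidechain_centers)
  if (L > 1) {
    step <- sqrt(rowSums((ca_coords[-1, , drop = FALSE] -
                            ca_coords[-L, , drop = FALSE])^2))
    if (any(step <= 0)) {
      stop_pf("consecutive C-alpha atoms must have positive separation",
              "phosfusion_invalid_record")
    }
  }
  structure(list(accession = as.character(accession), sequence = sequence,
                 ca_coords = unname(ca_coords), plddt = unname(plddt),
                 sidechain_centers = unname(sidechain_centers)),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s: %d residues, mean pLDDT %.1f\n",
              x$accession, nchar(x$sequence), mean(x$plddt)))
  invisible(x)
}

#' @export
length.protein_record <- function(x) nchar(x$sequence)

#' Read a protein structure (PDB or mmCIF)
#'
#' Reads the first polymer chain of a PDB or mmCIF file into a
#' [protein_record()]. The per-residue confidence is taken from the
#' B-factor column of the C-alpha atom, following the AlphaFold model
#' convention of storing pLDDT there; for experimental structures the
#' B-factor is used as a stand-in and should be interpreted accordingly.
#' Sidechain centres are geometric means of sidechain heavy atoms;
#' residues without any (glycine) get an `NA` centre. Non-standard
#' residues are mapped to `X`.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param accession Identifier to store; defaults to the file base name.
#' @return A [protein_record()].
#' @export
read_structure <- function(path, accession = NULL) {
  if (!file.exists(path)) {
    stop_pf("structure file not found: %s", "phosfusion_parse_error", path)
  }
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path) else
      bio3d::read.pdb(path),
    error = function(e) {
      stop_pf("could not parse structure %s: %s", "phosfusion_parse_error",
              path, conditionMessage(e))
    })
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  chains <- unique(atoms$chain)
  if (length(chains) > 1) {
    warning(sprintf("%s has %d chains; using the first (%s)",
                    basename(path), length(chains), chains[[1]]))
  }
  atoms <- atoms[atoms$chain == chains[[1]], , drop = FALSE]
  # drop hydrogens and alternate locations beyond the first
  atoms <- atoms[!grepl("^[0-9]*[HD]", atoms$elety), , drop = FALSE]
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  if (nrow(ca) == 0) {
    stop_pf("no C-alpha atoms in first chain of %s",
            "phosfusion_empty_structure", path)
  }
  ca <- ca[order(ca$resno), , drop = FALSE]
  seq3 <- ca$resid
  seq1 <- suppressWarnings(bio3d::aa321(seq3))
  seq1[is.na(seq1) | !(seq1 %in% AA_ALPHABET)] <- "X"
  backbone <- c("N", "CA", "C", "O", "OXT")
  sc <- matrix(NA_real_, nrow(ca), 3)
  side <- atoms[!(atoms$elety %in% backbone), , drop = FALSE]
  if (nrow(side) > 0) {
    idx <- match(side$resno, ca$resno)
    keep <- !is.na(idx)
    side <- side[keep, , drop = FALSE]
    idx <- idx[keep]
    for (j in 1:3) {
      col <- c("x", "y", "z")[j]
      s <- rowsum(side[[col]], idx)
      n <- rowsum(rep(1, length(idx)), idx)
      sc[as.integer(rownames(s)), j] <- s / n
    }
  }
  protein_record(accession %||% sub("\\.(pdb|cif|mmcif)$", "",
                                    basename(path), ignore.case = TRUE),
                 paste(seq1, collapse = ""),
                 as.matrix(ca[, c("x", "y", "z")]),
                 ca$b, sc)
}

#' Read a FASTA file of protein sequences
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names are the first
#'   whitespace-separated token of each header).
#' @export
read_fasta <- function(path) {
  fa <- bio3d::read.fasta(path, rm.dup = FALSE)
  seqs <- apply(fa$ali, 1, function(r) paste(r[r != "-"], collapse = ""))
  names(seqs) <- vapply(strsplit(fa$id, "\\s+"), `[[`, "", 1L)
  toupper(seqs)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    writeLines(gsub("(.{60})", "\\1\n", seqs[[i]]), con)
  }
  invisible(path)
}

#' Read a phosphorylation-site table
#'
#' Reads a UTF-8 TSV with header columns `accession`, `position`,
#' `residue`, `annotations` (additional columns are preserved).
#' Positions are 1-based; annotation strings are kept as a single
#' delimiter-joined field and can be split with [split_annotations()].
#'
#' @param path Path to the TSV file.
#' @param ann_delim Delimiter between annotation strings within the
#'   `annotations` field (default `";"`).
#' @return A data frame with one row per site.
#' @export
read_site_table <- function(path, ann_delim = ";") {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  need <- c("accession", "position", "residue")
  if (!all(need %in% names(df))) {
    stop_pf("site table must have columns accession, position, residue",
            "phosfusion_parse_error")
  }
  if (!"annotations" %in% names(df)) df$annotations <- ""
  pos <- suppressWarnings(as.integer(df$position))
  bad <- which(is.na(pos) | pos < 1)
  if (length(bad) > 0) {
    stop_pf("malformed position at line %d: %s (positions are 1-based)",
            "phosfusion_parse_error", bad[[1]] + 1L, df$position[bad[[1]]])
  }
  df$position <- pos
  df$residue <- toupper(df$residue)
  attr(df, "ann_delim") <- ann_delim
  df
}

#' Split the annotations field of a site table into string sets
#'
#' @param sites Data frame from [read_site_table()].
#' @param ann_delim Annotation delimiter.
#' @return List of character vectors, one per site.
#' @export
split_annotations <- function(sites, ann_delim = NULL) {
  d <- ann_delim %||% attr(sites, "ann_delim") %||% ";"
  lapply(strsplit(as.character(sites$annotations), d, fixed = TRUE),
         function(x) trimws(x[nzchar(trimws(x))]))
}

#' Check that sites are consistent with their protein sequences
#'
#' A site is consistent when its position is within the sequence bounds
#' and the stated residue letter matches the sequence at that position.
#'
#' @param sites Site data frame.
#' @param proteins Named list of [protein_record()] (or named character
#'   vector of sequences), keyed by accession.
#' @return Logical vector, `TRUE` where the site is consistent.
#' @export
validate_sites <- function(sites, proteins) {
  seqs <- if (is.character(proteins)) proteins else
    vapply(proteins, function(p) p$sequence, "")
  vapply(seq_len(nrow(sites)), function(i) {
    s <- seqs[[sites$accession[i]]]
    if (is.null(s) || is.na(s)) return(FALSE)
    p <- sites$position[i]
    p >= 1 && p <= nchar(s) && substr(s, p, p) == sites$residue[i]
  }, logical(1))
}

#' Classify scores into predicted classes
#'
#' Scores strictly greater than the threshold are the positive class;
#' a score exactly at the threshold maps to the negative class.
#'
#' @param score Numeric scores in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5).
#' @return Integer vector of 0/1 classes.
#' @export
classify_scores <- function(score, threshold = 0.5) {
  if (any(score < 0 | score > 1, na.rm = TRUE)) {
    stop_pf("scores must lie in [0, 1]", "phosfusion_validation_error")
  }
  as.integer(score > threshold)
}

#' Write a prediction table
#'
#' Writes a TSV with columns `accession`, `position`, `residue`,
#' `score`, `predicted_class`; scores are printed with 6 decimals and
#' the class column is recomputed from the strictly-greater-than-0.5
#' rule so the file is always internally consistent.
#'
#' @param rows Data frame with at least accession, position, residue,
#'   score columns.
#' @param path Output path.
#' @param threshold Decision threshold (default 0.5).
#' @export
write_predictions <- function(rows, path, threshold = 0.5) {
  cls <- classify_scores(rows$score, threshold)
  out <- data.frame(accession = rows$accession, position = rows$position,
                    residue = rows$residue,
                    score = sprintf("%.6f", rows$score),
                    predicted_class = cls, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a prediction table written by [write_predictions()]
#'
#' @param path Path to the TSV.
#' @return Data frame with numeric `score` and integer `predicted_class`.
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  df$score <- as.numeric(df$score)
  df$position <- as.integer(df$position)
  df$predicted_class <- as.integer(df$predicted_class)
  df
}
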