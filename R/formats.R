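# Readers/writers for the external representations the pipeline touches:
# FASTA sequences, two-column ASCII centroided peak lists, PDB structures
# with pLDDT in the B-factor column, and TSV result tables.

.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
.aa1to3 <- structure(names(.aa3to1), names = unname(.aa3to1))

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and whitespace/gap characters stripped; record
#' order is preserved. Any residue outside the 20 standard codes is a format
#' error naming the offending record.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns \code{id} (first token of the header)
#'   and \code{sequence}.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  ids <- names(recs)
  seqs <- toupper(gsub("[-[:space:]*]", "", vapply(recs, `[[`, "", 1L)))
  for (i in seq_along(seqs)) {
    bad <- setdiff(unique(strsplit(seqs[i], "")[[1]]),
                   names(.residue_avg_mass))
    if (length(bad) > 0L)
      stop("record '", ids[i], "' contains non-residue character(s): ",
           paste(bad, collapse = ", "))
    if (nchar(seqs[i]) == 0L)
      stop("record '", ids[i], "' has an empty sequence")
  }
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector (names become headers).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(paste0(">", names(sequences)[i]), con)
    writeLines(gsub("(.{60})", "\\1\n", sequences[i]), con)
  }
  invisible(path)
}

#' Read a centroided MS/MS peak list
#'
#' Parses a two-column ASCII export (m/z, absolute intensity). Columns may be
#' separated by spaces or tabs; lines whose first two fields are not numeric
#' (headers, comments) are skipped. Peaks are returned sorted by m/z;
#' duplicate m/z values are merged keeping the maximum intensity.
#'
#' @param path Path to the ASCII peak list.
#' @return A data.frame with columns \code{mz} (strictly increasing) and
#'   \code{intensity} (non-negative).
#' @export
read_centroid_spectrum <- function(path) {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  toks <- strsplit(trimws(lines), "[\t ,]+")
  rows <- vapply(toks, function(tk) {
    if (length(tk) < 2L) return(c(NA_real_, NA_real_))
    suppressWarnings(as.numeric(tk[1:2]))
  }, numeric(2))
  keep <- !is.na(rows[1, ]) & !is.na(rows[2, ])
  if (!any(keep)) stop("no numeric (m/z, intensity) rows in: ", path)
  spec <- data.frame(mz = rows[1, keep], intensity = rows[2, keep])
  if (any(spec$intensity < 0)) stop("negative intensity in: ", path)
  spec <- spec[order(spec$mz, -spec$intensity), ]
  spec <- spec[!duplicated(spec$mz), ]
  rownames(spec) <- NULL
  spec
}

#' Write a centroided peak list as two-column ASCII
#'
#' @param spectrum data.frame with \code{mz} and \code{intensity}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_centroid_spectrum <- function(spectrum, path) {
  stopifnot(all(c("mz", "intensity") %in% names(spectrum)))
  writeLines(sprintf("%.6f\t%.6f", spectrum$mz, spectrum$intensity), path)
  invisible(path)
}

#' Read a predicted protein structure from a PDB file
#'
#' Reads ATOM records of the first model, chain A (the single chain of an
#' Alphafold2 monomer prediction); when no chain A exists and the file has a
#' single chain, that chain is used. The first alternate location is kept;
#' insertion codes are rejected. The B-factor column is preserved and
#' interpreted downstream as per-residue pLDDT confidence. Residues missing
#' any of the four backbone atoms (N, CA, C, O) are flagged so that
#' backbone-dependent operations can exclude them.
#'
#' @param path Path to a PDB file.
#' @return An object of class \code{psd_structure}: a data.frame of atoms
#'   with columns \code{resno} (1-based, contiguous), \code{resid} (1-letter),
#'   \code{elety} (atom name), \code{element}, \code{x}, \code{y}, \code{z}
#'   (Angstrom), \code{b}; attribute \code{incomplete_backbone} lists residue
#'   numbers lacking full backbones.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE,
                         verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in: ", path)
  if (any(!is.na(at$insert) & nzchar(at$insert)))
    stop("insertion codes are not supported: ", path)
  chains <- unique(at$chain)
  if ("A" %in% chains) {
    at <- at[at$chain == "A", , drop = FALSE]
  } else if (length(chains) > 1L) {
    stop("multiple chains and none named 'A' in: ", path)
  }
  unknown <- setdiff(unique(at$resid), names(.aa3to1))
  if (length(unknown) > 0L)
    stop("unknown residue name(s): ", paste(unknown, collapse = ", "))
  element <- at$elesy
  noel <- is.na(element) | !nzchar(trimws(element))
  element[noel] <- substr(gsub("[0-9]", "", at$elety[noel]), 1L, 1L)
  atoms <- data.frame(
    resno = at$resno,
    resid = unname(.aa3to1[at$resid]),
    elety = at$elety,
    element = trimws(element),
    x = at$x, y = at$y, z = at$z,
    b = at$b,
    stringsAsFactors = FALSE
  )
  # renumber to contiguous 1-based indices, preserving order
  atoms$resno <- match(atoms$resno, sort(unique(atoms$resno)))
  incomplete <- vapply(split(atoms$elety, atoms$resno), function(e)
    !all(c("N", "CA", "C", "O") %in% e), logical(1))
  bad <- as.integer(names(incomplete))[incomplete]
  if (length(bad) > 0L)
    warning("residue(s) with incomplete backbone excluded from ",
            "backbone-dependent operations: ", paste(bad, collapse = ", "))
  structure(atoms, class = c("psd_structure", "data.frame"),
            incomplete_backbone = bad)
}

#' Write a structure to a PDB file
#'
#' Emits standard fixed-width ATOM records (single chain A, one model),
#' with the B-factor column carrying pLDDT. Coordinates are written at
#' 3 decimals, the PDB precision, so a written-then-read structure recovers
#' them exactly when they are already rounded to 3 decimals.
#'
#' @param struct A \code{psd_structure} (or compatible data.frame of atoms).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(struct, path) {
  stopifnot(all(c("resno", "resid", "elety", "x", "y", "z", "b")
                %in% names(struct)))
  res3 <- .aa1to3[struct$resid]
  if (anyNA(res3)) stop("unknown 1-letter residue code in structure")
  el <- if ("element" %in% names(struct)) struct$element
        else substr(struct$elety, 1L, 1L)
  name4 <- ifelse(nchar(struct$elety) < 4L,
                  sprintf(" %-3s", struct$elety),
                  sprintf("%-4s", struct$elety))
  lines <- sprintf(
    "ATOM  %5d %s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(struct)), name4, res3, "A", struct$resno,
    struct$x, struct$y, struct$z, 1.00, struct$b, el
  )
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Sequence of a structure
#'
#' @param struct A \code{psd_structure}.
#' @return 1-letter sequence string over residues in index order.
#' @export
structure_sequence <- function(struct) {
  paste(vapply(split(struct$resid, struct$resno), `[[`, "", 1L),
        collapse = "")
}

#' Write a results table as TSV
#'
#' @param df data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
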