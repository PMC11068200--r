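# In-silico b/y fragment prediction at D/E/N cleavage sites.
#
# Post-source decay of low-charge intact protein ions is dominated by the
# aspartic-acid effect: backbone cleavage on the C-terminal side of D, E and
# N residues (and enhanced at X-P bonds through the same sites). For every
# internal D/E/N residue we predict the singly protonated average-mass b ion
# (N-terminal piece) and y ion (C-terminal piece), together with their
# ammonia- and water-loss satellites.

#' Enumerate D/E/N cleavage sites of a sequence
#'
#' One site per internal D, E or N residue (cleavage C-terminal to the
#' residue). Sites at the final residue are excluded: cleavage there yields
#' no fragment pair. The N- and C-terminal neighbour identities are recorded
#' for the categorical analyses; a missing N-terminal neighbour (site at
#' position 1) is coded \code{"^"}.
#'
#' @param sequence Protein sequence, 1-letter codes.
#' @param protein_id Optional id copied into the result.
#' @return A data.frame with columns \code{protein_id}, \code{position}
#'   (1-based), \code{residue}, \code{nterm_neighbor}, \code{cterm_neighbor},
#'   ordered by position. Zero rows when the sequence has no internal D/E/N.
#' @examples
#' enumerate_cleavage_sites("ADGKE")
#' @export
enumerate_cleavage_sites <- function(sequence, protein_id = NA_character_) {
  res <- .check_sequence(sequence)
  n <- length(res)
  pos <- which(res %in% c("D", "E", "N"))
  pos <- pos[pos < n]
  data.frame(
    protein_id = rep(protein_id, length(pos)),
    position = pos,
    residue = res[pos],
    nterm_neighbor = ifelse(pos == 1L, "^", res[pmax(pos - 1L, 1L)]),
    cterm_neighbor = res[pos + 1L],
    stringsAsFactors = FALSE
  )
}

#' Predict the b/y fragment-ion pair for one cleavage site
#'
#' The b ion covers residues 1..position and carries the charging proton
#' only; the y ion covers position+1..n and additionally carries the water
#' of the intact C-terminus. Ammonia (-17.0305) and water (-18.0153) loss
#' variants are reported for both ions. All masses are average and singly
#' charged.
#'
#' @param sequence Protein sequence.
#' @param position 1-based index of the D/E/N residue; cleavage occurs on its
#'   C-terminal side, so \code{position} must be < sequence length.
#' @return A data.frame with one row per series (\code{"b"}, \code{"y"}):
#'   columns \code{series}, \code{length}, \code{mz}, \code{mz_nh3_loss},
#'   \code{mz_h2o_loss}.
#' @export
predict_fragments <- function(sequence, position) {
  res <- .check_sequence(sequence)
  n <- length(res)
  if (!is.numeric(position) || length(position) != 1L ||
      position < 1L || position >= n)
    stop("'position' must be an internal residue index (1 <= position < ",
         n, ")")
  position <- as.integer(position)
  b_mz <- sum(.residue_avg_mass[res[seq_len(position)]]) + MASS_PROTON
  y_mz <- sum(.residue_avg_mass[res[(position + 1L):n]]) +
    MASS_WATER + MASS_PROTON
  mz <- c(b = b_mz, y = y_mz)
  data.frame(
    series = c("b", "y"),
    length = c(position, n - position),
    mz = unname(mz),
    mz_nh3_loss = unname(mz - MASS_AMMONIA),
    mz_h2o_loss = unname(mz - MASS_WATER),
    stringsAsFactors = FALSE
  )
}

#' Predicted fragment table for a whole protein
#'
#' Runs \code{\link{enumerate_cleavage_sites}} and
#' \code{\link{predict_fragments}} over a sequence and returns the combined
#' per-site fragment table used by the scoring step.
#'
#' @inheritParams enumerate_cleavage_sites
#' @return A data.frame with one row per (site, series): the site columns of
#'   \code{enumerate_cleavage_sites} plus the fragment columns of
#'   \code{predict_fragments}.
#' @export
fragment_table <- function(sequence, protein_id = NA_character_) {
  sites <- enumerate_cleavage_sites(sequence, protein_id)
  if (nrow(sites) == 0L) {
    return(cbind(sites, data.frame(
      series = character(0), length = integer(0), mz = numeric(0),
      mz_nh3_loss = numeric(0), mz_h2o_loss = numeric(0)
    )))
  }
  frags <- lapply(sites$position, function(p) predict_fragments(sequence, p))
  out <- cbind(
    sites[rep(seq_len(nrow(sites)), each = 2L), , drop = FALSE],
    do.call(rbind, frags)
  )
  rownames(out) <- NULL
  out
}
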