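# Matching predicted fragments to a centroided spectrum and scoring them.
#
# Each predicted fragment ion (and its ammonia/water-loss satellites) is
# matched to the most intense centroid peak within +/- 5 m/z. The per-site
# fragment signal u is the larger of the matched b and y parent intensities,
# and the signal score is u divided by the standard deviation of all
# unassigned (background) peak intensities — the study's metric of
# fragmentation efficiency, comparable across spectra of differing noise.

#' Match a predicted m/z to the strongest peak in a window
#'
#' Returns the peak of maximum intensity with |mz - target| <= tol. An
#' equal-intensity tie is broken towards the peak nearer the target; a
#' further tie towards lower m/z.
#'
#' @param spectrum data.frame with \code{mz}, \code{intensity} (sorted).
#' @param target_mz Predicted m/z (Da).
#' @param tol Window half-width in m/z units (default 5).
#' @return A list with \code{index}, \code{mz}, \code{intensity}, or
#'   \code{NULL} when no peak falls in the window.
#' @export
match_peak <- function(spectrum, target_mz, tol = 5) {
  if (tol <= 0) stop("'tol' must be positive")
  if (nrow(spectrum) == 0L) return(NULL)
  lo <- findInterval(target_mz - tol, spectrum$mz) + 1L
  hi <- findInterval(target_mz + tol, spectrum$mz)
  if (lo > hi) return(NULL)
  idx <- lo:hi
  ints <- spectrum$intensity[idx]
  best <- idx[ints == max(ints)]
  if (length(best) > 1L) {
    d <- abs(spectrum$mz[best] - target_mz)
    best <- best[d == min(d)]
    best <- best[1L]  # lower m/z on a residual tie (mz sorted ascending)
  }
  list(index = best, mz = spectrum$mz[best],
       intensity = spectrum$intensity[best])
}

#' Assign predicted fragments (and loss variants) to spectrum peaks
#'
#' Every fragment's parent ion and its -NH3 / -H2O variants are matched
#' independently; all matched peaks are marked assigned so that they are
#' excluded from the background. Windows are wide relative to peak spacing,
#' so a peak may satisfy several fragments and is not consumed by a match.
#'
#' @param spectrum Centroided spectrum data.frame.
#' @param fragments Fragment table as from \code{\link{fragment_table}}
#'   (columns \code{mz}, \code{mz_nh3_loss}, \code{mz_h2o_loss}).
#' @param tol Matching half-window (m/z, default 5).
#' @return A list with \code{parent_intensity} (numeric per fragment row, 0
#'   when unmatched) and \code{assigned} (integer indices of spectrum peaks
#'   matched by any parent or loss variant).
#' @export
assign_fragments <- function(spectrum, fragments, tol = 5) {
  n <- nrow(fragments)
  parent <- numeric(n)
  assigned <- integer(0)
  for (i in seq_len(n)) {
    hit <- match_peak(spectrum, fragments$mz[i], tol)
    if (!is.null(hit)) {
      parent[i] <- hit$intensity
      assigned <- c(assigned, hit$index)
    }
    for (v in c("mz_nh3_loss", "mz_h2o_loss")) {
      hv <- match_peak(spectrum, fragments[[v]][i], tol)
      if (!is.null(hv)) assigned <- c(assigned, hv$index)
    }
  }
  list(parent_intensity = parent, assigned = sort(unique(assigned)))
}

#' Standard deviation of the unassigned background
#'
#' Sample (n-1) standard deviation of the intensities of all centroid peaks
#' not assigned to any predicted fragment or loss variant. Peaks within
#' \code{tol} of the precursor m/z can additionally be excluded (metastable
#' suppressor artifacts near the precursor).
#'
#' @param spectrum Centroided spectrum.
#' @param assigned Integer indices of assigned peaks.
#' @param precursor_mz Optional precursor m/z whose neighbourhood is
#'   excluded from the background.
#' @param tol Exclusion half-window around the precursor (default 5).
#' @return Positive scalar standard deviation.
#' @export
background_sigma <- function(spectrum, assigned, precursor_mz = NULL,
                             tol = 5) {
  keep <- setdiff(seq_len(nrow(spectrum)), assigned)
  if (!is.null(precursor_mz)) {
    near <- which(abs(spectrum$mz - precursor_mz) <= tol)
    keep <- setdiff(keep, near)
  }
  if (length(keep) < 2L)
    stop("fewer than 2 unassigned background peaks; ",
         "estimate a noise floor externally and rescore")
  s <- stats::sd(spectrum$intensity[keep])
  if (s == 0)
    stop("degenerate background: unassigned intensities are constant")
  s
}

#' Score all D/E/N cleavage sites of one protein
#'
#' Runs the full matching workflow for one protein: predict fragments,
#' match parents and loss variants at +/- tol m/z, estimate the background
#' standard deviation from unassigned peaks, then per site take the larger
#' of the matched b and y parent intensities as the fragment signal u and
#' report score = u / sigma. The winning series is recorded (\code{"none"}
#' when neither series matched; \code{"b"} preferred on an exact tie).
#'
#' @param sequence Protein sequence.
#' @param spectrum Centroided spectrum data.frame.
#' @param protein_id Identifier copied into the result.
#' @param precursor_mz Optional precursor m/z excluded from background.
#' @param tol Matching half-window (default 5 m/z).
#' @return A data.frame with one row per cleavage site: site columns plus
#'   \code{winning_series}, \code{u}, \code{sigma}, \code{score}.
#' @export
score_protein <- function(sequence, spectrum, protein_id = NA_character_,
                          precursor_mz = NULL, tol = 5) {
  frags <- fragment_table(sequence, protein_id)
  sites <- unique(frags[, c("protein_id", "position", "residue",
                            "nterm_neighbor", "cterm_neighbor")])
  rownames(sites) <- NULL
  if (nrow(sites) == 0L)
    return(cbind(sites, data.frame(winning_series = character(0),
                                   u = numeric(0), sigma = numeric(0),
                                   score = numeric(0))))
  asg <- assign_fragments(spectrum, frags, tol)
  sigma <- background_sigma(spectrum, asg$assigned, precursor_mz, tol)
  u_b <- asg$parent_intensity[frags$series == "b"]
  u_y <- asg$parent_intensity[frags$series == "y"]
  u <- pmax(u_b, u_y)
  series <- ifelse(u == 0, "none", ifelse(u_b >= u_y, "b", "y"))
  cbind(sites, data.frame(winning_series = series, u = u, sigma = sigma,
                          score = u / sigma, stringsAsFactors = FALSE))
}
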