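# Synthetic-data generator: sequences with controlled D/E/N/P/G content,
# backbone-complete structures with ideal secondary-structure geometry and
# pLDDT values, and centroided spectra whose fragment peaks follow the
# log-linear negative-binomial model over known property values, plus
# background peaks of known scale. Every generator is deterministic given
# its seed and returns the ground truth needed for parameter-recovery tests.

# Swiss-Prot-like amino-acid background composition
.aa_background_freq <- c(
  A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.37, Q = 3.93, E = 6.75,
  G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84, M = 2.42, F = 3.86,
  P = 4.70, S = 6.56, T = 5.34, W = 1.08, Y = 2.92, V = 6.87
)

#' Generate a random protein sequence with site and motif quotas
#'
#' Draws residues from a background composition, then guarantees at least
#' the requested counts of internal D/E/N cleavage sites and of D-P, N-P,
#' D-G dipeptide motifs (the enhanced-cleavage motifs) by overwriting
#' non-overlapping positions.
#'
#' @param length Sequence length (>= 10).
#' @param weights Named residue sampling weights (default Swiss-Prot-like).
#' @param site_quota Named counts, e.g. \code{c(D = 3, E = 2, N = 2)}:
#'   minimum internal occurrences per residue class.
#' @param motif_quota Named counts over \code{c("DP", "NP", "DG")}: minimum
#'   dipeptide occurrences.
#' @param seed Optional integer seed.
#' @return Sequence string.
#' @export
generate_sequence <- function(length, weights = .aa_background_freq,
                              site_quota = c(D = 0, E = 0, N = 0),
                              motif_quota = c(DP = 0, NP = 0, DG = 0),
                              seed = NULL) {
  if (length < 10L) stop("'length' must be at least 10")
  if (!is.null(seed)) set.seed(seed)
  need <- 2L * sum(motif_quota) + sum(site_quota)
  if (need > floor(length / 2))
    stop("site/motif quotas infeasible for sequence length ", length)
  res <- sample(names(weights), length, replace = TRUE,
                prob = weights / sum(weights))
  used <- rep(FALSE, length)
  # plant motifs on non-overlapping internal positions
  for (m in names(motif_quota)) {
    k <- motif_quota[[m]]
    if (k == 0L) next
    aa <- strsplit(m, "")[[1]]
    for (q in seq_len(k)) {
      free <- which(!used[seq_len(length - 2L)] &
                    !used[seq_len(length - 2L) + 1L])
      if (length(free) == 0L) stop("no room left for motif ", m)
      i <- if (length(free) == 1L) free else sample(free, 1L)
      res[i] <- aa[1]; res[i + 1L] <- aa[2]
      used[i] <- used[i + 1L] <- TRUE
    }
  }
  # top up internal single-residue site counts
  for (r in names(site_quota)) {
    deficit <- site_quota[[r]] - sum(res[seq_len(length - 1L)] == r)
    if (deficit <= 0L) next
    free <- which(!used[seq_len(length - 1L)] &
                  res[seq_len(length - 1L)] != r)
    if (length(free) < deficit)
      stop("no room left for ", deficit, " extra ", r, " site(s)")
    i <- if (length(free) == 1L) free else sample(free, deficit)
    res[i] <- r
    used[i] <- TRUE
  }
  paste(res, collapse = "")
}

# TRUE when no b-ion parent of one site falls within 2*tol of a y-ion
# parent of another site; within-series parents are always separated by at
# least one residue mass. Sequences passing this check yield spectra whose
# planted per-site truth is exactly what an ideal scorer recovers.
.fragment_windows_disjoint <- function(sequence, tol = 5) {
  ft <- fragment_table(sequence)
  b <- ft[ft$series == "b", ]
  y <- ft[ft$series == "y", ]
  if (nrow(b) < 2L) return(TRUE)
  d <- abs(outer(b$mz, y$mz, "-"))
  same <- outer(b$position, y$position, "==")
  all(d[!same] > 2 * tol)
}

# ideal peptide internal geometry (Angstrom / degrees)
.geom <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.530,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
  a_n_ca_cb = 110.5, omega = 180
)

# place atom D from A-B-C with bond r(C-D), angle theta(B-C-D) and torsion
# chi(A-B-C-D); standard internal-to-Cartesian (NeRF) construction
.place_atom <- function(A, B, C, r, theta, chi) {
  th <- theta * pi / 180; ph <- chi * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  nv <- c(ab[2] * bc[3] - ab[3] * bc[2],
          ab[3] * bc[1] - ab[1] * bc[3],
          ab[1] * bc[2] - ab[2] * bc[1])
  nv <- nv / sqrt(sum(nv^2))
  mv <- c(nv[2] * bc[3] - nv[3] * bc[2],
          nv[3] * bc[1] - nv[1] * bc[3],
          nv[1] * bc[2] - nv[2] * bc[1])
  d2 <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  C + cbind(bc, mv, nv) %*% d2
}

.arch_torsions <- function(architecture, n, seed_state) {
  # per-residue (phi, psi); helix (-57, -47), extended strand (-135, 135)
  switch(architecture,
    helix = matrix(c(-57, -47), n, 2, byrow = TRUE),
    extended = matrix(c(-135, 135), n, 2, byrow = TRUE),
    mixed = {
      phi_psi <- matrix(NA_real_, n, 2)
      i <- 1L
      while (i <= n) {
        len <- sample(5:12, 1L)
        kind <- sample(c("helix", "extended", "coil"), 1L,
                       prob = c(0.45, 0.3, 0.25))
        idx <- i:min(n, i + len - 1L)
        phi_psi[idx, ] <- switch(kind,
          helix = matrix(c(-57, -47), length(idx), 2, byrow = TRUE),
          extended = matrix(c(-135, 135), length(idx), 2, byrow = TRUE),
          coil = cbind(stats::runif(length(idx), -150, -50),
                       stats::runif(length(idx), -60, 160)))
        i <- i + len
      }
      phi_psi
    },
    stop("unknown architecture: ", architecture))
}

#' Generate a backbone-complete structure with ideal geometry
#'
#' Builds N, CA, C, O (plus a CB stub for non-glycine residues) from ideal
#' internal coordinates with architecture-determined phi/psi torsions
#' (helix: -57/-47; extended: -135/135; mixed: random helix, strand and coil
#' segments). The B-factor column carries the supplied pLDDT profile.
#' Coordinates are rounded to 3 decimals so that writing to PDB and reading
#' back is lossless.
#'
#' @param sequence Protein sequence.
#' @param architecture One of \code{"mixed"}, \code{"helix"},
#'   \code{"extended"}.
#' @param plddt Per-residue pLDDT (scalar recycled; default 90).
#' @param seed Optional integer seed (used by the mixed architecture).
#' @return A \code{psd_structure}.
#' @export
generate_structure <- function(sequence, architecture = "mixed",
                               plddt = 90, seed = NULL) {
  res <- .check_sequence(sequence)
  n <- length(res)
  if (!is.null(seed)) set.seed(seed)
  plddt <- rep_len(plddt, n)
  tors <- .arch_torsions(architecture, n, NULL)
  g <- .geom
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N; O <- N; CB <- N
  # seed atoms of residue 1
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  th <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n)) {
    if (i > 1L) {
      N[i, ] <- .place_atom(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                            g$b_c_n, g$a_ca_c_n, tors[i - 1L, 2])  # psi
      CA[i, ] <- .place_atom(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                             g$b_n_ca, g$a_c_n_ca, g$omega)
      C[i, ] <- .place_atom(C[i - 1L, ], N[i, ], CA[i, ],
                            g$b_ca_c, g$a_n_ca_c, tors[i, 1])      # phi
    }
    # carbonyl O: anti-periplanar to the next N along the psi torsion
    O[i, ] <- .place_atom(N[i, ], CA[i, ], C[i, ],
                          g$b_c_o, g$a_ca_c_o, tors[i, 2] + 180)
    if (res[i] != "G") {
      u <- N[i, ] - CA[i, ]; u <- u / sqrt(sum(u^2))
      v <- C[i, ] - CA[i, ]; v <- v / sqrt(sum(v^2))
      bis <- -(u + v); bis <- bis / sqrt(sum(bis^2))
      pr <- c(u[2] * v[3] - u[3] * v[2],
              u[3] * v[1] - u[1] * v[3],
              u[1] * v[2] - u[2] * v[1])
      pr <- pr / sqrt(sum(pr^2))
      ang <- 54.5 * pi / 180
      CB[i, ] <- CA[i, ] + g$b_ca_cb * (cos(ang) * bis + sin(ang) * pr)
    }
  }
  rows <- list()
  for (i in seq_len(n)) {
    at <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    nm <- c("N", "CA", "C", "O")
    el <- c("N", "C", "C", "O")
    if (res[i] != "G") {
      at <- rbind(at, CB[i, ]); nm <- c(nm, "CB"); el <- c(el, "C")
    }
    rows[[i]] <- data.frame(resno = i, resid = res[i], elety = nm,
                            element = el,
                            x = round(at[, 1], 3), y = round(at[, 2], 3),
                            z = round(at[, 3], 3), b = plddt[i],
                            stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  structure(atoms, class = c("psd_structure", "data.frame"),
            incomplete_backbone = integer(0))
}

#' Generate a centroided spectrum with planted fragment peaks
#'
#' Inverts the scoring model over the negative-binomial signal model: for
#' each D/E/N cleavage site a true score is drawn from
#' NB(mu = exp(beta0 + x' beta + offset), size = dispersion), a winning
#' series (b or y) is chosen at random, and a peak of intensity
#' score * sigma_bg is planted at that fragment's parent m/z. Background
#' peaks are placed at uniform random m/z avoiding every fragment parent and
#' loss window, with intensities drawn half-normal (default) or Gaussian
#' around 5*sigma_bg; either way \code{sigma_bg} is the standard deviation
#' of the background intensities, so planted score = u / sigma_bg matches
#' what the scoring step recovers up to sampling error of its sigma
#' estimate.
#'
#' @param sequence Protein sequence.
#' @param properties data.frame of per-site explanatory variables scaled to
#'   [0, 1]; one row per site of
#'   \code{\link{enumerate_cleavage_sites}(sequence)}. May be NULL when
#'   \code{beta} is empty.
#' @param beta0 Intercept on the log scale.
#' @param beta Named slope vector over columns of \code{properties}.
#' @param offset Optional per-site additive term on the log scale (e.g.
#'   neighbour-motif effects).
#' @param dispersion NB size parameter theta (default 1).
#' @param sigma_bg Background intensity scale (default 1).
#' @param n_background Number of background peaks (default 200).
#' @param background \code{"halfnormal"} or \code{"gaussian"}.
#' @param tol Fragment window half-width to keep background clear of
#'   (default 5 m/z).
#' @param seed Optional integer seed.
#' @return List with \code{spectrum} (data.frame) and \code{truth}
#'   (data.frame: site columns, \code{true_score}, \code{u},
#'   \code{winning_series}, plus attributes \code{sigma_bg}, \code{beta0},
#'   \code{beta}, \code{dispersion}).
#' @export
generate_spectrum <- function(sequence, properties = NULL, beta0 = log(5),
                              beta = numeric(0), offset = 0,
                              dispersion = 1, sigma_bg = 1,
                              n_background = 200L,
                              background = c("halfnormal", "gaussian"),
                              tol = 5, seed = NULL) {
  background <- match.arg(background)
  if (!is.null(seed)) set.seed(seed)
  sites <- enumerate_cleavage_sites(sequence)
  ns <- nrow(sites)
  if (ns == 0L) stop("sequence has no internal D/E/N site")
  eta <- rep(beta0, ns) + rep_len(offset, ns)
  if (length(beta) > 0L) {
    if (is.null(properties) || nrow(properties) != ns)
      stop("'properties' must have one row per cleavage site")
    X <- as.matrix(properties[, names(beta), drop = FALSE])
    if (any(X < 0 | X > 1)) stop("'properties' must be scaled to [0, 1]")
    eta <- eta + as.numeric(X %*% beta)
  }
  true_score <- stats::rnbinom(ns, mu = exp(eta), size = dispersion)
  series <- sample(c("b", "y"), ns, replace = TRUE)
  frags <- fragment_table(sequence)
  # honour the ground-truth contract (planted score = u / sigma as an ideal
  # scorer would recover it): where possible, plant the winning series whose
  # parent m/z stays out of every other site's matching window, so one
  # site's peak cannot masquerade as another site's fragment signal
  mz_of <- function(pos, ser)
    frags$mz[match(paste(pos, ser), paste(frags$position, frags$series))]
  for (i in seq_len(ns)) {
    others <- c(mz_of(sites$position[-i], "b"), mz_of(sites$position[-i], "y"))
    clear <- vapply(c("b", "y"), function(s)
      all(abs(others - mz_of(sites$position[i], s)) > tol), logical(1))
    if (!clear[[series[i]]] && any(clear))
      series[i] <- names(clear)[clear][1]
  }
  frag_mz <- mz_of(sites$position, series)
  u <- true_score * sigma_bg
  peaks <- data.frame(mz = frag_mz[u > 0], intensity = u[u > 0])
  # background peaks avoid every parent and loss window
  avoid <- sort(unique(c(frags$mz, frags$mz_nh3_loss, frags$mz_h2o_loss)))
  mz_lo <- 9; mz_hi <- protonated_mass(sequence) + 500
  bg_mz <- numeric(0)
  while (length(bg_mz) < n_background) {
    cand <- stats::runif(2L * n_background, mz_lo, mz_hi)
    near <- vapply(cand, function(m) any(abs(avoid - m) <= tol + 0.01),
                   logical(1))
    bg_mz <- c(bg_mz, cand[!near])
  }
  bg_mz <- bg_mz[seq_len(n_background)]
  bg_int <- switch(background,
    # half-normal rescaled so that the intensity standard deviation —
    # the quantity the scoring step estimates — equals sigma_bg
    halfnormal = abs(stats::rnorm(n_background, 0,
                                  sigma_bg / sqrt(1 - 2 / pi))),
    gaussian = pmax(stats::rnorm(n_background, 5 * sigma_bg, sigma_bg), 0))
  peaks <- rbind(peaks, data.frame(mz = bg_mz, intensity = bg_int))
  peaks <- peaks[order(peaks$mz), ]
  peaks <- peaks[!duplicated(peaks$mz), ]
  rownames(peaks) <- NULL
  truth <- cbind(sites,
                 data.frame(true_score = true_score, u = u,
                            winning_series = ifelse(u > 0, series, "none"),
                            stringsAsFactors = FALSE))
  attr(truth, "sigma_bg") <- sigma_bg
  attr(truth, "beta0") <- beta0
  attr(truth, "beta") <- beta
  attr(truth, "dispersion") <- dispersion
  list(spectrum = peaks, truth = truth)
}

#' Generate a multi-protein dataset with known regression ground truth
#'
#' Property-direct mode: per-site explanatory variables are drawn uniform on
#' [0, 1] and spectra are planted under the log-linear NB model, so the full
#' predict-score-regress chain can be checked against the true coefficients
#' without structure generation.
#'
#' @param n_proteins Number of proteins (default 30).
#' @param sites_per_protein Approximate D/E/N sites per protein (default 15).
#' @param beta0 True intercept.
#' @param beta Named true slopes; property columns are created for each name.
#' @param dispersion NB size theta.
#' @param sigma_bg Background scale.
#' @param n_background Background peaks per spectrum.
#' @param background Background intensity model (see
#'   \code{\link{generate_spectrum}}).
#' @param seed Integer seed.
#' @return List with \code{proteins} (list of \code{id}, \code{sequence},
#'   \code{spectrum}), \code{properties} (per-site data.frame with
#'   \code{protein_id}, \code{position} and one column per property) and
#'   \code{truth} (row-bound truth tables).
#' @export
generate_dataset <- function(n_proteins = 30L, sites_per_protein = 15L,
                             beta0 = log(5),
                             beta = c(x1 = 1.5, x2 = -1, x3 = 0.8),
                             dispersion = 1, sigma_bg = 1,
                             n_background = 150L,
                             background = "gaussian", seed = 1L) {
  set.seed(seed)
  per_class <- max(1L, round(sites_per_protein / 3))
  proteins <- vector("list", n_proteins)
  props <- list(); truths <- list()
  for (k in seq_len(n_proteins)) {
    # resample until all cross-site fragment windows are disjoint, so the
    # planted ground truth is unambiguous for parameter-recovery checks
    repeat {
      seq_k <- generate_sequence(
        length = max(40L, 4L * sites_per_protein),
        site_quota = c(D = per_class, E = per_class, N = per_class))
      if (.fragment_windows_disjoint(seq_k)) break
    }
    sites <- enumerate_cleavage_sites(seq_k)
    P <- as.data.frame(matrix(stats::runif(nrow(sites) * length(beta)),
                              ncol = length(beta),
                              dimnames = list(NULL, names(beta))))
    gen <- generate_spectrum(seq_k, properties = P, beta0 = beta0,
                             beta = beta, dispersion = dispersion,
                             sigma_bg = sigma_bg,
                             n_background = n_background,
                             background = background)
    id <- sprintf("synth%02d", k)
    proteins[[k]] <- list(id = id, sequence = seq_k,
                          spectrum = gen$spectrum)
    props[[k]] <- cbind(data.frame(protein_id = id,
                                   position = sites$position), P)
    tr <- gen$truth; tr$protein_id <- id
    truths[[k]] <- tr
  }
  list(proteins = proteins,
       properties = do.call(rbind, props),
       truth = do.call(rbind, truths),
       beta0 = beta0, beta = beta, dispersion = dispersion,
       sigma_bg = sigma_bg)
}
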