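# Secondary-structure assignment by the Kabsch-Sander criterion.
#
# Backbone hydrogen bonds are detected with the classic electrostatic model:
# the amide hydrogen is rebuilt on each nitrogen (opposite the preceding
# carbonyl), and a C=O(i)...H-N(j) bond is called when the Kabsch-Sander
# energy is below -0.5 kcal/mol. The standard pattern rules then yield the
# 8-state alphabet {H, G, I, E, B, T, S, -}: n-turns define helices (H =
# 4-turn alpha helix, G = 3-10, I = pi), bridge patterns define strands
# (E) and isolated bridges (B), remaining turn spans are T and tight CA
# bends are S.

.KS_Q <- 0.084 * 332  # kcal/mol * Angstrom, Kabsch-Sander coupling constant

.backbone_coords <- function(struct) {
  resnos <- sort(unique(struct$resno))
  get <- function(name) {
    a <- struct[struct$elety == name, , drop = FALSE]
    m <- matrix(NA_real_, length(resnos), 3L)
    m[match(a$resno, resnos), ] <- .coord_matrix(a)
    m
  }
  list(resno = resnos,
       code = vapply(split(struct$resid, struct$resno), `[[`, "", 1L),
       N = get("N"), CA = get("CA"), C = get("C"), O = get("O"))
}

# Kabsch-Sander H-bond energy matrix: e[i, j] = energy of CO(i) ... HN(j)
.ks_energy <- function(bb, break_after) {
  n <- length(bb$resno)
  # amide H: on N, 1.0 A along the direction of the preceding C=O bond
  H <- matrix(NA_real_, n, 3L)
  for (j in 2:n) {
    if (break_after[j - 1L]) next
    if (bb$code[j] == "P") next  # proline has no amide hydrogen
    co <- bb$C[j - 1L, ] - bb$O[j - 1L, ]
    len <- sqrt(sum(co^2))
    if (!is.finite(len) || len == 0) next
    H[j, ] <- bb$N[j, ] + co / len
  }
  dist1 <- function(a, b) sqrt(rowSums((a - b)^2))
  e <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    if (anyNA(bb$C[i, ]) || anyNA(bb$O[i, ])) next
    ok <- which(!is.na(H[, 1]) & !is.na(bb$N[, 1]))
    # exclude self and the donor whose H was rebuilt from this carbonyl
    ok <- ok[ok != i & ok != i + 1L]
    if (length(ok) == 0L) next
    # CA-CA prefilter at 9 A
    ca_ok <- ok[dist1(bb$CA[ok, , drop = FALSE],
                      matrix(bb$CA[i, ], length(ok), 3, byrow = TRUE)) < 9]
    if (length(ca_ok) == 0L) next
    Oi <- matrix(bb$O[i, ], length(ca_ok), 3, byrow = TRUE)
    Ci <- matrix(bb$C[i, ], length(ca_ok), 3, byrow = TRUE)
    Nj <- bb$N[ca_ok, , drop = FALSE]
    Hj <- H[ca_ok, , drop = FALSE]
    e[i, ca_ok] <- .KS_Q * (1 / dist1(Oi, Nj) + 1 / dist1(Ci, Hj) -
                            1 / dist1(Oi, Hj) - 1 / dist1(Ci, Nj))
  }
  e
}

#' Assign 8-state secondary structure (Kabsch-Sander rules)
#'
#' Built-in implementation of the DSSP convention on the heavy-atom
#' backbone. Residues with incomplete backbones or across chain breaks
#' (peptide C-N distance > 2.5 Angstrom) are coded \code{"-"}.
#'
#' @param struct A \code{psd_structure}.
#' @param hbond_cutoff Hydrogen-bond energy threshold in kcal/mol
#'   (default -0.5).
#' @return Named character vector over residues, names = residue indices;
#'   codes in \code{{H, G, I, E, B, T, S, -}}.
#' @export
assign_secondary_structure <- function(struct, hbond_cutoff = -0.5) {
  bb <- .backbone_coords(struct)
  n <- length(bb$resno)
  ss <- rep("-", n)
  names(ss) <- bb$resno
  if (n < 3L) return(ss)
  complete <- !is.na(bb$N[, 1]) & !is.na(bb$CA[, 1]) &
              !is.na(bb$C[, 1]) & !is.na(bb$O[, 1])
  # chain break after residue i when the peptide bond C(i)-N(i+1) is broken
  break_after <- rep(FALSE, n)
  for (i in seq_len(n - 1L)) {
    if (!complete[i] || !complete[i + 1L]) { break_after[i] <- TRUE; next }
    break_after[i] <-
      sqrt(sum((bb$C[i, ] - bb$N[i + 1L, ])^2)) > 2.5
  }
  e <- .ks_energy(bb, break_after)
  hb <- e < hbond_cutoff  # hb[i, j]: CO(i) accepts from NH(j)
  hbond <- function(i, j) {
    i >= 1L && j >= 1L && i <= n && j <= n && isTRUE(hb[i, j])
  }
  # n-turns: turn[n-2][i] TRUE when CO(i) ... HN(i+n)
  turn <- lapply(3:5, function(k) {
    t <- rep(FALSE, n)
    idx <- seq_len(n - k)
    t[idx] <- hb[cbind(idx, idx + k)]
    t
  })
  names(turn) <- c("3", "4", "5")

  set_if_open <- function(ss, idx, code) {
    open <- ss[idx] == "-" | ss[idx] == "T" | ss[idx] == "S"
    ss[idx[open]] <- code
    ss
  }
  # alpha helix: two consecutive 4-turns at i-1 and i mark i..i+3
  for (i in 2:max(1L, n - 4L)) {
    if (turn[["4"]][i - 1L] && turn[["4"]][i])
      ss[i:(i + 3L)] <- "H"
  }
  # bridges and strands
  bridge <- rep(FALSE, n)
  for (i in 2:(n - 1L)) {
    for (j in 2:(n - 1L)) {
      if (abs(i - j) < 3L) next
      par <- (hbond(i - 1L, j) && hbond(j, i + 1L)) ||
             (hbond(j - 1L, i) && hbond(i, j + 1L))
      anti <- (hbond(i, j) && hbond(j, i)) ||
              (hbond(i - 1L, j + 1L) && hbond(j - 1L, i + 1L))
      if (par || anti) bridge[i] <- TRUE
    }
  }
  if (any(bridge)) {
    runs <- rle(bridge)
    pos <- cumsum(c(1L, runs$lengths))
    for (k in seq_along(runs$values)) {
      if (!runs$values[k]) next
      idx <- pos[k]:(pos[k + 1L] - 1L)
      code <- if (length(idx) >= 2L) "E" else "B"
      keep <- ss[idx] != "H"
      ss[idx[keep]] <- code
    }
  }
  # 3-10 helix: two consecutive 3-turns
  for (i in 2:max(1L, n - 3L)) {
    if (turn[["3"]][i - 1L] && turn[["3"]][i])
      ss <- set_if_open(ss, i:(i + 2L), "G")
  }
  # pi helix: two consecutive 5-turns
  for (i in 2:max(1L, n - 5L)) {
    if (turn[["5"]][i - 1L] && turn[["5"]][i])
      ss <- set_if_open(ss, i:(i + 4L), "I")
  }
  # turn: residues strictly inside any single n-turn span
  for (k in 3:5) {
    tk <- turn[[as.character(k)]]
    for (i in which(tk)) {
      idx <- (i + 1L):(i + k - 1L)
      idx <- idx[idx <= n]
      open <- ss[idx] == "-"
      ss[idx[open]] <- "T"
    }
  }
  # bend: CA direction change > 70 degrees
  for (i in 3:(n - 2L)) {
    if (ss[i] != "-") next
    if (!complete[i - 2L] || !complete[i] || !complete[i + 2L]) next
    v1 <- bb$CA[i, ] - bb$CA[i - 2L, ]
    v2 <- bb$CA[i + 2L, ] - bb$CA[i, ]
    cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
    if (acos(pmin(pmax(cosang, -1), 1)) * 180 / pi > 70) ss[i] <- "S"
  }
  ss[!complete] <- "-"
  ss
}
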