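# Independent oracles and fixture builders used across the suite.

# --- elemental-composition mass oracle (independent of the package's
# residue mass table): average atomic masses summed over residue formulas
.atomic_avg <- c(C = 12.011, H = 1.00794, N = 14.0067, O = 15.9994,
                 S = 32.060)
.residue_formula <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)
oracle_residue_mass <- function(code) {
  f <- .residue_formula[[code]]
  sum(.atomic_avg[names(f)] * f)
}
oracle_water <- sum(.atomic_avg[c("H", "O")] * c(2, 1))

# --- brute-force graph oracles from an adjacency matrix (unit weights)
oracle_floyd_warshall <- function(A) {
  n <- nrow(A)
  d <- ifelse(A > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}
oracle_path_counts <- function(A, d) {
  # sigma[s, t]: number of shortest s-t paths, by DP over distance layers
  n <- nrow(A)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in seq_len(n)) {
    ord <- order(d[s, ])
    for (t in ord) {
      if (t == s || !is.finite(d[s, t])) next
      pred <- which(A[, t] > 0 & d[s, ] == d[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, pred])
    }
  }
  sigma
}
oracle_betweenness <- function(A) {
  n <- nrow(A)
  d <- oracle_floyd_warshall(A)
  sigma <- oracle_path_counts(A, d)
  bt <- numeric(n)
  for (v in seq_len(n))
    for (s in seq_len(n - 1))
      for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(d[s, t])) next
        if (d[s, v] + d[v, t] == d[s, t] && sigma[s, t] > 0)
          bt[v] <- bt[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
  bt
}
oracle_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sum(A[nb, nb]) / 2 / (k * (k - 1) / 2)
  }, numeric(1))
}

# random connected unit-weight graph on n nodes as an adjacency matrix
random_connected_adjacency <- function(n, p = 0.4) {
  repeat {
    A <- matrix(0, n, n)
    up <- which(upper.tri(A))
    on <- up[stats::runif(length(up)) < p]
    A[on] <- 1
    A <- A + t(A)
    # connect via a random spanning chain to guarantee connectivity
    ord <- sample(n)
    for (i in seq_len(n - 1)) {
      A[ord[i], ord[i + 1]] <- 1
      A[ord[i + 1], ord[i]] <- 1
    }
    if (all(rowSums(A) > 0)) return(A)
  }
}

graph_from_adjacency <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# place n CA-only residues at given coordinates (for RIN fixtures)
ca_structure <- function(xyz, codes = NULL) {
  n <- nrow(xyz)
  if (is.null(codes)) codes <- rep("A", n)
  structure(
    data.frame(resno = seq_len(n), resid = codes, elety = "CA",
               element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               b = 90, stringsAsFactors = FALSE),
    class = c("psd_structure", "data.frame"),
    incomplete_backbone = integer(0))
}

# exact two-sided Mann-Whitney p by enumeration of all label arrangements
oracle_mwu_exact <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pooled), n1)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  us <- apply(idx, 2, function(ii) u_of(pooled[ii], pooled[-ii]))
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(p, 1)
}

# tie-corrected Kruskal-Wallis H from the rank formula
oracle_kw_H <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  r <- rank(x)
  ri <- split(r, rep(seq_along(groups), lengths(groups)))
  H <- 12 / (n * (n + 1)) *
    sum(vapply(ri, function(rr) sum(rr)^2 / length(rr), numeric(1))) -
    3 * (n + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}
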