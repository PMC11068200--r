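# Residue interaction network construction and centralities, against
# closed forms and brute-force oracles.

test_that("RIN edges follow the 7 A inclusive cutoff", {
  st <- ca_structure(rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0)))
  g <- build_rin(st)
  expect_equal(igraph::ecount(g), 2L)          # 10 A pair excluded
  expect_false(igraph::are_adjacent(g, 1, 3))
  tri <- ca_structure(rbind(c(0, 0, 0), c(5, 0, 0), c(2.5, 5 * sqrt(3) / 2, 0)))
  expect_equal(igraph::ecount(build_rin(tri)), 3L)
  pair <- ca_structure(rbind(c(0, 0, 0), c(7, 0, 0)))
  expect_equal(igraph::ecount(build_rin(pair)), 1L)  # exactly 7.0 is an edge
  expect_error(build_rin(ca_structure(cbind(0, 0, 0))), "at least 2")
})

test_that("closeness and eccentricity match closed forms on small graphs", {
  path3 <- graph_from_adjacency(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  expect_equal(rin_closeness(path3), c(2 / 3, 1, 2 / 3))
  expect_equal(rin_eccentricity(path3), c(1, 0.5, 1))
  k4 <- graph_from_adjacency(matrix(1, 4, 4) - diag(4))
  expect_equal(rin_closeness(k4), rep(1, 4))
  expect_equal(rin_eccentricity(k4), rep(1, 4))
})

test_that("eigenvector centrality is the unit-norm principal eigenvector", {
  k3 <- graph_from_adjacency(matrix(1, 3, 3) - diag(3))
  expect_equal(rin_eigenvector(k3), rep(1 / sqrt(3), 3))
  star <- graph_from_adjacency(rbind(c(0, 1, 1, 1), c(1, 0, 0, 0),
                                     c(1, 0, 0, 0), c(1, 0, 0, 0)))
  v <- rin_eigenvector(star)
  expect_gt(v[1], v[2])
  expect_equal(v[2], v[3])
  set.seed(5)
  for (r in 1:10) {
    A <- random_connected_adjacency(sample(4:12, 1))
    v <- rin_eigenvector(graph_from_adjacency(A))
    ev <- eigen(A, symmetric = TRUE)
    ref <- abs(ev$vectors[, which.max(ev$values)])
    ref <- ref / sqrt(sum(ref^2))
    expect_equal(v, ref, tolerance = 1e-8)
  }
})

test_that("average nearest-neighbour degree matches direct enumeration", {
  star <- graph_from_adjacency(rbind(c(0, 1, 1, 1), c(1, 0, 0, 0),
                                     c(1, 0, 0, 0), c(1, 0, 0, 0)))
  expect_equal(rin_annd(star), c(1, 3, 3, 3))
  path3 <- graph_from_adjacency(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  expect_equal(rin_annd(path3, node = 2), 1)
})

test_that("degree/strength/clustering/betweenness closed forms hold", {
  tri <- graph_from_adjacency(matrix(1, 3, 3) - diag(3))
  bc <- rin_basic_centralities(tri)
  expect_equal(bc$clustering, rep(1, 3))
  expect_equal(bc$betweenness, rep(0, 3))
  path3 <- graph_from_adjacency(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  bp <- rin_basic_centralities(path3)
  expect_equal(bp$betweenness, c(0, 1, 0))   # the single transiting pair
  expect_equal(bp$clustering, c(0, 0, 0))
  expect_equal(bp$strength, bp$degree)       # unit weights
})

test_that("centralities agree with brute-force oracles on random graphs", {
  set.seed(17)
  for (r in 1:40) {
    A <- random_connected_adjacency(sample(4:12, 1))
    g <- graph_from_adjacency(A)
    n <- nrow(A)
    d <- oracle_floyd_warshall(A)
    expect_equal(rin_closeness(g), (n - 1) / rowSums(d), tolerance = 1e-8)
    ecc <- apply(d, 1, max)
    expect_equal(rin_eccentricity(g), ecc / max(ecc), tolerance = 1e-8)
    bt <- oracle_betweenness(A) / ((n - 1) * (n - 2) / 2)
    expect_equal(rin_basic_centralities(g)$betweenness, bt,
                 tolerance = 1e-8)
    expect_equal(rin_basic_centralities(g)$clustering,
                 oracle_clustering(A), tolerance = 1e-8)
    annd <- vapply(seq_len(n), function(u)
      mean(rowSums(A)[A[u, ] > 0]), numeric(1))
    expect_equal(rin_annd(g), annd, tolerance = 1e-8)
  }
})

test_that("node relabeling permutes but does not alter centralities", {
  set.seed(29)
  A <- random_connected_adjacency(9)
  perm <- sample(9)
  Ap <- A[perm, perm]
  g <- graph_from_adjacency(A); gp <- graph_from_adjacency(Ap)
  expect_equal(rin_closeness(gp), rin_closeness(g)[perm])
  expect_equal(rin_annd(gp), rin_annd(g)[perm])
  expect_equal(rin_basic_centralities(gp)$betweenness,
               rin_basic_centralities(g)$betweenness[perm])
})

test_that("a chain-like protein yields a path graph with known formulas", {
  n <- 8
  xyz <- cbind(seq_len(n) * 6.5, 0, 0)  # only consecutive CA within 7 A
  g <- build_rin(ca_structure(xyz))
  expect_equal(igraph::ecount(g), n - 1L)
  cl <- rin_closeness(g)
  i <- seq_len(n)
  expect_equal(cl, (n - 1) / (((i - 1) * i + (n - i) * (n - i + 1)) / 2))
  expect_equal(rin_eccentricity(g), pmax(i - 1, n - i) / (n - 1))
})

test_that("disconnected graphs use component-local distances", {
  A <- matrix(0, 5, 5)
  A[1, 2] <- A[2, 1] <- 1; A[2, 3] <- A[3, 2] <- 1  # path of 3 + edge pair
  A[4, 5] <- A[5, 4] <- 1
  g <- graph_from_adjacency(A)
  expect_equal(rin_closeness(g), c(2 / 3, 1, 2 / 3, 1, 1))
  expect_equal(rin_eccentricity(g), c(1, 0.5, 1, 1, 1))
})
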