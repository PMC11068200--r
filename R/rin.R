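# Residue interaction network (RIN) and the eight centrality measures.
#
# Residues are nodes; an edge joins residues i and j when their CA-CA
# distance is at most 7 Angstrom (inclusive) and |i - j| >= 1. Edges carry
# unit weight by default: with unit weights strength equals degree exactly
# (their observed correlation of 1 motivates removing strength from the
# regression), and shortest paths are unweighted hop counts. A
# distance-derived weighting is available behind a flag.

#' Build the CA residue interaction network
#'
#' @param struct A \code{psd_structure}.
#' @param threshold Contact cutoff in Angstrom, inclusive (default 7).
#' @param min_sep Minimum sequence separation |i-j| (default 1 = any pair).
#' @param weighted If TRUE edge weights are the CA-CA distances; default
#'   unit weights.
#' @return An \code{igraph} undirected graph whose vertex names are residue
#'   indices.
#' @export
build_rin <- function(struct, threshold = 7, min_sep = 1L,
                      weighted = FALSE) {
  ca <- .ca_matrix(struct)
  n <- nrow(ca)
  if (n < 2L) stop("need at least 2 residues with CA atoms")
  d <- .pairwise_dist(ca, ca)
  idx <- which(upper.tri(d) & d <= threshold, arr.ind = TRUE)
  sep <- abs(idx[, 1] - idx[, 2])
  idx <- idx[sep >= min_sep, , drop = FALSE]
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = rownames(ca))
  if (nrow(idx) > 0L) {
    g <- igraph::add_edges(g, t(idx))
    igraph::E(g)$weight <- if (weighted) d[idx] else 1
  }
  g
}

.components_of <- function(graph) {
  comp <- igraph::components(graph)
  lapply(seq_len(comp$no), function(k)
    which(comp$membership == k))
}

#' Closeness centrality
#'
#' \eqn{(n-1) / \sum_v dist(u, v)} with unweighted shortest-path distances.
#' On a disconnected graph, n and the distances are local to the node's
#' connected component; single-node components are NA.
#'
#' @param graph RIN graph.
#' @param node Optional vertex index/indices (default all).
#' @return Numeric vector of closeness values.
#' @export
rin_closeness <- function(graph, node = NULL) {
  n <- igraph::vcount(graph)
  out <- rep(NA_real_, n)
  for (members in .components_of(graph)) {
    if (length(members) < 2L) next
    sub <- igraph::induced_subgraph(graph, members)
    d <- igraph::distances(sub, weights = NA)
    out[members] <- (length(members) - 1) / rowSums(d)
  }
  if (is.null(node)) out else out[node]
}

#' Eccentricity normalized to the network diameter
#'
#' A node's farthest shortest-path distance divided by the network diameter
#' (the maximum eccentricity), making values comparable across proteins.
#' Component-local on disconnected graphs; errors on a zero diameter.
#'
#' @inheritParams rin_closeness
#' @return Numeric vector in (0, 1].
#' @export
rin_eccentricity <- function(graph, node = NULL) {
  n <- igraph::vcount(graph)
  out <- rep(NA_real_, n)
  for (members in .components_of(graph)) {
    if (length(members) < 2L) {
      if (n == 1L) stop("single-node network has zero diameter")
      next
    }
    sub <- igraph::induced_subgraph(graph, members)
    ecc <- igraph::eccentricity(sub, weights = NA)
    diam <- max(ecc)
    if (diam == 0) stop("zero network diameter")
    out[members] <- ecc / diam
  }
  if (is.null(node)) out else out[node]
}

#' Eigenvector centrality
#'
#' Principal eigenvector of the adjacency matrix, non-negative and scaled to
#' unit Euclidean norm. Computed per connected component (each component's
#' sub-vector has unit norm).
#'
#' @param graph RIN graph.
#' @return Numeric vector over all vertices.
#' @export
rin_eigenvector <- function(graph) {
  n <- igraph::vcount(graph)
  out <- rep(NA_real_, n)
  for (members in .components_of(graph)) {
    if (length(members) < 2L) { out[members] <- 1; next }
    sub <- igraph::induced_subgraph(graph, members)
    v <- igraph::eigen_centrality(sub, weights = NA)$vector
    v <- abs(v)
    out[members] <- v / sqrt(sum(v^2))
  }
  out
}

#' Average nearest-neighbour degree
#'
#' Mean degree of a node's direct neighbours; NA for isolated nodes.
#'
#' @inheritParams rin_closeness
#' @return Numeric vector.
#' @export
rin_annd <- function(graph, node = NULL) {
  deg <- igraph::degree(graph)
  out <- vapply(seq_len(igraph::vcount(graph)), function(u) {
    nb <- igraph::neighbors(graph, u)
    if (length(nb) == 0L) return(NA_real_)
    mean(deg[nb])
  }, numeric(1))
  if (is.null(node)) out else out[node]
}

#' Degree, strength, clustering and betweenness
#'
#' Degree is the neighbour count; strength the sum of incident edge weights
#' (equal to degree under unit weights); clustering the local transitivity
#' (0 when degree < 2); betweenness the shortest-path betweenness normalized
#' by (n-1)(n-2)/2 with component-local n.
#'
#' @param graph RIN graph.
#' @return data.frame with columns \code{degree}, \code{strength},
#'   \code{clustering}, \code{betweenness}.
#' @export
rin_basic_centralities <- function(graph) {
  n <- igraph::vcount(graph)
  betw <- rep(NA_real_, n)
  for (members in .components_of(graph)) {
    if (length(members) < 2L) { betw[members] <- 0; next }
    sub <- igraph::induced_subgraph(graph, members)
    betw[members] <- igraph::betweenness(
      sub, weights = NA,
      normalized = length(members) > 2L)
  }
  data.frame(
    degree = igraph::degree(graph),
    strength = igraph::strength(graph),
    clustering = igraph::transitivity(graph, type = "localundirected",
                                      isolates = "zero", weights = NA),
    betweenness = betw
  )
}

#' All eight RIN centralities per residue
#'
#' @param graph RIN graph from \code{\link{build_rin}}.
#' @return data.frame with columns \code{residue_index}, \code{degree},
#'   \code{strength}, \code{clustering}, \code{closeness},
#'   \code{betweenness}, \code{eigenvector}, \code{eccentricity},
#'   \code{annd}.
#' @export
rin_centralities <- function(graph) {
  basic <- rin_basic_centralities(graph)
  nm <- igraph::vertex_attr(graph, "name")
  data.frame(
    residue_index = if (is.null(nm)) seq_len(igraph::vcount(graph))
                    else as.integer(nm),
    basic,
    closeness = rin_closeness(graph),
    eigenvector = rin_eigenvector(graph),
    eccentricity = rin_eccentricity(graph),
    annd = rin_annd(graph),
    row.names = NULL
  )
}
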