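# Hypergraph statistics: node- and hyperedge-level descriptors, clustering,
# assortativity, hypertriangles, and the null-model significance ratio.

#' Node hyperdegrees
#'
#' The hyperdegree of a node is the number of hyperedges it belongs to
#' (incidence-matrix row sum).
#'
#' @param H a `hypergraph`.
#' @return integer vector of length `n_nodes(H)`.
#' @export
hyperdegrees <- function(H) {
  tabulate(unlist(H$hyperedges, use.names = FALSE), nbins = n_nodes(H))
}

#' Hyperedge degrees
#'
#' The degree (cardinality) of each hyperedge: the number of nodes it contains
#' (incidence-matrix column sum).
#'
#' @param H a `hypergraph`.
#' @return integer vector of length `n_hyperedges(H)`.
#' @export
hyperedge_degrees <- function(H) lengths(H$hyperedges)

#' Projection degrees
#'
#' Number of distinct neighbors of each node in the unweighted clique
#' projection. This is the "degree" reported alongside the hyperdegree in
#' network summary tables.
#'
#' @param H a `hypergraph`.
#' @return integer vector of length n.
#' @export
projection_degrees <- function(H) {
  as.integer(rowSums(.pair_count_matrix(H) > 0))
}

#' Hyperdegree distribution
#'
#' Probability that a uniformly chosen node has hyperdegree k, for each
#' observed k.
#'
#' @param H a `hypergraph`.
#' @return named numeric vector (names are hyperdegree values) summing to 1.
#' @export
hyperdegree_distribution <- function(H) {
  tab <- table(hyperdegrees(H))
  p <- as.numeric(tab) / n_nodes(H)
  setNames(p, names(tab))
}

#' Per-hyperedge joint hyperdegree signature
#'
#' For each hyperedge, the sorted multiset of its members' hyperdegrees. The
#' H2k and H2.25k null models preserve this signature hyperedge by hyperedge.
#'
#' @param H a `hypergraph`.
#' @return list of sorted integer vectors, one per hyperedge.
#' @export
joint_hyperdegree_signature <- function(H) {
  d <- hyperdegrees(H)
  lapply(H$hyperedges, function(e) sort(d[e]))
}

#' Co-average hyperdegree
#'
#' For each node, the mean hyperdegree of its distinct neighbors in the
#' projection. Nodes without neighbors (members of singleton hyperedges only)
#' are reported as 0, with a message.
#'
#' @param H a `hypergraph`.
#' @return numeric vector of length n.
#' @export
co_average_hyperdegree <- function(H) {
  nb <- .neighbor_lists(H)
  d <- hyperdegrees(H)
  out <- vapply(nb, function(v) if (length(v)) mean(d[v]) else 0, numeric(1))
  if (any(lengths(nb) == 0L))
    message(sum(lengths(nb) == 0L), " node(s) isolated in the projection; ",
            "co-average hyperdegree reported as 0")
  out
}

#' Average neighbor degree
#'
#' For each node, the mean projection degree of its distinct projection
#' neighbors; `mean(average_neighbor_degree(H))` is the network-level value.
#' Isolated nodes are reported as 0, with a message.
#'
#' @param H a `hypergraph`.
#' @return numeric vector of length n.
#' @export
average_neighbor_degree <- function(H) {
  nb <- .neighbor_lists(H)
  deg <- lengths(nb)
  out <- vapply(nb, function(v) if (length(v)) mean(deg[v]) else 0, numeric(1))
  if (any(deg == 0L))
    message(sum(deg == 0L), " node(s) isolated in the projection; ",
            "average neighbor degree reported as 0")
  out
}

#' Node strength
#'
#' The strength of node i is the total number of hyperedges it shares with
#' other nodes, counted with multiplicity: the i-th row sum of the adjacency
#' matrix A.
#'
#' @param H a `hypergraph`.
#' @return integer vector of length n.
#' @export
node_strength <- function(H) {
  as.integer(rowSums(.pair_count_matrix(H)))
}

#' Local and mean clustering coefficients
#'
#' The clustering coefficient of a node is the fraction of pairs among its
#' distinct projection neighbors that are themselves connected (share a
#' hyperedge); nodes with fewer than two neighbors contribute 0. The
#' hypergraph clustering coefficient is the average over all n nodes.
#'
#' @param H a `hypergraph`.
#' @return `local_clustering`: numeric vector in `[0, 1]` of length n;
#'   `mean_clustering`: scalar.
#' @export
local_clustering <- function(H) {
  g <- projected_graph(H)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  # igraph returns NaN for degree-1 vertices under some versions; force 0
  cc[!is.finite(cc)] <- 0
  unname(cc)
}

#' @rdname local_clustering
#' @export
mean_clustering <- function(H) mean(local_clustering(H))

#' Degree assortativity of the projection
#'
#' Newman's assortativity coefficient evaluated over the M edges of the
#' unweighted projection,
#' \deqn{r = \frac{M^{-1}\sum_i j_i k_i - [M^{-1}\sum_i \frac12(j_i+k_i)]^2}{
#'            M^{-1}\sum_i \frac12(j_i^2+k_i^2) - [M^{-1}\sum_i \frac12(j_i+k_i)]^2}}
#' where \eqn{j_i, k_i} are the degrees at the two ends of edge i. Endpoint
#' degrees are projection degrees by default; `endpoint = "hyperdegree"`
#' evaluates the same formula with node hyperdegrees at the edge ends.
#'
#' @param H a `hypergraph`.
#' @param endpoint which degree to attach to edge endpoints.
#' @return scalar in `[-1, 1]`, or `NaN` (with a warning) when the endpoint
#'   degrees have zero variance over edges (e.g. a regular projection).
#' @export
hypergraph_assortativity <- function(H, endpoint = c("projection", "hyperdegree")) {
  endpoint <- match.arg(endpoint)
  adj <- .pair_count_matrix(H) > 0
  ends <- which(adj & upper.tri(adj), arr.ind = TRUE)
  M <- nrow(ends)
  if (M < 1L) stop("projection has no edges")
  deg <- if (endpoint == "projection") rowSums(adj) else hyperdegrees(H)
  j <- deg[ends[, 1L]]; k <- deg[ends[, 2L]]
  mid <- mean((j + k) / 2)
  num <- mean(j * k) - mid^2
  den <- mean((j^2 + k^2) / 2) - mid^2
  if (den <= .Machine$double.eps * max(1, mid^2)) {
    warning("assortativity undefined: endpoint degrees have zero variance")
    return(NaN)
  }
  num / den
}

#' Count hypertriangles
#'
#' A hypertriangle is a set of three distinct nodes \{u, v, w\} whose three
#' pairs are covered by three pairwise-distinct hyperedges, excluding triples
#' that lie entirely inside a single hyperedge. Existence of three distinct
#' covering hyperedges is a system-of-distinct-representatives condition over
#' the three pair-cover sets, checked by Hall's criterion.
#'
#' @param H a `hypergraph`.
#' @return integer count.
#' @export
count_hypertriangles <- function(H) {
  g <- projected_graph(H)
  tri <- igraph::triangles(g)
  if (length(tri) == 0L) return(0L)
  tri <- matrix(as.integer(tri), ncol = 3L, byrow = TRUE)
  d <- hyperdegrees(H)
  edges_of <- vector("list", n_nodes(H))
  for (j in seq_along(H$hyperedges))
    for (i in H$hyperedges[[j]]) edges_of[[i]] <- c(edges_of[[i]], j)
  count <- 0L
  for (t in seq_len(nrow(tri))) {
    u <- tri[t, 1L]; v <- tri[t, 2L]; w <- tri[t, 3L]
    Euv <- intersect(edges_of[[u]], edges_of[[v]])
    Evw <- intersect(edges_of[[v]], edges_of[[w]])
    Ewu <- intersect(edges_of[[w]], edges_of[[u]])
    # excluded when one hyperedge contains all three nodes (covering two of
    # the pairs implies covering the triple)
    if (length(intersect(Euv, Evw))) next
    # Hall's condition for a system of distinct representatives on 3 sets
    if (length(unique(c(Euv, Evw))) < 2L) next
    if (length(unique(c(Evw, Ewu))) < 2L) next
    if (length(unique(c(Euv, Ewu))) < 2L) next
    if (length(unique(c(Euv, Evw, Ewu))) < 3L) next
    count <- count + 1L
  }
  count
}

#' Null-model significance ratio
#'
#' The ratio mu = (statistic on the null model) / (statistic on the original
#' network). Deviation of mu from 1 quantifies how nontrivial the statistic is
#' relative to what the retained constraints alone produce.
#'
#' @param stat_null statistic value(s) on the null model.
#' @param stat_original statistic value(s) on the original network (nonzero).
#' @return numeric; `NA` with a warning where `stat_original == 0`.
#' @export
significance_mu <- function(stat_null, stat_original) {
  out <- stat_null / stat_original
  bad <- stat_original == 0
  if (any(bad)) {
    warning("significance ratio undefined where the original statistic is 0")
    out[bad] <- NA_real_
  }
  out
}

#' Full statistical report of a hypergraph
#'
#' Bundles the per-node vectors (hyperdegree, projection degree, clustering,
#' co-average hyperdegree, average neighbor degree, strength), the hyperedge
#' degree vector, the network scalars (mean degree, mean hyperdegree, mean
#' clustering, assortativity), the hyperdegree distribution and the joint
#' hyperdegree signatures.
#'
#' @param H a `hypergraph`.
#' @return a list of class `stat_report`.
#' @export
stat_report <- function(H) {
  pd <- projection_degrees(H)
  hd <- hyperdegrees(H)
  out <- list(
    n = n_nodes(H),
    m = n_hyperedges(H),
    hyperdegree = hd,
    projection_degree = pd,
    hyperedge_degree = hyperedge_degrees(H),
    local_clustering = local_clustering(H),
    co_average_hyperdegree = suppressMessages(co_average_hyperdegree(H)),
    average_neighbor_degree = suppressMessages(average_neighbor_degree(H)),
    strength = node_strength(H),
    mean_degree = mean(pd),
    mean_hyperdegree = mean(hd),
    mean_clustering = NA_real_,
    assortativity = suppressWarnings(hypergraph_assortativity(H)),
    hyperdegree_distribution = hyperdegree_distribution(H),
    joint_hyperdegree_signature = joint_hyperdegree_signature(H)
  )
  out$mean_clustering <- mean(out$local_clustering)
  class(out) <- "stat_report"
  out
}

#' @export
print.stat_report <- function(x, ...) {
  cat("hypergraph statistics\n")
  cat(sprintf("  n = %d nodes, m = %d hyperedges\n", x$n, x$m))
  cat(sprintf("  mean degree <k>        = %.3f\n", x$mean_degree))
  cat(sprintf("  mean hyperdegree <kH>  = %.3f\n", x$mean_hyperdegree))
  cat(sprintf("  mean clustering C      = %.3f\n", x$mean_clustering))
  cat(sprintf("  assortativity r        = %.3f\n", x$assortativity))
  invisible(x)
}
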