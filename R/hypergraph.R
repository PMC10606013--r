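#' hypernull: hyperedge-swapping null models for hypergraphs
#'
#' Build degree-constrained null models of a hypergraph by in-place hyperedge
#' swaps on its incidence matrix, quantify their randomness by the entropy of
#' the hyperdegree distribution, and compare original and randomized networks
#' through topological statistics, dismantling, and threshold SIR contagion.
#'
#' @useDynLib hypernull, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rbinom runif sd setNames
#' @importFrom utils head
#' @keywords internal
"_PACKAGE"

# ---- construction -----------------------------------------------------------

#' Build a hypergraph from labelled hyperedges
#'
#' A hypergraph is a node set \eqn{V} (n nodes) together with m hyperedges,
#' each a non-empty subset of \eqn{V} whose union covers \eqn{V}. Nodes are
#' stored internally as integer indices `1..n` against a sorted label map, so
#' all numeric machinery is independent of the dataset's labelling convention.
#' Duplicate hyperedges are permitted (swap-based randomization never forbids
#' them); a duplicated label *within* one hyperedge is collapsed to a single
#' membership, with a message.
#'
#' @param raw_hyperedges list of vectors of node labels (coerced to character),
#'   one element per hyperedge.
#' @return An object of class `hypergraph`: a list with `node_labels`
#'   (character, length n) and `hyperedges` (list of sorted integer index
#'   vectors, length m).
#' @examples
#' H <- hypergraph(list(c("a", "b", "c"), c("c", "d"), c("a", "d")))
#' n_nodes(H); n_hyperedges(H)
#' @export
hypergraph <- function(raw_hyperedges) {
  if (!is.list(raw_hyperedges)) raw_hyperedges <- as.list(raw_hyperedges)
  if (length(raw_hyperedges) == 0L) stop("a hypergraph needs at least one hyperedge")
  raw_hyperedges <- lapply(raw_hyperedges, as.character)
  sizes <- lengths(raw_hyperedges)
  if (any(sizes == 0L)) {
    stop("empty hyperedge at position ", which(sizes == 0L)[1L],
         ": every hyperedge must be a non-empty subset of the node set")
  }
  n_dup <- sum(vapply(raw_hyperedges, anyDuplicated, 0L) > 0L)
  if (n_dup > 0L) {
    message("collapsed duplicated node labels within ", n_dup,
            " hyperedge(s) (hyperedges have set semantics)")
    raw_hyperedges <- lapply(raw_hyperedges, unique)
  }
  labels <- sort(unique(unlist(raw_hyperedges, use.names = FALSE)))
  edges <- lapply(raw_hyperedges, function(e) sort(match(e, labels)))
  new_hypergraph(labels, edges)
}

# Low-level constructor from integer index edges; validates all invariants.
new_hypergraph <- function(node_labels, hyperedges) {
  n <- length(node_labels)
  stopifnot(n >= 1L, length(hyperedges) >= 1L)
  hyperedges <- lapply(hyperedges, function(e) sort(as.integer(e)))
  idx <- unlist(hyperedges, use.names = FALSE)
  if (any(lengths(hyperedges) == 0L)) stop("empty hyperedge")
  if (min(idx) < 1L || max(idx) > n) stop("node index out of range")
  if (any(vapply(hyperedges, anyDuplicated, 0L) > 0L))
    stop("repeated node within a hyperedge")
  if (length(unique(idx)) != n)
    stop("every node must appear in at least one hyperedge (union of hyperedges = V)")
  structure(list(node_labels = as.character(node_labels), hyperedges = hyperedges),
            class = "hypergraph")
}

#' @rdname hypergraph
#' @param H a `hypergraph`.
#' @export
n_nodes <- function(H) length(H$node_labels)

#' @rdname hypergraph
#' @export
n_hyperedges <- function(H) length(H$hyperedges)

#' @export
print.hypergraph <- function(x, ...) {
  cat("hypergraph: ", n_nodes(x), " nodes, ", n_hyperedges(x), " hyperedges; ",
      "hyperedge sizes ", min(lengths(x$hyperedges)), "-",
      max(lengths(x$hyperedges)), "\n", sep = "")
  invisible(x)
}

#' Compare two hypergraphs as labelled edge multisets
#'
#' Two hypergraphs are considered identical when they have the same node label
#' set and the same multiset of hyperedges (as label sets), optionally ignoring
#' the order in which hyperedges are listed.
#'
#' @param a,b hypergraphs.
#' @param ignore_edge_order compare hyperedges as an unordered multiset
#'   (default `TRUE`).
#' @return logical.
#' @export
hypergraph_identical <- function(a, b, ignore_edge_order = TRUE) {
  if (!identical(sort(a$node_labels), sort(b$node_labels))) return(FALSE)
  key <- function(H) {
    k <- unname(vapply(H$hyperedges,
                       function(e) paste(sort(H$node_labels[e]), collapse = "\r"),
                       character(1)))
    if (ignore_edge_order) sort(k) else k
  }
  identical(key(a), key(b))
}

# ---- matrices ---------------------------------------------------------------

#' Incidence matrix of a hypergraph
#'
#' The n x m binary matrix C with `C[i, j] = 1` iff node i belongs to
#' hyperedge j. Row sums are the node hyperdegrees, column sums the hyperedge
#' degrees. Realized sparsely (a `Matrix::sparseMatrix`) once `n * m` exceeds
#' `sparse_threshold`; values are identical either way.
#'
#' @param H a `hypergraph`.
#' @param sparse logical or `NULL` (auto by size).
#' @param sparse_threshold element count above which the sparse form is used.
#' @return n x m 0/1 matrix with node labels as rownames.
#' @export
incidence_matrix <- function(H, sparse = NULL, sparse_threshold = 1e6) {
  n <- n_nodes(H); m <- n_hyperedges(H)
  if (is.null(sparse)) sparse <- (as.double(n) * m) > sparse_threshold
  i <- unlist(H$hyperedges, use.names = FALSE)
  j <- rep.int(seq_len(m), lengths(H$hyperedges))
  dn <- list(H$node_labels, paste0("e", seq_len(m)))
  if (sparse) {
    Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, m), dimnames = dn)
  } else {
    C <- matrix(0L, n, m, dimnames = dn)
    C[cbind(i, j)] <- 1L
    C
  }
}

# dense integer incidence used by the C++ swap engine
.dense_incidence <- function(H) {
  n <- n_nodes(H); m <- n_hyperedges(H)
  C <- matrix(0L, n, m)
  C[cbind(unlist(H$hyperedges, use.names = FALSE),
          rep.int(seq_len(m), lengths(H$hyperedges)))] <- 1L
  C
}

.hypergraph_from_incidence <- function(C, node_labels) {
  edges <- lapply(seq_len(ncol(C)), function(j) which(C[, j] != 0))
  new_hypergraph(node_labels, edges)
}

#' Hypergraph adjacency matrix A = C C' - D
#'
#' `A[i, j]` counts the hyperedges containing both node i and node j (so
#' entries can exceed 1 when two nodes co-occur in several hyperedges); the
#' diagonal is exactly zero. D is the hyperdegree matrix, whose diagonal holds
#' the node hyperdegrees, so subtracting it from `C %*% t(C)` removes the
#' self-co-occurrence counts. The row sums of A are the node strengths.
#'
#' @inheritParams incidence_matrix
#' @return symmetric n x n integer-valued matrix with zero diagonal.
#' @export
adjacency_matrix <- function(H, sparse = NULL) {
  C <- incidence_matrix(H, sparse = sparse)
  A <- Matrix::tcrossprod(C)
  diag(A) <- 0
  A
}

#' Hyperedge adjacency matrix B = C'C - De
#'
#' `B[j, k]` is the number of nodes shared by hyperedges j and k; De is the
#' diagonal matrix of hyperedge degrees, so the diagonal of B is zero.
#'
#' @inheritParams incidence_matrix
#' @return symmetric m x m matrix with zero diagonal.
#' @export
hyperedge_adjacency_matrix <- function(H, sparse = NULL) {
  C <- incidence_matrix(H, sparse = sparse)
  B <- Matrix::crossprod(C)
  diag(B) <- 0
  B
}

#' Degree matrices D and De
#'
#' `D[i, j]` is the number of hyperedges containing both nodes i and j, with
#' the node hyperdegree on the diagonal; `De[j, k]` is the number of nodes in
#' both hyperedges j and k, with the hyperedge degree on the diagonal.
#'
#' @inheritParams incidence_matrix
#' @return list with components `D` (n x n) and `De` (m x m).
#' @export
degree_matrices <- function(H, sparse = NULL) {
  C <- incidence_matrix(H, sparse = sparse)
  list(D = Matrix::tcrossprod(C), De = Matrix::crossprod(C))
}

# ---- projection & connectivity ---------------------------------------------

#' Unweighted clique projection of a hypergraph
#'
#' The simple undirected graph on V in which two nodes are linked iff they
#' share at least one hyperedge (no self-loops; multiplicity of shared
#' hyperedges is ignored). Most node-level statistics (degree, clustering,
#' neighbor averages, assortativity) are evaluated on this projection.
#'
#' @param H a `hypergraph`.
#' @return an [igraph::graph] with vertex names equal to `node_labels`.
#' @export
projected_graph <- function(H) {
  A <- adjacency_matrix(H)
  igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected", diag = FALSE)
}

# adjacency (pair-count) as base dense matrix, for small-n statistics
.pair_count_matrix <- function(H) {
  as.matrix(adjacency_matrix(H, sparse = NULL))
}

# neighbor index lists in the projection
.neighbor_lists <- function(H) {
  A <- .pair_count_matrix(H) > 0
  lapply(seq_len(nrow(A)), function(i) which(A[i, ]))
}

#' Size of the giant connected component after removals
#'
#' Connectivity is defined through the projection: two surviving nodes are
#' connected when they share a surviving hyperedge. Component structure is
#' computed on the node-hyperedge bipartite (star) expansion, which has the
#' same node components as the clique projection without materializing cliques.
#' Isolated surviving nodes count as components of size 1.
#'
#' @param H a `hypergraph`.
#' @param removed_nodes integer node indices removed from the network.
#' @param removed_hyperedges integer hyperedge indices removed.
#' @return integer: number of nodes in the largest surviving component
#'   (0 when every node is removed).
#' @export
giant_component_size <- function(H, removed_nodes = integer(),
                                 removed_hyperedges = integer()) {
  n <- n_nodes(H); m <- n_hyperedges(H)
  removed_nodes <- as.integer(removed_nodes)
  removed_hyperedges <- as.integer(removed_hyperedges)
  stopifnot(all(removed_nodes %in% seq_len(n) | length(removed_nodes) == 0L),
            all(removed_hyperedges %in% seq_len(m) | length(removed_hyperedges) == 0L))
  node_alive <- rep(TRUE, n); node_alive[removed_nodes] <- FALSE
  edge_alive <- rep(TRUE, m); edge_alive[removed_hyperedges] <- FALSE
  if (!any(node_alive)) return(0L)
  pairs <- lapply(which(edge_alive), function(j) {
    mem <- H$hyperedges[[j]]
    mem <- mem[node_alive[mem]]
    if (length(mem) == 0L) return(NULL)
    cbind(mem, n + j)  # star expansion: node vertex -- edge vertex
  })
  el <- do.call(rbind, pairs)
  g <- igraph::make_empty_graph(n = n + m, directed = FALSE)
  if (!is.null(el)) g <- igraph::add_edges(g, t(el))
  comp <- igraph::components(g)
  memb <- comp$membership[seq_len(n)][node_alive]
  max(tabulate(memb, nbins = comp$no))
}
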