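# Shared fixtures and brute-force oracles, deliberately independent of the
# package's own computation paths.

# T1: 4 nodes, 3 hyperedges {1,2,3}, {3,4}, {1,4}
T1 <- function() hypergraph(list(c("1", "2", "3"), c("3", "4"), c("1", "4")))

# hub-and-spokes of dyads {c, x1} ... {c, x9}
star_of_dyads <- function(k = 9) {
  hypergraph(lapply(paste0("x", seq_len(k)), function(x) c("c", x)))
}

random_hypergraph <- function(n, m, seed, ...) {
  generate_synthetic_hypergraph(
    n = n, m = m,
    size_probs = c("2" = 0.3, "3" = 0.3, "4" = 0.2, "5" = 0.1, "6" = 0.1),
    rng_seed = seed, ...)
}

# pair-count matrix by direct enumeration over hyperedges
oracle_pair_counts <- function(H) {
  n <- n_nodes(H)
  A <- matrix(0, n, n)
  for (e in H$hyperedges) {
    if (length(e) < 2) next
    for (a in seq_along(e)) for (b in seq_along(e)) {
      if (a != b) A[e[a], e[b]] <- A[e[a], e[b]] + 1
    }
  }
  A
}

# hyperedge intersection sizes by direct set intersection
oracle_intersections <- function(H) {
  m <- n_hyperedges(H)
  B <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j) B[i, j] <- length(intersect(H$hyperedges[[i]], H$hyperedges[[j]]))
  }
  B
}

# size of the largest component of the surviving projection, by BFS over a
# neighbor structure built from scratch
oracle_gcc <- function(H, removed_nodes = integer(), removed_hyperedges = integer()) {
  n <- n_nodes(H)
  alive <- setdiff(seq_len(n), removed_nodes)
  if (length(alive) == 0) return(0L)
  nb <- lapply(seq_len(n), function(i) integer())
  for (j in setdiff(seq_len(n_hyperedges(H)), removed_hyperedges)) {
    mem <- intersect(H$hyperedges[[j]], alive)
    for (u in mem) nb[[u]] <- union(nb[[u]], setdiff(mem, u))
  }
  seen <- rep(FALSE, n)
  best <- 0L
  for (s in alive) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; size <- 0L
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]; size <- size + 1L
      fresh <- nb[[u]][!seen[nb[[u]]]]
      seen[fresh] <- TRUE
      queue <- c(queue, fresh)
    }
    best <- max(best, size)
  }
  best
}

# hypertriangle count by exhaustive enumeration of node triples and ordered
# hyperedge triples
oracle_hypertriangles <- function(H) {
  n <- n_nodes(H); m <- n_hyperedges(H)
  if (n < 3 || m < 3) return(0L)
  count <- 0L
  has <- function(e, v) v %in% H$hyperedges[[e]]
  for (u in 1:(n - 2)) for (v in (u + 1):(n - 1)) for (w in (v + 1):n) {
    contained <- any(vapply(seq_len(m),
                            function(e) has(e, u) && has(e, v) && has(e, w),
                            logical(1)))
    if (contained) next
    found <- FALSE
    for (e1 in seq_len(m)) {
      if (!(has(e1, u) && has(e1, v))) next
      for (e2 in seq_len(m)) {
        if (e2 == e1 || !(has(e2, v) && has(e2, w))) next
        for (e3 in seq_len(m)) {
          if (e3 == e1 || e3 == e2 || !(has(e3, w) && has(e3, u))) next
          found <- TRUE; break
        }
        if (found) break
      }
      if (found) break
    }
    if (found) count <- count + 1L
  }
  count
}

# mean clustering by direct neighbor-pair counting on the unweighted projection
oracle_mean_clustering <- function(H) {
  A <- oracle_pair_counts(H) > 0
  n <- n_nodes(H)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ])
    if (length(nb) < 2) return(0)
    pairs <- utils::combn(nb, 2)
    mean(A[cbind(pairs[1, ], pairs[2, ])])
  }, numeric(1))
  mean(vals)
}
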