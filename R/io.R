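# File formats, synthetic hypergraph generation, and reference fixtures.
#
# Two on-disk formats are supported:
#  * hyperedge list: one hyperedge per line, node labels separated by
#    whitespace or commas, `#` starts a comment;
#  * simplex pair:   <name>-nverts.txt (one hyperedge size per line) and
#    <name>-simplices.txt (concatenated 1-based node ids), the layout used by
#    public higher-order network dataset repositories.

#' Read a hypergraph from a file
#'
#' @param path for `edgelist`, the file; for `simplex`, either the common base
#'   path (`<base>` expanded to `<base>-nverts.txt` / `<base>-simplices.txt`)
#'   or the path of one of the two files.
#' @param format `"edgelist"` or `"simplex"`.
#' @return a `hypergraph`; original labels are preserved (simplex node ids
#'   become their decimal string labels).
#' @export
read_hypergraph <- function(path, format = c("edgelist", "simplex")) {
  format <- match.arg(format)
  if (format == "edgelist") .read_edgelist(path) else .read_simplex(path)
}

.read_edgelist <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  stripped <- sub("#.*$", "", lines)
  keep <- which(trimws(stripped) != "")
  if (length(keep) == 0L) stop("no hyperedges in ", path)
  edges <- lapply(keep, function(ln) {
    line <- trimws(stripped[ln])
    # a comma anywhere makes the line comma-delimited (labels may then
    # contain spaces); otherwise split on whitespace
    toks <- if (grepl(",", line, fixed = TRUE))
      trimws(strsplit(line, ",", fixed = TRUE)[[1L]])
    else strsplit(line, "[[:space:]]+")[[1L]]
    toks <- toks[toks != ""]
    if (length(toks) == 0L)
      stop("empty hyperedge at line ", ln, " of ", path)
    toks
  })
  hypergraph(edges)
}

.simplex_paths <- function(path) {
  base <- sub("-(nverts|simplices)\\.txt$", "", path)
  list(nverts = paste0(base, "-nverts.txt"),
       simplices = paste0(base, "-simplices.txt"))
}

.read_simplex <- function(path) {
  p <- .simplex_paths(path)
  if (!file.exists(p$nverts)) stop("file not found: ", p$nverts)
  if (!file.exists(p$simplices)) stop("file not found: ", p$simplices)
  nverts <- scan(p$nverts, what = integer(), quiet = TRUE)
  ids <- scan(p$simplices, what = integer(), quiet = TRUE)
  if (sum(nverts) != length(ids))
    stop("inconsistent simplex files: sizes sum to ", sum(nverts),
         " but ", length(ids), " node ids were listed")
  if (any(nverts < 1L)) stop("empty hyperedge in ", p$nverts)
  stops <- cumsum(nverts)
  starts <- c(1L, head(stops, -1L) + 1L)
  edges <- mapply(function(a, b) as.character(ids[a:b]), starts, stops,
                  SIMPLIFY = FALSE)
  hypergraph(edges)
}

#' Write a hypergraph to a file
#'
#' `read_hypergraph(write_hypergraph(H, ...))` round-trips `H` up to hyperedge
#' order. The hyperedge-list writer separates labels with a space, switching
#' to commas automatically when any label contains whitespace; the simplex
#' writer emits 1-based node ids in the current internal node order.
#'
#' @param H a `hypergraph`.
#' @param path output path (for `simplex`, the base path).
#' @param format `"edgelist"` or `"simplex"`.
#' @return `path`, invisibly.
#' @export
write_hypergraph <- function(H, path, format = c("edgelist", "simplex")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    sep <- if (any(grepl("[[:space:]]", H$node_labels))) "," else " "
    lines <- vapply(H$hyperedges,
                    function(e) paste(H$node_labels[e], collapse = sep),
                    character(1))
    writeLines(lines, path)
  } else {
    p <- .simplex_paths(path)
    writeLines(as.character(lengths(H$hyperedges)), p$nverts)
    writeLines(as.character(unlist(H$hyperedges, use.names = FALSE)),
               p$simplices)
  }
  invisible(path)
}

#' Generate a random hypergraph
#'
#' Draws `m` hyperedge sizes (a constant size, or sizes sampled from a
#' discrete distribution) and fills each hyperedge by sampling nodes without
#' replacement — uniformly by default, or with probability proportional to
#' `rank^(-node_weight_exponent)` to produce hyperdegree-heterogeneous
#' networks. Any node left uncovered is appended to a uniformly chosen
#' hyperedge so that the union of hyperedges is the full node set. A sampled
#' size larger than n is resampled (up to 100 times, then capped at n with a
#' warning).
#'
#' @param n number of nodes (labels `"v1" ... "vn"`).
#' @param m number of hyperedges.
#' @param sizes a single integer (constant hyperedge size) — ignored when
#'   `size_probs` is given.
#' @param size_probs optional named numeric vector of hyperedge-size
#'   probabilities (names are sizes); normalized internally.
#' @param node_weight_exponent Zipf exponent for member sampling weights
#'   (default 0 = uniform).
#' @param rng_seed optional seed for reproducibility.
#' @return a `hypergraph` with n nodes and m hyperedges.
#' @examples
#' H <- generate_synthetic_hypergraph(n = 50, m = 100, rng_seed = 1)
#' @export
generate_synthetic_hypergraph <- function(n, m, sizes = 3L, size_probs = NULL,
                                          node_weight_exponent = 0,
                                          rng_seed = NULL) {
  stopifnot(n >= 1L, m >= 1L)
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  draw_size <- if (is.null(size_probs)) {
    stopifnot(length(sizes) == 1L, sizes >= 1L)
    function() as.integer(sizes)
  } else {
    vals <- as.integer(names(size_probs))
    stopifnot(!anyNA(vals), all(vals >= 1L))
    function() sample(vals, 1L, prob = size_probs)
  }
  w <- seq_len(n)^(-node_weight_exponent)
  edges <- vector("list", m)
  capped <- FALSE
  for (j in seq_len(m)) {
    s <- draw_size()
    tries <- 0L
    while (s > n && tries < 100L) { s <- draw_size(); tries <- tries + 1L }
    if (s > n) { s <- n; capped <- TRUE }
    edges[[j]] <- sort(sample.int(n, s, prob = w))
  }
  if (capped) warning("hyperedge sizes larger than n capped at n")
  uncovered <- setdiff(seq_len(n), unique(unlist(edges, use.names = FALSE)))
  for (v in uncovered) {
    j <- sample.int(m, 1L)
    edges[[j]] <- sort(c(edges[[j]], v))
  }
  new_hypergraph(paste0("v", seq_len(n)), edges)
}

#' Path hypergraph of dyads
#'
#' A deterministic connected fixture: nodes `v1 ... vn` joined by the `n - 1`
#' dyadic hyperedges `{v1,v2}, {v2,v3}, ...`.
#'
#' @param n number of nodes (>= 2).
#' @return a `hypergraph`.
#' @export
path_hypergraph <- function(n) {
  stopifnot(n >= 2L)
  new_hypergraph(paste0("v", seq_len(n)),
                 lapply(seq_len(n - 1L), function(i) c(i, i + 1L)))
}

#' Five-node, four-hyperedge toy hypergraph
#'
#' A small worked-example hypergraph with nodes `v1 ... v5` and hyperedges
#' `e1 = {v3, v4}`, `e2 = {v2, v5}`, `e3 = {v1, v5}`, `e4 = {v1, v2, v3}`.
#' It realizes the textbook hypertriangle configuration: the nodes
#' `v1, v2, v5` form a hypertriangle through the three distinct hyperedges
#' `e4, e2, e3`, while `v1, v2, v3` do not (they lie inside the single
#' hyperedge `e4`). The exact membership of a published drawing of this
#' configuration is underdetermined; this fixture is a reconstruction chosen
#' to satisfy every stated constraint, not ground truth.
#'
#' @return a `hypergraph` with n = 5 and m = 4.
#' @export
toy_figure1_hypergraph <- function() {
  new_hypergraph(paste0("v", 1:5),
                 list(c(3L, 4L), c(2L, 5L), c(1L, 5L), c(1L, 2L, 3L)))
}
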