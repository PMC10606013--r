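# Hyperedge-swapping null models: the six-model hierarchy
# H0k <= {H1k-HD, H1k-HED} <= HD-HED <= H2k <= H2.25k <= original,
# each preserving a growing set of constraints of the original hypergraph.

.MODEL_NAMES <- c("H0k", "H1k-HD", "H1k-HED", "HD-HED", "H2k", "H2.25k")

#' Names of the available null models
#'
#' The hierarchy, ordered from most to least random: `H0k` preserves n, m and
#' the total membership count (hence the mean hyperdegree); `H1k-HD` the full
#' hyperdegree vector; `H1k-HED` the hyperedge-degree vector; `HD-HED` both
#' degree vectors; `H2k` additionally the per-hyperedge joint hyperdegree
#' signature; `H2.25k` additionally the mean clustering coefficient.
#'
#' @return character vector of the six model names.
#' @export
hyper_null_models <- function() .MODEL_NAMES

.model_code <- function(model) {
  model <- match.arg(model, .MODEL_NAMES)
  match(model, .MODEL_NAMES) - 1L
}

#' Generate a null model by repeated hyperedge swaps
#'
#' Starting from a deep copy of `H`, applies `n_swaps` *accepted* swaps of the
#' configured type; each accepted swap is preceded by at most
#' `max_attempts_per_swap` random candidate swaps (a rejected candidate leaves
#' the hypergraph untouched). A swap is always rejected when it would empty a
#' hyperedge or drop a node out of every hyperedge, so the result is a valid
#' hypergraph at all times. The default number of swaps is 10 times the number
#' of hyperedges, past the point where the randomness of the ensemble
#' plateaus.
#'
#' @param H a `hypergraph`.
#' @param model one of [hyper_null_models()].
#' @param n_swaps number of accepted swaps (default `10 * n_hyperedges(H)`).
#' @param max_attempts_per_swap attempt cap per accepted swap (default 100).
#' @param cc_tolerance H2.25k only: maximum allowed change of the mean
#'   clustering coefficient per accepted swap (default `1e-12`).
#' @param rng_seed optional integer; when given, `set.seed(rng_seed)` is
#'   called so that generation is exactly reproducible.
#' @param checkpoints optional non-decreasing integer vector of accepted-swap
#'   counts at which to snapshot the hyperdegree vector (used for entropy
#'   trajectories).
#' @return list with components `hypergraph` (the randomized copy; `H` itself
#'   is never modified) and `log` (a `swap_log` with attempt/acceptance
#'   counts, and `snapshots` when checkpoints were requested). If the attempt
#'   budget is exhausted before `n_swaps` acceptances a warning is issued and
#'   the partial result returned.
#' @examples
#' H <- generate_synthetic_hypergraph(n = 30, m = 60, rng_seed = 1)
#' nm <- generate_null_model(H, "H1k-HD", rng_seed = 7)
#' identical(hyperdegrees(nm$hypergraph), hyperdegrees(H))
#' @export
generate_null_model <- function(H, model = hyper_null_models(),
                                n_swaps = NULL, max_attempts_per_swap = 100L,
                                cc_tolerance = 1e-12, rng_seed = NULL,
                                checkpoints = NULL) {
  stopifnot(inherits(H, "hypergraph"))
  code <- .model_code(model)
  m <- n_hyperedges(H)
  if (is.null(n_swaps)) n_swaps <- 10L * m
  n_swaps <- as.integer(n_swaps)
  stopifnot(n_swaps >= 0L, max_attempts_per_swap >= 1L, cc_tolerance >= 0)
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  cps <- if (is.null(checkpoints)) integer() else as.integer(sort(checkpoints))
  res <- cpp_generate_null(.dense_incidence(H), code, n_swaps,
                           as.integer(max_attempts_per_swap),
                           as.numeric(cc_tolerance), cps)
  out <- .hypergraph_from_incidence(res$incidence, H$node_labels)
  log <- structure(
    list(model = .MODEL_NAMES[code + 1L],
         requested = n_swaps,
         accepted = res$accepted,
         attempted = res$attempted,
         rejected_equal = res$rejected_equal,
         rejected_empty = res$rejected_empty,
         rejected_membership = res$rejected_membership,
         rejected_cc = res$rejected_cc,
         exhausted = res$exhausted),
    class = "swap_log")
  if (length(cps)) {
    log$snapshots <- res$snapshots
    colnames(log$snapshots) <- cps
  }
  if (res$exhausted) {
    warning(sprintf(
      "attempt budget exhausted after %d of %d accepted %s swaps; partial null model returned",
      res$accepted, n_swaps, log$model))
  }
  list(hypergraph = out, log = log)
}

#' @export
print.swap_log <- function(x, ...) {
  cat(sprintf("swap log [%s]: %d/%d accepted in %.0f attempts\n",
              x$model, x$accepted, x$requested, x$attempted))
  cat(sprintf("  rejections: equal-entries %.0f, would-empty %.0f, membership %.0f, clustering %.0f\n",
              x$rejected_equal, x$rejected_empty, x$rejected_membership, x$rejected_cc))
  invisible(x)
}

# single candidate swap of the given type; returns the (possibly unchanged)
# hypergraph plus an acceptance flag
.attempt_swap <- function(H, model, cc_tolerance = 1e-12) {
  res <- suppressWarnings(
    generate_null_model(H, model, n_swaps = 1L, max_attempts_per_swap = 1L,
                        cc_tolerance = cc_tolerance))
  list(hypergraph = res$hypergraph, accepted = res$log$accepted == 1L,
       log = res$log)
}

#' Single swap attempts
#'
#' One random candidate swap of the given model type. Rejection is a normal
#' outcome (the hypergraph is returned unchanged); acceptance applies exactly
#' one swap. These are the elementary moves iterated by
#' [generate_null_model()].
#'
#' @param H a `hypergraph`.
#' @param cc_tolerance for `attempt_swap_h2_25k`: allowed mean-clustering
#'   change.
#' @return list with `hypergraph`, logical `accepted`, and the `log`.
#' @export
attempt_swap_h0k <- function(H) .attempt_swap(H, "H0k")

#' @rdname attempt_swap_h0k
#' @export
attempt_swap_h1k_hd <- function(H) .attempt_swap(H, "H1k-HD")

#' @rdname attempt_swap_h0k
#' @export
attempt_swap_h1k_hed <- function(H) .attempt_swap(H, "H1k-HED")

#' @rdname attempt_swap_h0k
#' @export
attempt_swap_hd_hed <- function(H) .attempt_swap(H, "HD-HED")

#' @rdname attempt_swap_h0k
#' @export
attempt_swap_h2k <- function(H) .attempt_swap(H, "H2k")

#' @rdname attempt_swap_h0k
#' @export
attempt_swap_h2_25k <- function(H, cc_tolerance = 1e-12)
  .attempt_swap(H, "H2.25k", cc_tolerance = cc_tolerance)

#' Verify the preservation hierarchy on generated instances
#'
#' Generates one instance of each null model from `H` and reports which
#' quantities it preserved: node and hyperedge counts, total membership count,
#' the hyperdegree vector, the hyperedge-degree vector, the per-hyperedge
#' joint hyperdegree signature, and the mean clustering coefficient (within
#' `cc_tolerance`). Higher-order models should preserve every invariant of
#' the models they contain.
#'
#' @param H a `hypergraph`.
#' @param rng_seed optional seed for reproducibility.
#' @param n_swaps accepted swaps per model (default `10 * m`).
#' @param cc_tolerance tolerance used both by H2.25k generation and by the
#'   clustering comparison column.
#' @return data.frame with one row per model and logical preservation columns.
#' @export
hierarchy_check <- function(H, rng_seed = NULL, n_swaps = NULL,
                            cc_tolerance = 1e-12) {
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  hd0 <- hyperdegrees(H)
  hed0 <- hyperedge_degrees(H)
  sig0 <- joint_hyperdegree_signature(H)
  cc0 <- mean_clustering(H)
  memb0 <- sum(hed0)
  rows <- lapply(hyper_null_models(), function(mod) {
    nm <- suppressWarnings(
      generate_null_model(H, mod, n_swaps = n_swaps,
                          cc_tolerance = cc_tolerance))$hypergraph
    data.frame(
      model = mod,
      counts = n_nodes(nm) == n_nodes(H) && n_hyperedges(nm) == n_hyperedges(H),
      memberships = sum(hyperedge_degrees(nm)) == memb0,
      hyperdegree_vector = identical(hyperdegrees(nm), hd0),
      hyperedge_degree_vector = identical(hyperedge_degrees(nm), hed0),
      joint_signature = identical(joint_hyperdegree_signature(nm), sig0),
      mean_clustering = abs(mean_clustering(nm) - cc0) <= cc_tolerance,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
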