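# Dynamics on hypergraphs: greedy dismantling (by nodes or hyperedges) with
# GCC curves and AUC, and a threshold SIR contagion process where hyperedges
# become infectious once enough of their members are.

.dismantling_result <- function(order, curve, auc, target, by) {
  structure(list(removal_order = order, gcc_curve = curve,
                 n_removed = length(order), auc = auc,
                 target_fraction = target, by = by),
            class = "dismantling_result")
}

#' @export
print.dismantling_result <- function(x, ...) {
  cat(sprintf("dismantling by %s: %d removed, final GCC fraction %.3f, AUC %.3f\n",
              x$by, x$n_removed,
              if (length(x$gcc_curve)) x$gcc_curve[length(x$gcc_curve)] else NA_real_,
              x$auc))
  invisible(x)
}

#' Dismantle a hypergraph by removing nodes
#'
#' Static greedy dismantling: nodes are ranked once by hyperdegree
#' (descending, ties by index) and removed one at a time; after each removal
#' the giant-connected-component (GCC) fraction of the projection is recorded.
#' Removal stops as soon as the GCC size falls below
#' `target_fraction * n` (no removal happens if it already is). The AUC is the
#' plain sum of the recorded GCC fractions: a larger AUC means the network
#' resists dismantling longer.
#'
#' @param H a `hypergraph`.
#' @param target_fraction GCC size target as a fraction of n, in (0, 1]
#'   (default 0.01).
#' @return a `dismantling_result` with `removal_order`, `gcc_curve` (GCC/n
#'   after each removal), `n_removed` and `auc`.
#' @export
dismantle_by_nodes <- function(H, target_fraction = 0.01) {
  stopifnot(target_fraction > 0, target_fraction <= 1)
  n <- n_nodes(H)
  target <- target_fraction * n
  ord <- order(-hyperdegrees(H), seq_len(n))
  removed <- integer(); curve <- numeric()
  gcc <- giant_component_size(H)
  for (v in ord) {
    if (gcc < target) break
    removed <- c(removed, v)
    gcc <- giant_component_size(H, removed_nodes = removed)
    curve <- c(curve, gcc / n)
  }
  .dismantling_result(removed, curve, sum(curve), target_fraction, "nodes")
}

#' Dismantle a hypergraph by removing hyperedges
#'
#' As [dismantle_by_nodes()], but the static ranking is over hyperedges by
#' hyperedge degree (descending, ties by index) and removals delete
#' hyperedges; nodes that lose all their hyperedges remain as isolated
#' components of size 1. If every hyperedge is removed without reaching the
#' target, the full curve is returned with a warning.
#'
#' @inheritParams dismantle_by_nodes
#' @return a `dismantling_result`.
#' @export
dismantle_by_hyperedges <- function(H, target_fraction = 0.01) {
  stopifnot(target_fraction > 0, target_fraction <= 1)
  n <- n_nodes(H); m <- n_hyperedges(H)
  target <- target_fraction * n
  ord <- order(-hyperedge_degrees(H), seq_len(m))
  removed <- integer(); curve <- numeric()
  gcc <- giant_component_size(H)
  for (e in ord) {
    if (gcc < target) break
    removed <- c(removed, e)
    gcc <- giant_component_size(H, removed_hyperedges = removed)
    curve <- c(curve, gcc / n)
  }
  if (gcc >= target)
    warning("all hyperedges removed before the GCC reached the target size")
  .dismantling_result(removed, curve, sum(curve), target_fraction, "hyperedges")
}

#' Select contagion seed nodes
#'
#' `random` draws uniformly without replacement; `degree` takes the top
#' `count` nodes by projection degree; `hyperdegree` the top `count` by
#' hyperdegree (ties broken by node index, ascending).
#'
#' @param H a `hypergraph`.
#' @param strategy one of `"random"`, `"degree"`, `"hyperdegree"`.
#' @param count number of seeds (at most n).
#' @return integer vector of node indices.
#' @export
seed_selection <- function(H, strategy = c("random", "degree", "hyperdegree"),
                           count) {
  strategy <- match.arg(strategy)
  n <- n_nodes(H)
  count <- as.integer(count)
  if (count > n) stop("cannot select more seeds than nodes")
  if (count < 1L) stop("need at least one seed")
  switch(strategy,
    random = sample.int(n, count),
    degree = order(-projection_degrees(H), seq_len(n))[seq_len(count)],
    hyperdegree = order(-hyperdegrees(H), seq_len(n))[seq_len(count)])
}

#' Threshold SIR contagion on a hypergraph
#'
#' Discrete-time synchronous SIR dynamics. At each step, evaluated from the
#' state at the start of the step: (1) a hyperedge is infectious when its
#' number of infectious members exceeds `theta` (strictly, by default);
#' (2) each susceptible node i collects `n_all`, the number of infectious
#' nodes in its infectious hyperedges — summed over hyperedges with
#' multiplicity by default, or as a distinct-node count with
#' `nall_mode = "distinct"` — and becomes infected with probability
#' \eqn{1 - e^{-\beta \, n_{all}}}; (3) each infectious node recovers with
#' probability `gamma`. Newly infected nodes become infectious at the next
#' step and cannot recover in the step they were infected. A run ends when no
#' infectious node remains; the recovered fraction at that absorbing state is
#' recorded, and the experiment is repeated `n_runs` times.
#'
#' @param H a `hypergraph`.
#' @param beta base infection rate (>= 0).
#' @param gamma recovery probability in (0, 1] (default 1).
#' @param theta hyperedge infection threshold (default 5).
#' @param seed_fraction fraction of nodes seeded infectious (default 0.01;
#'   at least one seed is always used, with a warning when the rounded count
#'   would be 0).
#' @param seed_strategy passed to [seed_selection()]; with `"random"`, seeds
#'   are redrawn each run.
#' @param n_runs independent repetitions (default 100).
#' @param rng_seed optional seed for reproducibility.
#' @param threshold_strict if `TRUE` (default) a hyperedge turns infectious
#'   when its infectious-member count is `> theta`; if `FALSE`, `>= theta`.
#' @param nall_mode `"multiplicity"` (default) or `"distinct"`, see above.
#' @param keep_trajectory record per-step S/I/R counts of each run.
#' @return object of class `sir_result`: list with
#'   `recovered_fraction_mean`, `recovered_fraction_sd`, `per_run_fractions`,
#'   and optionally `trajectories`.
#' @export
run_sir <- function(H, beta, gamma = 1, theta = 5, seed_fraction = 0.01,
                    seed_strategy = c("random", "degree", "hyperdegree"),
                    n_runs = 100L, rng_seed = NULL, threshold_strict = TRUE,
                    nall_mode = c("multiplicity", "distinct"),
                    keep_trajectory = FALSE) {
  seed_strategy <- match.arg(seed_strategy)
  nall_mode <- match.arg(nall_mode)
  stopifnot(beta >= 0, gamma > 0, gamma <= 1, theta >= 1,
            seed_fraction > 0, seed_fraction <= 1, n_runs >= 1L)
  n <- n_nodes(H)
  n_seeds <- round(seed_fraction * n)
  if (n_seeds < 1L) {
    warning("seed_fraction * n < 1; using a single seed")
    n_seeds <- 1L
  }
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  C <- incidence_matrix(H, sparse = TRUE)
  fixed_seeds <- if (seed_strategy != "random")
    seed_selection(H, seed_strategy, n_seeds)
  fractions <- numeric(n_runs)
  trajectories <- if (keep_trajectory) vector("list", n_runs)

  for (run in seq_len(n_runs)) {
    seeds <- if (seed_strategy == "random")
      seed_selection(H, "random", n_seeds) else fixed_seeds
    state <- integer(n)           # 0 = S, 1 = I, 2 = R
    state[seeds] <- 1L
    traj <- if (keep_trajectory)
      list(c(S = n - n_seeds, I = n_seeds, R = 0L))
    while (any(state == 1L)) {
      inf <- state == 1L
      edge_inf_count <- as.vector(Matrix::crossprod(C, inf))
      ie <- if (threshold_strict) edge_inf_count > theta else edge_inf_count >= theta
      new_inf <- logical(n)
      if (any(ie)) {
        if (nall_mode == "multiplicity") {
          n_all <- as.vector(C[, ie, drop = FALSE] %*% edge_inf_count[ie])
        } else {
          Ci <- C[, ie, drop = FALSE]
          reach <- Matrix::tcrossprod(Ci) > 0 # share an infectious hyperedge
          n_all <- as.vector(reach %*% inf)   # distinct infectious co-members
        }
        sus <- state == 0L & n_all > 0
        if (any(sus)) {
          p <- 1 - exp(-beta * n_all[sus])
          new_inf[which(sus)[runif(sum(sus)) < p]] <- TRUE
        }
      }
      recov <- inf & (runif(n) < gamma)
      state[recov] <- 2L
      state[new_inf] <- 1L
      if (keep_trajectory)
        traj[[length(traj) + 1L]] <- c(S = sum(state == 0L),
                                       I = sum(state == 1L),
                                       R = sum(state == 2L))
    }
    fractions[run] <- sum(state == 2L) / n
    if (keep_trajectory)
      trajectories[[run]] <- do.call(rbind, traj)
  }

  structure(list(
    recovered_fraction_mean = mean(fractions),
    recovered_fraction_sd = sd(fractions),
    per_run_fractions = fractions,
    trajectories = trajectories,
    config = list(beta = beta, gamma = gamma, theta = theta,
                  seed_fraction = seed_fraction, seed_strategy = seed_strategy,
                  n_runs = n_runs, threshold_strict = threshold_strict,
                  nall_mode = nall_mode)),
    class = "sir_result")
}

#' @export
print.sir_result <- function(x, ...) {
  cat(sprintf(
    "threshold SIR (beta=%.3g, gamma=%.3g, theta=%g, %s seeds %.3g): recovered %.4f +/- %.4f over %d runs\n",
    x$config$beta, x$config$gamma, x$config$theta, x$config$seed_strategy,
    x$config$seed_fraction, x$recovered_fraction_mean, x$recovered_fraction_sd,
    x$config$n_runs))
  invisible(x)
}

#' Compare a dynamic across the original hypergraph and its null models
#'
#' Runs the chosen dynamic (node or hyperedge dismantling, or threshold SIR)
#' on the original hypergraph and on a freshly generated instance of each
#' requested null model, with the same dynamics seed for every network so
#' rows are comparable.
#'
#' @param H a `hypergraph`.
#' @param models subset of `c("original", hyper_null_models())`.
#' @param dynamic which dynamic to run.
#' @param rng_seed base seed; null-model generation and the dynamic derive
#'   their seeds from it.
#' @param ... passed to the dynamic ([dismantle_by_nodes()],
#'   [dismantle_by_hyperedges()] or [run_sir()]).
#' @return data.frame with one row per network: `auc` and `n_removed` for
#'   dismantling, `recovered_fraction_mean`/`sd` for SIR.
#' @export
compare_dynamics <- function(H, models = c("original", hyper_null_models()),
                             dynamic = c("dismantle_nodes",
                                         "dismantle_hyperedges", "sir"),
                             rng_seed = NULL, ...) {
  dynamic <- match.arg(dynamic)
  models <- match.arg(models, c("original", hyper_null_models()),
                      several.ok = TRUE)
  base_seed <- if (is.null(rng_seed)) sample.int(1e6, 1L) else as.integer(rng_seed)
  rows <- lapply(seq_along(models), function(k) {
    mod <- models[k]
    net <- if (mod == "original") H else
      suppressWarnings(
        generate_null_model(H, mod, rng_seed = base_seed + k))$hypergraph
    if (dynamic == "sir") {
      r <- run_sir(net, rng_seed = base_seed, ...)
      data.frame(model = mod,
                 recovered_fraction_mean = r$recovered_fraction_mean,
                 recovered_fraction_sd = r$recovered_fraction_sd,
                 stringsAsFactors = FALSE)
    } else {
      f <- if (dynamic == "dismantle_nodes") dismantle_by_nodes
           else dismantle_by_hyperedges
      r <- suppressWarnings(f(net, ...))
      data.frame(model = mod, auc = r$auc, n_removed = r$n_removed,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
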