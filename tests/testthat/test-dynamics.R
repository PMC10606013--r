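test_that("node dismantling removes hubs first and stops below the target", {
  star <- star_of_dyads(9)
  res <- dismantle_by_nodes(star, target_fraction = 0.2)
  expect_equal(res$n_removed, 1)  # the hub disconnects everything
  expect_equal(res$gcc_curve, 0.1)
  expect_equal(res$removal_order, which(star$node_labels == "c"))
  expect_equal(res$auc, sum(res$gcc_curve))

  # already below target -> no removals
  matching <- hypergraph(list(c("a", "b"), c("c", "d")))
  res2 <- dismantle_by_nodes(matching, target_fraction = 1)
  expect_equal(res2$n_removed, 0)
  expect_equal(res2$auc, 0)

  expect_error(dismantle_by_nodes(star, target_fraction = 0), "target_fraction")
  expect_error(dismantle_by_nodes(star, target_fraction = 1.5), "target_fraction")
})

test_that("node-removal curves are non-increasing and end below target", {
  for (seed in 81:83) {
    H <- random_hypergraph(40, 60, seed = seed)
    res <- dismantle_by_nodes(H, target_fraction = 0.1)
    expect_true(all(diff(res$gcc_curve) <= 0))
    expect_lt(res$gcc_curve[length(res$gcc_curve)], 0.1)
    expect_equal(res$auc, sum(res$gcc_curve))
    expect_true(all(res$gcc_curve >= 0 & res$gcc_curve <= 1))
    # hand-checked against the component oracle at every step
    for (k in seq_len(res$n_removed)) {
      expect_equal(res$gcc_curve[k],
                   oracle_gcc(H, removed_nodes = res$removal_order[seq_len(k)]) / 40)
    }
  }
})

test_that("hyperedge dismantling follows the worked T1 sequence", {
  T1 <- T1()
  res <- dismantle_by_hyperedges(T1, target_fraction = 0.5)
  # e1 (degree 3) first: GCC {1,3,4}; then e2: GCC {1,4}; then e3: isolated
  expect_equal(res$removal_order, c(1L, 2L, 3L))
  expect_equal(res$gcc_curve, c(3, 2, 1) / 4)
  expect_equal(res$n_removed, 3)
  expect_equal(res$auc, 1.5)

  single <- hypergraph(list(letters[1:6]))
  res1 <- suppressWarnings(dismantle_by_hyperedges(single, target_fraction = 0.5))
  expect_equal(res1$n_removed, 1)
  expect_equal(res1$gcc_curve, 1 / 6)

  # warning when the target is unreachable even with all hyperedges gone
  expect_warning(dismantle_by_hyperedges(T1, target_fraction = 0.1),
                 "all hyperedges removed")
})

test_that("seed selection honors strategy and tie-breaks", {
  T1 <- T1()
  expect_equal(seed_selection(T1, "hyperdegree", 1), 1L)  # first of the max ties
  expect_equal(sort(seed_selection(T1, "hyperdegree", 4)), 1:4)
  star <- star_of_dyads(5)
  expect_equal(seed_selection(star, "degree", 1), which(star$node_labels == "c"))
  set.seed(84)
  s1 <- seed_selection(T1, "random", 2)
  set.seed(84)
  s2 <- seed_selection(T1, "random", 2)
  expect_identical(s1, s2)
  expect_error(seed_selection(T1, "random", 5), "more seeds than nodes")
})

test_that("SIR degenerate limits recover exactly the seed fraction", {
  H <- random_hypergraph(100, 200, seed = 85)
  # beta = 0: nobody beyond the seeds is ever infected
  r0 <- run_sir(H, beta = 0, theta = 5, seed_fraction = 0.01, n_runs = 20,
                rng_seed = 86)
  expect_true(all(r0$per_run_fractions == 0.01))
  # threshold above the largest hyperedge: no hyperedge ever infectious
  rtheta <- run_sir(H, beta = 5, theta = max(hyperedge_degrees(H)) + 1,
                    seed_fraction = 0.05, n_runs = 20, rng_seed = 87)
  expect_true(all(rtheta$per_run_fractions == 0.05))
  expect_equal(r0$recovered_fraction_mean, mean(r0$per_run_fractions))
})

test_that("SIR bookkeeping conserves S + I + R and recovers monotonically", {
  H <- random_hypergraph(60, 120, seed = 88)
  res <- run_sir(H, beta = 0.3, gamma = 0.7, theta = 2, seed_fraction = 0.05,
                 n_runs = 5, rng_seed = 89, keep_trajectory = TRUE)
  for (traj in res$trajectories) {
    expect_true(all(rowSums(traj) == 60))
    expect_true(all(diff(traj[, "R"]) >= 0))
    expect_equal(unname(traj[nrow(traj), "I"]), 0)
  }
  expect_true(all(res$per_run_fractions >= 0.05 - 1e-12))
})

test_that("single-hyperedge epidemic matches the exact two-step enumeration", {
  # one hyperedge of 10 nodes, 6 seeds, theta = 5, gamma = 1: the seeds are
  # infectious for one step (n_all = 6), the second generation (at most 4
  # nodes) can never re-activate the hyperedge, so
  # recovered = 6 + Binomial(4, 1 - exp(-6 beta))
  one <- hypergraph(list(paste0("n", 1:10)))
  beta <- 0.2
  res <- run_sir(one, beta = beta, gamma = 1, theta = 5, seed_fraction = 0.6,
                 n_runs = 1e4, rng_seed = 90)
  p <- 1 - exp(-6 * beta)
  expected <- (6 + 4 * p) / 10
  se <- sqrt(4 * p * (1 - p)) / 10 / sqrt(1e4)
  expect_lt(abs(res$recovered_fraction_mean - expected), 3 * se)
})

test_that("recovered fraction increases with beta in expectation", {
  H <- random_hypergraph(100, 200, seed = 91)
  lo <- run_sir(H, beta = 0.05, theta = 1, seed_fraction = 0.1,
                seed_strategy = "hyperdegree", n_runs = 100, rng_seed = 92)
  hi <- run_sir(H, beta = 0.5, theta = 1, seed_fraction = 0.1,
                seed_strategy = "hyperdegree", n_runs = 100, rng_seed = 92)
  pooled_sd <- sqrt(lo$recovered_fraction_sd^2 + hi$recovered_fraction_sd^2) / sqrt(100)
  expect_gte(hi$recovered_fraction_mean,
             lo$recovered_fraction_mean - 2 * pooled_sd)
  # and the epidemic actually spreads beyond the seeds at high beta
  expect_gt(hi$recovered_fraction_mean, 0.1)
})

test_that("gamma = 1 makes every node infectious for exactly one step", {
  H <- random_hypergraph(50, 100, seed = 93)
  res <- run_sir(H, beta = 0.4, gamma = 1, theta = 1, seed_fraction = 0.1,
                 n_runs = 3, rng_seed = 94, keep_trajectory = TRUE)
  for (traj in res$trajectories) {
    # with gamma = 1, everyone infectious at step t is recovered at t+1:
    # R(t+1) - R(t) = I(t)
    expect_equal(diff(traj[, "R"]), traj[-nrow(traj), "I"], ignore_attr = TRUE)
  }
})

test_that("compare_dynamics lines up original and null models", {
  H <- random_hypergraph(50, 100, seed = 95)
  solo <- compare_dynamics(H, models = "original", dynamic = "dismantle_nodes",
                           rng_seed = 96, target_fraction = 0.1)
  direct <- dismantle_by_nodes(H, target_fraction = 0.1)
  expect_equal(solo$auc, direct$auc)
  expect_equal(solo$n_removed, direct$n_removed)

  tab <- suppressWarnings(compare_dynamics(
    H, models = c("original", "H0k"), dynamic = "sir", rng_seed = 97,
    beta = 0.1, theta = 2, seed_fraction = 0.05, n_runs = 30,
    seed_strategy = "hyperdegree"))
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$recovered_fraction_mean >= 0 &
                    tab$recovered_fraction_mean <= 1))
  # identical seeds -> deterministic dismantling rows repeat
  t1 <- suppressWarnings(compare_dynamics(H, models = c("original", "H1k-HD"),
                                          dynamic = "dismantle_hyperedges",
                                          rng_seed = 98, target_fraction = 0.1))
  t2 <- suppressWarnings(compare_dynamics(H, models = c("original", "H1k-HD"),
                                          dynamic = "dismantle_hyperedges",
                                          rng_seed = 98, target_fraction = 0.1))
  expect_identical(t1, t2)
})
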