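prev_mat <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  m
}

test_that("one-sample enumeration finds exactly the feasible trees", {
  prev <- prev_mat(F = 1.0, A = 0.6, B = 0.3)
  ts <- enumerate_trees(prev, epsilon = 0.05)
  expect_equal(ts$reason, "ok")
  expect_length(ts$trees, 2)
  parents <- sort(vapply(ts$trees, function(t) parent_key(t$parent),
                         character(1)))
  # branched (A,B under F) and chain F -> A -> B; chain F -> B -> A violates
  # the sum rule (0.6 > 0.3 + eps)
  expect_equal(parents, sort(c("0,1,1", "0,1,2")))
  # the branched tree is more parsimonious: slack 0 vs ... both have 0 slack
  # but the branched uses 0.9 of the founder; ordering is by slack
  expect_true(all(vapply(ts$trees, function(t) t$slack, numeric(1)) >= 0))
})

test_that("a second sample disambiguates chain vs branched topologies", {
  prev <- prev_mat(F = c(1.0, 1.0), A = c(0.6, 0.1), B = c(0.3, 0.5))
  ts <- enumerate_trees(prev, epsilon = 0.05)
  parents <- vapply(ts$trees, function(t) parent_key(t$parent), character(1))
  expect_true("0,1,1" %in% parents)       # branched survives
  expect_false("0,1,2" %in% parents)      # chain F->A->B fails in sample 2
})

test_that("enumeration agrees with the brute-force generator up to 6 clusters", {
  set.seed(23)
  for (k in 3:6) {
    for (rep in 1:3) {
      # random prevalences with a guaranteed founder
      prev <- matrix(runif(2 * (k - 1), 0, 0.6), k - 1, 2)
      prev <- rbind(1, prev)
      rownames(prev) <- paste0("C", seq_len(k))
      eps <- 0.05
      ts <- enumerate_trees(prev, epsilon = eps)
      got <- sort(vapply(ts$trees, function(t) parent_key(t$parent),
                         character(1)))
      want <- oracle_all_trees(k, 1)
      want <- want[vapply(want, oracle_tree_feasible, logical(1),
                          prev = prev, eps = eps)]
      want <- sort(vapply(want, parent_key, character(1)))
      expect_identical(got, want)
    }
  }
})

test_that("exclusive fractions renormalise the prevalence residuals", {
  prev <- prev_mat(F = 1.0, A = 0.6, B = 0.3)
  ts <- enumerate_trees(prev, epsilon = 0.05)
  branched <- ts$trees[[which(vapply(ts$trees, function(t)
    parent_key(t$parent), character(1)) == "0,1,1")]]
  f <- exclusive_fractions(branched)
  expect_equal(unname(f[, 1]), c(0.1, 0.6, 0.3), tolerance = 1e-12)
  expect_equal(sum(f), 1, tolerance = 1e-9)
  # monoclonal: founder carries everything
  ts1 <- enumerate_trees(prev_mat(F = 0.9))
  expect_equal(unname(exclusive_fractions(ts1$trees[[1]])[1, 1]), 1)
  # negative residual within epsilon is clipped then renormalised
  prev2 <- prev_mat(F = c(1.0), A = c(0.55), B = c(0.48))
  ts2 <- enumerate_trees(prev2, epsilon = 0.05)
  chains <- vapply(ts2$trees, function(t) parent_key(t$parent), character(1))
  tree <- ts2$trees[[which(chains == "0,1,1")]]
  f2 <- exclusive_fractions(tree)
  expect_true(all(f2 >= 0))
  expect_equal(sum(f2), 1, tolerance = 1e-9)
})

test_that("feasible-set properties hold on simulated cases", {
  set.seed(31)
  hits <- 0
  n_cases <- 20
  for (i in seq_len(n_cases)) {
    k <- sample(2:4, 1)
    cfg <- simulation_config(k, sample(c("stable", "dynamic"), 1),
                             purity_by_sample = runif(2, 0.5, 1),
                             depth_mean = 150, n_variants_per_clone = 40,
                             seed = 400 + i)
    sim <- simulate_case(cfg, min_vaf_separation = 0.12)
    prev <- clone_prevalence(sim$truth)
    evaf <- sweep(prev, 2, sim$truth$purity, `*`) / 2
    # prevalence reconstructed from expected VAFs and purity
    prev_hat <- sapply(colnames(evaf), function(s)
      prevalence_from_cluster(evaf[, s], sim$truth$purity[s]))
    ts <- enumerate_trees(prev_hat, epsilon = 0.05)
    expect_gt(length(ts$trees), 0)
    keys <- vapply(ts$trees, function(t) parent_key(t$parent), character(1))
    if (parent_key(sim$truth$tree_parent) %in% keys) hits <- hits + 1
    for (t in ts$trees) {
      f <- exclusive_fractions(t)
      expect_true(all(f >= 0))
      expect_equal(unname(colSums(f)), rep(1, ncol(f)), tolerance = 1e-9)
    }
  }
  expect_gte(hits / n_cases, 0.95)
})

test_that("prevalence conversion follows the diploid heterozygous rule", {
  expect_equal(prevalence_from_cluster(0.5), 1)
  expect_equal(prevalence_from_cluster(0.25), 0.5)
  expect_equal(prevalence_from_cluster(0.6), 1)   # clamped
  expect_equal(prevalence_from_cluster(0.2, purity = 0.8), 0.5)
  # simulated recovery of a planted prevalence
  cfg <- simulation_config(2, "stable", purity_by_sample = 1,
                           depth_mean = 200, n_variants_per_clone = 80,
                           seed = 8)
  sim <- simulate_case(cfg, min_vaf_separation = 0.1)
  cl <- cluster_vafs(sim$variants, k_max = 4, n_restarts = 5, seed = 8)
  cp <- cluster_prevalence(cl)
  truth_prev <- clone_prevalence(sim$truth)
  got <- sort(cp$prevalence[, "BL_c1"])
  want <- sort(truth_prev[, "BL_c1"])
  expect_true(all(abs(got - want) <= 0.05))
})

test_that("collision evidence distinguishes disjoint variants from infeasible trees", {
  # BRC38-like: no cluster spans both time points
  cfg <- simulation_config(4, "collision", purity_by_sample = 0.8,
                           depth_mean = 120, n_variants_per_clone = 30,
                           seed = 55)
  sim <- simulate_case(cfg, min_vaf_separation = 0.1)
  res <- run_case(sim$variants, seed = 5)
  expect_true(res$collision$is_collision)
  expect_equal(res$collision$evidence, "disjoint_variants")
  expect_equal(res$pattern, "collision")

  # BRC21-like: shared founder, but a cluster rises above every other
  # cluster at surgery -> no single-origin tree
  prev <- prev_mat(F = c(0.9, 0.4), A = c(0.4, 0.05), B = c(0.005, 0.6))
  ts <- enumerate_trees(prev, epsilon = 0.05)
  expect_length(ts$trees, 0)
  cl_fake <- structure(list(
    summary = tibble::tibble(
      cluster = rep(1:3, each = 2),
      sample = rep(c("BL_c1", "SURG_c1"), 3),
      median_vaf = c(0.45, 0.2, 0.2, 0.025, 0.0025, 0.3),
      theta = c(0.45, 0.2, 0.2, 0.025, 0.0025, 0.3),
      n_members = 30, total_depth = 3000),
    samples = c("BL_c1", "SURG_c1"), K = 3),
    class = "clone_clusters")
  call <- detect_collision(cl_fake, ts,
                           c(BL_c1 = "baseline", SURG_c1 = "surgical"))
  expect_true(call$is_collision)
  expect_equal(call$evidence, "no_feasible_tree")
  expect_gte(call$shared_cluster_count, 1)

  # a stable 3-clone tumour is not a collision
  cfg2 <- simulation_config(3, "stable", purity_by_sample = 0.9,
                            depth_mean = 150, n_variants_per_clone = 40,
                            seed = 56)
  sim2 <- simulate_case(cfg2, min_vaf_separation = 0.1)
  res2 <- run_case(sim2$variants, seed = 6)
  expect_false(res2$collision$is_collision)

  # single-time-point cases are not evaluable
  one_tp <- dplyr::filter(sim2$variants, timepoint == "baseline")
  cl <- cluster_vafs(one_tp, k_max = 4, n_restarts = 3, seed = 1)
  call2 <- detect_collision(cl, NULL, c(BL_c1 = "baseline"))
  expect_equal(call2$status, "not_evaluable")
})

test_that("no dominant cluster means no founder and triggers collision review", {
  prev <- prev_mat(A = c(0.8, 0.2), B = c(0.3, 0.9))
  ts <- enumerate_trees(prev, epsilon = 0.05)
  expect_equal(ts$reason, "no_founder")
  expect_length(ts$trees, 0)
  expect_error(enumerate_trees(matrix(0.5, 11, 1)),
               class = "clonaldrift_config_error")
})
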