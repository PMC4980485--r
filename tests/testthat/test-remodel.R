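test_that("instability index hits its analytic endpoints and midpoints", {
  expect_identical(instability_index(c(A = 1), c(B = 1)), 1)
  expect_identical(instability_index(c(A = 1), c(A = 1)), 0)
  expect_equal(instability_index(c(A = 0.6, B = 0.4), c(A = 0.4, B = 0.6)),
               0.2)
  expect_true(is.na(instability_index(NULL, c(A = 1))))
})

test_that("index is symmetric, relabel-invariant and bounded", {
  set.seed(3)
  for (i in 1:25) {
    k <- sample(1:6, 1)
    pre <- runif(k); pre <- setNames(pre / sum(pre), paste0("C", 1:k))
    post <- runif(k); post <- setNames(post / sum(post), paste0("C", 1:k))
    idx <- instability_index(pre, post)
    expect_gte(idx, 0)
    expect_lte(idx, 1)
    expect_equal(idx, instability_index(post, pre))
    perm <- sample(k)
    expect_equal(idx, instability_index(pre[perm], post[perm]))
    # zero iff identical over the union of detected clones
    expect_equal(instability_index(pre, pre), 0)
    if (k >= 2 && idx > 0) expect_gt(idx, 0)
  }
  # disjoint multi-clone time points: (sum pre + sum post) / n_union
  pre <- c(A = 0.6, B = 0.4)
  post <- c(C = 0.7, D = 0.3)
  expect_equal(instability_index(pre, post), 0.5)
})

test_that("time-point aggregation averages cores with zero fill", {
  fr <- tibble::tibble(
    clone = c("A", "B", "A", "B"),
    sample = c("c1", "c1", "c2", "c2"),
    timepoint = "baseline",
    fraction = c(0.8, 0.2, 0.4, 0.6))
  expect_equal(timepoint_fractions(fr, "baseline"), c(A = 0.6, B = 0.4))
  one <- timepoint_fractions(fr[1:2, ], "baseline")
  expect_equal(one, c(A = 0.8, B = 0.2))
  # clone present in only one of two cores contributes zero for the other
  fr2 <- tibble::tibble(clone = c("A", "A", "B"),
                        sample = c("c1", "c2", "c2"),
                        timepoint = "baseline",
                        fraction = c(1, 0.5, 0.5))
  expect_equal(timepoint_fractions(fr2, "baseline"), c(A = 0.75, B = 0.25))
  expect_null(timepoint_fractions(fr, "surgical"))
})

test_that("pattern classification follows the four-way rules", {
  expect_equal(classify_pattern(FALSE, 4, 0.097), "complex_stable")
  expect_equal(classify_pattern(FALSE, 1, 0), "simple_stable")
  expect_equal(classify_pattern(FALSE, 3, 0.5), "complex_dynamic")
  expect_equal(classify_pattern(TRUE, 5, 1), "collision")
  expect_equal(classify_pattern(FALSE, 2, 0.1), "complex_stable")  # inclusive
  expect_equal(classify_pattern(FALSE, NA, 0.4), "complex_dynamic")
  expect_equal(classify_pattern(FALSE, NA, NA, manual_pattern = "complex_dynamic"),
               "complex_dynamic")
  expect_equal(classify_pattern(FALSE, NA, NA, unclusterable = TRUE), "manual")
  expect_error(classify_pattern(FALSE, 2, NA),
               class = "clonaldrift_validation_error")
})

test_that("Ki67 response thresholds match the cohort definition", {
  expect_equal(ki67_response(0.012), "sensitive")
  expect_equal(ki67_response(0.104), "resistant")
  expect_equal(ki67_response(0.10), "sensitive")   # strict inequality
  expect_equal(ki67_response(NA), "unknown")
})

test_that("the packaged cohort table reproduces the published group statistics", {
  clin <- nai_cohort_clinical()
  expect_equal(nrow(clin), 22)
  cases <- dplyr::mutate(clin, pattern = classify_pattern(
    collision, n_clones, instability_index, manual_pattern))
  cs <- cohort_summary(cases)
  counts <- setNames(cs$pattern_counts$n_cases, cs$pattern_counts$pattern)
  expect_equal(counts[["collision"]], 2)
  expect_equal(counts[["simple_stable"]], 1)
  expect_equal(counts[["complex_stable"]], 1)
  expect_equal(counts[["complex_dynamic"]], 18)
  expect_equal(cs$dynamic_group$n_computed_index, 15)
  expect_equal(cs$dynamic_group$index_median, 0.53)
  expect_equal(cs$dynamic_group$index_min, 0.25)
  expect_equal(cs$dynamic_group$index_max, 0.90)
  expect_equal(cs$dynamic_group$n_sensitive, 10)
  ki <- cs$ki67_by_response
  expect_equal(ki$ki67_surg_median_pct[ki$ki67_response == "sensitive"], 1.1)
  expect_equal(ki$ki67_surg_max_pct[ki$ki67_response == "sensitive"], 7.0)
  expect_equal(ki$ki67_surg_median_pct[ki$ki67_response == "resistant"], 24.6)
  expect_equal(ki$ki67_surg_min_pct[ki$ki67_response == "resistant"], 10.4)
})

test_that("an empty dynamic group summarises without error", {
  cases <- tibble::tibble(case = c("X1", "X2"),
                          pattern = c("simple_stable", "collision"),
                          instability_index = c(0, 1),
                          ki67_surg = c(0.01, NA),
                          ki67_response = c("sensitive", NA))
  cs <- cohort_summary(cases)
  expect_equal(cs$dynamic_group$n_cases, 0)
  expect_true(is.na(cs$dynamic_group$index_median))
})

test_that("per-gene VAF shifts are screened with a mutation-count floor", {
  panel <- nai_panel_druggable()
  shifts <- gene_vaf_shift(panel, min_mutations = 5)
  expect_true("PIK3CA" %in% shifts$gene)
  expect_false("ESR1" %in% shifts$gene)   # only 3 mutations
  pik <- dplyr::filter(panel, gene == "PIK3CA")
  expect_equal(shifts$mean_delta_vaf[shifts$gene == "PIK3CA"],
               mean(pik$vaf_surgical - pik$vaf_baseline))
})
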