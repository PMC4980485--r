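test_that("planted phylogenies satisfy the generative invariants", {
  for (seed in 1:8) {
    sc <- c("stable", "dynamic", "emergent", "collision")[(seed - 1) %% 4 + 1]
    tr <- simulate_phylogeny(4, sc, seed = seed, n_cores_per_timepoint = 2)
    f <- tr$exclusive_fraction
    expect_true(all(f >= 0))
    expect_equal(unname(colSums(f)), rep(1, ncol(f)), tolerance = 1e-12)
    # sum rule: parent prevalence >= sum of children's, every sample
    prev <- clone_prevalence(tr)
    for (i in seq_along(tr$tree_parent)) {
      ch <- which(!is.na(tr$tree_parent) & tr$tree_parent == i)
      if (length(ch) > 0) {
        expect_true(all(prev[i, ] >= colSums(prev[ch, , drop = FALSE]) - 1e-12))
      }
    }
    # roots are founders of their tumours: prevalence = 1 over their samples
    roots <- which(is.na(tr$tree_parent))
    present <- colSums(f[tr$tumour == tr$tumour[roots[1]], , drop = FALSE]) > 0
    expect_true(all(abs(prev[roots[1], present] - 1) < 1e-12))
  }
})

test_that("monoclonal scenario is a single founder at fraction 1", {
  tr <- simulate_phylogeny(1, "monoclonal", seed = 7)
  expect_length(tr$tree_parent, 1)
  expect_equal(unname(tr$exclusive_fraction[1, ]), c(1, 1))
})

test_that("dynamic scenario swaps a dominant and a rare subclone", {
  for (seed in c(1, 2, 5, 9)) {
    tr <- simulate_phylogeny(5, "dynamic", seed = seed)
    d <- tr$exclusive_fraction[, "SURG_c1"] - tr$exclusive_fraction[, "BL_c1"]
    expect_gte(max(abs(d)), 0.5)       # near-complete subclone replacement
    expect_lte(min(d), -0.5)           # a dominant baseline subclone is lost
  }
})

test_that("collision scenario plants two disjoint tumours, one per time point", {
  tr <- simulate_phylogeny(4, "collision", seed = 3)
  expect_length(unique(tr$tumour), 2)
  t1 <- tr$tumour == 1
  expect_true(all(tr$exclusive_fraction[!t1, "BL_c1"] == 0))
  expect_true(all(tr$exclusive_fraction[t1, "SURG_c1"] == 0))
  expect_equal(sum(is.na(tr$tree_parent)), 2)  # two founders
  cfg <- simulation_config(4, "collision", seed = 3)
  v <- simulate_reads(tr, cfg)
  keys <- split(paste(v$chrom, v$pos, sep = ":"), v$clone)
  expect_length(intersect(unlist(keys[names(which(tr$tumour == 1))]),
                          unlist(keys[names(which(tr$tumour == 2))])), 0)
})

test_that("read counts follow the purity-scaled heterozygous binomial model", {
  tr <- simulate_phylogeny(1, "monoclonal", seed = 2)
  cfg <- simulation_config(1, "monoclonal", purity_by_sample = 0.5,
                           depth_mean = 1000, n_variants_per_clone = 200,
                           seed = 2)
  v <- simulate_reads(tr, cfg)
  m <- mean(vaf(v$dna_ref_reads, v$dna_var_reads))
  expect_lt(abs(m - 0.25), 0.01)

  # corrected founder VAF converges to 0.5 at high depth
  cfg2 <- simulation_config(1, "monoclonal", purity_by_sample = 0.8,
                            depth_mean = 10000, n_variants_per_clone = 150,
                            seed = 3)
  v2 <- simulate_reads(tr, cfg2)
  cc <- correct_counts(v2$dna_ref_reads, v2$dna_var_reads, 0.8)
  expect_lt(abs(mean(cc$corrected_vaf) - 0.5), 0.005)
})

test_that("an emergent clone is mostly invisible at baseline depth 50", {
  tr <- simulate_phylogeny(2, "emergent", seed = 5)
  cfg <- simulation_config(2, "emergent", purity_by_sample = 1,
                           depth_mean = 50, n_variants_per_clone = 200,
                           seed = 5)
  v <- simulate_reads(tr, cfg)
  em <- v$clone == "C2" & v$timepoint == "baseline"
  expect_gt(mean(v$dna_var_reads[em] == 0), 0.5)
  # and its expected baseline VAF sits below the ~1% detection limit
  expect_false(apply_detection_limit(tr$exclusive_fraction["C2", "BL_c1"] / 2))
})

test_that("fixed seeds give byte-identical fixtures", {
  dirs <- file.path(tempfile(), c("a", "b"))
  for (d in dirs) {
    cfg <- simulation_config(3, "dynamic", seed = 31, depth_mean = 60,
                             n_variants_per_clone = 12)
    sim <- simulate_case(cfg)
    write_fixture(sim$variants, sim$truth, d)
  }
  for (f in c("variants.tsv", "clinical.csv", "segments.bed", "truth.json")) {
    expect_identical(readLines(file.path(dirs[1], f)),
                     readLines(file.path(dirs[2], f)))
  }
})

test_that("fixtures round-trip losslessly through the readers", {
  cfg <- simulation_config(2, "stable", seed = 17, depth_mean = 80,
                           n_variants_per_clone = 15)
  sim <- simulate_case(cfg)
  d <- tempfile()
  write_fixture(sim$variants, sim$truth, d)
  v <- read_variant_table(file.path(d, "variants.tsv"))
  expect_equal(nrow(v), nrow(sim$variants))
  expect_equal(v$dna_var_reads, sim$variants$dna_var_reads)
  expect_equal(v$normal_ref_reads, sim$variants$normal_ref_reads)
  tr <- read_truth(file.path(d, "truth.json"))
  expect_equal(tr$exclusive_fraction, sim$truth$exclusive_fraction,
               tolerance = 1e-12)
  expect_equal(unname(colSums(tr$exclusive_fraction)),
               rep(1, ncol(tr$exclusive_fraction)), tolerance = 1e-9)
  expect_equal(tr$purity, sim$truth$purity, tolerance = 1e-12)
  expect_identical(tr$tree_parent, sim$truth$tree_parent)
})

test_that("configuration errors are raised for invalid settings", {
  expect_error(simulation_config(3, "bogus"), class = "clonaldrift_config_error")
  expect_error(simulation_config(3, "stable", depth_mean = 0),
               class = "clonaldrift_config_error")
  expect_error(simulation_config(0, "stable"), class = "clonaldrift_config_error")
  tr <- simulate_phylogeny(2, "stable", seed = 1)
  expect_error(simulate_reads(tr, simulation_config(3, "stable", seed = 1)),
               class = "clonaldrift_config_error")
})
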