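make_variants <- function(n = 4) {
  tibble::tibble(
    case = "T1", sample = rep(c("BL_c1", "SURG_c1"), each = n),
    timepoint = rep(c("baseline", "surgical"), each = n),
    chrom = rep(paste0("chr", 1:n), 2), pos = rep(100L * (1:n), 2),
    ref = "A", alt = "T",
    dna_ref_reads = 60L, dna_var_reads = 40L,
    rna_ref_reads = 10L, rna_var_reads = 5L,
    gene = NA_character_, aa_change = NA_character_, tier = 1L)
}

test_that("variant tables round-trip byte-identically through TSV", {
  v <- make_variants()
  p1 <- tempfile(fileext = ".tsv")
  p2 <- tempfile(fileext = ".tsv")
  write_variant_table(v, p1)
  write_variant_table(read_variant_table(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("validation names the offending rows", {
  v <- make_variants()
  v$dna_var_reads[3] <- -3L
  p <- tempfile(fileext = ".tsv")
  readr::write_tsv(v, p)
  expect_error(read_variant_table(p), regexp = "row\\(s\\) 3",
               class = "clonaldrift_validation_error")
  v2 <- make_variants()[, -2]
  expect_error(write_variant_table(v2, tempfile()),
               class = "clonaldrift_format_error")
  expect_error(read_variant_table(tempfile()),
               class = "clonaldrift_io_error")
})

test_that("VCF input with AD fields yields the same records as the TSV", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNORM\tTUM_BL\tTUM_SURG",
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT:AD\t0/0:100,0\t0/1:60,40\t0/1:30,70",
    "chr2\t200\t.\tG\tC,A\t.\tPASS\t.\tGT:AD\t0/0:99,0,1\t0/1:50,25,25\t0/1:80,10,10")
  p <- tempfile(fileext = ".vcf")
  writeLines(vcf, p)
  info <- tibble::tibble(
    vcf_sample = c("NORM", "TUM_BL", "TUM_SURG"),
    case = "T1", sample = c("N1", "BL_c1", "SURG_c1"),
    timepoint = c("normal", "baseline", "surgical"))
  v <- read_variant_vcf(p, info)
  expect_equal(nrow(v), 6)  # multi-allelic split: (1 + 2 alts) x 2 samples
  one <- dplyr::filter(v, chrom == "chr1", sample == "BL_c1")
  expect_equal(one$dna_ref_reads, 60L)
  expect_equal(one$dna_var_reads, 40L)
  expect_equal(one$normal_var_reads, 0L)
  split2 <- dplyr::filter(v, chrom == "chr2", sample == "SURG_c1")
  expect_equal(split2$alt, c("C", "A"))
  expect_equal(split2$dna_var_reads, c(10L, 10L))
  expect_equal(split2$dna_ref_reads, c(80L, 80L))
})

test_that("LLR filter retains clear somatic calls and rejects germline ones", {
  s <- llr_somatic_filter(70, 30, 100, 0)
  expect_true(s$retained)
  expect_gt(s$llr, 3)
  g <- llr_somatic_filter(50, 50, 50, 50)
  expect_false(g$retained)
  expect_lte(g$llr, 0)
  # depth below 10 in the tumour is never retained
  d <- llr_somatic_filter(4, 5, 100, 0)
  expect_false(d$retained)
  expect_error(llr_somatic_filter(10, 5, 10, 0, error_rate = 0.7),
               class = "clonaldrift_config_error")
})

test_that("LLR matches direct likelihood evaluation and is monotone", {
  set.seed(42)
  tr <- sample(0:60, 200, TRUE); tv <- sample(0:40, 200, TRUE)
  nr <- sample(0:80, 200, TRUE); nv <- sample(0:5, 200, TRUE)
  got <- llr_somatic_filter(tr, tv, nr, nv)$llr
  want <- mapply(oracle_llr, tr, tv, nr, nv)
  expect_equal(got, unname(want), tolerance = 1e-10)
  # adding variant reads never decreases the LLR while the wild-type model
  # is the best germline alternative (at VAFs approaching 50% the somatic
  # and heterozygous models converge, so the LLR correctly falls again)
  lls <- llr_somatic_filter(rep(50, 15), 1:15, 100, 0)$llr
  expect_true(all(diff(lls) > -1e-9))
})

test_that("copy-number-neutral mask applies the margin rule per locus", {
  v <- make_variants()
  seg <- function(cn_bl, cn_surg, chrom = "chr1") tibble::tibble(
    chrom = chrom, start = 0L, end = 1000L,
    sample = c("BL_c1", "SURG_c1"), copy_number = c(cn_bl, cn_surg))
  # diploid everywhere: kept
  expect_equal(nrow(cn_neutral_mask(v, seg(2, 2))), nrow(v))
  # |2.25 - 2| <= 0.25: boundary kept; 2.26 dropped
  expect_equal(nrow(cn_neutral_mask(v, seg(2.25, 2))), nrow(v))
  expect_equal(nrow(cn_neutral_mask(v, seg(2.26, 2))), nrow(v) - 2)
  # neutral at baseline, amplified at surgery: locus dropped in all samples
  out <- cn_neutral_mask(v, seg(2.0, 3.1))
  expect_false(any(out$chrom == "chr1"))
  # uncovered loci default to copy number 2
  expect_equal(nrow(cn_neutral_mask(v, seg(5, 5, chrom = "chr9"))), nrow(v))
  # margin -> Inf is the identity
  expect_identical(cn_neutral_mask(v, seg(9, 0.1), margin = Inf), v)
  # contradictory overlapping segments are an error
  bad <- tibble::tibble(chrom = "chr1", start = c(0L, 50L), end = c(1000L, 500L),
                        sample = "BL_c1", copy_number = c(2, 3))
  expect_error(cn_neutral_mask(v, bad), class = "clonaldrift_validation_error")
})

test_that("detection limit is inclusive at 1% VAF", {
  expect_false(apply_detection_limit(0.009))
  expect_true(apply_detection_limit(0.01))
  expect_false(apply_detection_limit(0))
  expect_true(apply_detection_limit(0.004, lod = 0.001))
})
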