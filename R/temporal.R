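# Two-sided exact p for a 2x2 table conditioned on its margins, by summing
# hypergeometric probabilities no larger than the observed table's
# (conventional definition; relative tolerance guards ties in floating point).
# a = ref reads in the baseline column; R = total ref, V = total var,
# B = baseline depth.
fisher_p_scalar <- function(a, R, V, B) {
  lo <- max(0L, B - V)
  hi <- min(R, B)
  if (hi < lo) return(1)
  xs <- lo:hi
  probs <- dhyper(xs, R, V, B)
  p_obs <- probs[a - lo + 1L]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Fisher's exact test for a VAF change between time points
#'
#' Two-sided exact test on the 2x2 table of (reference, variant) reads by
#' (baseline, surgical) time point, computed on purity-corrected integer
#' counts. An all-zero table is undefined and returns p = 1 with a warning.
#'
#' @param baseline_ref,baseline_var,surgical_ref,surgical_var Non-negative
#'   integer read counts (vectorised).
#' @return Numeric vector of two-sided p-values.
#' @examples
#' fisher_change_test(100, 0, 50, 50)   # strong enrichment
#' @export
fisher_change_test <- function(baseline_ref, baseline_var,
                               surgical_ref, surgical_var) {
  n <- length(baseline_ref)
  counts <- cbind(baseline_ref, baseline_var, surgical_ref, surgical_var)
  if (any(counts < 0)) {
    abort("read counts must be non-negative",
          class = "clonaldrift_validation_error")
  }
  if (any(rowSums(counts) == 0)) {
    warn("all-zero 2x2 table(s); returning p = 1")
  }
  vapply(seq_len(n), function(i) {
    a <- counts[i, 1]; b <- counts[i, 2]; c <- counts[i, 3]; d <- counts[i, 4]
    if (a + b + c + d == 0) return(1)
    fisher_p_scalar(a, a + c, b + d, a + b)
  }, numeric(1))
}

# p-values for every feasible table with margins (R ref, V var, B baseline
# depth); used by exhaustive cross-checks. Returns a vector indexed by
# a = lo:hi.
fisher_p_all <- function(R, V, B) {
  lo <- max(0L, B - V)
  hi <- min(R, B)
  if (hi < lo) return(numeric(0))
  probs <- dhyper(lo:hi, R, V, B)
  ord <- order(probs)
  cum <- cumsum(probs[ord])
  # p(a) = sum of probs <= probs[a]*(1+tol): with sorted probs, find the
  # last index whose prob is within tolerance of each observed prob
  thr <- probs[ord] * (1 + 1e-7)
  idx <- findInterval(thr, probs[ord])
  p_sorted <- pmin(1, cum[idx])
  out <- numeric(length(probs))
  out[ord] <- p_sorted
  out
}

#' Classify each variant's temporal behaviour across treatment
#'
#' For every variant seen in a case with both baseline and surgical samples,
#' tests each baseline x surgical core pair with Fisher's exact test on
#' purity-corrected counts, takes the minimum p across pairs (direction by
#' majority vote over pairs, ties resolved by the most significant pair),
#' and assigns a category:
#'
#' * `shared_stable` when p >= alpha;
#' * `enriched` / `depleted` when significant and both corrected VAFs are at
#'   least `specific_vaf`;
#' * `surgical_specific` when significant, baseline corrected VAF below
#'   `specific_vaf`, and at least `min_rna_reads` variant-supporting RNA
#'   reads at surgery (symmetrically `baseline_specific`); a call failing
#'   only the RNA requirement degrades to enriched/depleted with
#'   `rna_degraded = TRUE`.
#'
#' Corrected VAFs per time point are means across cores; RNA support is
#' summed across cores of the own time point.
#'
#' @param records Variant tibble for one case (baseline and surgical rows).
#' @param purity Purity tibble or named vector (see
#'   [correct_variant_counts()]).
#' @param alpha Significance threshold for retention (default 0.05; no
#'   multiple-testing correction by default, mirroring per-variant retention
#'   at p < 0.05).
#' @param specific_vaf VAF ceiling in the other time point for *_specific
#'   calls (default 0.10).
#' @param min_rna_reads Minimum RNA variant reads in the own time point for
#'   *_specific calls (default 1).
#' @param p_adjust Multiple-testing correction passed to
#'   [stats::p.adjust()]; default `"none"`.
#' @return Tibble, one row per variant: key columns, `p_value`, `direction`
#'   (`up` = higher at surgery), `category`, corrected VAFs, RNA support and
#'   `rna_degraded`.
#' @export
classify_temporal <- function(records, purity, alpha = 0.05,
                              specific_vaf = 0.10, min_rna_reads = 1,
                              p_adjust = "none") {
  x <- correct_variant_counts(records, purity)
  x <- dplyr::filter(x, .data$timepoint %in% c("baseline", "surgical"))
  x$key <- variant_key(x$chrom, x$pos, x$ref, x$alt)
  both <- x |>
    dplyr::group_by(.data$key) |>
    dplyr::filter(dplyr::n_distinct(.data$timepoint) == 2) |>
    dplyr::ungroup()
  if (nrow(both) == 0) {
    abort("no variant observed at both time points",
          class = "clonaldrift_validation_error")
  }
  per_variant <- both |>
    tidyr::nest(data = -dplyr::all_of(c("key", "chrom", "pos", "ref", "alt",
                                        "gene", "aa_change"))) |>
    mutate(res = purrr::map(.data$data, function(d) {
      bl <- dplyr::filter(d, .data$timepoint == "baseline")
      sg <- dplyr::filter(d, .data$timepoint == "surgical")
      pairs <- tidyr::expand_grid(i = seq_len(nrow(bl)), j = seq_len(nrow(sg)))
      p <- fisher_change_test(bl$dna_adjusted_ref_reads[pairs$i],
                              bl$dna_var_reads[pairs$i],
                              sg$dna_adjusted_ref_reads[pairs$j],
                              sg$dna_var_reads[pairs$j])
      dvaf <- sg$dna_corrected_vaf[pairs$j] - bl$dna_corrected_vaf[pairs$i]
      best <- which.min(p)
      dir_votes <- sign(dvaf)
      direction <- if (sum(dir_votes > 0) > sum(dir_votes < 0)) "up"
                   else if (sum(dir_votes < 0) > sum(dir_votes > 0)) "down"
                   else if (dvaf[best] > 0) "up"
                   else if (dvaf[best] < 0) "down" else "none"
      tibble(p_value = p[best], direction = direction,
             vaf_baseline_corrected = mean(bl$dna_corrected_vaf),
             vaf_surgical_corrected = mean(sg$dna_corrected_vaf),
             rna_support_baseline = sum(bl$rna_var_reads, na.rm = TRUE),
             rna_support_surgical = sum(sg$rna_var_reads, na.rm = TRUE))
    })) |>
    dplyr::select(-"data") |>
    tidyr::unnest("res")
  per_variant$p_value <- stats::p.adjust(per_variant$p_value, method = p_adjust)
  per_variant |>
    mutate(
      category = dplyr::case_when(
        .data$p_value >= alpha | .data$direction == "none" ~ "shared_stable",
        .data$direction == "up" &
          .data$vaf_baseline_corrected < specific_vaf &
          .data$rna_support_surgical >= min_rna_reads ~ "surgical_specific",
        .data$direction == "down" &
          .data$vaf_surgical_corrected < specific_vaf &
          .data$rna_support_baseline >= min_rna_reads ~ "baseline_specific",
        .data$direction == "up" ~ "enriched",
        TRUE ~ "depleted"),
      rna_degraded = .data$p_value < alpha & .data$direction != "none" &
        ((.data$direction == "up" &
            .data$vaf_baseline_corrected < specific_vaf &
            .data$rna_support_surgical < min_rna_reads) |
         (.data$direction == "down" &
            .data$vaf_surgical_corrected < specific_vaf &
            .data$rna_support_baseline < min_rna_reads)))
}
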