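#' Purity-correct read counts
#'
#' Removes the read mass contributed by contaminating normal cells by
#' subtracting `(1 - purity) * depth` from the reference-supporting reads.
#' This is the unique linear rule mapping a founder heterozygous variant
#' (raw VAF = purity/2) to a corrected VAF of 0.5. Corrected reference
#' counts are rounded half-up to integers so that downstream exact tests
#' receive counts; purity 1 is the identity.
#'
#' @param ref_reads,var_reads Non-negative read counts (vectorised).
#' @param purity Tumour purity in (0, 1] (vectorised).
#' @return Tibble with `adjusted_ref_reads` (integer) and `corrected_vaf`.
#' @examples
#' correct_counts(75, 25, 0.5)   # founder variant at 50% purity -> VAF 0.5
#' @export
correct_counts <- function(ref_reads, var_reads, purity) {
  if (any(is.na(purity)) || any(purity <= 0) || any(purity > 1)) {
    abort("purity must lie in (0, 1]", class = "clonaldrift_config_error")
  }
  depth <- ref_reads + var_reads
  adj <- pmax(0, round_half_up(ref_reads - (1 - purity) * depth))
  cvaf <- ifelse(var_reads + adj > 0, var_reads / (var_reads + adj),
                 ifelse(var_reads == 0, 0, 1))
  tibble(adjusted_ref_reads = as.integer(adj), corrected_vaf = cvaf)
}

#' Purity-correct a variant allele fraction directly
#'
#' Continuous-scale equivalent of [correct_counts()]:
#' `min(1, vaf / purity)`.
#'
#' @param vaf Raw VAF in `[0, 1]`.
#' @param purity Tumour purity in (0, 1].
#' @return Corrected VAF.
#' @export
correct_vaf <- function(vaf, purity) {
  if (any(purity <= 0, na.rm = TRUE) || any(purity > 1, na.rm = TRUE)) {
    abort("purity must lie in (0, 1]", class = "clonaldrift_config_error")
  }
  pmin(1, vaf / purity)
}

#' Estimate tumour purity from SNV allele fractions
#'
#' Purity is twice the median VAF of the founder cluster (clamped to 1),
#' under the copy-number-neutral heterozygous model. With a clustering
#' result (`cluster_hint`), the founder is the cluster detected in every
#' sample of the case whose worst-sample median VAF is highest; if no
#' cluster spans all samples (as in collision tumours) each sample falls
#' back to its own top cluster. Without a hint the upper mode of a
#' kernel-smoothed VAF histogram stands in for the founder cluster, and the
#' median is taken over variants within 0.05 of that mode.
#'
#' Requires at least `min_variants` copy-number-neutral variants with depth
#' at least `min_depth` per sample; supply purity externally when a sample
#' has fewer.
#'
#' @param records Variant tibble for one case (copy-number-neutral; apply
#'   [cn_neutral_mask()] first when segments are available).
#' @param cluster_hint Optional `clone_clusters` object from
#'   [cluster_vafs()].
#' @param min_variants,min_depth Estimation preconditions (defaults 20, 20).
#' @param lod Detection limit used for cluster presence.
#' @return Tibble with columns `sample`, `purity`, `method`
#'   (`founder_cluster` or `vaf_mode`), `founder_median_vaf`.
#' @export
estimate_purity <- function(records, cluster_hint = NULL,
                            min_variants = 20, min_depth = 20,
                            lod = LOD_DEFAULT) {
  samples <- unique(records$sample)
  depths <- records$dna_ref_reads + records$dna_var_reads
  enough <- vapply(samples, function(s) {
    sum(records$sample == s & depths >= min_depth)
  }, numeric(1))
  if (any(enough < min_variants)) {
    abort(sprintf(
      "sample(s) %s have fewer than %d copy-number-neutral variants with depth >= %d; supply purity directly",
      paste(samples[enough < min_variants], collapse = ", "),
      min_variants, min_depth),
      class = "clonaldrift_estimation_error")
  }
  if (!is.null(cluster_hint)) {
    stopifnot(inherits(cluster_hint, "clone_clusters"))
    med <- tidyr::pivot_wider(cluster_hint$summary,
                              id_cols = "cluster", names_from = "sample",
                              values_from = "median_vaf")
    m <- as.matrix(med[, samples, drop = FALSE])
    rownames(m) <- med$cluster
    spanning <- apply(m, 1, function(r) all(!is.na(r) & r >= lod))
    founder_of <- function(s) {
      if (any(spanning)) {
        cand <- which(spanning)
        cand[which.max(apply(m[cand, , drop = FALSE], 1, min))]
      } else {
        which.max(m[, s])   # collision-style case: per-sample top cluster
      }
    }
    out <- purrr::map(samples, function(s) {
      fm <- m[founder_of(s), s]
      tibble(sample = s, purity = min(1, 2 * fm),
             method = "founder_cluster", founder_median_vaf = fm)
    })
    return(dplyr::bind_rows(out))
  }
  # kernel bandwidth ~ binomial VAF noise at typical depth, so that modes a
  # cluster apart stay resolvable
  bw <- 0.02
  out <- purrr::map(samples, function(s) {
    idx <- records$sample == s & depths >= min_depth
    v <- vaf(records$dna_ref_reads[idx], records$dna_var_reads[idx])
    v <- v[!is.na(v)]
    d <- density(v, bw = bw, from = 0, to = max(0.75, max(v)), n = 512)
    peaks <- which(diff(sign(diff(d$y))) < 0) + 1L
    if (length(peaks) == 0) peaks <- which.max(d$y)
    peaks <- peaks[d$y[peaks] >= 0.1 * max(d$y)]
    mode_x <- max(d$x[peaks])
    # the founder is the top cluster: take the median of everything from
    # just below the upper mode upward
    fm <- median(v[v >= mode_x - 2.5 * bw])
    tibble(sample = s, purity = min(1, 2 * fm),
           method = "vaf_mode", founder_median_vaf = fm)
  })
  dplyr::bind_rows(out)
}

#' Attach purity-corrected DNA counts and VAFs to a variant table
#'
#' @param records Variant tibble.
#' @param purity Either a tibble from [estimate_purity()] (columns `sample`,
#'   `purity`) or a named numeric vector keyed by sample.
#' @return `records` with added columns `purity`, `dna_adjusted_ref_reads`,
#'   `dna_corrected_vaf`.
#' @export
correct_variant_counts <- function(records, purity) {
  if (is.numeric(purity)) {
    purity <- tibble(sample = names(purity), purity = unname(purity))
  }
  assert_cols(purity, c("sample", "purity"), "purity table")
  missing <- setdiff(unique(records$sample), purity$sample)
  if (length(missing) > 0) {
    abort(sprintf("no purity for sample(s): %s", paste(missing, collapse = ", ")),
          class = "clonaldrift_config_error")
  }
  x <- dplyr::left_join(records, purity[, c("sample", "purity")], by = "sample")
  cc <- correct_counts(x$dna_ref_reads, x$dna_var_reads, x$purity)
  x$dna_adjusted_ref_reads <- cc$adjusted_ref_reads
  x$dna_corrected_vaf <- cc$corrected_vaf
  x
}
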