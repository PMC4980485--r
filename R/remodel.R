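#' Mean exclusive clone fractions at one time point
#'
#' Averages exclusive fractions across the biopsy cores of a time point;
#' clones absent from a core contribute 0 there.
#'
#' @param fractions Tibble with columns `clone`, `sample`, `timepoint`,
#'   `fraction` (one row per clone per core).
#' @param timepoint Which time point to aggregate.
#' @return Named numeric vector of mean fractions per clone; `NULL` when the
#'   time point has no cores.
#' @export
timepoint_fractions <- function(fractions, timepoint) {
  assert_cols(fractions, c("clone", "sample", "timepoint", "fraction"),
              "fractions")
  x <- dplyr::filter(fractions, .data$timepoint == !!timepoint)
  if (nrow(x) == 0) return(NULL)
  cores <- unique(x$sample)
  out <- x |>
    dplyr::group_by(.data$clone) |>
    dplyr::summarise(fraction = sum(.data$fraction) / length(cores),
                     .groups = "drop")
  setNames(out$fraction, out$clone)
}

#' Clonal instability index
#'
#' The mean of absolute differences between pre- and post-treatment clone
#' fractions, taken over the union of clones detected (fraction at or above
#' `lod`) at either time point, with absent clones contributing 0. An index
#' of 0 means no change in clonal architecture; 1 means completely distinct
#' tumours (e.g. each time point one unrelated clone at fraction 1).
#'
#' @param pre,post Named vectors of exclusive clone fractions (each summing
#'   to 1 over its tumour cells); `NULL` marks an unavailable time point and
#'   yields `NA`.
#' @param lod Detection threshold on the fraction scale applied when forming
#'   the union of clones (default 0.01).
#' @return A number in `[0, 1]`, or `NA_real_` when either time point is
#'   undefined.
#' @examples
#' instability_index(c(A = 1), c(B = 1))         # unrelated tumours -> 1
#' instability_index(c(A = 1), c(A = 1))         # unchanged monoclonal -> 0
#' instability_index(c(A = 0.6, B = 0.4), c(A = 0.4, B = 0.6))
#' @export
instability_index <- function(pre, post, lod = LOD_DEFAULT) {
  if (is.null(pre) || is.null(post) || length(pre) + length(post) == 0) {
    return(NA_real_)
  }
  clones <- union(names(pre), names(post))
  p1 <- setNames(rep(0, length(clones)), clones)
  p2 <- p1
  p1[names(pre)] <- pre
  p2[names(post)] <- post
  detected <- p1 >= lod | p2 >= lod
  if (!any(detected)) return(NA_real_)
  mean(abs(p1[detected] - p2[detected]))
}

#' Classify a case into one of the four genomic patterns
#'
#' * `collision`: genomic evidence of two independent tumours;
#' * `simple_stable`: a single clone with index at or below `cutoff`;
#' * `complex_stable`: multiple clones, index at or below `cutoff`;
#' * `complex_dynamic`: index above `cutoff`;
#' * `manual`: the case could not be clustered automatically and carries no
#'   pre-assigned pattern.
#'
#' The stable/dynamic boundary is inclusive on the stable side (index 0.1 is
#' stable). A `manual_pattern` value, when present, is consumed verbatim
#' (the route for cases assigned by expert review).
#'
#' @param collision Logical: collision call (vectorised).
#' @param n_clones Integer clone count (`NA` allowed when the index exceeds
#'   `cutoff`).
#' @param index Clonal instability index (`NA` only for manual cases).
#' @param manual_pattern Optional character: pre-assigned pattern, `NA` to
#'   classify automatically.
#' @param unclusterable Logical: flag cases where clustering failed.
#' @param cutoff Stable/dynamic boundary (default 0.1).
#' @return Character vector of pattern labels.
#' @export
classify_pattern <- function(collision, n_clones, index,
                             manual_pattern = NA_character_,
                             unclusterable = FALSE, cutoff = 0.1) {
  n <- max(length(collision), length(n_clones), length(index),
           length(manual_pattern), length(unclusterable))
  collision <- rep_len(collision, n)
  n_clones <- rep_len(n_clones, n)
  index <- rep_len(index, n)
  manual_pattern <- rep_len(manual_pattern, n)
  unclusterable <- rep_len(unclusterable, n)
  bad <- is.na(manual_pattern) & !unclusterable & is.na(index) &
    !(collision %in% TRUE)
  if (any(bad)) {
    abort("undefined instability index without a manual pattern or unclusterable flag",
          class = "clonaldrift_validation_error")
  }
  dplyr::case_when(
    !is.na(manual_pattern) ~ manual_pattern,
    unclusterable ~ "manual",
    collision %in% TRUE ~ "collision",
    !is.na(n_clones) & n_clones == 1 & index <= cutoff ~ "simple_stable",
    index <= cutoff ~ "complex_stable",
    TRUE ~ "complex_dynamic")
}

#' Aromatase-inhibitor response from surgical Ki67
#'
#' A case is resistant when the proportion of Ki67-positive cells at surgery
#' exceeds 10% (strict inequality; the sensitive group tops out at 7% and
#' the resistant group starts at 10.4%). Used when a response label is not
#' supplied (e.g. simulations).
#'
#' @param ki67_surgical Proportion in `[0, 1]` (vectorised).
#' @return `"sensitive"`, `"resistant"` or `"unknown"` (missing input).
#' @examples
#' ki67_response(c(0.012, 0.104, NA))
#' @export
ki67_response <- function(ki67_surgical) {
  dplyr::case_when(
    is.na(ki67_surgical) ~ "unknown",
    ki67_surgical > 0.10 ~ "resistant",
    TRUE ~ "sensitive")
}

#' Cohort-level summary of clonal remodelling
#'
#' Summarises per-case results: pattern counts; size, response composition
#' and computed-index statistics (median/range over cases with a defined
#' index, two decimals) of the clonally complex and treatment dynamic group;
#' and median/range of surgical Ki67 (percent, one decimal) per response
#' label.
#'
#' @param cases Tibble with one row per case and columns `case`, `pattern`,
#'   `instability_index`, `ki67_surg` (proportion), `ki67_response`.
#' @return List of class `cohort_summary` with tibbles `pattern_counts`,
#'   `dynamic_group`, `ki67_by_response`.
#' @export
cohort_summary <- function(cases) {
  assert_cols(cases, c("case", "pattern", "instability_index", "ki67_surg",
                       "ki67_response"), "cases")
  pattern_counts <- cases |>
    dplyr::count(.data$pattern, name = "n_cases") |>
    dplyr::arrange(.data$pattern)
  dyn <- dplyr::filter(cases, .data$pattern == "complex_dynamic")
  idx <- dyn$instability_index[!is.na(dyn$instability_index)]
  dynamic_group <- tibble(
    n_cases = nrow(dyn),
    n_sensitive = sum(dyn$ki67_response == "sensitive", na.rm = TRUE),
    n_resistant = sum(dyn$ki67_response == "resistant", na.rm = TRUE),
    n_computed_index = length(idx),
    index_median = if (length(idx)) round_half_up(median(idx), 2) else NA_real_,
    index_min = if (length(idx)) round_half_up(min(idx), 2) else NA_real_,
    index_max = if (length(idx)) round_half_up(max(idx), 2) else NA_real_)
  ki67_by_response <- cases |>
    dplyr::filter(.data$ki67_response %in% c("sensitive", "resistant"),
                  !is.na(.data$ki67_surg)) |>
    dplyr::group_by(.data$ki67_response) |>
    dplyr::summarise(
      n_cases = dplyr::n(),
      ki67_surg_median_pct = round_half_up(median(.data$ki67_surg) * 100, 1),
      ki67_surg_min_pct = round_half_up(min(.data$ki67_surg) * 100, 1),
      ki67_surg_max_pct = round_half_up(max(.data$ki67_surg) * 100, 1),
      .groups = "drop")
  structure(list(pattern_counts = pattern_counts,
                 dynamic_group = dynamic_group,
                 ki67_by_response = ki67_by_response),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Pattern counts:\n"); print(x$pattern_counts)
  cat("\nClonally complex, treatment dynamic group:\n"); print(x$dynamic_group)
  cat("\nSurgical Ki67 by response:\n"); print(x$ki67_by_response)
  invisible(x)
}

#' Per-gene mean VAF shift between time points
#'
#' A screening table of the mean change in VAF (surgical minus baseline) for
#' genes with at least `min_mutations` mutations, as used to ask whether
#' mutations in particular genes drive clonal response.
#'
#' @param tbl Tibble with columns `gene`, `vaf_baseline`, `vaf_surgical`
#'   (fractions or percent, consistently).
#' @param min_mutations Minimum mutations per gene (default 5).
#' @return Tibble: `gene`, `n_mutations`, `mean_delta_vaf`.
#' @export
gene_vaf_shift <- function(tbl, min_mutations = 5) {
  assert_cols(tbl, c("gene", "vaf_baseline", "vaf_surgical"), "tbl")
  tbl |>
    dplyr::filter(!is.na(.data$vaf_baseline), !is.na(.data$vaf_surgical)) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n_mutations = dplyr::n(),
                     mean_delta_vaf = mean(.data$vaf_surgical - .data$vaf_baseline),
                     .groups = "drop") |>
    dplyr::filter(.data$n_mutations >= min_mutations) |>
    dplyr::arrange(dplyr::desc(.data$mean_delta_vaf))
}
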