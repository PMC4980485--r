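#' Run the full clonal-remodelling analysis for one case
#'
#' Orchestrates the per-case pipeline: somatic LLR filtering (when matched
#' normal counts are present), copy-number-neutral masking, VAF clustering,
#' purity estimation (unless supplied), purity correction, clone-tree
#' enumeration under the sum rule, collision detection, per-time-point
#' exclusive clone fractions, the clonal instability index and the pattern
#' class. Cases that cannot be clustered (too few variants) come back with
#' pattern `"manual"`.
#'
#' For collision cases the two time points are resolved as separate tumours:
#' trees are enumerated per time point over the clusters detectable there,
#' and the index is computed over the union of clones.
#'
#' @param variants Variant tibble for one case.
#' @param segments Optional copy-number segments (see [cn_neutral_mask()]).
#' @param purity Optional named per-sample purity vector or tibble; when
#'   absent it is estimated from the founder cluster.
#' @param k_max,n_restarts,seed,min_members Clustering controls (see
#'   [cluster_vafs()]).
#' @param lod Detection limit on the VAF scale.
#' @param epsilon Fixed sum-rule tolerance (see [enumerate_trees()]).
#' @param cutoff Stable/dynamic boundary on the instability index.
#' @param error_rate,min_llr,min_depth LLR filter controls (see
#'   [llr_somatic_filter()]); the filter runs only when normal counts are
#'   present.
#' @param temporal Also classify per-variant temporal behaviour (requires
#'   RNA counts for *_specific calls); default TRUE when RNA columns carry
#'   data.
#' @return An object of class `case_result`; see [glance.case_result()] for
#'   the one-row summary and [tidy.case_result()] for per-clone fractions.
#' @export
run_case <- function(variants, segments = NULL, purity = NULL,
                     k_max = 10, n_restarts = 10, seed = NULL,
                     min_members = 5, lod = LOD_DEFAULT, epsilon = 0.05,
                     cutoff = 0.1, error_rate = 0.001, min_llr = 3,
                     min_depth = 10, temporal = NULL) {
  validate_variants(variants)
  case_id <- unique(variants$case)
  if (length(case_id) != 1) {
    abort("run_case expects exactly one case; see run_cohort()",
          class = "clonaldrift_config_error")
  }
  x <- variants
  notes <- character(0)

  has_normal <- all(c("normal_ref_reads", "normal_var_reads") %in% names(x)) &&
    any(!is.na(x$normal_ref_reads))
  if (has_normal) {
    flt <- llr_somatic_filter(x$dna_ref_reads, x$dna_var_reads,
                              x$normal_ref_reads, x$normal_var_reads,
                              error_rate = error_rate, min_llr = min_llr,
                              min_depth = min_depth)
    x$key <- variant_key(x$chrom, x$pos, x$ref, x$alt)
    somatic_keys <- unique(x$key[flt$retained])
    x <- dplyr::filter(x, .data$key %in% somatic_keys) |>
      dplyr::select(-"key")
  }
  x <- cn_neutral_mask(x, segments)

  # clustering needs the full variant x sample grid
  x$key <- variant_key(x$chrom, x$pos, x$ref, x$alt)
  n_samples <- dplyr::n_distinct(x$sample)
  x <- x |>
    dplyr::group_by(.data$key) |>
    dplyr::filter(dplyr::n() == n_samples) |>
    dplyr::ungroup()

  timepoints <- x |>
    dplyr::distinct(.data$sample, .data$timepoint)
  tp_map <- setNames(timepoints$timepoint, timepoints$sample)

  clusters <- tryCatch(
    cluster_vafs(x, k_max = k_max, n_restarts = n_restarts, seed = seed,
                 min_members = min_members),
    clonaldrift_cluster_error = function(e) e)
  if (inherits(clusters, "error")) {
    return(structure(list(
      case = case_id, clusters = NULL, purity = NULL, trees = NULL,
      collision = NULL, fractions = NULL, instability_index = NA_real_,
      n_clones = NA_integer_, pattern = "manual",
      notes = c(notes, conditionMessage(clusters)), temporal = NULL),
      class = "case_result"))
  }

  if (is.null(purity)) {
    purity_tbl <- estimate_purity(x, cluster_hint = clusters, lod = lod)
  } else if (is.numeric(purity)) {
    purity_tbl <- tibble(sample = names(purity), purity = unname(purity),
                         method = "supplied", founder_median_vaf = NA_real_)
  } else {
    purity_tbl <- purity
  }
  pur <- setNames(purity_tbl$purity, purity_tbl$sample)

  cp <- cluster_prevalence(clusters, purity = pur, lod = lod)
  trees <- enumerate_trees(cp$prevalence, epsilon = epsilon, se = cp$se)
  collision <- detect_collision(clusters, trees, tp_map, purity = pur,
                                lod = lod)

  frac_of_tree <- function(tree) {
    f <- exclusive_fractions(tree)
    tibble(clone = rep(rownames(f), ncol(f)),
           sample = rep(colnames(f), each = nrow(f)),
           fraction = as.vector(f)) |>
      mutate(timepoint = unname(tp_map[.data$sample]))
  }

  fractions <- NULL
  best_tree <- NULL
  if (isTRUE(collision$is_collision)) {
    parts <- purrr::map(c("baseline", "surgical"), function(tp) {
      smp <- names(tp_map)[tp_map == tp]
      pres <- cp$present[, smp, drop = FALSE]
      rows <- which(apply(pres, 1, any))
      if (length(rows) == 0) return(NULL)
      sub <- cp$prevalence[rows, smp, drop = FALSE]
      subse <- cp$se[rows, smp, drop = FALSE]
      ts <- enumerate_trees(sub, epsilon = epsilon, se = subse)
      if (length(ts$trees) > 0) {
        frac_of_tree(ts$trees[[1]])
      } else {
        # no within-time-point tree either; fall back to normalised
        # prevalence as the fraction estimate
        f <- sweep(sub, 2, pmax(colSums(sub), 1e-12), `/`)
        tibble(clone = rep(rownames(f), ncol(f)),
               sample = rep(colnames(f), each = nrow(f)),
               fraction = as.vector(f)) |>
          mutate(timepoint = tp)
      }
    })
    fractions <- dplyr::bind_rows(parts)
  } else if (length(trees$trees) > 0) {
    best_tree <- trees$trees[[1]]
    fractions <- frac_of_tree(best_tree)
  } else {
    notes <- c(notes, "no feasible tree and no collision evidence")
  }

  idx <- NA_real_
  if (!is.null(fractions)) {
    pre <- timepoint_fractions(fractions, "baseline")
    post <- timepoint_fractions(fractions, "surgical")
    idx <- instability_index(pre, post, lod = lod)
  }
  n_clones <- clusters$K
  pattern <- if (isTRUE(collision$is_collision)) {
    "collision"
  } else if (is.na(idx)) {
    notes <- c(notes, "index undefined; pattern needs manual review")
    "manual"
  } else {
    classify_pattern(FALSE, n_clones, idx, cutoff = cutoff)
  }

  temporal_calls <- NULL
  want_temporal <- temporal %||%
    (any(!is.na(x$rna_var_reads)) &&
       all(c("baseline", "surgical") %in% tp_map))
  if (isTRUE(want_temporal)) {
    temporal_calls <- tryCatch(
      classify_temporal(x, purity_tbl),
      error = function(e) {
        notes <<- c(notes, paste("temporal classification failed:",
                                 conditionMessage(e)))
        NULL
      })
  }

  structure(list(case = case_id, clusters = clusters, purity = purity_tbl,
                 trees = trees, best_tree = best_tree, collision = collision,
                 fractions = fractions, instability_index = idx,
                 n_clones = n_clones, pattern = pattern, notes = notes,
                 temporal = temporal_calls),
            class = "case_result")
}

#' @export
print.case_result <- function(x, ...) {
  cat(sprintf("<case_result> %s: %s (instability index %s, %s clone(s))\n",
              x$case, x$pattern,
              ifelse(is.na(x$instability_index), "-",
                     format(round_half_up(x$instability_index, 3))),
              ifelse(is.na(x$n_clones), "?", x$n_clones)))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Run the pipeline over a cohort and summarise it
#'
#' Splits a variant table by case, runs [run_case()] on each, joins clinical
#' information and produces the cohort report. Missing response labels are
#' derived from surgical Ki67 via [ki67_response()]; a `manual_pattern`
#' column in the clinical table overrides the computed pattern (the route
#' for expert-reviewed cases).
#'
#' @param variants Variant tibble (any number of cases).
#' @param segments Optional copy-number segments.
#' @param clinical Optional clinical tibble (`case`, `ki67_surg`,
#'   `ki67_response`, `manual_pattern`, ...).
#' @param purity Optional purity tibble with a `case` column, or `NULL`.
#' @param ... Passed to [run_case()].
#' @return List of class `cohort_result`: `cases` (list of `case_result`),
#'   `results` (one row per case) and `summary` ([cohort_summary()]).
#' @export
run_cohort <- function(variants, segments = NULL, clinical = NULL,
                       purity = NULL, ...) {
  ids <- unique(variants$case)
  cases <- purrr::map(ids, function(id) {
    pur <- NULL
    if (!is.null(purity)) {
      pur <- dplyr::filter(purity, .data$case == id) |>
        dplyr::select(-"case")
      if (nrow(pur) == 0) pur <- NULL
    }
    run_case(dplyr::filter(variants, .data$case == id),
             segments = segments, purity = pur, ...)
  })
  names(cases) <- ids
  results <- dplyr::bind_rows(purrr::map(cases, glance))
  if (!is.null(clinical)) {
    results <- dplyr::left_join(results,
                                dplyr::select(clinical, dplyr::any_of(
                                  c("case", "ki67_bl", "ki67_surg",
                                    "ki67_response", "manual_pattern"))),
                                by = "case")
  }
  if (!"ki67_surg" %in% names(results)) results$ki67_surg <- NA_real_
  if (!"ki67_response" %in% names(results)) results$ki67_response <- NA_character_
  if (!"manual_pattern" %in% names(results)) results$manual_pattern <- NA_character_
  derived_response <- ki67_response(results$ki67_surg)
  results <- results |>
    mutate(
      ki67_response = dplyr::coalesce(.data$ki67_response, derived_response),
      pattern = ifelse(is.na(.data$manual_pattern), .data$pattern,
                       .data$manual_pattern))
  structure(list(cases = cases, results = results,
                 summary = cohort_summary(results)),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d case(s)\n", nrow(x$results)))
  print(x$summary)
  invisible(x)
}
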