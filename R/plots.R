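#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_histogram geom_col
#'   facet_wrap labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a clustering result
#'
#' With two or more samples, a scatter plot of VAFs in the first two samples
#' coloured by cluster (the classic clonality plot); with one sample, a
#' VAF histogram faceted by cluster.
#'
#' @param object A `clone_clusters` object.
#' @param records The variant tibble that was clustered.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot clone_clusters
#' @export
autoplot.clone_clusters <- function(object, records, ...) {
  records$.key <- variant_key(records$chrom, records$pos, records$ref,
                              records$alt)
  records$.vaf <- vaf(records$dna_ref_reads, records$dna_var_reads)
  d <- dplyr::left_join(records,
                        dplyr::rename(object$assignments, .key = "key"),
                        by = ".key") |>
    mutate(cluster = factor(.data$cluster))
  if (length(object$samples) >= 2) {
    wide <- tidyr::pivot_wider(d, id_cols = c(".key", "cluster"),
                               names_from = "sample", values_from = ".vaf")
    s1 <- object$samples[1]; s2 <- object$samples[2]
    ggplot(wide, aes(x = .data[[s1]], y = .data[[s2]],
                     colour = .data$cluster)) +
      geom_point(alpha = 0.6) +
      labs(x = paste("VAF,", s1), y = paste("VAF,", s2),
           colour = "cluster") +
      theme_minimal()
  } else {
    ggplot(d, aes(x = .data$.vaf, fill = .data$cluster)) +
      geom_histogram(bins = 50) +
      facet_wrap(~cluster) +
      labs(x = "VAF") +
      theme_minimal()
  }
}

#' Stacked clone-fraction plot for a case
#'
#' Exclusive clone fractions per sample, stacked to 1, showing how the
#' clonal composition shifts between baseline and surgery.
#'
#' @param result A `case_result` object.
#' @return A ggplot.
#' @export
plot_clone_fractions <- function(result) {
  stopifnot(inherits(result, "case_result"))
  d <- tidy(result)
  if (nrow(d) == 0) {
    abort("case has no fractions to plot (manual case)",
          class = "clonaldrift_validation_error")
  }
  ggplot(d, aes(x = .data$sample, y = .data$fraction,
                fill = factor(.data$clone))) +
    geom_col() +
    facet_wrap(~timepoint, scales = "free_x") +
    labs(x = NULL, y = "exclusive clone fraction", fill = "clone",
         title = result$case) +
    theme_minimal()
}

#' @rdname plot_clone_fractions
#' @param object A `case_result`.
#' @param ... Unused.
#' @method autoplot case_result
#' @export
autoplot.case_result <- function(object, ...) {
  plot_clone_fractions(object)
}
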