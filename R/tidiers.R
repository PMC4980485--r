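#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a clustering result
#'
#' One row per variant: cluster assignment, maximum posterior and outlier
#' flag.
#'
#' @param x A `clone_clusters` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy clone_clusters
#' @export
tidy.clone_clusters <- function(x, ...) {
  x$assignments
}

#' One-row summary of a clustering result
#'
#' @param x A `clone_clusters` object.
#' @param ... Unused.
#' @return A tibble with `k_clusters`, `log_lik`, `bic`, `n_variants`,
#'   `n_samples`, `n_outliers`, `low_separation`.
#' @method glance clone_clusters
#' @export
glance.clone_clusters <- function(x, ...) {
  tibble(k_clusters = x$K, log_lik = x$loglik, bic = min(x$bic, na.rm = TRUE),
         n_variants = nrow(x$assignments), n_samples = length(x$samples),
         n_outliers = sum(x$assignments$outlier),
         low_separation = x$low_separation)
}

#' Tidy a clone tree
#'
#' Long tibble of node, parent, sample, cellular prevalence and exclusive
#' fraction.
#'
#' @param x A `clone_tree` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy clone_tree
#' @export
tidy.clone_tree <- function(x, ...) {
  f <- exclusive_fractions(x)
  nodes <- rownames(x$prevalence)
  parent <- ifelse(is.na(x$parent), NA_character_, nodes[x$parent])
  tidyr::expand_grid(node = nodes, sample = colnames(x$prevalence)) |>
    mutate(parent = parent[match(.data$node, nodes)],
           prevalence = x$prevalence[cbind(.data$node, .data$sample)],
           exclusive_fraction = f[cbind(.data$node, .data$sample)]) |>
    dplyr::relocate("node", "parent")
}

#' Per-clone fractions of a case result
#'
#' @param x A `case_result` object.
#' @param ... Unused.
#' @return Tibble with `clone`, `sample`, `timepoint`, `fraction` (empty for
#'   manual cases).
#' @method tidy case_result
#' @export
tidy.case_result <- function(x, ...) {
  x$fractions %||% tibble(clone = character(), sample = character(),
                          fraction = numeric(), timepoint = character())
}

#' One-row summary of a case result
#'
#' @param x A `case_result` object.
#' @param ... Unused.
#' @return A tibble with case id, clone count, instability index, pattern,
#'   collision evidence and notes.
#' @method glance case_result
#' @export
glance.case_result <- function(x, ...) {
  tibble(case = x$case,
         n_clones = x$n_clones %||% NA_integer_,
         instability_index = x$instability_index,
         pattern = x$pattern,
         collision = isTRUE(x$collision$is_collision),
         collision_evidence = x$collision$evidence %||% NA_character_,
         low_separation = x$clusters$low_separation %||% NA,
         notes = paste(x$notes, collapse = "; "))
}

#' Export a clone tree in Graphviz DOT format
#'
#' @param tree A `clone_tree`.
#' @param path Optional file to write; `NULL` returns the DOT text.
#' @return The DOT source, invisibly when written to `path`.
#' @export
tree_to_dot <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "clone_tree"))
  nodes <- rownames(tree$prevalence)
  edges <- purrr::imap_chr(as.list(tree$parent), function(p, i) {
    if (is.na(p)) "" else sprintf("  \"%s\" -> \"%s\";", nodes[p], i)
  })
  dot <- paste(c("digraph clonetree {",
                 sprintf("  \"%s\";", nodes),
                 edges[nzchar(edges)], "}"), collapse = "\n")
  if (!is.null(path)) {
    writeLines(dot, path)
    return(invisible(dot))
  }
  dot
}
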