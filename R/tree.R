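#' Cellular prevalence implied by a cluster's median VAF
#'
#' Under the copy-number-neutral heterozygous model, a clone at cellular
#' prevalence q and tumour purity p yields VAF = p*q/2, so
#' `prevalence = min(1, 2 * vaf / purity)`.
#'
#' @param median_vaf Median VAF(s) of the cluster (raw, or corrected if
#'   `purity = 1`).
#' @param purity Tumour purity in (0, 1]; default 1 (already-corrected VAFs).
#' @return Prevalence in `[0, 1]`.
#' @examples
#' prevalence_from_cluster(0.5)    # founder
#' prevalence_from_cluster(0.25)   # half the tumour cells
#' @export
prevalence_from_cluster <- function(median_vaf, purity = 1) {
  if (any(purity <= 0 | purity > 1)) {
    abort("purity must lie in (0, 1]", class = "clonaldrift_config_error")
  }
  pmin(1, 2 * median_vaf / purity)
}

#' Per-cluster per-sample prevalence matrix from a clustering result
#'
#' Corrects cluster median VAFs for purity, zeroes clusters whose corrected
#' median VAF is below the detection limit in a sample, and converts to
#' cellular prevalences. Also returns the binomial standard error of each
#' prevalence (2x the VAF standard error at the cluster's summed depth),
#' used to relax the sum rule at finite depth.
#'
#' @param clusters A `clone_clusters` object.
#' @param purity Named per-sample purity vector or tibble (`sample`,
#'   `purity`); default all 1.
#' @param lod Detection limit on the corrected VAF scale.
#' @return List with matrices `prevalence` and `se` (clusters x samples) and
#'   logical matrix `present`.
#' @export
cluster_prevalence <- function(clusters, purity = NULL, lod = LOD_DEFAULT) {
  stopifnot(inherits(clusters, "clone_clusters"))
  if (is.data.frame(purity)) {
    purity <- setNames(purity$purity, purity$sample)
  }
  if (is.null(purity)) {
    purity <- setNames(rep(1, length(clusters$samples)), clusters$samples)
  }
  s <- clusters$summary |>
    mutate(p = unname(purity[.data$sample]),
           cvaf = pmin(1, .data$median_vaf / .data$p),
           present = .data$cvaf >= lod,
           prev = ifelse(.data$present,
                         prevalence_from_cluster(.data$cvaf), 0),
           se = 2 * sqrt(pmax(.data$cvaf * (1 - .data$cvaf), 0.25 * lod) /
                           pmax(.data$total_depth, 1)) / pmax(.data$p, 1e-6))
  to_mat <- function(col) {
    m <- tidyr::pivot_wider(s, id_cols = "cluster", names_from = "sample",
                            values_from = dplyr::all_of(col))
    out <- as.matrix(m[, clusters$samples, drop = FALSE])
    rownames(out) <- m$cluster
    out
  }
  list(prevalence = to_mat("prev"), se = to_mat("se"),
       present = to_mat("present") > 0)
}

tree_slack <- function(parent, prev, eps) {
  k <- nrow(prev)
  viol <- 0
  feasible <- TRUE
  for (node in seq_len(k)) {
    ch <- which(!is.na(parent) & parent == node)
    if (length(ch) == 0) next
    childsum <- colSums(prev[ch, , drop = FALSE])
    excess <- childsum - prev[node, ]
    viol <- viol + sum(pmax(0, excess))
    if (any(excess > eps[node, ])) feasible <- FALSE
  }
  list(slack = viol, feasible = feasible)
}

#' Enumerate feasible clonal evolution trees under the sum rule
#'
#' Exhaustively enumerates rooted trees over the clusters, rooted at the
#' founder (the cluster whose prevalence is maximal in every sample), and
#' keeps those satisfying the sum rule -- in every sample a parent's
#' prevalence must be at least the sum of its children's prevalences --
#' within a tolerance that combines a fixed epsilon with the sampling error
#' of each cluster's prevalence. Feasible trees are ordered by total slack
#' (summed positive violation mass; most parsimonious first).
#'
#' @param prevalence Clusters x samples matrix of cellular prevalences (see
#'   [cluster_prevalence()]).
#' @param epsilon Fixed component of the tolerance (default 0.05).
#' @param se Optional clusters x samples matrix of prevalence standard
#'   errors, added to `epsilon`.
#' @param max_clusters Safety bound on the brute-force enumeration
#'   (default 10).
#' @return An object of class `clone_tree_set`: list of `clone_tree` objects
#'   (each with `parent`, `prevalence`, `slack`, `epsilon`), plus fields
#'   `founder` (row index, `NA` when no cluster dominates every sample) and
#'   `reason` (`"ok"`, `"no_founder"` or `"no_feasible_tree"`).
#' @examples
#' prev <- rbind(founder = c(1.0), A = c(0.6), B = c(0.3))
#' enumerate_trees(prev)
#' @export
enumerate_trees <- function(prevalence, epsilon = 0.05, se = NULL,
                            max_clusters = 10) {
  prev <- as.matrix(prevalence)
  k <- nrow(prev)
  if (k > max_clusters) {
    abort(sprintf("%d clusters exceed the brute-force bound of %d", k,
                  max_clusters),
          class = "clonaldrift_config_error")
  }
  eps <- matrix(epsilon, k, ncol(prev))
  if (!is.null(se)) eps <- eps + as.matrix(se)
  # founder: at least as prevalent as every other cluster in every sample
  dominant <- vapply(seq_len(k), function(i) {
    all(vapply(seq_len(ncol(prev)), function(s) {
      prev[i, s] >= max(prev[-i, s], -Inf) - 1e-9
    }, logical(1)))
  }, logical(1))
  if (k == 1) {
    tree <- structure(list(parent = setNames(NA_integer_, rownames(prev)),
                           prevalence = prev, slack = 0, epsilon = eps),
                      class = "clone_tree")
    return(structure(list(trees = list(tree), founder = 1L, reason = "ok"),
                     class = "clone_tree_set"))
  }
  if (!any(dominant)) {
    return(structure(list(trees = list(), founder = NA_integer_,
                          reason = "no_founder"),
                     class = "clone_tree_set"))
  }
  cand <- which(dominant)
  root <- cand[which.max(rowSums(prev[cand, , drop = FALSE]))]
  others <- setdiff(seq_len(k), root)
  trees <- list()
  # depth-first assignment of parents with incremental sum-rule pruning:
  # children sums only grow, so a partial violation can never recover
  childsum <- matrix(0, k, ncol(prev))
  assign_next <- function(pos, parent) {
    if (pos > length(others)) {
      # connectivity check (cycles among the assigned parents)
      for (v in others) {
        u <- v; hops <- 0
        while (!is.na(parent[u])) {
          u <- parent[u]; hops <- hops + 1
          if (hops > k) return(invisible(NULL))
        }
        if (u != root) return(invisible(NULL))
      }
      res <- tree_slack(parent, prev, eps)
      if (res$feasible) {
        pm <- parent
        names(pm) <- rownames(prev)
        trees[[length(trees) + 1]] <<- structure(
          list(parent = pm, prevalence = prev, slack = res$slack,
               epsilon = eps),
          class = "clone_tree")
      }
      return(invisible(NULL))
    }
    v <- others[pos]
    for (p in seq_len(k)) {
      if (p == v) next
      newsum <- childsum[p, ] + prev[v, ]
      if (any(newsum - prev[p, ] > eps[p, ])) next
      childsum[p, ] <<- newsum
      parent[v] <- p
      assign_next(pos + 1, parent)
      childsum[p, ] <<- childsum[p, ] - prev[v, ]
    }
    invisible(NULL)
  }
  assign_next(1, setNames(rep(NA_integer_, k), NULL))
  if (length(trees) == 0) {
    return(structure(list(trees = list(), founder = root,
                          reason = "no_feasible_tree"),
                     class = "clone_tree_set"))
  }
  # order by slack; ties broken by a label-invariant canonical form (nodes
  # ranked by total prevalence), so relabelling clusters cannot change which
  # tree ranks first
  canon <- rank(-rowSums(prev), ties.method = "first")
  keys <- vapply(trees, function(t) {
    p <- t$parent
    paste(ifelse(is.na(p), 0L, canon[p])[order(canon)], collapse = ",")
  }, character(1))
  ord <- order(vapply(trees, `[[`, numeric(1), "slack"), keys)
  structure(list(trees = trees[ord], founder = root, reason = "ok"),
            class = "clone_tree_set")
}

#' @export
print.clone_tree_set <- function(x, ...) {
  cat(sprintf("<clone_tree_set> %d feasible tree(s); founder = %s; status = %s\n",
              length(x$trees),
              if (is.na(x$founder)) "none" else as.character(x$founder),
              x$reason))
  invisible(x)
}

#' Exclusive clone fractions of a tree
#'
#' The exclusive fraction of a clone in a sample is its prevalence minus the
#' summed prevalence of its children, clipped at 0 (residuals within the sum
#' rule tolerance), then renormalised so fractions sum to 1 over tumour
#' cells in each sample.
#'
#' @param tree A `clone_tree`.
#' @return Clusters x samples matrix of exclusive fractions (columns sum
#'   to 1).
#' @export
exclusive_fractions <- function(tree) {
  stopifnot(inherits(tree, "clone_tree"))
  prev <- tree$prevalence
  k <- nrow(prev)
  f <- prev
  for (node in seq_len(k)) {
    ch <- which(!is.na(tree$parent) & tree$parent == node)
    if (length(ch) > 0) {
      f[node, ] <- pmax(0, prev[node, ] - colSums(prev[ch, , drop = FALSE]))
    }
  }
  tot <- colSums(f)
  for (s in seq_len(ncol(f))) {
    if (tot[s] > 0) {
      f[, s] <- f[, s] / tot[s]
    } else if (any(prev[, s] > 0)) {
      # degenerate: all mass consumed by children; put it on the founder
      root <- which(is.na(tree$parent))[1]
      f[root, s] <- 1
    }
  }
  f
}

#' Detect collision tumours (two independent tumours in one site)
#'
#' Evidence is `disjoint_variants` when no cluster is detectable (median
#' corrected VAF at or above the LOD) in both a baseline and a surgical
#' sample, and `no_feasible_tree` when shared clusters exist but no
#' single-origin tree satisfies the sum rule (including the case where no
#' cluster dominates every sample, so no founder exists).
#'
#' @param clusters A `clone_clusters` object.
#' @param trees A `clone_tree_set` from [enumerate_trees()] over all
#'   samples.
#' @param timepoints Named character vector mapping sample id to
#'   `"baseline"`/`"surgical"`.
#' @param purity Optional purity (see [cluster_prevalence()]).
#' @param lod Detection limit.
#' @return List of class `collision_call`: `is_collision`, `evidence`
#'   (`disjoint_variants`, `no_feasible_tree` or `none`),
#'   `shared_cluster_count`, `status` (`"ok"` or `"not_evaluable"` for
#'   single-time-point cases).
#' @export
detect_collision <- function(clusters, trees, timepoints, purity = NULL,
                             lod = LOD_DEFAULT) {
  stopifnot(inherits(clusters, "clone_clusters"))
  tp <- timepoints[clusters$samples]
  if (length(unique(tp[!is.na(tp)])) < 2) {
    return(structure(list(is_collision = NA, evidence = "none",
                          shared_cluster_count = NA_integer_,
                          status = "not_evaluable"),
                     class = "collision_call"))
  }
  cp <- cluster_prevalence(clusters, purity = purity, lod = lod)
  pres <- cp$present
  bl <- colnames(pres)[tp[colnames(pres)] == "baseline"]
  sg <- colnames(pres)[tp[colnames(pres)] == "surgical"]
  shared <- apply(pres, 1, function(r) any(r[bl]) && any(r[sg]))
  n_shared <- sum(shared)
  if (n_shared == 0) {
    res <- list(is_collision = TRUE, evidence = "disjoint_variants",
                shared_cluster_count = 0L, status = "ok")
  } else if (inherits(trees, "clone_tree_set") && length(trees$trees) == 0) {
    res <- list(is_collision = TRUE, evidence = "no_feasible_tree",
                shared_cluster_count = as.integer(n_shared), status = "ok")
  } else {
    res <- list(is_collision = FALSE, evidence = "none",
                shared_cluster_count = as.integer(n_shared), status = "ok")
  }
  structure(res, class = "collision_call")
}
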