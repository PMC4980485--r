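# One EM fit of a K-component S-dimensional binomial mixture.
# V, D: n x S matrices of variant reads and depths. theta0: K x S start.
# Returns list(theta, pi, loglik, trace, resp). The binomial coefficient
# terms are constant across components and across K and are omitted from
# the log likelihood (they cancel in posteriors and shift BIC uniformly).
em_binom_fit <- function(V, D, theta0, max_iter = 150, tol = 1e-7) {
  n <- nrow(V); K <- nrow(theta0)
  theta <- pmin(pmax(theta0, 1e-6), 0.75)
  pi_k <- rep(1 / K, K)
  U <- D - V
  trace <- numeric(0)
  ll_old <- -Inf
  resp <- NULL
  for (it in seq_len(max_iter)) {
    A <- V %*% t(log(theta)) + U %*% t(log1p(-theta))
    A <- sweep(A, 2, log(pi_k), `+`)
    mx <- A[, 1]
    if (K > 1) for (k in 2:K) mx <- pmax(mx, A[, k])
    lse <- mx + log(rowSums(exp(A - mx)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    resp <- exp(A - lse)
    if (is.finite(ll_old) && ll - ll_old < tol * abs(ll)) break
    ll_old <- ll
    num <- t(resp) %*% V
    den <- t(resp) %*% D
    theta <- pmin(pmax(num / pmax(den, 1e-12), 1e-6), 0.75)
    pi_k <- pmax(colMeans(resp), 1e-12)
    pi_k <- pi_k / sum(pi_k)
  }
  list(theta = theta, pi = pi_k, loglik = trace[length(trace)],
       trace = trace, resp = resp)
}

# quantile-spaced starting values plus seeded jitter
em_init_theta <- function(vafs, K, S, jitter = 0.02) {
  probs <- seq(0.1, 0.95, length.out = K)
  th <- sapply(seq_len(S), function(s) quantile(vafs[, s], probs, names = FALSE))
  th <- matrix(th, nrow = K)
  th + matrix(runif(K * S, -jitter, jitter), K, S)
}

#' Cluster variant allele fractions into subclones
#'
#' Jointly clusters the VAFs of copy-number-neutral variants across all
#' samples of a case by fitting S-dimensional binomial mixture models with
#' expectation-maximisation for K = 1..`k_max` (with `n_restarts` seeded
#' restarts each) and selecting K by the Bayesian information criterion.
#' Each variant is assigned to its maximum-posterior cluster; assignments
#' with maximum posterior below `outlier_posterior` are flagged as outliers
#' but retained. Clusters ending up with fewer than `min_members` members
#' are dissolved and their members reassigned to the remaining clusters.
#' Results are deterministic under a fixed seed.
#'
#' @param records Variant tibble (one case) with counts for every variant in
#'   every sample; zero variant reads are allowed, missing rows are not.
#' @param k_max Largest number of clusters considered (default 10).
#' @param n_restarts EM restarts per K (default 10).
#' @param seed Integer seed.
#' @param min_members Minimum cluster size (default 5).
#' @param outlier_posterior Posterior threshold below which an assignment is
#'   flagged (default 0.8).
#' @param ref_col,var_col Names of the count columns to cluster on (defaults
#'   `dna_ref_reads`/`dna_var_reads`; use the adjusted columns to cluster
#'   corrected counts).
#' @param min_variants Minimum number of variants (default 10); fewer raises
#'   a clustering error, flagging the case for manual review.
#' @return An object of class `clone_clusters`: list with `assignments`
#'   (tibble: variant key columns, `cluster`, `max_posterior`, `outlier`),
#'   `summary` (tibble: `cluster`, `sample`, `median_vaf`, `theta`,
#'   `n_members`), `K`, `loglik`, `loglik_trace`, `bic` (per candidate K),
#'   `pi`, `samples`, and `low_separation` (TRUE when some cluster pair's
#'   theta differ by < 0.05 in every sample).
#' @examples
#' sim <- simulate_case(simulation_config(2, "stable", depth_mean = 150,
#'                                        seed = 1))
#' cluster_vafs(sim$variants, k_max = 3, n_restarts = 3, seed = 1)
#' @export
cluster_vafs <- function(records, k_max = 10, n_restarts = 10, seed = NULL,
                         min_members = 5, outlier_posterior = 0.8,
                         ref_col = "dna_ref_reads", var_col = "dna_var_reads",
                         min_variants = 10) {
  assert_cols(records, c("sample", "chrom", "pos", "ref", "alt",
                         ref_col, var_col), "records")
  records$.key <- variant_key(records$chrom, records$pos, records$ref,
                              records$alt)
  samples <- sort(unique(records$sample))
  wide_v <- tidyr::pivot_wider(records, id_cols = ".key",
                               names_from = "sample",
                               values_from = dplyr::all_of(var_col))
  wide_d <- records |>
    mutate(.depth = .data[[ref_col]] + .data[[var_col]]) |>
    tidyr::pivot_wider(id_cols = ".key", names_from = "sample",
                       values_from = ".depth")
  V <- as.matrix(wide_v[, samples, drop = FALSE])
  D <- as.matrix(wide_d[, samples, drop = FALSE])
  if (anyNA(V) || anyNA(D)) {
    abort("every variant must have counts in every sample (zero reads allowed)",
          class = "clonaldrift_validation_error")
  }
  n <- nrow(V)
  if (n < min_variants) {
    abort(sprintf(
      "only %d variants; at least %d required for clustering - case flagged for manual review",
      n, min_variants), class = "clonaldrift_cluster_error")
  }
  S <- length(samples)
  vafs <- V / pmax(D, 1)
  local_seed(seed, {
    fits <- vector("list", k_max)
    bic <- rep(NA_real_, k_max)
    for (K in seq_len(k_max)) {
      best <- NULL
      for (r in seq_len(if (K == 1) 1 else n_restarts)) {
        fit <- em_binom_fit(V, D, em_init_theta(vafs, K, S))
        if (is.null(best) || fit$loglik > best$loglik) best <- fit
      }
      fits[[K]] <- best
      bic[K] <- -2 * best$loglik + (K * S + (K - 1)) * log(n)
      # stop scanning once BIC has worsened for two consecutive K
      if (K >= 3 && bic[K] > bic[K - 1] && bic[K - 1] > bic[K - 2]) break
    }
    K_hat <- which.min(bic)
    fit <- fits[[K_hat]]
    # dissolve undersized clusters, reassigning members to the survivors
    repeat {
      assign <- max.col(fit$resp, ties.method = "first")
      sizes <- tabulate(assign, nbins = nrow(fit$theta))
      small <- which(sizes > 0 & sizes < min_members)
      drop <- c(which(sizes == 0), small)
      if (length(drop) == 0 || nrow(fit$theta) - length(drop) < 1) break
      keep <- setdiff(seq_len(nrow(fit$theta)), drop)
      fit <- em_binom_fit(V, D, fit$theta[keep, , drop = FALSE],
                          max_iter = 50)
    }
    assign <- max.col(fit$resp, ties.method = "first")
    maxpost <- fit$resp[cbind(seq_len(n), assign)]
    K_final <- nrow(fit$theta)

    assignments <- tibble(
      key = wide_v$.key, cluster = assign, max_posterior = maxpost,
      outlier = maxpost < outlier_posterior)
    summary <- tidyr::expand_grid(cluster = seq_len(K_final),
                                  s = seq_len(S)) |>
      mutate(sample = samples[.data$s],
             median_vaf = purrr::map2_dbl(.data$cluster, .data$s, function(k, s) {
               members <- assign == k
               if (!any(members)) return(NA_real_)
               median(vafs[members, s])
             }),
             theta = fit$theta[cbind(.data$cluster, .data$s)],
             n_members = tabulate(assign, nbins = K_final)[.data$cluster],
             total_depth = purrr::map2_dbl(.data$cluster, .data$s, function(k, s) {
               sum(D[assign == k, s])
             })) |>
      dplyr::select(-"s")
    sep <- TRUE
    low_separation <- FALSE
    if (K_final > 1) {
      pairs <- utils::combn(K_final, 2)
      low_separation <- any(apply(pairs, 2, function(ij) {
        all(abs(fit$theta[ij[1], ] - fit$theta[ij[2], ]) < 0.05)
      }))
    }
    structure(list(assignments = assignments, summary = summary,
                   K = K_final, loglik = fit$loglik,
                   loglik_trace = fit$trace, bic = bic, pi = fit$pi,
                   theta = fit$theta, samples = samples,
                   low_separation = low_separation),
              class = "clone_clusters")
  })
}

#' @export
print.clone_clusters <- function(x, ...) {
  cat(sprintf("<clone_clusters> %d cluster(s) over %d sample(s), %d variants\n",
              x$K, length(x$samples), nrow(x$assignments)))
  if (x$low_separation) cat("  note: some clusters separated by < 0.05 VAF in all samples\n")
  print(x$summary, n = min(nrow(x$summary), 20))
  invisible(x)
}

#' Is a cluster detectable in a sample?
#'
#' A cluster is called present in a sample when its median corrected VAF
#' there is at or above the limit of detection (inclusive boundary).
#'
#' @param clusters A `clone_clusters` object.
#' @param cluster Cluster id(s).
#' @param sample Sample id(s).
#' @param lod Detection limit on the VAF scale (default 0.01).
#' @return Logical vector.
#' @export
cluster_presence <- function(clusters, cluster, sample, lod = LOD_DEFAULT) {
  stopifnot(inherits(clusters, "clone_clusters"))
  key <- paste(cluster, sample)
  med <- setNames(clusters$summary$median_vaf,
                  paste(clusters$summary$cluster, clusters$summary$sample))
  apply_detection_limit(pmin(1, pmax(0, med[key])), lod = lod)
}
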