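# Independent oracles used to cross-check the package's computations.

# Two-sided Fisher p by direct enumeration of all tables with the observed
# margins, probabilities from log binomial coefficients only.
oracle_fisher_p <- function(b_ref, b_var, s_ref, s_var) {
  R <- b_ref + s_ref          # total reference reads
  V <- b_var + s_var          # total variant reads
  B <- b_ref + b_var          # baseline depth
  N <- R + V
  if (N == 0) return(1)
  lo <- max(0, B - V)
  hi <- min(R, B)
  xs <- lo:hi
  lp <- lchoose(R, xs) + lchoose(V, B - xs) - lchoose(N, B)
  p <- exp(lp)
  p_obs <- p[xs == b_ref]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# same, for every feasible baseline-ref count at fixed margins
oracle_fisher_p_all <- function(R, V, B) {
  N <- R + V
  lo <- max(0, B - V)
  hi <- min(R, B)
  if (hi < lo) return(numeric(0))
  xs <- lo:hi
  p <- exp(lchoose(R, xs) + lchoose(V, B - xs) - lchoose(N, B))
  vapply(seq_along(xs), function(i) min(1, sum(p[p <= p[i] * (1 + 1e-7)])),
         numeric(1))
}

# Somatic-vs-germline LLR by direct dbinom evaluation (binomial coefficients
# cancel between hypotheses sharing the same counts).
oracle_llr <- function(t_ref, t_var, n_ref, n_var, e = 0.001) {
  td <- t_ref + t_var
  nd <- n_ref + n_var
  f <- max(ifelse(td > 0, t_var / td, 0), e)
  som <- dbinom(n_var, nd, e, log = TRUE) + dbinom(t_var, td, f, log = TRUE)
  het <- dbinom(n_var, nd, 0.5, log = TRUE) + dbinom(t_var, td, 0.5, log = TRUE)
  wt  <- dbinom(n_var, nd, e, log = TRUE) + dbinom(t_var, td, e, log = TRUE)
  som - max(het, wt)
}

# All rooted labelled trees on 1..n with the given root, as parent vectors,
# generated by filtering every candidate parent assignment (n^(n-1) raw
# candidates including self-loops).
oracle_all_trees <- function(n, root) {
  others <- setdiff(seq_len(n), root)
  if (length(others) == 0) return(list(rep(NA_integer_, n)))
  grid <- do.call(expand.grid, rep(list(seq_len(n)), length(others)))
  out <- list()
  for (r in seq_len(nrow(grid))) {
    parent <- rep(NA_integer_, n)
    parent[others] <- as.integer(grid[r, ])
    ok <- TRUE
    for (v in others) {
      u <- v
      hops <- 0
      repeat {
        if (u == root) break
        u <- parent[u]
        hops <- hops + 1
        if (is.na(u) || hops > n) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) out[[length(out) + 1]] <- parent
  }
  out
}

# sum rule check for the oracle's trees
oracle_tree_feasible <- function(parent, prev, eps) {
  for (node in seq_len(nrow(prev))) {
    ch <- which(!is.na(parent) & parent == node)
    if (length(ch) == 0) next
    excess <- colSums(prev[ch, , drop = FALSE]) - prev[node, ]
    if (any(excess > eps)) return(FALSE)
  }
  TRUE
}

parent_key <- function(parent) paste(ifelse(is.na(parent), 0L, parent),
                                     collapse = ",")

# map fitted clusters onto planted clones by majority vote and return the
# per-variant agreement
assignment_accuracy <- function(clusters, variants) {
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt,
               sep = ":")
  truth <- tapply(variants$clone, key, `[`, 1)
  a <- clusters$assignments
  tab <- table(a$cluster, truth[a$key])
  map <- colnames(tab)[apply(tab, 1, which.max)]
  mean(map[a$cluster] == truth[a$key])
}

# vectorised form of oracle_llr
oracle_llr_vec <- function(t_ref, t_var, n_ref, n_var, e = 0.001) {
  td <- t_ref + t_var
  nd <- n_ref + n_var
  f <- pmax(ifelse(td > 0, t_var / td, 0), e)
  som <- dbinom(n_var, nd, e, log = TRUE) + dbinom(t_var, td, f, log = TRUE)
  het <- dbinom(n_var, nd, 0.5, log = TRUE) +
    dbinom(t_var, td, 0.5, log = TRUE)
  wt <- dbinom(n_var, nd, e, log = TRUE) + dbinom(t_var, td, e, log = TRUE)
  som - pmax(het, wt)
}

# majority-vote map from fitted cluster id to planted clone name
cluster_to_clone_map <- function(clusters, variants) {
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt,
               sep = ":")
  truth <- tapply(variants$clone, key, `[`, 1)
  a <- clusters$assignments
  tab <- table(a$cluster, truth[a$key])
  setNames(colnames(tab)[apply(tab, 1, which.max)], rownames(tab))
}

# express a fitted tree's parent map in planted-clone coordinates; returns
# NULL when the cluster-to-clone map is not a bijection
translate_parent <- function(parent, map, clone_names) {
  ids <- names(parent)
  clones <- unname(map[ids])
  if (anyNA(clones) || any(duplicated(clones)) ||
      length(clones) != length(clone_names)) {
    return(rep(-1L, length(clone_names)))
  }
  out <- rep(NA_integer_, length(clone_names))
  for (j in seq_along(ids)) {
    ci <- match(clones[j], clone_names)
    p <- parent[j]
    out[ci] <- if (is.na(p)) NA_integer_ else match(map[ids[p]], clone_names)
  }
  out
}
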