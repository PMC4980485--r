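#' Simulation configuration for synthetic tumour cases
#'
#' Bundles the knobs of the synthetic-data generator. Defaults emulate the
#' study conditions the analysis targets: whole-genome depth of around 100x
#' (discovery plus validation sequencing), tumour purity anywhere between
#' 12% and 100%, one or two biopsy cores per time point, and RNA support
#' reads at moderate depth.
#'
#' @param n_clones Number of clones (including founder(s)); `monoclonal`
#'   forces 1.
#' @param scenario One of `"stable"`, `"dynamic"`, `"emergent"`,
#'   `"collision"`, `"monoclonal"`.
#' @param purity_by_sample Tumour purity per sample in `[0.12, 1]`; a scalar
#'   is recycled; `NULL` draws per-sample purities uniformly on `[0.12, 1]`.
#' @param depth_mean Mean DNA sequencing depth (reads); per-variant depths
#'   are Poisson around this with a floor of 1.
#' @param n_variants_per_clone Somatic variants planted per clone.
#' @param n_cores_per_timepoint Biopsy cores per time point.
#' @param rna_depth_mean Mean RNA depth at variant loci (may yield 0 reads).
#' @param error_rate Per-allele sequencing error rate (substitutions), used
#'   for the matched normal and as background noise in tumour reads.
#' @param core_concentration Dirichlet concentration for per-core jitter of
#'   clone fractions when `n_cores_per_timepoint > 1`; `Inf` makes cores
#'   identical. The default (50) yields the moderate spatial heterogeneity
#'   seen in concurrent biopsies.
#' @param purity_range Range purities are drawn from when
#'   `purity_by_sample = NULL` (default `c(0.12, 1)`, the observed range).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A list of class `sim_config`.
#' @examples
#' simulation_config(3, "dynamic", seed = 1)
#' @export
simulation_config <- function(n_clones = 3,
                              scenario = c("stable", "dynamic", "emergent",
                                           "collision", "monoclonal"),
                              purity_by_sample = NULL,
                              depth_mean = 100,
                              n_variants_per_clone = 30,
                              n_cores_per_timepoint = 1,
                              rna_depth_mean = 30,
                              error_rate = 0.001,
                              core_concentration = 50,
                              purity_range = c(0.12, 1),
                              seed = NULL) {
  scenario <- tryCatch(match.arg(scenario),
                       error = function(e) abort(
                         sprintf("invalid scenario name '%s'", scenario[1]),
                         class = "clonaldrift_config_error"))
  if (depth_mean <= 0) {
    abort("depth_mean must be positive", class = "clonaldrift_config_error")
  }
  if (n_clones < 1) {
    abort("n_clones must be >= 1", class = "clonaldrift_config_error")
  }
  if (scenario == "monoclonal") n_clones <- 1L
  if (scenario == "collision" && n_clones < 2) {
    abort("collision scenario needs at least 2 clones (one per tumour)",
          class = "clonaldrift_config_error")
  }
  if (!is.null(purity_by_sample) &&
      any(purity_by_sample <= 0 | purity_by_sample > 1)) {
    abort("purity must lie in (0, 1]", class = "clonaldrift_config_error")
  }
  structure(list(
    n_clones = as.integer(n_clones), scenario = scenario,
    purity_by_sample = purity_by_sample, depth_mean = depth_mean,
    n_variants_per_clone = as.integer(n_variants_per_clone),
    n_cores_per_timepoint = as.integer(n_cores_per_timepoint),
    rna_depth_mean = rna_depth_mean, error_rate = error_rate,
    core_concentration = core_concentration, purity_range = purity_range,
    seed = seed
  ), class = "sim_config")
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(x == 0)) x <- rep(1, length(alpha))
  x / sum(x)
}

sample_names <- function(n_cores) {
  tibble(
    sample = c(paste0("BL_c", seq_len(n_cores)), paste0("SURG_c", seq_len(n_cores))),
    timepoint = rep(c("baseline", "surgical"), each = n_cores),
    core = rep(seq_len(n_cores), 2L)
  )
}

# Per-time-point exclusive clone fractions for each scenario. Returns a
# clones x 2 matrix (columns baseline, surgical) plus the tumour membership
# of each clone (collision plants two independent tumours).
scenario_fractions <- function(n_clones, scenario) {
  k <- n_clones
  tumour <- rep(1L, k)
  pre <- post <- numeric(k)
  if (scenario == "monoclonal") {
    pre <- post <- 1
  } else if (scenario == "stable") {
    pre <- rdirichlet1(rep(1.5, k))
    if (k == 1) {
      post <- pre
    } else {
      d <- runif(k, -0.025, 0.025)
      d <- d - mean(d)                      # sums to zero, |d| <= 0.05
      scl <- min(1, pre[d < 0] / -d[d < 0], na.rm = TRUE)
      post <- pre + d * min(1, scl)
    }
  } else if (scenario == "dynamic") {
    if (k == 1) abort("dynamic scenario needs >= 2 clones",
                      class = "clonaldrift_config_error")
    sub <- if (k == 2) 2L else sample(2:k, 2L)
    loser <- sub[1]
    riser <- if (k == 2) 1L else sub[2]    # with 2 clones the founder swings
    pre[loser] <- runif(1, 0.6, 0.85)
    pre[riser] <- runif(1, 0.01, 0.03)
    post[loser] <- runif(1, 0, 0.04)
    post[riser] <- runif(1, 0.55, 0.85)
    rest <- setdiff(seq_len(k), c(loser, riser))
    if (length(rest) > 0) {
      pre[rest] <- rdirichlet1(rep(2, length(rest))) * (1 - sum(pre))
      post[rest] <- rdirichlet1(rep(2, length(rest))) * (1 - sum(post))
    } else {
      # two-clone case: normalise the pair
      pre <- pre / sum(pre)
      post <- post / sum(post)
    }
  } else if (scenario == "emergent") {
    if (k == 1) abort("emergent scenario needs >= 2 clones",
                      class = "clonaldrift_config_error")
    em <- k                                 # emergent clone is the last leaf
    pre[em] <- runif(1, 0.002, 0.008)       # below ~1% VAF at any purity
    post[em] <- runif(1, 0.6, 0.9)
    rest <- setdiff(seq_len(k), em)
    pre[rest] <- rdirichlet1(rep(2, length(rest))) * (1 - pre[em])
    post[rest] <- rdirichlet1(rep(2, length(rest))) * (1 - post[em])
  } else if (scenario == "collision") {
    ka <- ceiling(k / 2)
    tumour <- rep(c(1L, 2L), c(ka, k - ka))
    pre[tumour == 1L] <- rdirichlet1(rep(2, ka))
    post[tumour == 2L] <- rdirichlet1(rep(2, k - ka))
  }
  list(fractions = cbind(baseline = pre, surgical = post), tumour = tumour)
}

#' Simulate a planted clonal phylogeny with per-sample clone fractions
#'
#' Draws a rooted clone tree (two disjoint trees for the collision scenario)
#' and per-sample exclusive clone fractions. Exclusive fractions are
#' non-negative and sum to 1 per sample over the tumour(s) present, which
#' guarantees the sum rule on cellular prevalences by construction. The
#' scenario controls the baseline-to-surgical shift:
#'
#' * `stable`: every clone moves by at most 0.05;
#' * `dynamic`: a dominant subclone (fraction 0.6-0.85) collapses below 0.04
#'   while a rare subclone (0.01-0.03) expands above 0.55, emulating
#'   near-complete replacement of a dominant baseline subclone;
#' * `emergent`: one leaf clone sits below the ~1% VAF detection limit at
#'   baseline and dominates the surgical sample;
#' * `collision`: two trees with disjoint clones, one present per time point;
#' * `monoclonal`: a single founder at fraction 1 at both time points.
#'
#' @param n_clones Clone count (see [simulation_config()]).
#' @param scenario Scenario name.
#' @param seed Integer seed (fixed seed gives identical truth sets).
#' @param n_cores_per_timepoint Cores per time point.
#' @param core_concentration Dirichlet concentration of per-core jitter
#'   (`Inf` = identical cores).
#' @return A list of class `clone_truth` with elements `tree_parent` (named
#'   integer vector, `NA` at roots), `exclusive_fraction` (clones x samples
#'   matrix), `samples` (tibble: sample, timepoint, core), `tumour` (clone
#'   membership for collision cases) and `scenario`.
#' @examples
#' simulate_phylogeny(3, "dynamic", seed = 1)
#' @export
simulate_phylogeny <- function(n_clones, scenario, seed = NULL,
                               n_cores_per_timepoint = 1,
                               core_concentration = 50) {
  cfg <- simulation_config(n_clones = n_clones, scenario = scenario,
                           n_cores_per_timepoint = n_cores_per_timepoint)
  local_seed(seed, {
    k <- cfg$n_clones
    sc <- scenario_fractions(k, cfg$scenario)
    clones <- paste0("C", seq_len(k))
    parent <- rep(NA_integer_, k)
    for (tu in unique(sc$tumour)) {
      idx <- which(sc$tumour == tu)
      for (j in seq_along(idx)[-1]) {
        parent[idx[j]] <- idx[sample.int(j - 1L, 1L)]
      }
    }
    names(parent) <- clones
    samples <- sample_names(cfg$n_cores_per_timepoint)
    frac <- matrix(0, k, nrow(samples),
                   dimnames = list(clones, samples$sample))
    for (i in seq_len(nrow(samples))) {
      f <- sc$fractions[, samples$timepoint[i]]
      if (cfg$n_cores_per_timepoint > 1 && is.finite(core_concentration) &&
          k > 1) {
        f <- rdirichlet1(core_concentration * f + 1e-3)
        # jitter must not resurrect clones from the other collision tumour
        f[sc$fractions[, samples$timepoint[i]] == 0] <- 0
        if (sum(f) > 0) f <- f / sum(f)
      }
      frac[, i] <- f
    }
    structure(list(tree_parent = parent, exclusive_fraction = frac,
                   samples = samples, tumour = setNames(sc$tumour, clones),
                   scenario = cfg$scenario),
              class = "clone_truth")
  })
}

#' Cellular prevalence of each clone in each sample of a truth set
#'
#' Prevalence of a clone is the summed exclusive fraction of its subtree
#' (clone plus all descendants).
#'
#' @param truth A `clone_truth` object.
#' @return Clones x samples matrix of prevalences in `[0, 1]`.
#' @export
clone_prevalence <- function(truth) {
  k <- length(truth$tree_parent)
  prev <- truth$exclusive_fraction
  # accumulate children into parents; process nodes deepest-first
  depth <- vapply(seq_len(k), function(i) {
    d <- 0L
    while (!is.na(truth$tree_parent[i])) { i <- truth$tree_parent[i]; d <- d + 1L }
    d
  }, integer(1))
  for (i in order(depth, decreasing = TRUE)) {
    p <- truth$tree_parent[i]
    if (!is.na(p)) prev[p, ] <- prev[p, ] + prev[i, ]
  }
  prev
}

#' Simulate read counts for a planted truth set
#'
#' For a variant assigned to clone `c` in sample `s`, the expected VAF is
#' `purity_s * prevalence_{c,s} / 2` (copy-number-neutral heterozygous
#' model). DNA and RNA depths are Poisson around their means (DNA floored at
#' 1 read) and variant reads are binomial at the expected VAF perturbed by
#' the per-allele sequencing error; the matched normal carries error-rate
#' noise only.
#'
#' @param truth A `clone_truth` from [simulate_phylogeny()].
#' @param config A [simulation_config()] consistent with `truth`.
#' @param case_id Case identifier written into the table.
#' @return A variant tibble in the package's standard layout (see
#'   [read_variant_table()]) with an extra `clone` column carrying the
#'   planted assignment, plus attribute `purity` (named per-sample vector).
#' @examples
#' tr <- simulate_phylogeny(2, "stable", seed = 1)
#' simulate_reads(tr, simulation_config(2, "stable", seed = 1))
#' @export
simulate_reads <- function(truth, config, case_id = "SIM1") {
  stopifnot(inherits(truth, "clone_truth"), inherits(config, "sim_config"))
  if (config$n_clones != length(truth$tree_parent) ||
      config$n_cores_per_timepoint * 2L != nrow(truth$samples)) {
    abort("truth and config disagree on clone or sample counts",
          class = "clonaldrift_config_error")
  }
  local_seed(config$seed, {
    smp <- truth$samples
    ns <- nrow(smp)
    purity <- config$purity_by_sample
    if (is.null(purity)) {
      pr <- config$purity_range %||% c(0.12, 1)
      purity <- runif(ns, pr[1], pr[2])
    }
    purity <- rep_len(purity, ns)
    names(purity) <- smp$sample
    prev <- clone_prevalence(truth)
    k <- config$n_clones
    nv <- config$n_variants_per_clone
    n <- k * nv
    e <- config$error_rate

    chrom <- paste0("chr", sample(1:22, n, replace = TRUE))
    pos <- sample.int(2e8, n)               # unique loci genome-wide
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    clone <- rep(rownames(prev), each = nv)

    rows <- purrr::map(seq_len(ns), function(s) {
      evaf <- purity[s] * prev[clone, s] / 2
      p <- evaf * (1 - e) + (1 - evaf) * e
      d_dna <- pmax(1L, rpois(n, config$depth_mean))
      v_dna <- rbinom(n, d_dna, p)
      d_nrm <- pmax(1L, rpois(n, config$depth_mean))
      v_nrm <- rbinom(n, d_nrm, e)
      d_rna <- rpois(n, config$rna_depth_mean)
      v_rna <- rbinom(n, d_rna, p)
      tibble(
        case = case_id, sample = smp$sample[s], timepoint = smp$timepoint[s],
        chrom = chrom, pos = pos, ref = ref, alt = alt,
        dna_ref_reads = d_dna - v_dna, dna_var_reads = v_dna,
        rna_ref_reads = d_rna - v_rna, rna_var_reads = v_rna,
        gene = NA_character_, aa_change = NA_character_, tier = 1L,
        normal_ref_reads = d_nrm - v_nrm, normal_var_reads = v_nrm,
        clone = clone
      )
    })
    out <- dplyr::bind_rows(rows)
    attr(out, "purity") <- purity
    out
  })
}

#' Simulate a complete two-time-point case
#'
#' Convenience wrapper: draws the phylogeny, per-sample purities and read
#' counts in one deterministic step. When `min_vaf_separation > 0` the
#' phylogeny and purities are redrawn (deterministically, bounded attempts)
#' until every clone pair's expected VAFs differ by at least that much in
#' some sample, so that the planted clusters are resolvable.
#'
#' @param config A [simulation_config()].
#' @param case_id Case identifier.
#' @param min_vaf_separation Minimum pairwise expected-VAF separation
#'   (max over samples) between clones; 0 disables the rejection step.
#' @return List with `truth` (`clone_truth`, plus `purity` element),
#'   `variants` (tibble from [simulate_reads()]) and `config`.
#' @export
simulate_case <- function(config, case_id = "SIM1", min_vaf_separation = 0) {
  stopifnot(inherits(config, "sim_config"))
  base_seed <- config$seed %||% 0L
  ns <- config$n_cores_per_timepoint * 2L
  for (attempt in seq_len(500L)) {
    seed_i <- (base_seed + 7919L * (attempt - 1L)) %% .Machine$integer.max
    truth <- simulate_phylogeny(config$n_clones, config$scenario,
                                seed = seed_i,
                                n_cores_per_timepoint = config$n_cores_per_timepoint,
                                core_concentration = config$core_concentration)
    purity <- config$purity_by_sample
    if (is.null(purity)) {
      pr <- config$purity_range %||% c(0.12, 1)
      purity <- local_seed(seed_i + 1L, runif(ns, pr[1], pr[2]))
    }
    purity <- rep_len(purity, ns)
    if (min_vaf_separation > 0 && config$n_clones > 1) {
      prev <- clone_prevalence(truth)
      evaf <- sweep(prev, 2, purity, `*`) / 2
      pairs <- utils::combn(nrow(evaf), 2)
      sep <- apply(pairs, 2, function(ij) {
        max(abs(evaf[ij[1], ] - evaf[ij[2], ]))
      })
      if (min(sep) < min_vaf_separation) next
    }
    cfg <- config
    cfg$purity_by_sample <- purity
    cfg$seed <- seed_i + 2L
    truth$purity <- setNames(purity, truth$samples$sample)
    variants <- simulate_reads(truth, cfg, case_id = case_id)
    return(list(truth = truth, variants = variants, config = cfg))
  }
  abort("could not satisfy min_vaf_separation in 500 attempts; lower it or reduce n_clones",
        class = "clonaldrift_config_error")
}

#' Planted clonal instability index and pattern of a truth set
#'
#' Computes, from the planted fractions, the same quantities the pipeline
#' estimates: per-time-point mean exclusive fractions across cores, the
#' instability index over clones detectable at the LOD, and the implied
#' pattern class.
#'
#' @param truth A `clone_truth` (with `purity` when available; defaults to 1).
#' @param lod Detection limit on the VAF scale.
#' @return List with `index`, `pattern`, `fractions_baseline`,
#'   `fractions_surgical`.
#' @export
truth_summary <- function(truth, lod = LOD_DEFAULT) {
  smp <- truth$samples
  f <- truth$exclusive_fraction
  pre <- rowMeans(f[, smp$sample[smp$timepoint == "baseline"], drop = FALSE])
  post <- rowMeans(f[, smp$sample[smp$timepoint == "surgical"], drop = FALSE])
  purity <- truth$purity %||% setNames(rep(1, nrow(smp)), smp$sample)
  prev <- clone_prevalence(truth)
  evaf <- sweep(prev, 2, purity[colnames(prev)], `*`) / 2
  det_pre <- apply(evaf[, smp$sample[smp$timepoint == "baseline"], drop = FALSE],
                   1, max) >= lod
  det_post <- apply(evaf[, smp$sample[smp$timepoint == "surgical"], drop = FALSE],
                    1, max) >= lod
  keep <- det_pre | det_post
  idx <- instability_index(pre[keep], post[keep], lod = 0)
  pattern <- if (truth$scenario == "collision") {
    "collision"
  } else if (length(truth$tree_parent) == 1) {
    "simple_stable"
  } else if (idx <= 0.1) "complex_stable" else "complex_dynamic"
  list(index = idx, pattern = pattern,
       fractions_baseline = pre, fractions_surgical = post)
}

#' Write a synthetic case to disk as plain-text fixtures
#'
#' Emits the four files downstream readers consume: `variants.tsv` (variant
#' read counts), `clinical.csv` (a clinical stub), `segments.bed`
#' (copy-number-neutral segments covering all loci, 0-based half-open) and
#' `truth.json` (tree, fractions, purity, assignments).
#'
#' @param records Variant tibble from [simulate_reads()].
#' @param truth The matching `clone_truth`.
#' @param directory Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(records, truth, directory) {
  if (nrow(records) == 0) {
    abort("records must be non-empty", class = "clonaldrift_config_error")
  }
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!ok) abort(sprintf("cannot create directory '%s'", directory),
                 class = "clonaldrift_io_error")
  paths <- file.path(directory,
                     c("variants.tsv", "clinical.csv", "segments.bed", "truth.json"))
  write_variant_table(dplyr::select(records, -dplyr::any_of("clone")), paths[1])

  clin <- tibble(case = unique(records$case), age = NA_integer_,
                 subtype_bl = NA_character_, subtype_surg = NA_character_,
                 ki67_bl = NA_real_, ki67_surg = NA_real_,
                 ki67_response = NA_character_,
                 allred_bl = NA_integer_, allred_surg = NA_integer_,
                 manual_pattern = NA_character_)
  readr::write_csv(clin, paths[2], na = "")

  seg <- tidyr::expand_grid(chrom = paste0("chr", 1:22),
                            sample = unique(records$sample)) |>
    mutate(start = 0L, end = 250000000L, copy_number = 2) |>
    select("chrom", "start", "end", "sample", "copy_number")
  readr::write_tsv(seg, paths[3], col_names = FALSE)

  purity <- truth$purity %||% attr(records, "purity")
  key <- variant_key(records$chrom, records$pos, records$ref, records$alt)
  assignment <- if ("clone" %in% names(records)) {
    tapply(records$clone, key, `[`, 1)
  } else NULL
  truth_json <- list(
    tree_parent = as.list(ifelse(is.na(truth$tree_parent), "",
                                 names(truth$tree_parent)[truth$tree_parent])) |>
      setNames(names(truth$tree_parent)),
    exclusive_fraction = apply(truth$exclusive_fraction, 2, as.list),
    samples = truth$samples, purity = as.list(purity),
    scenario = truth$scenario,
    variant_assignment = as.list(assignment)
  )
  jsonlite::write_json(truth_json, paths[4], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Read back a truth-set JSON written by [write_fixture()]
#' @param path Path to `truth.json`.
#' @return A `clone_truth` object.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path)
  clones <- names(x$tree_parent)
  parent <- match(unlist(x$tree_parent), clones)
  names(parent) <- clones
  frac <- sapply(x$exclusive_fraction, function(col) unlist(col)[clones])
  if (is.null(dim(frac))) frac <- matrix(frac, nrow = length(clones),
                                         dimnames = list(clones, names(x$exclusive_fraction)))
  rownames(frac) <- clones
  samples <- dplyr::bind_rows(lapply(x$samples, as_tibble))
  structure(list(tree_parent = parent, exclusive_fraction = frac,
                 samples = samples, purity = unlist(x$purity),
                 scenario = x$scenario,
                 variant_assignment = unlist(x$variant_assignment)),
            class = "clone_truth")
}
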