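VARIANT_COLUMNS <- c("case", "sample", "timepoint", "chrom", "pos", "ref",
                     "alt", "dna_ref_reads", "dna_var_reads",
                     "rna_ref_reads", "rna_var_reads", "gene", "aa_change",
                     "tier")
COUNT_COLUMNS <- c("dna_ref_reads", "dna_var_reads", "rna_ref_reads",
                   "rna_var_reads", "normal_ref_reads", "normal_var_reads")

validate_variants <- function(x, what = "variant table") {
  assert_cols(x, VARIANT_COLUMNS, what)
  counts <- intersect(COUNT_COLUMNS, names(x))
  for (col in counts) {
    bad <- which(!is.na(x[[col]]) & x[[col]] < 0)
    if (length(bad) > 0) {
      abort(sprintf("negative %s in %s at row(s) %s", col, what,
                    paste(head(bad, 5), collapse = ", ")),
            class = "clonaldrift_validation_error")
    }
  }
  bad_tp <- which(!x$timepoint %in% c("baseline", "surgical", "eot"))
  if (length(bad_tp) > 0) {
    abort(sprintf("invalid timepoint in %s at row(s) %s (must be baseline/surgical/eot)",
                  what, paste(head(bad_tp, 5), collapse = ", ")),
          class = "clonaldrift_validation_error")
  }
  bad_tier <- which(!is.na(x$tier) & !x$tier %in% 1:3)
  if (length(bad_tier) > 0) {
    abort(sprintf("tier outside 1-3 in %s at row(s) %s", what,
                  paste(head(bad_tier, 5), collapse = ", ")),
          class = "clonaldrift_validation_error")
  }
  invisible(x)
}

#' Read a per-variant read-count table (TSV)
#'
#' The table has one row per variant per sample with DNA, RNA and (optional)
#' matched-normal read counts. Mandatory columns: case, sample, timepoint
#' (baseline/surgical/eot), chrom, pos (1-based), ref, alt, dna_ref_reads,
#' dna_var_reads, rna_ref_reads, rna_var_reads, gene, aa_change, tier.
#' Optional: normal_ref_reads, normal_var_reads, manually_flagged.
#'
#' @param path Path to a tab-separated file.
#' @return A validated tibble of variant records.
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "clonaldrift_io_error")
  }
  x <- readr::read_tsv(path, na = "", show_col_types = FALSE,
                       col_types = readr::cols(
                         chrom = readr::col_character(),
                         ref = readr::col_character(),
                         alt = readr::col_character(),
                         .default = readr::col_guess()))
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    abort(sprintf("unparseable row(s) in %s at line(s) %s", path,
                  paste(unique(head(probs$row, 5)), collapse = ", ")),
          class = "clonaldrift_format_error")
  }
  validate_variants(x, what = path)
  x
}

#' Write a variant table as TSV
#'
#' Inverse of [read_variant_table()]; the round trip is lossless (and
#' byte-identical for integer counts).
#'
#' @param records Variant tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_variant_table <- function(records, path) {
  validate_variants(records)
  ordered <- c(VARIANT_COLUMNS, setdiff(names(records), VARIANT_COLUMNS))
  readr::write_tsv(records[, ordered], path, na = "")
  invisible(path)
}

#' Read variants from a VCF (AD-style allelic depths)
#'
#' Reads a VCF 4.x with per-sample `AD` fields (ref,alt read counts), splits
#' multi-allelic records into one row per alternate allele, and maps VCF
#' sample columns to case/sample/time point via `sample_info`. RNA counts are
#' not carried by VCF and are returned as `NA`.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param sample_info Tibble with columns `vcf_sample`, `case`, `sample`,
#'   `timepoint`; rows restrict and rename the samples read. A row with
#'   `timepoint == "normal"` designates the matched normal, whose counts are
#'   attached to every tumour row as `normal_ref_reads`/`normal_var_reads`.
#' @return Variant tibble in the same layout as [read_variant_table()].
#' @export
read_variant_vcf <- function(path, sample_info) {
  assert_cols(sample_info, c("vcf_sample", "case", "sample", "timepoint"),
              "sample_info")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad)) {
    abort("VCF has no AD field", class = "clonaldrift_format_error")
  }
  missing <- setdiff(sample_info$vcf_sample, colnames(ad))
  if (length(missing) > 0) {
    abort(sprintf("VCF lacks sample(s): %s", paste(missing, collapse = ", ")),
          class = "clonaldrift_format_error")
  }
  n <- nrow(fix)
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  rows <- purrr::map(seq_len(n), function(i) {
    counts <- lapply(sample_info$vcf_sample, function(sm) {
      as.integer(strsplit(ad[i, sm], ",", fixed = TRUE)[[1]])
    })
    purrr::map(seq_along(alts[[i]]), function(j) {
      tibble(
        vcf_sample = sample_info$vcf_sample,
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[[i]][j],
        ref_reads = vapply(counts, `[`, integer(1), 1L),
        var_reads = vapply(counts, `[`, integer(1), j + 1L)
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  rows <- dplyr::left_join(rows, sample_info, by = "vcf_sample")
  normal <- dplyr::filter(rows, .data$timepoint == "normal") |>
    dplyr::select("chrom", "pos", "ref", "alt",
                  normal_ref_reads = "ref_reads", normal_var_reads = "var_reads")
  out <- dplyr::filter(rows, .data$timepoint != "normal") |>
    dplyr::transmute(
      case = .data$case, sample = .data$sample, timepoint = .data$timepoint,
      chrom = .data$chrom, pos = .data$pos, ref = .data$ref, alt = .data$alt,
      dna_ref_reads = .data$ref_reads, dna_var_reads = .data$var_reads,
      rna_ref_reads = NA_integer_, rna_var_reads = NA_integer_,
      gene = NA_character_, aa_change = NA_character_, tier = 1L)
  if (nrow(normal) > 0) {
    out <- dplyr::left_join(out, normal, by = c("chrom", "pos", "ref", "alt"))
  }
  validate_variants(out, what = path)
  out
}

#' Somatic binomial log-likelihood-ratio filter
#'
#' Compares, per variant, the binomial log likelihood of a somatic model
#' (normal at the sequencing error rate, tumour at its maximum-likelihood
#' allele fraction floored at the error rate) against the best germline
#' explanation (heterozygous: both samples at 0.5; wild type: both at the
#' error rate). A call is retained when both tumour and normal have at least
#' `min_depth` coverage and the log-likelihood ratio exceeds `min_llr`.
#' Natural logarithms are used.
#'
#' @param tumour_ref,tumour_var,normal_ref,normal_var Non-negative read
#'   counts (vectorised).
#' @param error_rate Per-allele sequencing error rate, in (0, 0.5).
#' @param min_llr Retention threshold on the LLR (default 3).
#' @param min_depth Minimum tumour and normal depth (default 10).
#' @return Tibble with columns `llr` and `retained`.
#' @examples
#' llr_somatic_filter(70, 30, 100, 0)
#' @export
llr_somatic_filter <- function(tumour_ref, tumour_var, normal_ref, normal_var,
                               error_rate = 0.001, min_llr = 3,
                               min_depth = 10) {
  if (error_rate <= 0 || error_rate >= 0.5) {
    abort("error_rate must lie in (0, 0.5)", class = "clonaldrift_config_error")
  }
  if (any(c(tumour_ref, tumour_var, normal_ref, normal_var) < 0)) {
    abort("read counts must be non-negative",
          class = "clonaldrift_validation_error")
  }
  td <- tumour_ref + tumour_var
  nd <- normal_ref + normal_var
  # 0 * log(0) arises when the MLE fraction is 0 or 1; define it as 0
  lbin <- function(v, d, f) {
    ifelse(v == 0, 0, v * log(f)) + ifelse(d - v == 0, 0, (d - v) * log1p(-f))
  }
  fhat <- pmax(ifelse(td > 0, tumour_var / td, 0), error_rate)
  l_som <- lbin(normal_var, nd, error_rate) + lbin(tumour_var, td, fhat)
  l_het <- lbin(normal_var, nd, 0.5) + lbin(tumour_var, td, 0.5)
  l_wt  <- lbin(normal_var, nd, error_rate) + lbin(tumour_var, td, error_rate)
  llr <- l_som - pmax(l_het, l_wt)
  tibble(llr = llr, retained = td >= min_depth & nd >= min_depth & llr > min_llr)
}

#' Read copy-number segments (BED-like, 0-based half-open)
#'
#' Columns (no header): chrom, start, end, sample, copy_number.
#'
#' @param path Path to the segment file.
#' @return Tibble with those columns.
#' @export
read_cn_segments <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "sample",
                                           "copy_number"),
                       col_types = "ciicd", na = "")
  if (any(x$start >= x$end)) {
    abort("segment with start >= end", class = "clonaldrift_validation_error")
  }
  if (any(x$copy_number < 0)) {
    abort("negative copy number", class = "clonaldrift_validation_error")
  }
  x
}

#' Keep only copy-number-neutral variants
#'
#' A variant locus is retained iff its copy number lies within `margin` of 2
#' in every sample of the case. Loci not covered by any segment default to
#' copy number 2. Overlapping segments with contradictory copy numbers for
#' the same sample raise a validation error.
#'
#' @param records Variant tibble.
#' @param segments Segment tibble from [read_cn_segments()] (chrom, start,
#'   end, sample, copy_number; 0-based half-open). `NULL` keeps everything.
#' @param margin Allowed deviation from copy number 2 (default 0.25, the
#'   margin used for copy-number-neutral clustering).
#' @return The subset of `records` at copy-number-neutral loci.
#' @export
cn_neutral_mask <- function(records, segments, margin = 0.25) {
  if (is.null(segments) || nrow(records) == 0) return(records)
  loci <- dplyr::distinct(records, .data$case, .data$chrom, .data$pos)
  cases <- dplyr::distinct(records, .data$case, .data$sample)
  grid <- dplyr::left_join(loci, cases, by = "case",
                           relationship = "many-to-many")
  hits <- dplyr::inner_join(grid, segments, by = c("chrom", "sample"),
                            relationship = "many-to-many") |>
    dplyr::filter(.data$start < .data$pos, .data$pos <= .data$end)
  contradictions <- hits |>
    dplyr::group_by(.data$case, .data$chrom, .data$pos, .data$sample) |>
    dplyr::summarise(ncn = dplyr::n_distinct(.data$copy_number),
                     .groups = "drop") |>
    dplyr::filter(.data$ncn > 1)
  if (nrow(contradictions) > 0) {
    abort(sprintf(
      "overlapping segments with contradictory copy numbers, e.g. %s:%d sample %s",
      contradictions$chrom[1], contradictions$pos[1], contradictions$sample[1]),
      class = "clonaldrift_validation_error")
  }
  cn <- dplyr::left_join(grid,
                         dplyr::distinct(hits, .data$case, .data$chrom,
                                         .data$pos, .data$sample,
                                         .data$copy_number),
                         by = c("case", "chrom", "pos", "sample")) |>
    mutate(copy_number = dplyr::coalesce(.data$copy_number, 2))
  keep <- cn |>
    dplyr::group_by(.data$case, .data$chrom, .data$pos) |>
    dplyr::summarise(neutral = all(abs(.data$copy_number - 2) <= margin),
                     .groups = "drop") |>
    dplyr::filter(.data$neutral)
  dplyr::semi_join(records, keep, by = c("case", "chrom", "pos"))
}
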