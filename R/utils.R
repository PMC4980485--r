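#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   across left_join bind_rows distinct pull n rename row_number if_else
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dbl map_lgl map_int map2 pmap imap keep
#' @importFrom stats median dbinom dpois rbinom rpois runif rgamma density
#'   setNames quantile fisher.test dhyper
#' @importFrom utils head tail
NULL

# Default limit of detection on the VAF scale (~1% VAF); clones or variants
# with VAF below this are treated as absent.
LOD_DEFAULT <- 0.01

#' Evaluate an expression under a fixed RNG seed, restoring RNG state after
#' @noRd
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Round half away from zero (so 0.535 -> 0.54, 24.55 -> 24.6)
#'
#' `base::round()` rounds half to even; report formatting here follows the
#' conventional half-up rule. A tiny epsilon guards against binary
#' representation of decimal halves.
#' @noRd
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Variant allele fraction from read counts
#'
#' @param ref_reads,var_reads Non-negative read counts.
#' @return `var_reads / (ref_reads + var_reads)`, `NA` where depth is zero.
#' @examples
#' vaf(70, 30)
#' @export
vaf <- function(ref_reads, var_reads) {
  depth <- ref_reads + var_reads
  ifelse(depth > 0, var_reads / depth, NA_real_)
}

#' Presence call at the detection limit
#'
#' Sequencing at the depths used here cannot support variants below roughly
#' 1% VAF; a variant (or clone median) is called present when its VAF is at
#' or above the limit of detection. The boundary is inclusive.
#'
#' @param vaf Variant allele fraction(s) in `[0, 1]`.
#' @param lod Limit of detection on the VAF scale (default 0.01).
#' @return Logical vector: `TRUE` when detectable.
#' @examples
#' apply_detection_limit(c(0, 0.009, 0.01, 0.5))
#' @export
apply_detection_limit <- function(vaf, lod = LOD_DEFAULT) {
  stopifnot(is.numeric(vaf), all(is.na(vaf) | (vaf >= 0 & vaf <= 1)))
  !is.na(vaf) & vaf >= lod
}

#' Stable key identifying one variant locus
#' @noRd
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

assert_cols <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing mandatory column(s): %s",
                  what, paste(missing, collapse = ", ")),
          class = "clonaldrift_format_error")
  }
  invisible(df)
}
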