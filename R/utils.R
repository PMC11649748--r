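# Internal condition constructors and small numeric helpers shared across
# modules.  Three error classes separate user-facing failure modes:
#   - config errors  (bad arguments / configuration; CLI exit status 2)
#   - parse errors   (malformed input files; CLI exit status 1)
#   - data errors    (valid files, invalid content; CLI exit status 1)

ff_config_error <- function(msg) {
  stop(errorCondition(msg,
    class = c("famfunnel_config_error", "famfunnel_error", "error")))
}

ff_parse_error <- function(msg) {
  stop(errorCondition(msg,
    class = c("famfunnel_parse_error", "famfunnel_data_error",
              "famfunnel_error", "error")))
}

ff_data_error <- function(msg) {
  stop(errorCondition(msg,
    class = c("famfunnel_data_error", "famfunnel_error", "error")))
}

#' Truncate a number to a fixed number of decimal places
#'
#' Truncation (chopping toward zero, no rounding) is the formatting dialect
#' used throughout the reports: a LOD of 1.505 prints as 1.50 and a carrier
#' frequency of 8/179 = 0.04469 prints as 0.044.  A tiny epsilon toward the
#' value guards against decimal fractions that are not exactly representable
#' in binary (e.g. 44/1000).
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return `x` truncated toward zero to `digits` decimals.
#' @examples
#' truncate_decimal(1.505, 2)      # 1.50
#' truncate_decimal(8 / 179, 3)    # 0.044
#' @export
truncate_decimal <- function(x, digits) {
  f <- 10^digits
  trunc(x * f + sign(x) * 1e-9) / f
}

# Canonical "chrom:pos:ref:alt" key used for set membership and joins.
#' Build the canonical variant key "chrom:pos:ref:alt"
#'
#' @param chrom,pos,ref,alt vectors of equal length.
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Format a numeric for text output: plain decimal notation, at most 6
# significant decimals, no trailing zeros.  All simulated scores are
# quantized to <= 6 decimals so this representation round-trips exactly.
ff_num <- function(x) {
  ifelse(is.na(x), ".", sub("\\.?0+$", "", sprintf("%.6f", x)))
}
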