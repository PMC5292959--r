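#' Upper-tail chi-square p-value on the -log10 scale, computed in log space
#'
#' Split-marker statistics routinely reach chi-square values around 200-300
#' (p down to 1e-60 and beyond), far below double-precision underflow on the
#' raw probability scale. The tail probability is therefore evaluated through
#' the log survival function and only ever handled as -log10(p).
#'
#' @param chisq Vector of chi-square statistics (nonnegative).
#' @param df Degrees of freedom.
#' @return `-log10` of the upper-tail p-value, same length as `chisq`.
#' @examples
#' chisq_neg_log10_p(271, df = 3) # ~57.7
#' @export
chisq_neg_log10_p <- function(chisq, df) {
  if (any(chisq < 0, na.rm = TRUE)) {
    rlang::abort("chi-square statistics must be nonnegative")
  }
  -stats::pchisq(chisq, df = df, lower.tail = FALSE, log.p = TRUE) / log(10)
}
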