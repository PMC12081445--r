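#' Round half away from zero at a fixed number of decimals
#'
#' Commercial ("half-up") rounding, as used when reporting percentages in
#' clinical cohort tables: 0.5 at the last kept digit always rounds up.
#' Base R's `round()` rounds half to even, which differs on exact halves.
#'
#' @param x Numeric vector (non-negative values expected for percentages).
#' @param digits Number of decimal places to keep.
#' @return Numeric vector rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(100 * 5 / 69, 2)  # 7.25
#' round_half_up(2.5, 0)           # 3 (base round() gives 2)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

ntrk_genes <- function() c("NTRK1", "NTRK2", "NTRK3")

verdict_levels <- function() c("ONCOGENIC", "LIKELY_ONCOGENIC", "VUS")

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_cols <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
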