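#' @keywords internal
"_PACKAGE"

# Internal validation helpers ------------------------------------------------

stop_bad_arg <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_lower = TRUE, allow_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_bad_arg(sprintf("'%s' must be a single finite number", name))
  ok_lo <- if (allow_lower) x >= lower else x > lower
  ok_hi <- if (allow_upper) x <= upper else x < upper
  if (!ok_lo || !ok_hi)
    stop_bad_arg(sprintf(
      "'%s' = %g is outside its valid range %s%g, %g%s", name, x,
      if (allow_lower) "[" else "(", lower, upper,
      if (allow_upper) "]" else ")"))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_number(x, name, lower = min)
  if (x != as.integer(x))
    stop_bad_arg(sprintf("'%s' must be a whole number", name))
  invisible(as.integer(x))
}

check_columns <- function(df, cols, name = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_bad_arg(sprintf("'%s' is missing required column(s): %s",
                         name, paste(missing, collapse = ", ")))
  invisible(df)
}

# Multiplicative Gaussian noise with coefficient of variation `cv`.
apply_noise_cv <- function(x, cv) {
  if (cv == 0) return(x)
  x * (1 + stats::rnorm(length(x), 0, cv))
}

#' Significance tier symbol for a p-value
#'
#' Maps a p-value onto the conventional significance tiers used for
#' group-comparison annotation in this field: p < 0.05, < 0.01, < 0.005 and
#' < 0.001 receive one to four marks respectively. Comparisons against a
#' primary reference group are marked with `"*"`, those against a secondary
#' reference with `"#"`.
#'
#' @param p p-value (numeric scalar in \[0, 1\]).
#' @param symbol single-character mark, usually `"*"` or `"#"`.
#' @param tiers decreasing vector of thresholds; the default matches the
#'   conventional four-tier annotation.
#' @return A string of 0-4 repeated symbols (`""` when not significant).
#' @examples
#' tier_symbol(0.03)    # "*"
#' tier_symbol(0.004)   # "***"
#' tier_symbol(0.0005)  # "****"
#' @export
tier_symbol <- function(p, symbol = "*", tiers = c(0.05, 0.01, 0.005, 0.001)) {
  if (is.na(p)) return("")
  if (any(diff(tiers) >= 0) || tiers[1] > 0.05)
    stop_bad_arg("'tiers' must be strictly decreasing and start at <= 0.05")
  strrep(symbol, sum(p < tiers))
}

#' Two-tailed pooled-variance (Student) t-test between two groups
#'
#' Classical Student t-test assuming equal variances, the test used throughout
#' for group comparisons. Welch's correction is available via `var_equal`.
#'
#' @param x,y numeric vectors of per-unit values (at least 2 each).
#' @param var_equal if `TRUE` (default) pooled-variance Student test,
#'   otherwise Welch.
#' @return A list with `mean_x`, `mean_y`, `sd_x`, `sd_y`, `t`, `df`, `p`,
#'   and `note` (non-`NA` when the statistic is degenerate).
#' @examples
#' student_t(c(10, 12, 11, 13), c(20, 22, 21, 23))$t
#' @export
student_t <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2)
    stop_bad_arg("both groups need at least 2 values")
  note <- NA_character_
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      # degenerate null: identical constants, report p = 1 rather than NaN
      return(list(mean_x = mean(x), mean_y = mean(y),
                  sd_x = 0, sd_y = 0, t = 0,
                  df = length(x) + length(y) - 2, p = 1,
                  note = "zero variance in both groups with equal means"))
    }
    note <- "zero variance in both groups; t is infinite"
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(mean_x = mean(x), mean_y = mean(y),
       sd_x = stats::sd(x), sd_y = stats::sd(y),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, note = note)
}
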