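# Echocardiographic systolic and diastolic indices and publication-style
# group statistics.

#' Systolic-function indices from M-mode dimensions and volumes
#'
#' Computes fractional shortening
#' `FS(%) = (LVID;d - LVID;s) / LVID;d * 100` from the left-ventricular
#' internal diameters and ejection fraction `EF(%) = (EDV - ESV) / EDV * 100`
#' from the instrument-supplied end-diastolic/systolic volumes. No volume is
#' estimated from dimensions (no Teichholz/cube formula): volumes are taken
#' as inputs.
#'
#' @param records data.frame with columns `lvid_d_mm`, `lvid_s_mm`, `edv_ul`,
#'   `esv_ul` (identifier columns are carried through).
#' @return The input data.frame with `fs_pct` and `ef_pct` appended.
#' @examples
#' compute_systolic(data.frame(lvid_d_mm = 4.0, lvid_s_mm = 2.8,
#'                             edv_ul = 70, esv_ul = 25))
#' @export
compute_systolic <- function(records) {
  check_columns(records, c("lvid_d_mm", "lvid_s_mm", "edv_ul", "esv_ul"),
                "records")
  with(records, {
    if (any(lvid_d_mm <= 0) || any(edv_ul <= 0))
      stop_bad_arg("LVID;d and EDV must be positive")
    if (any(lvid_s_mm > lvid_d_mm) || any(esv_ul > edv_ul))
      stop_bad_arg("non-physiological record: LVID;s > LVID;d or ESV > EDV")
  })
  records$fs_pct <- (records$lvid_d_mm - records$lvid_s_mm) /
    records$lvid_d_mm * 100
  records$ef_pct <- (records$edv_ul - records$esv_ul) / records$edv_ul * 100
  records
}

#' Diastolic-function indices from Doppler velocities
#'
#' Computes the transmitral inflow ratio `E/A` and the inflow-to-annular
#' ratio `E/E'` from peak early (E) and late (A) diastolic transmitral flow
#' velocities and the early diastolic mitral-annular tissue velocity (E').
#'
#' Two reporting conventions exist and both are supported: `mode =
#' "per_animal"` computes the ratio for every record (the statistical
#' convention), while `mode = "group_means"` computes the ratio of genotype
#' group means rounded to one decimal (the convention of summary tables built
#' from group-mean velocities).
#'
#' @param records data.frame with columns `e_mm_s`, `a_mm_s`, `eprime_mm_s`
#'   (and `genotype` for group mode).
#' @param mode `"per_animal"` or `"group_means"`.
#' @param digits rounding for group-mean mode (default 1, the table
#'   convention).
#' @return For `"per_animal"`: the input with `e_over_a` and `e_over_eprime`
#'   appended. For `"group_means"`: a data.frame with one row per genotype
#'   (`genotype`, `e_over_a`, `e_over_eprime`, rounded).
#' @examples
#' compute_diastolic(data.frame(e_mm_s = 569.7, a_mm_s = 408.0,
#'                              eprime_mm_s = 25.6))
#' @export
compute_diastolic <- function(records, mode = c("per_animal", "group_means"),
                              digits = 1) {
  mode <- match.arg(mode)
  check_columns(records, c("e_mm_s", "a_mm_s", "eprime_mm_s"), "records")
  if (any(records$a_mm_s <= 0) || any(records$eprime_mm_s <= 0))
    stop_bad_arg("zero or negative Doppler denominator (A or E')")
  if (mode == "per_animal") {
    records$e_over_a <- records$e_mm_s / records$a_mm_s
    records$e_over_eprime <- records$e_mm_s / records$eprime_mm_s
    return(records)
  }
  check_columns(records, "genotype", "records")
  out <- do.call(rbind, lapply(split(records, records$genotype), function(g) {
    data.frame(genotype = g$genotype[1L],
               e_over_a = round(mean(g$e_mm_s) / mean(g$a_mm_s), digits),
               e_over_eprime = round(mean(g$e_mm_s) / mean(g$eprime_mm_s),
                                     digits),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Publication-style group summary of echocardiographic metrics
#'
#' Produces a summary-table layout: mean +/- SD per genotype for each metric,
#' with two-tailed pooled-variance Student t-tests of every genotype against
#' each designated reference group. Comparisons against the first reference
#' are annotated with `"*"` tier symbols and against the second with `"#"`,
#' using the conventional thresholds p < 0.05, 0.01, 0.005, 0.001 (no
#' multiple-testing correction, matching common practice for such tables).
#'
#' @param records data.frame with `animal_id`, `genotype` and numeric metric
#'   columns (e.g. the output of [compute_systolic()] /
#'   [compute_diastolic()]).
#' @param metrics character vector of metric column names to summarize
#'   (default: all numeric columns).
#' @param reference reference genotype(s), length 1 or 2.
#' @param tiers decreasing significance thresholds (see [tier_symbol()]).
#' @param var_equal pooled-variance Student test (default) or Welch.
#' @return A list of class `echo_summary` with `table` (genotype x metric
#'   rows: mean, sd, n, annotation string combining both references' marks)
#'   and `tests` (long data.frame of each comparison).
#' @export
summarize_groups <- function(records, metrics = NULL, reference,
                             tiers = c(0.05, 0.01, 0.005, 0.001),
                             var_equal = TRUE) {
  check_columns(records, c("animal_id", "genotype"), "records")
  if (is.null(metrics)) {
    metrics <- names(records)[vapply(records, is.numeric, logical(1))]
  }
  if (!length(metrics)) stop_bad_arg("no metric columns to summarize")
  check_columns(records, metrics, "records")
  if (length(reference) < 1 || length(reference) > 2)
    stop_bad_arg("supply 1 or 2 reference genotypes")
  if (!all(reference %in% records$genotype))
    stop_bad_arg("unknown reference label: ",
                 paste(setdiff(reference, records$genotype), collapse = ", "))
  counts <- table(records$genotype)
  if (any(counts[reference] < 2))
    stop_bad_arg("reference group needs at least 2 animals")

  marks <- c("*", "#")
  tests <- list()
  rows <- list()
  for (g in unique(records$genotype)) {
    gg <- records[records$genotype == g, , drop = FALSE]
    for (m in metrics) {
      ann <- ""
      for (r in seq_along(reference)) {
        if (g == reference[r]) next
        ref <- records[records$genotype == reference[r], m]
        if (nrow(gg) < 2) next
        tt <- student_t(gg[[m]], ref, var_equal = var_equal)
        sym <- tier_symbol(tt$p, marks[r], tiers)
        ann <- paste0(ann, sym)
        tests[[length(tests) + 1L]] <- data.frame(
          genotype = g, reference = reference[r], metric = m,
          t = tt$t, df = tt$df, p = tt$p, tier = sym,
          stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = g, metric = m, mean = mean(gg[[m]]),
        sd = if (nrow(gg) > 1) stats::sd(gg[[m]]) else NA_real_,
        n = nrow(gg), annotation = ann, stringsAsFactors = FALSE)
    }
  }
  structure(list(
    table = do.call(rbind, rows),
    tests = if (length(tests)) do.call(rbind, tests) else NULL,
    reference = reference, tiers = tiers,
    test = if (var_equal) "Student (pooled variance)" else "Welch"),
    class = "echo_summary")
}

#' @export
print.echo_summary <- function(x, ...) {
  cat(sprintf("Group summary (%s t-tests vs %s)\n", x$test,
              paste(x$reference, collapse = " and ")))
  tab <- x$table
  tab$mean <- signif(tab$mean, 4)
  tab$sd <- signif(tab$sd, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
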