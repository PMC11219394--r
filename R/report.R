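#' Render an analysis object as a deterministic text report
#'
#' Produces machine-readable (`"tsv"`) or human-readable (`"text"`) output for
#' the package's result objects, printing numbers at fixed precision so the
#' same object always renders to byte-identical output. The TSV form of a
#' stratum table round-trips all estimates at the printed precision.
#'
#' @param report a `stratum_estimate_set`, `pooled_estimate_set`,
#'   `nco_report` or `transition_matrix`.
#' @param format `"tsv"` or `"text"`.
#' @param path optional file to write to.
#' @return Invisibly, a character vector of lines.
#' @export
render_report <- function(report, format = c("tsv", "text"), path = NULL) {
  if (length(format) > 1L) format <- format[1]
  if (!format %in% c("tsv", "text"))
    stop_("unknown format '", format, "' (use \"tsv\" or \"text\")")
  lines <- if (format == "tsv") render_tsv(report) else render_text(report)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

report_frame <- function(report) UseMethod("report_frame")

#' @export
report_frame.stratum_estimate_set <- function(report) {
  tab <- report$table
  data.frame(method = report$method, outcome = report$outcome,
             tab[, c("stratum", "n", "mean_exposure", "min_exposure",
                     "max_exposure", "mean_instrument", "beta", "se",
                     "ci_low", "ci_high", "p_value", "fs_beta", "fs_se")])
}

#' @export
report_frame.transition_matrix <- function(report) {
  J <- report$J
  data.frame(occasion1 = rep(seq_len(J), each = J),
             occasion2 = rep(seq_len(J), times = J),
             count = as.integer(t(report$counts)),
             proportion = as.numeric(t(report$proportions)))
}

#' @export
report_frame.nco_report <- function(report) {
  rows <- list(data.frame(
    method = character(0), outcome = character(0), stratum = integer(0),
    n = integer(0), mean_exposure = numeric(0), min_exposure = numeric(0),
    max_exposure = numeric(0), mean_instrument = numeric(0),
    beta = numeric(0), se = numeric(0), ci_low = numeric(0),
    ci_high = numeric(0), p_value = numeric(0), fs_beta = numeric(0),
    fs_se = numeric(0)))
  for (outc in names(report$outcomes)) {
    o <- report$outcomes[[outc]]
    ov <- o$overall
    rows[[length(rows) + 1L]] <- data.frame(
      method = "conventional", outcome = outc, stratum = 0L, n = ov$n,
      mean_exposure = NA_real_, min_exposure = NA_real_,
      max_exposure = NA_real_, mean_instrument = NA_real_,
      beta = ov$beta, se = ov$se, ci_low = ov$ci_low, ci_high = ov$ci_high,
      p_value = ov$p_value, fs_beta = NA_real_, fs_se = NA_real_)
    for (meth in names(o$per_method))
      rows[[length(rows) + 1L]] <-
        report_frame(o$per_method[[meth]]$set)
  }
  do.call(rbind, rows)
}

render_tsv <- function(report) {
  df <- report_frame(report)
  num <- vapply(df, is.numeric, TRUE) &
    !vapply(df, is.integer, TRUE)
  for (cn in names(df)[num]) df[[cn]] <- fmt_num(df[[cn]])
  body <- if (nrow(df))
    apply(df, 1, function(r) paste(r, collapse = "\t")) else character(0)
  c(paste(names(df), collapse = "\t"), body)
}

render_text <- function(report) {
  df <- report_frame(report)
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  for (cn in names(df)[num]) df[[cn]] <- fmt_num(df[[cn]], digits = 4)
  c(utils::capture.output(print(df, row.names = FALSE)))
}
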