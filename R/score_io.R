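#' Weighted allele score from a dosage matrix
#'
#' Builds the polygenic instrument as a summed weighted allele score,
#' `score_i = sum_k weight_k * dosage_ik`, with each allele weighted by its
#' effect on the exposure. Missing dosages are mean-imputed per variant
#' (standard PRS practice), so the score of rows with complete data never
#' changes. Weights files are assumed pre-harmonized to the effect allele;
#' strand-ambiguity resolution is out of scope.
#'
#' @param dosages numeric matrix (or data.frame) of allele counts in
#'   \[0, 2\], columns named by variant id.
#' @param weights data.frame with columns `variant_id`, `effect_allele`
#'   (one of A/C/G/T) and `weight` (exposure units per allele); variant ids
#'   unique. See [read_weights()].
#' @return Numeric vector of scores, one per row of `dosages`.
#' @export
score_individuals <- function(dosages, weights) {
  if (is.data.frame(dosages)) dosages <- as.matrix(dosages)
  stopifnot(is.matrix(dosages))
  check_weights(weights)
  missing_v <- setdiff(weights$variant_id, colnames(dosages))
  if (length(missing_v))
    stop_("variant(s) in weights absent from dosages: ",
          paste(missing_v, collapse = ", "))
  D <- dosages[, weights$variant_id, drop = FALSE]
  storage.mode(D) <- "double"
  rng <- range(D, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop_("dosages must lie in [0, 2]")
  if (anyNA(D)) {
    for (k in seq_len(ncol(D))) {
      nas <- is.na(D[, k])
      if (any(nas)) D[nas, k] <- mean(D[, k], na.rm = TRUE)
    }
  }
  unname(drop(D %*% weights$weight))
}

check_weights <- function(weights) {
  stopifnot(is.data.frame(weights))
  need <- c("variant_id", "effect_allele", "weight")
  miss <- setdiff(need, names(weights))
  if (length(miss))
    stop_("weights table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(weights$variant_id))
    stop_("duplicate variant_id in weights: ",
          paste(unique(weights$variant_id[duplicated(weights$variant_id)]),
                collapse = ", "))
  if (!all(weights$effect_allele %in% c("A", "C", "G", "T")))
    stop_("effect_allele must be one of A, C, G, T")
  if (any(!is.finite(weights$weight))) stop_("weights must be finite")
  invisible(weights)
}

#' Read a variant-weights file
#'
#' Three-column delimited text (`variant_id`, `effect_allele`, `weight`),
#' tab- or comma-separated, with a header row.
#'
#' @param path file path.
#' @return A validated weights data.frame.
#' @export
read_weights <- function(path) {
  w <- as.data.frame(data.table::fread(path, na.strings = "NA"))
  check_weights(w)
  w
}

#' Read a dosage matrix
#'
#' Delimited text with a header of variant ids; an optional leading `id`
#' column is used for row names. Values must lie in \[0, 2\]; `NA` marks
#' missing dosages (mean-imputed at scoring time).
#'
#' @param path file path.
#' @return A numeric matrix with variant-id column names.
#' @export
read_dosages <- function(path) {
  d <- as.data.frame(data.table::fread(path, na.strings = "NA"))
  if (names(d)[1] == "id") {
    rn <- d$id
    d <- d[, -1, drop = FALSE]
    m <- as.matrix(d)
    rownames(m) <- rn
  } else m <- as.matrix(d)
  storage.mode(m) <- "double"
  m
}

#' Read a cohort file
#'
#' Delimited text (TSV by default; comma accepted) with a header row and
#' `NA` for missing values. Required columns are checked by name and numeric
#' columns validated; a non-numeric value in a numeric column is reported
#' with its row number.
#'
#' @param path file path.
#' @param required columns that must be present.
#' @param numeric_cols columns that must parse as numeric.
#' @return A cohort data.frame.
#' @export
read_cohort <- function(path,
                        required = c("id", "instrument_score", "exposure"),
                        numeric_cols = intersect(
                          c("instrument_score", "exposure", "exposure_repeat",
                            "age", "sex", "outcome_continuous",
                            "outcome_binary", "selected"), required)) {
  co <- as.data.frame(data.table::fread(path, na.strings = "NA"))
  miss <- setdiff(required, names(co))
  if (length(miss))
    stop_("cohort file missing required column(s): ",
          paste(miss, collapse = ", "))
  for (cn in intersect(numeric_cols, names(co))) {
    if (!is.numeric(co[[cn]])) {
      suppressWarnings(v <- as.numeric(co[[cn]]))
      bad <- which(is.na(v) & !is.na(co[[cn]]))
      if (length(bad))
        stop_("non-numeric value in column '", cn, "' at row ", bad[1],
              " ('", co[[cn]][bad[1]], "')")
      co[[cn]] <- v
    }
  }
  co
}

#' Write a cohort (or any tabular result) to delimited text
#'
#' Tab-separated with a header row and `NA` for missing values; numeric
#' values are written at full (round-trip) precision.
#'
#' @param cohort a data.frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  data.table::fwrite(cohort, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Write an analysis result to a file
#'
#' Data.frames are written as TSV via [write_cohort()]; the package's result
#' objects are rendered with [render_report()].
#'
#' @param object a data.frame or a result object with a report method.
#' @param path file path.
#' @param format passed to [render_report()] for result objects.
#' @return `path`, invisibly.
#' @export
write_results <- function(object, path, format = "tsv") {
  if (is.data.frame(object)) return(write_cohort(object, path))
  render_report(object, format = format, path = path)
  invisible(path)
}
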