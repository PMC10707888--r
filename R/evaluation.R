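# MAE / RMSE / MAX error reports per SAPT component.

# Coerce a named list of sapt_record into an n x 5 matrix.
records_matrix <- function(records) {
  m <- t(vapply(records, function(r) {
    c(r$elst, r$exch, r$indu, r$disp, r$total)
  }, numeric(5)))
  colnames(m) <- c("Elst", "Exch", "Indu", "Disp", "Total")
  m
}

#' Error metrics per SAPT component
#'
#' MAE = mean |delta|, RMSE = sqrt(mean delta^2), MAX = max |delta| for
#' each of Elst/Exch/Indu/Disp/Total, with delta = predicted - reference
#' in kcal/mol.  Records are aligned by id when both lists are named.
#'
#' @param predicted,reference Lists of `sapt_record`, equal length; if
#'   both are named the names must match as sets (reference is reordered
#'   to the prediction ids).
#' @return data.frame of class `error_report`: rows
#'   Elst/Exch/Indu/Disp/Total, columns MAE/RMSE/MAX, plus attribute
#'   `n_records`.
#' @export
error_metrics <- function(predicted, reference) {
  if (length(predicted) != length(reference)) {
    stop(sprintf("length mismatch: %d predicted vs %d reference records",
                 length(predicted), length(reference)))
  }
  if (length(predicted) == 0) stop("no records to compare")
  if (!is.null(names(predicted)) && !is.null(names(reference))) {
    if (!setequal(names(predicted), names(reference))) {
      stop("record ids do not match between predicted and reference")
    }
    reference <- reference[names(predicted)]
  }
  d <- records_matrix(predicted) - records_matrix(reference)
  rep <- data.frame(
    MAE = colMeans(abs(d)),
    RMSE = sqrt(colMeans(d^2)),
    MAX = apply(abs(d), 2, max)
  )
  attr(rep, "n_records") <- length(predicted)
  class(rep) <- c("error_report", "data.frame")
  rep
}

#' Write an error report to CSV
#'
#' Rows Elst/Exch/Indu/Disp/Total, columns MAE/RMSE/MAX, kcal/mol.
#'
#' @param report An `error_report`.
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
write_error_report <- function(report, file) {
  out <- cbind(component = rownames(report), as.data.frame(report))
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Export per-dimer correlation data
#'
#' One row per (dimer, component) with reference and predicted energies,
#' sufficient to regenerate reference-vs-predicted correlation plots.
#'
#' @param predicted,reference Named lists of `sapt_record`, aligned by id.
#' @param file Output CSV path.
#' @param class_labels Optional named character vector of class labels by
#'   dimer id.
#' @return Invisibly, the data.frame written.
#' @export
correlation_export <- function(predicted, reference, file,
                               class_labels = NULL) {
  if (length(predicted) != length(reference)) stop("length mismatch")
  if (!is.null(names(predicted)) && !is.null(names(reference))) {
    if (!setequal(names(predicted), names(reference))) {
      stop("record ids do not match")
    }
    reference <- reference[names(predicted)]
  }
  pm <- records_matrix(predicted)
  rm_ <- records_matrix(reference)
  ids <- if (!is.null(names(predicted))) names(predicted) else
    as.character(seq_along(predicted))
  comps <- colnames(pm)
  df <- data.frame(
    dimer_id = rep(ids, each = length(comps)),
    class = if (is.null(class_labels)) NA_character_ else
      rep(unname(class_labels[ids]), each = length(comps)),
    component = rep(comps, times = length(ids)),
    reference_kcal = as.vector(t(rm_)),
    predicted_kcal = as.vector(t(pm)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(df)
}
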