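# Tab-separated subject tables: one row per subject, required IID column.

#' Read a subject-keyed TSV/CSV table
#'
#' @param path file path; delimiter inferred from the extension (`.csv` →
#'   comma, otherwise tab).
#' @param required column names that must be present (besides `IID`).
#' @return data frame with a character `IID` column.
#' @export
read_subject_table <- function(path, required = character()) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!"IID" %in% names(d)) stop("'", path, "' has no IID column")
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop("'", path, "' lacks required column(s): ", paste(miss, collapse = ", "))
  d$IID <- as.character(d$IID)
  if (anyDuplicated(d$IID)) stop("duplicated IID values in '", path, "'")
  d
}

#' Write imputed probabilities, labels and weights
#'
#' Emits the standard four-column TSV (`IID`, `P_AFFECTED`, `Y_IMPUTED`,
#' `WEIGHT`) from affection probabilities via [impute_and_weight()].
#'
#' @param path output file.
#' @param iid subject ids.
#' @param p affection probabilities.
#' @export
write_probabilities <- function(path, iid, p) {
  iw <- impute_and_weight(p)
  utils::write.table(
    data.frame(IID = iid, P_AFFECTED = p, Y_IMPUTED = iw$y, WEIGHT = iw$w),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
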