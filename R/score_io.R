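#' Read a docking score matrix from delimited text
#'
#' Expects a header row `compound_id,label,<structure_id_1>,...`; one row per
#' compound, labels in \{0, 1\}, `.` as decimal separator. Row order is
#' preserved.
#'
#' @param path Path to a CSV/TSV file.
#' @param sep Field delimiter; `","` (default) or `"\t"`.
#' @param allow_missing Logical; if `TRUE`, empty score cells or `NA` become
#'   missing values instead of errors (see [score_matrix()]).
#' @return A validated [score_matrix()].
#' @seealso [write_score_matrix()]
#' @export
read_score_matrix <- function(path, sep = ",", allow_missing = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 4L)
    stop("expected columns compound_id, label and at least 2 structures; got ",
         ncol(df), " columns")
  if (!identical(tolower(names(df)[1:2]), c("compound_id", "label")))
    stop("header must start with 'compound_id,label'; got '",
         paste(names(df)[1:2], collapse = ","), "'")

  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate compound_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  lab_raw <- trimws(df[[2L]])
  bad_lab <- which(!lab_raw %in% c("0", "1"))
  if (length(bad_lab))
    stop("label must be 0 or 1; row ", bad_lab[1L], " (compound '",
         ids[bad_lab[1L]], "') has label '", lab_raw[bad_lab[1L]], "'")
  labels <- as.integer(lab_raw)

  struct_ids <- names(df)[-(1:2)]
  scores <- matrix(NA_real_, nrow(df), length(struct_ids))
  for (j in seq_along(struct_ids)) {
    cell <- trimws(df[[j + 2L]])
    empty <- cell == "" | toupper(cell) == "NA"
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(val) & !empty)
    if (length(bad))
      stop("non-numeric score '", cell[bad[1L]], "' at row ", bad[1L],
           " (compound '", ids[bad[1L]], "'), column '", struct_ids[j], "'")
    if (any(empty) && !allow_missing)
      stop("missing score at row ", which(empty)[1L], ", column '",
           struct_ids[j], "' (use allow_missing = TRUE to accept)")
    scores[, j] <- val
  }
  score_matrix(scores, labels, compound_ids = ids,
               structure_ids = struct_ids, allow_missing = allow_missing)
}

#' Write a docking score matrix to delimited text
#'
#' @param m A [score_matrix()].
#' @param path Output file path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(m, path, sep = ",") {
  stopifnot(inherits(m, "score_matrix"))
  df <- data.frame(compound_id = m$compound_ids, label = m$labels,
                   check.names = FALSE, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(m$scores, check.names = FALSE))
  write_table(df, path, sep = sep)
}

#' Write a result table as delimited text
#'
#' Deterministic column order (as given), header always written; reading the
#' file back with [utils::read.csv()] reproduces the content.
#'
#' @param rows A data frame (possibly zero rows).
#' @param path Output file path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, sep = ",") {
  rows <- as.data.frame(rows, check.names = FALSE)
  utils::write.table(rows, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a run-configuration file
#'
#' YAML (or flat `key: value`) file holding run parameters such as `seed`,
#' `folds`, `alpha` and the null-distribution mode. Values are returned as a
#' named list; callers override them with function arguments.
#'
#' @param path Path to a YAML file.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("configuration file must define key: value pairs")
  cfg
}
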