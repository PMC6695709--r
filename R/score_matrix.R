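#' Construct a docking score matrix
#'
#' A `score_matrix` holds the raw per-structure docking scores of a
#' retrospective virtual screen: one row per compound, one column per protein
#' structure, plus a binary activity label per compound. Scores follow the
#' docking convention that lower (more negative) values mean better predicted
#' binding.
#'
#' @param scores Numeric matrix, rows = compounds, columns = structures.
#'   Lower = better.
#' @param labels Binary vector (1 = active, 0 = inactive/decoy), one entry
#'   per compound.
#' @param compound_ids Character vector of unique compound identifiers.
#'   Defaults to the rownames of `scores` or `CPD1..CPDn`.
#' @param structure_ids Character vector of unique structure identifiers.
#'   Defaults to the colnames of `scores` or `S1..Sm`.
#' @param allow_missing Logical; if `FALSE` (default) any non-finite score is
#'   an error. If `TRUE`, `NA` entries are kept and downstream fusion rules
#'   aggregate over the available values only.
#'
#' @return An object of class `score_matrix`: a list with elements
#'   `scores`, `labels`, `compound_ids`, `structure_ids`, `allow_missing`.
#' @examples
#' m <- score_matrix(matrix(c(-10, -9, -4, -5), 2, 2, byrow = TRUE),
#'                   labels = c(1, 0))
#' m
#' @export
score_matrix <- function(scores, labels, compound_ids = NULL,
                         structure_ids = NULL, allow_missing = FALSE) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  n <- nrow(scores)
  p <- ncol(scores)
  if (is.null(compound_ids)) {
    compound_ids <- rownames(scores)
    if (is.null(compound_ids)) compound_ids <- paste0("CPD", seq_len(n))
  }
  if (is.null(structure_ids)) {
    structure_ids <- colnames(scores)
    if (is.null(structure_ids)) structure_ids <- paste0("S", seq_len(p))
  }
  compound_ids <- as.character(compound_ids)
  structure_ids <- as.character(structure_ids)
  labels <- as.integer(labels)

  if (length(compound_ids) != n || length(labels) != n)
    stop("lengths of 'compound_ids' and 'labels' must equal nrow(scores)")
  if (length(structure_ids) != p)
    stop("length of 'structure_ids' must equal ncol(scores)")
  if (p < 2L)
    stop("a score matrix needs at least 2 structures (got ", p, ")")
  if (anyDuplicated(compound_ids))
    stop("duplicate compound_id: ",
         paste(unique(compound_ids[duplicated(compound_ids)]), collapse = ", "))
  if (anyDuplicated(structure_ids))
    stop("duplicate structure_id: ",
         paste(unique(structure_ids[duplicated(structure_ids)]), collapse = ", "))
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop("labels must be 0 (inactive) or 1 (active)")
  if (sum(labels == 1L) < 1L || sum(labels == 0L) < 1L)
    stop("need at least one active and one inactive compound")
  if (allow_missing) {
    if (any(is.nan(scores) | is.infinite(scores)))
      stop("scores must be finite or NA when allow_missing = TRUE")
    if (any(rowSums(is.finite(scores)) == 0L))
      stop("every compound needs at least one non-missing score")
  } else if (!all(is.finite(scores))) {
    bad <- which(!is.finite(scores), arr.ind = TRUE)[1L, ]
    stop("non-finite score for compound '", compound_ids[bad[1L]],
         "', structure '", structure_ids[bad[2L]], "'")
  }

  dimnames(scores) <- list(compound_ids, structure_ids)
  structure(
    list(scores = scores, labels = labels, compound_ids = compound_ids,
         structure_ids = structure_ids, allow_missing = allow_missing),
    class = "score_matrix"
  )
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("Docking score matrix: ", length(x$compound_ids), " compounds (",
      sum(x$labels == 1L), " actives, ", sum(x$labels == 0L),
      " inactives) x ", length(x$structure_ids), " structures\n", sep = "")
  cat("Structures:", paste(x$structure_ids, collapse = ", "), "\n")
  cat("Score range: [", format(min(x$scores, na.rm = TRUE)), ", ",
      format(max(x$scores, na.rm = TRUE)), "] (lower = better)\n", sep = "")
  invisible(x)
}

#' @export
dim.score_matrix <- function(x) dim(x$scores)

#' Subset a score matrix by compounds
#'
#' @param x A [score_matrix()].
#' @param i Row (compound) index vector.
#' @param ... Unused.
#' @return A `score_matrix` restricted to the selected compounds.
#' @export
`[.score_matrix` <- function(x, i, ...) {
  score_matrix(x$scores[i, , drop = FALSE], x$labels[i],
               compound_ids = x$compound_ids[i],
               structure_ids = x$structure_ids,
               allow_missing = x$allow_missing)
}
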