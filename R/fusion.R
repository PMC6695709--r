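#' The supported data-fusion rules
#'
#' @return Character vector of the seven rule names: minimum (`MIN`),
#'   maximum (`MAX`), arithmetic mean (`SUM`), geometric mean (`GEOM`),
#'   harmonic mean (`HARM`), median (`MED`) and Euclidean norm (`EUC`).
#' @export
fusion_rules <- function() c("MIN", "MAX", "SUM", "GEOM", "HARM", "MED", "EUC")

#' Fuse the docking scores of one compound
#'
#' Aggregates the per-structure docking scores `DS_1 .. DS_n` of a single
#' compound into one consensus score. Docking scores are negative-valued with
#' lower = better; the geometric and harmonic means are therefore computed on
#' the magnitudes and the common sign is restored, which keeps them
#' well-defined for any n. The Euclidean norm grows with more-negative
#' (better) scores, so its consensus is canonicalized by negation
#' (`canonical = TRUE`, the default) to share the lower-is-better orientation
#' of every other rule.
#'
#' @param scores Numeric vector of length >= 2 (or >= 1 with `na_rm = TRUE`
#'   after removing missing values); all finite, and for `GEOM`/`HARM`/`EUC`
#'   canonicalization all of uniform sign and nonzero.
#' @param rule One of [fusion_rules()].
#' @param canonical Logical; negate the Euclidean norm so that lower = better
#'   (requires all-negative input scores).
#' @param na_rm Logical; drop missing scores before fusing (the
#'   `allow_missing` policy).
#' @return A single consensus score.
#' @examples
#' fuse_row(c(-8, -6, -10), "GEOM")   # -(8*6*10)^(1/3)
#' fuse_row(c(-8, -6, -10), "EUC")    # -sqrt(200)
#' @export
fuse_row <- function(scores, rule, canonical = TRUE, na_rm = FALSE) {
  rule <- match.arg(rule, fusion_rules())
  if (na_rm) scores <- scores[!is.na(scores)]
  if (length(scores) < 2L && !na_rm)
    stop("need at least 2 scores to fuse (got ", length(scores), ")")
  if (length(scores) < 1L)
    stop("no scores left to fuse after removing missing values")
  if (!all(is.finite(scores))) stop("scores must be finite")
  switch(rule,
    MIN = min(scores),
    MAX = max(scores),
    SUM = mean(scores),
    MED = stats::median(scores),
    GEOM = {
      s <- .uniform_sign(scores, "GEOM")
      s * exp(mean(log(abs(scores))))
    },
    HARM = {
      s <- .uniform_sign(scores, "HARM")
      s * length(scores) / sum(1 / abs(scores))
    },
    EUC = {
      nrm <- sqrt(sum(scores^2))
      if (!canonical) return(nrm)
      s <- .uniform_sign(scores, "EUC canonicalization")
      if (s > 0)
        stop("EUC canonicalization assumes negative (lower = better) scores")
      -nrm
    }
  )
}

.uniform_sign <- function(scores, what) {
  sg <- sign(scores)
  if (any(sg == 0)) stop(what, " undefined for zero scores")
  if (length(unique(sg)) != 1L)
    stop(what, " undefined for mixed-sign scores")
  sg[1L]
}

#' Fuse a full score matrix with a set of rules
#'
#' Applies [fuse_row()] compound-wise for each requested rule and returns a
#' `fused_table` whose columns are all oriented lower-is-better
#' (canonicalized), ready for ranking and enrichment evaluation.
#'
#' @param m A [score_matrix()].
#' @param rules Character vector, nonempty subset of [fusion_rules()].
#' @return A `fused_table`: list with `compound_ids`, `labels`, `rules`,
#'   `values` (compounds x rules matrix) and `orientation`
#'   (`"lower_better"` for every canonicalized column).
#' @examples
#' m <- score_matrix(matrix(c(-10, -9, -4, -5), 2, 2, byrow = TRUE),
#'                   labels = c(1, 0))
#' fuse_matrix(m, c("MIN", "SUM"))$values
#' @export
fuse_matrix <- function(m, rules = fusion_rules()) {
  stopifnot(inherits(m, "score_matrix"))
  if (length(rules) == 0L) stop("'rules' must be a nonempty subset of fusion_rules()")
  rules <- unname(vapply(rules, match.arg, "", choices = fusion_rules()))
  if (anyDuplicated(rules)) stop("duplicate rules requested")
  vals <- matrix(NA_real_, length(m$compound_ids), length(rules),
                 dimnames = list(m$compound_ids, rules))
  for (r in rules) {
    vals[, r] <- vapply(seq_along(m$compound_ids), function(i) {
      tryCatch(
        fuse_row(m$scores[i, ], r, canonical = TRUE, na_rm = m$allow_missing),
        error = function(e) stop("compound '", m$compound_ids[i], "': ",
                                 conditionMessage(e), call. = FALSE)
      )
    }, numeric(1))
  }
  structure(
    list(compound_ids = m$compound_ids, labels = m$labels, rules = unname(rules),
         values = vals,
         orientation = stats::setNames(rep("lower_better", length(rules)), rules)),
    class = "fused_table"
  )
}

#' @export
print.fused_table <- function(x, ...) {
  cat("Consensus scores: ", length(x$compound_ids), " compounds x ",
      length(x$rules), " fusion rules (", paste(x$rules, collapse = ", "),
      "), all lower = better\n", sep = "")
  invisible(x)
}
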