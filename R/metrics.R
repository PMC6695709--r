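#' @name enrichment-metrics
#' @title Enrichment metrics for a ranked retrospective screen
#'
#' @description
#' All three metrics consume a vector of consensus (or single-structure)
#' scores with the docking orientation, lower = better, and a binary label
#' vector (1 = active). They are rank-based: any strictly monotone transform
#' of the scores leaves them unchanged. Ties receive average (mid) ranks, the
#' standard Mann-Whitney convention.
#'
#' * `auc_roc()` is the area under the ROC curve (TPR vs FPR over all score
#'   thresholds), computed in its rank (Mann-Whitney) formulation: the
#'   probability that a random active scores better than a random inactive,
#'   ties counted one half.
#' * `average_precision()` integrates the precision-recall curve with step
#'   integration, `AP = sum_k (R_k - R_{k-1}) P_k`, over increasing (i.e.
#'   worsening) score thresholds; tied scores enter as one threshold group.
#' * `bedroc()` is the Boltzmann-enhanced discrimination of ROC of Truchon
#'   and Bayly: the exponentially rank-weighted robust initial enhancement
#'   (RIE), rescaled to `[0, 1]`, emphasising early enrichment. `alpha`
#'   controls how fast the weight decays with rank; `alpha = 20` puts ~80% of
#'   the weight on the top ~8% of the ranking.
#'
#' @param scores Numeric vector, lower = better.
#' @param labels Binary vector, 1 = active, 0 = inactive.
#' @param alpha Positive early-recognition weight parameter (BEDROC only);
#'   default 20.
#' @return A single value in `[0, 1]`.
#' @examples
#' sc <- c(-10, -6, -5, -4); lb <- c(1, 0, 1, 0)
#' auc_roc(sc, lb)            # 0.75
#' average_precision(sc, lb)  # 5/6
#' bedroc(sc, lb)
NULL

.check_screen <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("'scores' and 'labels' must have equal length")
  if (!all(is.finite(scores))) stop("scores must be finite")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 or 1")
  n_act <- sum(labels == 1L)
  if (n_act == 0L || n_act == length(labels))
    stop("need at least one active and one inactive")
  labels
}

#' @rdname enrichment-metrics
#' @export
auc_roc <- function(scores, labels) {
  labels <- .check_screen(scores, labels)
  r <- rank(scores)              # rank 1 = best (lowest) score, midranks
  n0 <- sum(labels == 0L)
  n1 <- sum(labels == 1L)
  (sum(r[labels == 0L]) - n0 * (n0 + 1) / 2) / (n0 * n1)
}

#' @rdname enrichment-metrics
#' @export
average_precision <- function(scores, labels) {
  labels <- .check_screen(scores, labels)
  ord <- order(scores)
  lab <- labels[ord]
  n_act <- sum(lab)
  tp <- cumsum(lab)
  # indices closing each distinct-score group (ties share one threshold)
  last <- which(diff(scores[ord]) > 0)
  last <- c(last, length(lab))
  recall <- tp[last] / n_act
  prec <- tp[last] / last
  sum(diff(c(0, recall)) * prec)
}

#' @rdname enrichment-metrics
#' @export
bedroc <- function(scores, labels, alpha = 20) {
  labels <- .check_screen(scores, labels)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("'alpha' must be a single positive number")
  N <- length(labels)
  r <- rank(scores)[labels == 1L]  # average ranks of the actives
  n <- length(r)
  ra <- n / N
  # RIE: observed exponential rank weight sum over its random expectation
  rie <- mean(exp(-alpha * r / N)) /
    ((1 / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  rie * ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
    1 / (1 - exp(alpha * (1 - ra)))
}

#' ROC and precision-recall curve points
#'
#' Curve coordinates for plotting (the basis of standard ROC / PR figures),
#' evaluated at every distinct score threshold with ties grouped.
#'
#' @inheritParams auc_roc
#' @return A data frame with columns `threshold`, `tpr`, `fpr`, `precision`,
#'   `recall`, one row per distinct threshold, in improving-to-worsening
#'   score order.
#' @export
screen_curves <- function(scores, labels) {
  labels <- .check_screen(scores, labels)
  ord <- order(scores)
  lab <- labels[ord]
  n_act <- sum(lab)
  n_inact <- length(lab) - n_act
  tp <- cumsum(lab)
  fp <- seq_along(lab) - tp
  last <- c(which(diff(scores[ord]) > 0), length(lab))
  data.frame(
    threshold = scores[ord][last],
    tpr = tp[last] / n_act,
    fpr = fp[last] / n_inact,
    precision = tp[last] / last,
    recall = tp[last] / n_act
  )
}
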