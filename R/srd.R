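#' Rank-transform a score vector
#'
#' Transforms values to ranks in increasing magnitude: the best (smallest,
#' i.e. most negative docking score) value receives rank 1. Ties receive
#' average ranks, so ranks always sum to `n(n+1)/2`.
#'
#' @param values Numeric vector of finite values, lower = better.
#' @return Numeric vector of (possibly fractional) ranks.
#' @examples
#' rank_transform(c(-10, -4, -7))  # 1 3 2
#' @export
rank_transform <- function(values) {
  if (!all(is.finite(values))) stop("values must be finite")
  rank(values, ties.method = "average")
}

#' Build the minimax reference vector
#'
#' The hypothetical ideal consensus method for SRD analysis: each structure
#' column is first rank-transformed across compounds (removing per-structure
#' score offsets), then the reference value of an active compound is the
#' minimum (best) of its per-structure ranks and that of an inactive is the
#' maximum (worst). An ideal method gives actives the best possible and
#' inactives the worst possible scores.
#'
#' @param m A [score_matrix()].
#' @return Numeric vector over compounds (lower = better) with attributes
#'   `construction = "minimax"`, class `srd_reference`.
#' @export
build_reference <- function(m) {
  stopifnot(inherits(m, "score_matrix"))
  rk <- apply(m$scores, 2, rank_transform)
  ref <- ifelse(m$labels == 1L,
                apply(rk, 1, min),
                apply(rk, 1, max))
  structure(as.numeric(ref), names = m$compound_ids,
            construction = "minimax", class = "srd_reference")
}

#' Sum of ranking differences of one method against a reference
#'
#' Both vectors are rank-transformed (average ranks for ties) and the
#' absolute rank differences are summed: the Manhattan distance between the
#' two rankings. Zero means the method orders the compounds exactly like the
#' reference; [srd_max()] is the worst case (reversed ranking).
#'
#' @param method Numeric vector of method values (lower = better).
#' @param ref Reference vector (e.g. from [build_reference()]), same length.
#' @return Nonnegative SRD value (fractional if ties produced average ranks).
#' @examples
#' srd_value(c(2, 1, 3, 4), 1:4)  # 2
#' @export
srd_value <- function(method, ref) {
  if (length(method) != length(ref))
    stop("'method' and 'ref' must have equal length")
  sum(abs(rank_transform(as.numeric(method)) - rank_transform(as.numeric(ref))))
}

#' Maximum attainable SRD value
#'
#' The Manhattan distance between a ranking of n items and its reverse:
#' `n^2/2` for even n, `(n^2 - 1)/2` for odd n. Used to normalize SRD to the
#' 0-100 scale.
#'
#' @param n Number of ranked items, >= 2.
#' @return The maximum SRD value.
#' @export
srd_max <- function(n) {
  if (length(n) != 1L || n != round(n) || n < 2)
    stop("'n' must be a single integer >= 2")
  if (n %% 2 == 0) n^2 / 2 else (n^2 - 1) / 2
}

#' Null distribution of SRD under random ranking
#'
#' Distribution of the SRD value of a uniformly random permutation against a
#' fixed reference ranking — the randomization test (CRRN) that decides
#' whether a method ranks compounds better than chance. Exact probabilities
#' are computed for `n <= 12` by dynamic programming over partial rank
#' assignments (the reference taken tie-free); larger problems use seeded
#' Monte-Carlo permutation sampling, which also honours tied reference
#' ranks when a reference is supplied.
#'
#' @param n Number of ranked items, >= 2.
#' @param mode `"auto"` (exact when `n <= 12`), `"exact"` or
#'   `"monte_carlo"`.
#' @param n_samples Number of Monte-Carlo permutations (default `1e5`).
#' @param seed Integer seed for Monte-Carlo sampling.
#' @param ref Optional reference vector (values, lower = better) whose tie
#'   structure the Monte-Carlo null should honour; defaults to a tie-free
#'   reference.
#' @return An object of class `srd_null`: list with `n`, `mode`, `values`
#'   (achievable SRD values), `prob`, `cdf`.
#' @examples
#' srd_null(3)$prob  # 1/6, 1/3, 1/2 at SRD 0, 2, 4
#' @export
srd_null <- function(n, mode = c("auto", "exact", "monte_carlo"),
                     n_samples = 1e5, seed = 1L, ref = NULL) {
  mode <- match.arg(mode)
  if (length(n) != 1L || n != round(n) || n < 2)
    stop("'n' must be a single integer >= 2")
  if (mode == "auto") mode <- if (n <= 12) "exact" else "monte_carlo"
  if (mode == "exact") {
    if (n > 12)
      stop("exact null limited to n <= 12; use mode = 'monte_carlo'")
    counts <- .srd_null_counts(n)
    values <- seq(0, srd_max(n), by = 2)
    prob <- counts / factorial(n)
  } else {
    if (n_samples < 1) stop("'n_samples' must be positive")
    refrank <- if (is.null(ref)) seq_len(n) else rank_transform(as.numeric(ref))
    if (!is.null(ref) && length(refrank) != n)
      stop("'ref' must have length n")
    set.seed(as.integer(seed))
    draws <- vapply(seq_len(n_samples),
                    function(i) sum(abs(sample.int(n) - refrank)),
                    numeric(1))
    tab <- table(draws)
    values <- as.numeric(names(tab))
    prob <- as.numeric(tab) / n_samples
  }
  structure(list(n = n, mode = mode, values = values, prob = prob,
                 cdf = cumsum(prob)),
            class = "srd_null")
}

# Exact permutation counts of D = sum |pi(i) - i| by DP over partial
# assignments: processing positions/values 1..n jointly, the state is the
# number of still-open positions (= open values); every open pair adds 2 to
# D at each boundary it straddles.
.srd_null_counts <- function(n) {
  dmax <- srd_max(n)
  nd <- dmax / 2 + 1            # D is always even: store D/2
  f <- matrix(0, nrow = n + 1, ncol = nd)   # [o + 1, D/2 + 1]
  f[1, 1] <- 1
  for (k in seq_len(n)) {
    g <- matrix(0, nrow = n + 1, ncol = nd)
    last <- k == n
    for (o in 0:(k - 1)) {
      row <- f[o + 1, ]
      if (!any(row != 0)) next
      add <- function(op, w) {
        shift <- if (last) 0 else op       # boundary cost 2*o' -> D/2 += o'
        idx <- seq_len(nd - shift)
        g[op + 1, idx + shift] <<- g[op + 1, idx + shift] + w * row[idx]
      }
      add(o, 1)                            # new position matches new value
      if (o > 0) {
        add(o - 1, o * o)                  # both match old open partners
        add(o, 2 * o)                      # exactly one matches an old partner
      }
      add(o + 1, 1)                        # both stay open
    }
    f <- g
  }
  f[1, ]
}

#' @export
print.srd_null <- function(x, ...) {
  cat("SRD random-ranking null, n = ", x$n, " (", x$mode, ")\n", sep = "")
  cat("  5th percentile: ", format(srd_null_quantile(x, 0.05)),
      " (normalized ", format(round(100 * srd_null_quantile(x, 0.05) /
                                      srd_max(x$n), 2)), ")\n", sep = "")
  invisible(x)
}

#' Quantile of the SRD null distribution
#'
#' Smallest achievable SRD value whose cumulative probability reaches `p`;
#' the 5% quantile is the usual significance threshold — methods with SRD
#' below it rank compounds significantly better than random.
#'
#' @param null An `srd_null` object.
#' @param p Probability in (0, 1).
#' @return SRD value (raw scale; divide by [srd_max()] x 100 for normalized).
#' @export
srd_null_quantile <- function(null, p = 0.05) {
  stopifnot(inherits(null, "srd_null"), p > 0, p < 1)
  null$values[which(null$cdf >= p)[1L]]
}

#' Full SRD analysis of fused consensus scores
#'
#' Runs the complete sum-of-ranking-differences procedure for a set of
#' fusion rules against the minimax reference of the underlying score
#' matrix: column standardization (z-score, kept for fidelity with the
#' classical workflow although provably rank-invariant), full-data SRD
#' values normalized to 0-100, the random-ranking null, and k-fold
#' cross-validated SRD values. Each fold's value is recomputed from scratch
#' on the retained (k-1)/k subset: column re-ranking, reference rebuild and
#' renormalization by the subset's own maximum.
#'
#' @param fused A `fused_table` from [fuse_matrix()].
#' @param m The [score_matrix()] the table was fused from (reference source).
#' @param k_folds Number of cross-validation folds (default 7).
#' @param seed Integer seed controlling fold assignment and the Monte-Carlo
#'   null.
#' @param include_singles Logical; also evaluate each single-structure score
#'   column (rank-transformed) alongside the fusion rules.
#' @param folds Optional precomputed fold assignment (from [make_folds()]);
#'   overrides `k_folds`/`seed` for the fold split.
#' @param null_mode,n_null Passed to [srd_null()].
#' @return An `srd_result`: list with `method_names`, `srd_raw`, `srd_norm`,
#'   `null` (an `srd_null`), `cv_values` (method x fold matrix of normalized
#'   SRDs), `n`, `folds`.
#' @export
srd_analysis <- function(fused, m, k_folds = 7, seed = 1L,
                         include_singles = FALSE, folds = NULL,
                         null_mode = "auto", n_null = 1e5) {
  stopifnot(inherits(fused, "fused_table"), inherits(m, "score_matrix"))
  if (!identical(fused$compound_ids, m$compound_ids))
    stop("'fused' and 'm' must be aligned on the same compounds")
  n <- length(m$compound_ids)
  if (is.null(folds)) {
    if (k_folds < 2 || k_folds > n)
      stop("'k_folds' must be between 2 and the number of compounds")
    folds <- make_folds(m$labels, k = k_folds, seed = seed)
  }
  k_folds <- length(unique(folds))

  X <- fused$values
  if (include_singles) {
    singles <- apply(m$scores, 2, rank_transform)
    colnames(singles) <- m$structure_ids
    X <- cbind(X, singles)
  }
  # z-score each column; rank-invariant, retained for workflow fidelity
  X <- scale(X)

  ref <- build_reference(m)
  raw <- apply(X, 2, srd_value, ref = ref)
  norm <- 100 * raw / srd_max(n)

  cv <- matrix(NA_real_, ncol(X), k_folds,
               dimnames = list(colnames(X), paste0("fold", seq_len(k_folds))))
  for (f in seq_len(k_folds)) {
    keep <- folds != f
    sub_ref <- build_reference(m[keep])
    sub_max <- srd_max(sum(keep))
    cv[, f] <- 100 * apply(X[keep, , drop = FALSE], 2,
                           srd_value, ref = sub_ref) / sub_max
  }

  null <- srd_null(n, mode = null_mode, n_samples = n_null,
                   seed = as.integer(seed) + 1L, ref = ref)

  structure(list(method_names = colnames(X), srd_raw = unname(raw),
                 srd_norm = stats::setNames(unname(norm), colnames(X)),
                 null = null, cv_values = cv, n = n, folds = folds),
            class = "srd_result")
}

#' @export
print.srd_result <- function(x, ...) {
  cat("SRD analysis of", length(x$method_names), "methods over", x$n,
      "compounds\n")
  thr <- 100 * srd_null_quantile(x$null, 0.05) / srd_max(x$n)
  tab <- data.frame(
    srd_norm = round(x$srd_norm, 2),
    cv_mean = round(rowMeans(x$cv_values), 2),
    cv_sd = round(apply(x$cv_values, 1, stats::sd), 2),
    beats_random = x$srd_norm < thr
  )
  print(tab[order(tab$srd_norm), ])
  cat("random-ranking 5% threshold (normalized):", round(thr, 2), "\n")
  invisible(x)
}
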