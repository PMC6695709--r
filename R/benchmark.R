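#' Label-stratified cross-validation folds
#'
#' Randomly assigns compounds to `k` disjoint folds, stratified by activity
#' label so that actives are spread as evenly as possible (with heavily
#' imbalanced screens an unstratified split could leave folds without
#' actives). Fold sizes differ by at most one within each label class, and
#' overall by at most one, because each class is dealt to the currently
#' smallest folds first. Reproducible given `seed`.
#'
#' @param labels Binary label vector (1 = active).
#' @param k Number of folds (default 7).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, one per compound.
#' @export
make_folds <- function(labels, k = 7, seed = 1L) {
  labels <- as.integer(labels)
  n <- length(labels)
  if (k < 2 || k > n) stop("'k' must be between 2 and length(labels)")
  if (sum(labels == 1L) < k)
    warning("fewer actives (", sum(labels == 1L), ") than folds (", k,
            "); some folds will contain no actives")
  set.seed(as.integer(seed))
  fold <- integer(n)
  sizes <- integer(k)
  for (cls in c(1L, 0L)) {
    idx <- sample(which(labels == cls))
    while (length(idx)) {
      take <- seq_len(min(k, length(idx)))
      dest <- order(sizes)[take]          # fill the smallest folds first
      fold[idx[take]] <- dest
      sizes[dest] <- sizes[dest] + 1L
      idx <- idx[-take]
    }
  }
  fold
}

#' Cross-validated enrichment metrics for every fusion rule
#'
#' The full evaluation grid: fuses the score matrix with each rule, splits
#' compounds into `k` stratified folds, and computes AUC, average precision,
#' BEDROC and the normalized SRD for every (rule, fold) cell. Enrichment
#' metrics are evaluated on each fold's retained (k-1)/k subset by default so
#' that they share folds (and subset sizes) with the SRD cross-validation;
#' `subset = "heldout"` switches to the complementary 1/k subset. The result
#' is deterministic given `seed`.
#'
#' @param m A [score_matrix()].
#' @param rules Fusion rules to compare (default all seven).
#' @param k Number of folds (default 7).
#' @param seed Integer seed (folds + Monte-Carlo SRD null).
#' @param alpha BEDROC early-recognition parameter (default 20).
#' @param subset `"retained"` (default) or `"heldout"`: which part of each
#'   fold split the enrichment metrics are computed on.
#' @param include_singles Also carry the single-structure score columns
#'   through the SRD analysis (they get no enrichment-metric rows).
#' @param null_mode,n_null Passed to [srd_null()] via [srd_analysis()].
#' @return A `metric_table`: data frame with columns `rule`, `fold`, `auc`,
#'   `ap`, `bedroc`, `srd_norm`, one row per (rule, fold); the underlying
#'   `srd_result` is attached as attribute `"srd"` and the fold assignment
#'   as `"folds"`.
#' @export
evaluate_all <- function(m, rules = fusion_rules(), k = 7, seed = 1L,
                         alpha = 20, subset = c("retained", "heldout"),
                         include_singles = FALSE,
                         null_mode = "auto", n_null = 1e5) {
  stopifnot(inherits(m, "score_matrix"))
  subset <- match.arg(subset)
  fused <- fuse_matrix(m, rules)
  folds <- make_folds(m$labels, k = k, seed = seed)
  srd <- srd_analysis(fused, m, folds = folds, seed = seed,
                      include_singles = include_singles,
                      null_mode = null_mode, n_null = n_null)
  grid <- expand.grid(rule = fused$rules, fold = seq_len(k),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cell <- function(r, f) {
    sel <- if (subset == "retained") folds != f else folds == f
    sc <- fused$values[sel, r]
    lb <- m$labels[sel]
    c(auc = auc_roc(sc, lb),
      ap = average_precision(sc, lb),
      bedroc = bedroc(sc, lb, alpha = alpha),
      srd_norm = unname(srd$cv_values[r, f]))
  }
  vals <- t(mapply(cell, grid$rule, grid$fold))
  out <- cbind(grid, as.data.frame(vals))
  rownames(out) <- NULL
  class(out) <- c("metric_table", "data.frame")
  attr(out, "srd") <- srd
  attr(out, "folds") <- folds
  out
}

#' One-way ANOVA and Tukey HSD across fusion rules
#'
#' For each performance metric, tests whether the fusion rule (as the single
#' factor) has a significant effect on the per-fold values, then runs the
#' Tukey honestly-significant-difference post-hoc test on all rule pairs at
#' family-wise level `alpha_sig`. A metric whose cells have zero
#' within-group variance is flagged degenerate instead of crashing.
#'
#' @param t A `metric_table` from [evaluate_all()] (or any data frame with a
#'   `rule` column and metric columns).
#' @param alpha_sig Significance level for the Tukey flags (default 0.05).
#' @param metrics Metric columns to analyse; defaults to those present among
#'   `auc`, `ap`, `bedroc`, `srd_norm`.
#' @return A `comparison_summary`: list with `means` (per rule x metric mean
#'   and SD), `anova` (per metric F, p, degenerate flag), `tukey` (per
#'   metric x rule pair: difference, interval, adjusted p, significance) and
#'   `alpha_sig`.
#' @export
anova_tukey <- function(t, alpha_sig = 0.05,
                        metrics = intersect(c("auc", "ap", "bedroc",
                                              "srd_norm"), names(t))) {
  if (!"rule" %in% names(t)) stop("'t' needs a 'rule' column")
  if (length(unique(t$rule)) < 2) stop("need at least 2 rules")
  if (!length(metrics)) stop("no metric columns found")
  t$rule <- factor(t$rule)
  if (min(table(t$rule)) < 2) stop("need at least 2 folds per rule")

  means <- do.call(rbind, lapply(metrics, function(mt) {
    agg <- stats::aggregate(t[[mt]], list(rule = t$rule),
                            function(v) c(mean = mean(v), sd = stats::sd(v)))
    data.frame(metric = mt, rule = as.character(agg$rule),
               mean = agg$x[, "mean"], sd = agg$x[, "sd"])
  }))

  anova_rows <- list()
  tukey_rows <- list()
  for (mt in metrics) {
    d <- data.frame(value = t[[mt]], rule = t$rule)
    within_var <- stats::ave(d$value, d$rule, FUN = stats::var)
    degenerate <- all(within_var < .Machine$double.eps^0.5)
    if (degenerate) {
      anova_rows[[mt]] <- data.frame(metric = mt, F = NA_real_,
                                     p = NA_real_, degenerate = TRUE)
      next
    }
    fit <- stats::aov(value ~ rule, data = d)
    s <- summary(fit)[[1]]
    anova_rows[[mt]] <- data.frame(metric = mt, F = s[["F value"]][1],
                                   p = s[["Pr(>F)"]][1], degenerate = FALSE)
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha_sig)$rule
    tukey_rows[[mt]] <- data.frame(metric = mt, pair = rownames(tk),
                                   diff = tk[, "diff"], lwr = tk[, "lwr"],
                                   upr = tk[, "upr"], p_adj = tk[, "p adj"],
                                   significant = tk[, "p adj"] < alpha_sig,
                                   row.names = NULL)
  }
  structure(list(means = means,
                 anova = do.call(rbind, c(anova_rows, make.row.names = FALSE)),
                 tukey = if (length(tukey_rows))
                   do.call(rbind, c(tukey_rows, make.row.names = FALSE))
                 else NULL,
                 alpha_sig = alpha_sig),
            class = "comparison_summary")
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat("One-way ANOVA (rule as factor):\n")
  print(x$anova, row.names = FALSE)
  if (!is.null(x$tukey)) {
    nsig <- tapply(x$tukey$significant, x$tukey$metric, sum)
    npair <- tapply(x$tukey$significant, x$tukey$metric, length)
    cat("\nTukey HSD at alpha =", x$alpha_sig, "- significant pairs:\n")
    for (mt in names(nsig))
      cat("  ", mt, ": ", nsig[[mt]], "/", npair[[mt]], "\n", sep = "")
  }
  invisible(x)
}

#' Bubble-plot summary table
#'
#' Per-rule fold averages of the four metrics, laid out for the 4D bubble
#' plot: mean AUC on x, mean AP on y, mean normalized SRD as bubble size
#' (smaller = better) and mean BEDROC as colour.
#'
#' @param t A `metric_table` from [evaluate_all()].
#' @param omit Rules to drop from the summary (e.g. `"MAX"`, whose distance
#'   from the rest tends to compress the plot).
#' @return Data frame with one row per rule: `rule`, `auc`, `ap`,
#'   `srd_norm`, `bedroc`.
#' @export
bubble_table <- function(t, omit = NULL) {
  stopifnot(all(c("rule", "auc", "ap", "bedroc", "srd_norm") %in% names(t)))
  t <- t[!t$rule %in% omit, ]
  agg <- stats::aggregate(t[c("auc", "ap", "srd_norm", "bedroc")],
                          list(rule = t$rule), mean)
  agg[order(agg$auc, decreasing = TRUE), ]
}

#' Draw the 4D bubble plot
#'
#' AUC vs AP scatter with bubble size mapped to normalized SRD (reversed, so
#' smaller SRD = bigger bubble is avoided; smaller SRD = smaller bubble,
#' matching "the smaller the better") and colour to BEDROC (red = low,
#' green = high). Requires ggplot2.
#'
#' @param bt A summary table from [bubble_table()].
#' @return A ggplot object.
#' @export
bubble_plot <- function(bt) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("bubble_plot() requires the ggplot2 package")
  ggplot2::ggplot(bt, ggplot2::aes(x = auc, y = ap, size = srd_norm,
                                   fill = bedroc)) +
    ggplot2::geom_point(shape = 21, alpha = 0.8) +
    ggplot2::geom_text(ggplot2::aes(label = rule), size = 3,
                       vjust = -2.2, show.legend = FALSE) +
    ggplot2::scale_fill_gradient(low = "red", high = "green") +
    ggplot2::labs(x = "AUC", y = "Average precision",
                  size = "SRD (smaller = better)", fill = "BEDROC") +
    ggplot2::theme_minimal()
}
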