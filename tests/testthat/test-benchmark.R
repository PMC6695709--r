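test_that("fold assignment is balanced, stratified and reproducible", {
  lb <- rep(c(1, 0), c(7, 7))
  f <- make_folds(lb, k = 7, seed = 1)
  expect_equal(as.vector(table(f)), rep(2L, 7))           # n = 14, even split
  expect_equal(as.vector(table(f[lb == 1])), rep(1L, 7))  # one active per fold

  f15 <- make_folds(rep(c(1, 0), c(7, 8)), k = 7, seed = 1)
  expect_lte(diff(range(table(f15))), 1)               # sizes differ by <= 1

  lb2 <- rep(c(1, 0), c(30, 170))
  expect_identical(make_folds(lb2, k = 7, seed = 9),
                   make_folds(lb2, k = 7, seed = 9))
  f2 <- make_folds(lb2, k = 7, seed = 9)
  expect_lte(diff(range(table(f2[lb2 == 1]))), 1)      # actives spread evenly
  expect_warning(make_folds(rep(c(1, 0), c(3, 97)), k = 7, seed = 1),
                 "fewer actives")
})

test_that("evaluate_all fills the full rule x fold grid deterministically", {
  m <- toy_matrix(12, 58, 4, seed = 83)
  t1 <- evaluate_all(m, k = 7, seed = 4)
  expect_s3_class(t1, "metric_table")
  expect_equal(nrow(t1), 7 * 7)
  expect_equal(as.vector(table(t1$rule)), rep(7L, 7))
  expect_true(all(t1$auc >= 0 & t1$auc <= 1))
  expect_true(all(t1$bedroc >= 0 & t1$bedroc <= 1))
  expect_true(all(t1$srd_norm >= 0 & t1$srd_norm <= 100))
  t2 <- evaluate_all(m, k = 7, seed = 4)
  attributes(t1) <- attributes(t2) <- NULL
  expect_identical(t1, t2)                             # bit-identical runs
})

test_that("a perfectly separable matrix gives AUC = AP = 1 in every fold", {
  sc <- cbind(c(-(20:11), -(10:1) / 10), c(-(20:11) - 1, -(10:1) / 20))
  m <- score_matrix(sc, rep(c(1, 0), c(10, 10)))
  t <- evaluate_all(m, k = 5, seed = 2)
  expect_true(all(t$auc == 1))
  expect_true(all(t$ap == 1))
})

test_that("identical structure columns make all location rules agree per fold", {
  col <- -c(10, 9.5, 8, 7.2, 6.6, 6, 5.5, 5, 4.2, 4, 3.3, 3, 2.2, 2)
  m <- score_matrix(matrix(col, 14, 3), rep(c(1, 0), 7))
  t <- evaluate_all(m, rules = c("MIN", "MAX", "SUM", "MED"), k = 7, seed = 3)
  for (mt in c("auc", "ap", "bedroc", "srd_norm")) {
    wide <- unstack(data.frame(v = t[[mt]], rule = t$rule), v ~ rule)
    expect_equal(wide$MIN, wide$MAX, info = mt)
    expect_equal(wide$MIN, wide$SUM, info = mt)
    expect_equal(wide$MIN, wide$MED, info = mt)
  }
})

test_that("ANOVA F matches a hand-coded sum-of-squares oracle", {
  toy <- data.frame(
    rule = rep(c("A", "B", "C"), each = 4),
    auc = c(0.91, 0.89, 0.93, 0.90, 0.85, 0.84, 0.87, 0.86,
            0.78, 0.80, 0.79, 0.81))
  cs <- anova_tukey(toy, metrics = "auc")
  grand <- mean(toy$auc)
  gm <- tapply(toy$auc, toy$rule, mean)
  ssb <- sum(4 * (gm - grand)^2)
  ssw <- sum((toy$auc - gm[toy$rule])^2)
  f_oracle <- (ssb / 2) / (ssw / 9)
  expect_equal(cs$anova$F, f_oracle, tolerance = 1e-10)
  expect_equal(cs$anova$p, stats::pf(f_oracle, 2, 9, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("degenerate all-equal cells are flagged, not crashed", {
  toy <- data.frame(rule = rep(c("A", "B"), each = 3), auc = rep(0.9, 6))
  cs <- anova_tukey(toy, metrics = "auc")
  expect_true(cs$anova$degenerate)
  expect_true(is.na(cs$anova$F))
  expect_null(cs$tukey)
})

test_that("forced separation between two rules is declared significant", {
  set.seed(89)
  toy <- data.frame(
    rule = rep(c("GOOD", "BAD"), each = 3),
    auc = c(0.9, 0.9, 0.9, 0.5, 0.5, 0.5) + stats::rnorm(6, 0, 1e-3))
  cs <- anova_tukey(toy, metrics = "auc")
  expect_false(cs$anova$degenerate)
  expect_true(all(cs$tukey$significant))
  expect_equal(nrow(cs$tukey), 1)            # C(2,2) pairs
})

test_that("Tukey table has one row per rule pair and metric", {
  m <- toy_matrix(12, 58, 4, seed = 97)
  cs <- anova_tukey(evaluate_all(m, k = 7, seed = 6))
  expect_equal(nrow(cs$tukey), 4 * choose(7, 2))
  expect_true(all(cs$tukey$p_adj >= 0 & cs$tukey$p_adj <= 1))
})

test_that("bubble table rows are the arithmetic fold means", {
  m <- toy_matrix(12, 58, 4, seed = 101)
  t <- evaluate_all(m, k = 7, seed = 7)
  bt <- bubble_table(t)
  expect_equal(nrow(bt), 7)
  for (r in bt$rule) {
    expect_equal(bt$auc[bt$rule == r], mean(t$auc[t$rule == r]),
                 tolerance = 1e-12)
    expect_equal(bt$srd_norm[bt$rule == r], mean(t$srd_norm[t$rule == r]),
                 tolerance = 1e-12)
  }
  bt2 <- bubble_table(t, omit = "MAX")
  expect_false("MAX" %in% bt2$rule)
  expect_equal(nrow(bt2), 6)
  # one rule only: summary equals its fold means
  bt1 <- bubble_table(t[t$rule == "GEOM", ])
  expect_equal(nrow(bt1), 1)
  expect_equal(bt1$ap, mean(t$ap[t$rule == "GEOM"]))
})
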