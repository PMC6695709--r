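test_that("rank transform: best score gets rank 1, ties averaged", {
  expect_equal(rank_transform(c(-10, -4, -7)), c(1, 3, 2))
  expect_equal(rank_transform(c(-5, -5, -1)), c(1.5, 1.5, 3))
  set.seed(61)
  for (i in 1:20) {
    x <- stats::rnorm(sample(3:30, 1))
    r <- rank_transform(x)
    expect_equal(sort(r), seq_along(x))       # a bijection when tie-free
    expect_equal(sum(r), length(x) * (length(x) + 1) / 2)
  }
})

test_that("minimax reference: row-min ranks for actives, row-max for inactives", {
  # column ranks: A = (3, 1), B = (1, 4), C = (2, 2), D = (4, 3)
  sc <- cbind(c(-8, -10, -9, -7), c(-10, -7, -9, -8))
  m <- score_matrix(sc, c(1, 0, 1, 0), compound_ids = c("A", "B", "C", "D"))
  ref <- build_reference(m)
  expect_equal(unname(ref), c(1, 4, 2, 4), ignore_attr = TRUE)
  expect_identical(attr(ref, "construction"), "minimax")
})

test_that("minimax reference degenerates to the common column when columns tie", {
  col <- c(-9, -5, -7, -3)
  m <- score_matrix(matrix(col, 4, 2), c(1, 0, 1, 0))
  expect_equal(unname(build_reference(m)), rank(col), ignore_attr = TRUE)
})

test_that("minimax reference agrees with a two-pass loop oracle", {
  set.seed(67)
  m <- toy_matrix(6, 14, 4, seed = 67)
  ref <- build_reference(m)
  rk <- apply(m$scores, 2, rank)
  for (i in 1:20) {
    expected <- if (m$labels[i] == 1) min(rk[i, ]) else max(rk[i, ])
    expect_equal(unname(ref[i]), expected, ignore_attr = TRUE)
  }
})

test_that("SRD values match hand sums and the enumerated maximum", {
  expect_equal(srd_value(1:4, 1:4), 0)
  expect_equal(srd_value(4:1, 1:4), 8)
  expect_equal(srd_value(c(2, 1, 3, 4), 1:4), 2)
  expect_error(srd_value(1:3, 1:4), "equal length")
  expect_error(srd_max(1), ">= 2")
  # exhaustive check of the n^2/2 and (n^2-1)/2 closed forms
  for (n in c(2, 4, 5)) {
    p <- all_perms(n)
    d <- apply(p, 1, function(pi) sum(abs(pi - seq_len(n))))
    expect_equal(srd_max(n), max(d))
  }
})

test_that("tie-free SRD values are even integers", {
  set.seed(71)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    v <- srd_value(sample(n), sample(n))
    expect_equal(v %% 2, 0)
  }
})

test_that("exact null distribution equals n! enumeration for n <= 8", {
  expect_equal(srd_null(3)$values, c(0, 2, 4))
  expect_equal(srd_null(3)$prob, c(1 / 6, 2 / 6, 3 / 6))
  for (n in c(4, 6, 8)) {
    nl <- srd_null(n, mode = "exact")
    p <- all_perms(n)
    d <- apply(p, 1, function(pi) sum(abs(pi - seq_len(n))))
    tab <- table(d)
    expect_equal(nl$values, as.numeric(names(tab)))
    expect_equal(nl$prob, as.numeric(tab) / factorial(n))
    expect_equal(sum(nl$prob), 1, tolerance = 1e-9)
    expect_equal(sum(nl$values * nl$prob), mean(d))   # enumeration mean
    expect_true(all(nl$values %% 2 == 0))
  }
})

test_that("exact null covers the DP range 9 <= n <= 12 and errors beyond", {
  nl <- srd_null(12, mode = "exact")
  expect_equal(sum(nl$prob), 1, tolerance = 1e-9)
  # mean displacement of a random permutation is (n^2 - 1) / 3
  expect_equal(sum(nl$values * nl$prob), (144 - 1) / 3, tolerance = 1e-9)
  expect_error(srd_null(13, mode = "exact"), "monte_carlo")
})

test_that("Monte-Carlo null matches the exact CDF at n = 8", {
  exact <- srd_null(8, mode = "exact")
  mc <- srd_null(8, mode = "monte_carlo", n_samples = 1e5, seed = 3)
  cdf_at <- function(nl, v) {
    vapply(v, function(x) {
      i <- which(nl$values <= x)
      if (length(i)) nl$cdf[max(i)] else 0
    }, numeric(1))
  }
  gap <- max(abs(cdf_at(mc, exact$values) - exact$cdf))
  expect_lt(gap, 0.01)
})

test_that("boundary methods: reference scores 0, reversed reference 100", {
  col <- -c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1, 0.5, 0.2, 0.1, 0.05)
  m <- score_matrix(matrix(col, 14, 2), rep(c(1, 0), 7))
  ref <- build_reference(m)
  fused <- manual_fused(m, cbind(SAME = as.numeric(ref),
                                 REV = -as.numeric(ref)))
  res <- srd_analysis(fused, m, k_folds = 7, seed = 2)
  expect_equal(unname(res$srd_norm["SAME"]), 0)
  expect_equal(unname(res$srd_norm["REV"]), 100)
  expect_equal(unname(res$cv_values["SAME", ]), rep(0, 7))
})

test_that("column z-scoring never changes an SRD value", {
  set.seed(73)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    method <- stats::rnorm(n)
    ref <- stats::rnorm(n)
    z <- (method - mean(method)) / stats::sd(method)
    expect_equal(srd_value(z, ref), srd_value(method, ref))
  }
})

test_that("srd_analysis returns aligned CV values, null and fold structure", {
  m <- toy_matrix(10, 60, 4, seed = 79)
  fused <- fuse_matrix(m)
  res <- srd_analysis(fused, m, k_folds = 7, seed = 5,
                      include_singles = TRUE)
  expect_identical(res$method_names, c(fusion_rules(), m$structure_ids))
  expect_equal(dim(res$cv_values), c(11L, 7L))
  expect_true(all(res$srd_norm >= 0 & res$srd_norm <= 100))
  expect_true(all(res$cv_values >= 0 & res$cv_values <= 100))
  expect_equal(sum(res$null$prob), 1, tolerance = 1e-9)
  expect_equal(res$srd_norm, 100 * res$srd_raw / srd_max(res$n),
               ignore_attr = TRUE)
  # deterministic given seed
  res2 <- srd_analysis(fused, m, k_folds = 7, seed = 5,
                       include_singles = TRUE)
  expect_equal(res$cv_values, res2$cv_values)
  expect_equal(res$null$prob, res2$null$prob)
  expect_error(srd_analysis(fused, m, k_folds = 1), "between 2")
})
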