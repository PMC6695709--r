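#' Configuration of the Gaussian docking-score generator
#'
#' The generator emulates the statistical structure of an ensemble-docking
#' retrospective screen with the simplest model carrying the two knobs the
#' downstream analysis needs: class separation and inter-structure
#' correlation. Each compound i has a latent quality
#' `b_i ~ N(mu_class(i), tau^2)`; its score against structure j is
#' `DS_ij = b_i + delta_j + e_ij` with `e_ij ~ N(0, sigma^2)` independent.
#' The correlation between two structures' scores for the same compound is
#' `tau^2 / (tau^2 + sigma^2)`.
#'
#' Defaults mimic negative docking scores in typical ranges: actives around
#' -12, inactives around -10, unit compound-level and noise SDs. The means
#' sit far enough below zero that simulated scores are negative with
#' overwhelming probability, keeping them inside the uniform-sign domain of
#' the geometric and harmonic fusion rules.
#'
#' @param n_act,n_inact Number of active / inactive compounds.
#' @param n_struct Number of protein structures (>= 2).
#' @param mu_act,mu_inact Class mean scores (`mu_act < mu_inact`, both
#'   negative by default; lower = better).
#' @param tau SD of the per-compound latent quality (>= 0).
#' @param sigma SD of the per-structure noise (>= 0; `tau + sigma > 0`).
#' @param delta Per-structure score offsets (length `n_struct`); by default
#'   drawn once from N(0, 1) with a sub-seed fixed by `seed` so that
#'   structures have nontrivial offsets (making the rank transform before
#'   reference construction matter).
#' @param seed Integer seed.
#' @return A `synthetic_config` list.
#' @seealso [simulate_scores()], [preset_config()]
#' @export
synthetic_config <- function(n_act = 82, n_inact = 1437, n_struct = 5,
                             mu_act = -12, mu_inact = -10, tau = 1, sigma = 1,
                             delta = NULL, seed = 1L) {
  if (n_act < 1 || n_inact < 1) stop("need at least 1 active and 1 inactive")
  if (n_struct < 2) stop("'n_struct' must be >= 2")
  if (mu_act > mu_inact) stop("'mu_act' must not exceed 'mu_inact' (lower = better)")
  if (tau < 0 || sigma < 0 || tau + sigma <= 0)
    stop("'tau' and 'sigma' must be nonnegative with tau + sigma > 0")
  if (is.null(delta)) {
    set.seed(as.integer(seed) + 7919L)   # fixed sub-seed for the offsets
    delta <- stats::rnorm(n_struct)
  }
  if (length(delta) != n_struct) stop("'delta' must have length n_struct")
  structure(list(n_act = as.integer(n_act), n_inact = as.integer(n_inact),
                 n_struct = as.integer(n_struct), mu_act = mu_act,
                 mu_inact = mu_inact, tau = tau, sigma = sigma,
                 delta = delta, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Preset configurations mirroring published case-study compositions
#'
#' Reproduces the compound and structure counts of five retrospective
#' ensemble-docking screens: two Janus kinase subtypes (JAK1: 5 structures,
#' 115 actives, 1644 inactives; JAK2: 5 structures, 82 actives, 1437
#' inactives), the 5-HT6 serotonin receptor with Drugmatrix inactives
#' (9 structures, 20 actives, 689 inactives), aldose reductase 2 (6
#' structures, 26 actives, 917 inactives) and the estrogen receptor (3
#' structures, 38 actives, 1344 inactives). Score means, variances and
#' structure offsets follow the generator defaults — only the counts are
#' taken from the case studies, whose raw docking scores are not public.
#'
#' @param name One of `"jak1"`, `"jak2"`, `"5ht6"`, `"alr2"`, `"er"`.
#' @param seed Integer seed.
#' @param ... Overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
preset_config <- function(name = c("jak1", "jak2", "5ht6", "alr2", "er"),
                          seed = 1L, ...) {
  name <- match.arg(name)
  counts <- switch(name,
    jak1 = c(115, 1644, 5),
    jak2 = c(82, 1437, 5),
    `5ht6` = c(20, 689, 9),
    alr2 = c(26, 917, 6),
    er = c(38, 1344, 3))
  args <- list(...)
  if (is.null(args$delta)) {
    # structure offsets are a fixed property of each preset, independent of
    # the simulation seed
    sub_seed <- 100L + match(name, c("jak1", "jak2", "5ht6", "alr2", "er"))
    set.seed(sub_seed)
    args$delta <- stats::rnorm(counts[3])
  }
  do.call(synthetic_config,
          c(list(n_act = counts[1], n_inact = counts[2],
                 n_struct = counts[3], seed = seed), args))
}

#' Simulate a docking score matrix
#'
#' Draws scores from the Gaussian additive model of [synthetic_config()]:
#' actives first (ids `ACT...`), then inactives (`INA...`). Deterministic
#' given the config's seed.
#'
#' @param config A `synthetic_config`.
#' @return A [score_matrix()].
#' @examples
#' m <- simulate_scores(synthetic_config(n_act = 10, n_inact = 90, seed = 7))
#' m
#' @export
simulate_scores <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_act + config$n_inact
  labels <- rep(c(1L, 0L), c(config$n_act, config$n_inact))
  mu <- ifelse(labels == 1L, config$mu_act, config$mu_inact)
  set.seed(config$seed)
  b <- stats::rnorm(n, mu, config$tau)
  e <- matrix(stats::rnorm(n * config$n_struct, 0, config$sigma),
              n, config$n_struct)
  scores <- b + e + matrix(config$delta, n, config$n_struct, byrow = TRUE)
  ids <- c(sprintf("ACT%04d", seq_len(config$n_act)),
           sprintf("INA%04d", seq_len(config$n_inact)))
  score_matrix(scores, labels, compound_ids = ids,
               structure_ids = paste0("S", seq_len(config$n_struct)))
}

#' Analytic AUC of the Gaussian generator
#'
#' Closed-form calibration check for [simulate_scores()]. A single
#' structure's score difference between a random inactive and a random
#' active is Gaussian with mean `mu_inact - mu_act` and variance
#' `2 (tau^2 + sigma^2)`, giving
#' `AUC = Phi((mu_inact - mu_act) / sqrt(2 (tau^2 + sigma^2)))`.
#' Averaging the structures (the arithmetic-mean SUM rule) shrinks the noise
#' term to `sigma^2 / n_struct`, which is the mechanism by which fusion
#' helps when `sigma > 0`.
#'
#' @param config A `synthetic_config`.
#' @return List with `single` (single-structure AUC) and `sum_fusion` (the
#'   SUM-rule analogue).
#' @export
expected_auc_single <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  gap <- config$mu_inact - config$mu_act
  list(
    single = stats::pnorm(gap / sqrt(2 * (config$tau^2 + config$sigma^2))),
    sum_fusion = stats::pnorm(
      gap / sqrt(2 * (config$tau^2 + config$sigma^2 / config$n_struct)))
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic docking-score config: ", x$n_act, " actives + ", x$n_inact,
      " inactives x ", x$n_struct, " structures\n", sep = "")
  cat("  mu_act = ", x$mu_act, ", mu_inact = ", x$mu_inact, ", tau = ",
      x$tau, ", sigma = ", x$sigma, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}
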