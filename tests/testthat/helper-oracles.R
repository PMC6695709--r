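# Independent oracles and small fixture builders shared across tests.

# All permutations of 1..n as an n! x n integer matrix (exhaustive oracle).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))   # relabel 1..n-1 to skip value i
  }))
}

# Brute-force AUC: fraction of (active, inactive) pairs ranked correctly,
# ties counted one half. Lower score = better.
auc_pairwise <- function(scores, labels) {
  a <- scores[labels == 1]
  i <- scores[labels == 0]
  cmp <- outer(a, i, function(x, y) (x < y) + 0.5 * (x == y))
  mean(cmp)
}

# Tie-free AP oracle: mean over actives of the precision at their own rank.
ap_tiefree <- function(scores, labels) {
  stopifnot(!anyDuplicated(scores))
  ord <- order(scores)
  lab <- labels[ord]
  hits <- which(lab == 1)
  mean(cumsum(lab)[hits] / hits)
}

# Independently coded BEDROC via the robust initial enhancement (RIE):
# observed exponential weight sum over its uniform-rank expectation, then
# the min-max rescaling to [0, 1].
bedroc_rie_oracle <- function(ranks_of_actives, N, alpha) {
  n <- length(ranks_of_actives)
  ra <- n / N
  w_sum <- sum(exp(-alpha * ranks_of_actives / N))
  e_rand <- n / N * sum(exp(-alpha * seq_len(N) / N))
  rie <- w_sum / e_rand
  rie_min <- (1 - exp(alpha * ra)) / (ra * (1 - exp(alpha)))
  rie_max <- (1 - exp(-alpha * ra)) / (ra * (1 - exp(-alpha)))
  (rie - rie_min) / (rie_max - rie_min)
}

# Small deterministic score matrix: first n_act rows active, negative scores.
toy_matrix <- function(n_act = 3, n_inact = 7, n_struct = 3, seed = 11) {
  set.seed(seed)
  n <- n_act + n_inact
  sc <- -10 + matrix(stats::rnorm(n * n_struct), n, n_struct)
  score_matrix(sc, rep(c(1, 0), c(n_act, n_inact)))
}

# Manually assembled fused_table holding arbitrary method columns.
manual_fused <- function(m, values) {
  structure(list(compound_ids = m$compound_ids, labels = m$labels,
                 rules = colnames(values), values = values,
                 orientation = stats::setNames(
                   rep("lower_better", ncol(values)), colnames(values))),
            class = "fused_table")
}
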