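# Shared fixture builders; all fixtures are generated in code.

# Small random count table with guaranteed positive column totals.
random_count_table <- function(n_taxa = 20, n_samples = 8, lambda = 10,
                               seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_taxa * n_samples, lambda) *
                rbinom(n_taxa * n_samples, 1, 0.7),
              nrow = n_taxa,
              dimnames = list(sprintf("Z%03d", seq_len(n_taxa)),
                              sprintf("S%03d", seq_len(n_samples))))
  zero <- colSums(m) == 0
  m[1, zero] <- 1L
  count_table(m)
}

# Neutral simulation shortcut returning table + truth.
neutral_sim <- function(S = 400, k = 30, N = 5000, Nm = 500, sigma = 1.5,
                        seed = 1) {
  p <- simulate_metacommunity(S, sigma, seed)
  simulate_neutral_counts(p, neutral_sim_config(S = S, k = k, N = N, Nm = Nm,
                                                abundance_sigma = sigma,
                                                seed = seed + 1000L))
}

# Minimal valid metadata frame for n samples split into groups.
toy_frame <- function(ids, groups, times = 0L, replicates = 1L,
                      lifestyles = "PA") {
  sample_frame(data.frame(sample_id = ids, group = groups,
                          time = times, replicate = replicates,
                          lifestyle = lifestyles,
                          stringsAsFactors = FALSE))
}

# Gini coefficient (independent implementation for metacommunity tests).
gini <- function(x) {
  x <- sort(x)
  n <- length(x)
  sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
}

# Independent PERMANOVA pseudo-F for a single two-group factor, computed
# straight from pairwise distances (SS_within via the classic
# sum-of-squared-distances identity), used as the enumeration oracle.
brute_pseudo_f <- function(d, grouping) {
  n <- nrow(d)
  ss_of <- function(idx) {
    sub <- d[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  ss_total <- sum(d[upper.tri(d)]^2) / n
  ss_within <- sum(vapply(unique(grouping),
                          function(g) ss_of(which(grouping == g)), numeric(1)))
  ss_between <- ss_total - ss_within
  a <- length(unique(grouping))
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

# Procrustes residual after optimal rotation/reflection of x onto y.
procrustes_error <- function(x, y) {
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  s <- svd(crossprod(yc, xc))
  rot <- s$v %*% t(s$u)
  sqrt(sum((xc %*% rot - yc)^2))
}
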