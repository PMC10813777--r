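# Shared container for permutation tests. `n_extreme` counts permutations
# at least as extreme as the observed statistic (direction depends on the
# statistic); the p estimator (1 + n_extreme) / (1 + n_perm) is never 0.
perm_test_result <- function(statistic, observed, n_extreme, n_perm, seed,
                             extra = list()) {
  structure(c(list(
    statistic = statistic,
    observed = observed,
    n_perm = as.integer(n_perm),
    p_value = (1 + n_extreme) / (1 + n_perm),
    seed = seed
  ), extra), class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s = %.4f, p = %.4g (%d permutations)\n",
              x$statistic, x$observed, x$p_value, x$n_perm))
  invisible(x)
}

# Enumerate all permutations of 1..n (n small) for exact tests.
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    for (s in sub) {
      k <- k + 1L
      rest <- seq_len(n)[-i]
      out[[k]] <- c(i, rest[s])
    }
  }
  out
}

# Build the sequential (Type I) hat-matrix decomposition for a list of
# model terms evaluated in order. Returns per-term projector differences,
# the full-model projector, and degrees of freedom.
sequential_projectors <- function(frame, terms) {
  n <- nrow(frame)
  data <- as.data.frame(frame)
  for (v in names(data)) {
    if (is.character(data[[v]])) data[[v]] <- factor(data[[v]])
  }
  h_prev <- matrix(1 / n, n, n)   # intercept-only projector
  rank_prev <- 1L
  projectors <- list()
  dfs <- integer(0)
  for (j in seq_along(terms)) {
    fml <- stats::reformulate(terms[seq_len(j)])
    x <- stats::model.matrix(fml, data = data)
    qrx <- qr(x)
    if (qrx$rank == rank_prev)
      stop_("aliased term '%s' adds no degrees of freedom", terms[j])
    q <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
    h <- tcrossprod(q)
    projectors[[terms[j]]] <- h - h_prev
    dfs[terms[j]] <- qrx$rank - rank_prev
    h_prev <- h
    rank_prev <- qrx$rank
  }
  list(projectors = projectors, h_full = h_prev, df = dfs,
       rank_full = rank_prev, n = n)
}

#' Permutational multivariate ANOVA (PERMANOVA)
#'
#' Distance-based partition of variance among design factors: the Gower-
#' centered matrix of the dissimilarities is projected on the sequentially
#' fitted model terms (Type I sums of squares, in the listed order,
#' interactions written `"a:b"`). Pseudo-F per term uses the full-model
#' residual; p-values come from free permutation of sample labels. Term R2
#' values plus the residual R2 sum to 1.
#'
#' @param dm a `dist_matrix`.
#' @param frame a [sample_frame()] (or data.frame) aligned to `dm`'s ids.
#' @param terms ordered character vector of model terms, e.g.
#'   `c("group", "time", "group:time")`.
#' @param n_perm number of permutations (>= 99), ignored when `exhaustive`.
#' @param seed integer seed.
#' @param exhaustive enumerate all `n!` label permutations (small n only);
#'   p is then the exact proportion of permutations with `F* >= F`.
#' @param factors convert these columns to factors before model building
#'   (characters always become factors; numeric columns listed here are
#'   treated as categorical).
#' @return data.frame of class `permanova_table`: one row per term plus
#'   `Residual` and `Total`, with `df`, `SumOfSqs`, `R2`, `F`, `p`.
#' @export
permanova <- function(dm, frame, terms, n_perm = 999L, seed = 1L,
                      exhaustive = FALSE, factors = character(0)) {
  d <- as_dist_matrix(dm)
  frame <- as.data.frame(frame)
  if (!is.null(frame$sample_id)) {
    idx <- match(rownames(d), frame$sample_id)
    if (anyNA(idx)) stop_("metadata missing sample(s): %s",
                          paste(rownames(d)[is.na(idx)], collapse = ", "))
    frame <- frame[idx, , drop = FALSE]
  } else if (nrow(frame) != nrow(d)) {
    stop_("frame and distance matrix disagree on samples")
  }
  for (v in factors) frame[[v]] <- factor(frame[[v]])
  if (!exhaustive && n_perm < 99L) stop_("n_perm must be >= 99")

  sp <- sequential_projectors(frame, terms)
  g <- gower_centre(d)
  n <- nrow(g)
  ss_total <- sum(diag(g))
  ss_terms <- vapply(sp$projectors, function(hd) sum(hd * g), numeric(1))
  ss_res <- ss_total - sum(sp$h_full * g)
  df_res <- n - sp$rank_full
  ms_res <- ss_res / df_res
  f_obs <- (ss_terms / sp$df) / ms_res

  perms <- if (exhaustive) {
    all_permutations(n)
  } else {
    with_seed(derive_seed(seed, 17L),
              lapply(seq_len(n_perm), function(b) sample.int(n)))
  }
  f_perm <- matrix(NA_real_, nrow = length(perms), ncol = length(terms))
  for (b in seq_along(perms)) {
    gp <- g[perms[[b]], perms[[b]]]
    ssb <- vapply(sp$projectors, function(hd) sum(hd * gp), numeric(1))
    ssrb <- ss_total - sum(sp$h_full * gp)
    f_perm[b, ] <- (ssb / sp$df) / (ssrb / df_res)
  }
  if (exhaustive) {
    p <- colMeans(sweep(f_perm, 2L, f_obs - 1e-12, ">="))
  } else {
    n_ge <- colSums(sweep(f_perm, 2L, f_obs - 1e-12, ">="))
    p <- (1 + n_ge) / (1 + length(perms))
  }

  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(sp$df, df_res, n - 1L),
    SumOfSqs = c(ss_terms, ss_res, ss_total),
    R2 = c(ss_terms, ss_res, ss_total) / ss_total,
    F = c(f_obs, NA, NA),
    p = c(p, NA, NA),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("permanova_table", "data.frame")
  attr(out, "n_perm") <- length(perms)
  attr(out, "seed") <- seed
  out
}

# Resolve a grouping argument (vector or metadata column) against dm ids.
resolve_grouping <- function(dm, grouping) {
  d <- as_dist_matrix(dm)
  g <- as.character(grouping)
  if (length(g) != nrow(d)) stop_("grouping length != number of samples")
  g
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based comparison of between- versus within-group dissimilarities:
#' `R = (mean rank between - mean rank within) / (M / 2)` with
#' `M = n (n - 1) / 2` ranked pairs (average ranks for ties). R near 1
#' means all between-group distances exceed within-group ones; the p-value
#' comes from permuting group labels.
#'
#' @param dm a `dist_matrix`.
#' @param grouping group label per sample, in `dm` order.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return A `perm_test` with `observed` = R.
#' @export
anosim <- function(dm, grouping, n_perm = 999L, seed = 1L) {
  d <- as_dist_matrix(dm)
  g <- resolve_grouping(dm, grouping)
  if (length(unique(g)) < 2L) stop_("need >= 2 groups")
  if (any(table(g) < 2L)) stop_("every group needs >= 2 samples")
  n <- nrow(d)
  ut <- upper.tri(d)
  r <- rank(d[ut])
  m_half <- (n * (n - 1) / 2) / 2
  same <- outer(g, g, "==")[ut]
  stat <- function(same_vec) {
    (mean(r[!same_vec]) - mean(r[same_vec])) / m_half
  }
  r_obs <- stat(same)
  r_perm <- with_seed(derive_seed(seed, 19L), vapply(seq_len(n_perm), function(b) {
    gp <- g[sample.int(n)]
    stat(outer(gp, gp, "==")[ut])
  }, numeric(1)))
  perm_test_result("ANOSIM R", r_obs, sum(r_perm >= r_obs - 1e-12),
                   n_perm, seed)
}

#' Multiresponse permutation procedure (MRPP)
#'
#' Weighted mean within-group dissimilarity `delta = sum_g (n_g / n) *
#' mean_within_g`, tested by label permutation (small delta = more
#' within-group homogeneity than expected). The chance-corrected agreement
#' is `A = 1 - delta / E[delta_perm]`.
#'
#' @inheritParams anosim
#' @return A `perm_test` with `observed` = delta and extra fields `A` and
#'   `expected_delta`.
#' @export
mrpp <- function(dm, grouping, n_perm = 999L, seed = 1L) {
  d <- as_dist_matrix(dm)
  g <- resolve_grouping(dm, grouping)
  if (length(unique(g)) < 2L) stop_("need >= 2 groups")
  if (any(table(g) < 2L)) stop_("every group needs >= 2 samples")
  n <- nrow(d)
  delta_of <- function(gv) {
    s <- 0
    for (lev in unique(gv)) {
      idx <- which(gv == lev)
      s <- s + length(idx) / n * mean(d[idx, idx][upper.tri(d[idx, idx])])
    }
    s
  }
  delta_obs <- delta_of(g)
  delta_perm <- with_seed(derive_seed(seed, 23L), vapply(seq_len(n_perm), function(b) {
    delta_of(g[sample.int(n)])
  }, numeric(1)))
  e_delta <- mean(delta_perm)
  perm_test_result("MRPP delta", delta_obs,
                   sum(delta_perm <= delta_obs + 1e-12), n_perm, seed,
                   extra = list(A = 1 - delta_obs / e_delta,
                                expected_delta = e_delta))
}

#' Mantel test between two distance matrices
#'
#' Correlation (Spearman by default, average ranks for ties) between the
#' upper triangles of two distance matrices over the same samples, tested
#' by jointly permuting rows and columns of the second matrix (one-sided:
#' large positive correlation).
#'
#' @param dm1,dm2 `dist_matrix` objects sharing sample ids (dm2 is
#'   reordered to dm1's ids).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return A `perm_test` with `observed` = correlation.
#' @export
mantel <- function(dm1, dm2, method = c("spearman", "pearson"),
                   n_perm = 999L, seed = 1L) {
  method <- match.arg(method)
  d1 <- as_dist_matrix(dm1)
  d2 <- as_dist_matrix(dm2)
  if (!setequal(rownames(d1), rownames(d2)))
    stop_("distance matrices disagree on sample ids")
  d2 <- d2[rownames(d1), rownames(d1)]
  n <- nrow(d1)
  ut <- upper.tri(d1)
  r_obs <- stats::cor(d1[ut], d2[ut], method = method)
  # a joint row/column permutation permutes the off-diagonal pairs, so for
  # Spearman the ranks can be assigned to the matrix once and permuted as
  # plain values (Pearson on ranks)
  if (method == "spearman") {
    m1 <- matrix(0, n, n); m2 <- matrix(0, n, n)
    m1[ut] <- rank(d1[ut]); m2[ut] <- rank(d2[ut])
    d1 <- m1 + t(m1); d2 <- m2 + t(m2)
  }
  v1 <- d1[ut]
  r_perm <- with_seed(derive_seed(seed, 29L), vapply(seq_len(n_perm), function(b) {
    pm <- sample.int(n)
    stats::cor(v1, d2[pm, pm][ut])
  }, numeric(1)))
  perm_test_result(sprintf("Mantel r (%s)", method), r_obs,
                   sum(r_perm >= r_obs - 1e-12), n_perm, seed)
}
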