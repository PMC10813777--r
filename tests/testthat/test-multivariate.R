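test_that("alpha diversity matches closed forms", {
  uni <- matrix(rep(7L, 12), 12, 1, dimnames = list(sprintf("z%d", 1:12), "s"))
  a <- alpha_diversity(count_table(uni))
  expect_equal(a$shannon, log(12), tolerance = 1e-12)
  expect_equal(a$pielou, 1, tolerance = 1e-12)
  expect_equal(a$observed, 12)

  single <- matrix(c(50L, 0L), 2, 1, dimnames = list(c("z1", "z2"), "s"))
  a1 <- alpha_diversity(count_table(single))
  expect_equal(a1$shannon, 0)
  expect_equal(a1$simpson, 0)

  # S_obs = 20 with F1 = 4 singletons, F2 = 2 doubletons: Chao1 = 24
  v <- c(rep(1L, 4), rep(2L, 2), rep(5L, 14))
  chao <- matrix(v, length(v), 1,
                 dimnames = list(sprintf("z%d", seq_along(v)), "s"))
  expect_equal(alpha_diversity(count_table(chao))$chao1, 24)

  expect_error(alpha_diversity(count_table(uni), metrics = "phylo"), "unknown")
})

test_that("Bray-Curtis matches hand arithmetic and vegan", {
  m <- matrix(c(6L, 0L, 2L, 2L, 2L, 0L), 3, 2,
              dimnames = list(c("x", "y", "z"), c("u", "v")))
  d_counts <- bray_curtis(count_table(m), scale = "counts")
  expect_equal(d_counts["u", "v"], 8 / 12, tolerance = 1e-12)

  same <- cbind(m, w = m[, "u"])
  dimnames(same)[[2]] <- c("u", "v", "w")
  expect_equal(unclass(bray_curtis(count_table(same), scale = "counts"))["u", "w"], 0)

  disjoint <- matrix(c(5L, 0L, 0L, 7L), 2, 2,
                     dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(unclass(bray_curtis(count_table(disjoint)))["s1", "s2"], 1)

  ct <- random_count_table(25, 9, seed = 2)
  skip_if_not_installed("vegan")
  ref <- as.matrix(vegan::vegdist(t(sweep(unclass(ct), 2, colSums(unclass(ct)), "/")),
                                  method = "bray"))
  expect_equal(unclass(bray_curtis(ct)), ref[rownames(ref), colnames(ref)],
               tolerance = 1e-12, ignore_attr = TRUE)

  # with equal totals, relative and count scales agree
  eq <- unclass(rarefy(ct, min(colSums(unclass(ct))), seed = 1))
  expect_equal(unclass(bray_curtis(count_table(eq), scale = "counts")),
               unclass(bray_curtis(count_table(eq), scale = "relative")),
               tolerance = 1e-12)
})

test_that("PERMANOVA matches exact enumeration on a 3+3 design", {
  ct <- random_count_table(15, 6, seed = 21)
  dm <- bray_curtis(ct)
  grp <- rep(c("a", "b"), each = 3)
  frame <- data.frame(g = grp)
  res <- permanova(dm, frame, "g", exhaustive = TRUE)

  # oracle: enumerate the 20 distinct splits with an independent pseudo-F
  d <- unclass(dm)
  combos <- combn(6, 3)
  f_all <- apply(combos, 2, function(idx) {
    gv <- rep("b", 6); gv[idx] <- "a"
    brute_pseudo_f(d, gv)
  })
  f_obs <- brute_pseudo_f(d, grp)
  expect_equal(res$F[1], f_obs, tolerance = 1e-10)
  expect_equal(res$p[1], mean(f_all >= f_obs - 1e-12), tolerance = 1e-12)
})

test_that("PERMANOVA partitions variance exactly and respects ordering invariance", {
  study <- simulate_study(study_design_config(S = 40, N = 900, seed = 3))
  keep <- study$samples$time %in% c(0L, 11L, 29L) & study$samples$lifestyle == "PA"
  ids <- study$samples$sample_id[keep]
  ct <- count_table(unclass(study$counts)[, ids])
  dm <- bray_curtis(filter_taxa(ct, 1))
  frame <- study$samples[keep, ]
  res <- permanova(dm, frame, c("group", "time", "group:time"),
                   n_perm = 99, seed = 1, factors = "time")
  expect_equal(sum(res$R2[res$term != "Total"]), 1, tolerance = 1e-9)
  expect_equal(sum(res$df[res$term != "Total"]), length(ids) - 1)
  expect_true(all(res$p[1:3] > 0))

  # simultaneous reordering of samples and metadata changes nothing
  ord <- sample(length(ids))
  dm2 <- dist_matrix(unclass(dm)[ord, ord])
  res2 <- permanova(dm2, frame[ord, ], c("group", "time", "group:time"),
                    n_perm = 99, seed = 1, factors = "time")
  expect_equal(res2$SumOfSqs, res$SumOfSqs, tolerance = 1e-10)
  expect_equal(res2$F[1:3], res$F[1:3], tolerance = 1e-10)

  expect_error(permanova(dm, cbind(frame, g2 = frame$group),
                         c("group", "g2"), n_perm = 99),
               "aliased term 'g2'")
})

test_that("PERMANOVA agrees with vegan::adonis2 on sequential terms", {
  skip_if_not_installed("vegan")
  ct <- random_count_table(30, 12, seed = 7)
  dm <- bray_curtis(ct)
  df <- data.frame(g = rep(c("A", "B", "C"), each = 4),
                   t = factor(rep(1:2, 6)))
  mine <- permanova(dm, df, c("g", "t", "g:t"), n_perm = 199, seed = 1)
  ref <- vegan::adonis2(as.dist(unclass(dm)) ~ g * t, data = df,
                        permutations = 199, by = "terms")
  expect_equal(mine$SumOfSqs[1:3], ref$SumOfSqs[1:3], tolerance = 1e-10)
  expect_equal(mine$F[1:3], ref$F[1:3], tolerance = 1e-10)
  expect_equal(mine$R2[1:3], ref$R2[1:3], tolerance = 1e-10)
})

test_that("ANOSIM separates and matches its rank definition", {
  # perfectly separated clusters: R = 1
  pts <- rbind(matrix(rnorm(8, 0, 0.01), 4), matrix(rnorm(8, 10, 0.01), 4))
  rownames(pts) <- sprintf("s%d", 1:8)
  dm <- euclidean_dist(pts, scale = FALSE)
  grp <- rep(c("a", "b"), each = 4)
  expect_equal(anosim(dm, grp, n_perm = 99, seed = 1)$observed, 1)

  # 4-sample hand computation
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 1
  d["a", "c"] <- d["c", "a"] <- 5
  d["a", "d"] <- d["d", "a"] <- 6
  d["b", "c"] <- d["c", "b"] <- 4
  d["b", "d"] <- d["d", "b"] <- 3
  d["c", "d"] <- d["d", "c"] <- 2
  g <- c("x", "x", "y", "y")
  # ranks: within pairs {ab=1, cd=2} -> mean 1.5; between {bd=3,bc=4,ac=5,ad=6} -> 4.5
  expect_equal(anosim(dist_matrix(d), g, n_perm = 99, seed = 1)$observed,
               (4.5 - 1.5) / (6 / 2), tolerance = 1e-12)

  expect_error(anosim(dm, rep("a", 8), n_perm = 99), ">= 2 groups")

  skip_if_not_installed("vegan")
  ct <- random_count_table(25, 10, seed = 4)
  dmx <- bray_curtis(ct)
  gx <- rep(c("u", "v"), each = 5)
  expect_equal(anosim(dmx, gx, n_perm = 99, seed = 2)$observed,
               unname(vegan::anosim(as.dist(unclass(dmx)), gx,
                                    permutations = 0)$statistic),
               tolerance = 1e-12)
})

test_that("ANOSIM is centred at zero under shuffled labels", {
  ct <- random_count_table(20, 12, seed = 5)
  dm <- bray_curtis(ct)
  set.seed(77)
  r_null <- vapply(1:200, function(i) {
    anosim(dm, sample(rep(c("a", "b"), each = 6)), n_perm = 99,
           seed = i)$observed
  }, numeric(1))
  expect_lt(abs(mean(r_null)), 3 * sd(r_null) / sqrt(200))
})

test_that("MRPP behaves at its structural extremes and matches vegan", {
  # all distances equal: no structure, A = 0 exactly
  n <- 8
  d <- matrix(1, n, n) - diag(n)
  dimnames(d) <- list(sprintf("s%d", 1:n), sprintf("s%d", 1:n))
  res <- mrpp(dist_matrix(d), rep(c("a", "b"), each = 4), n_perm = 99, seed = 1)
  expect_equal(res$A, 0, tolerance = 1e-12)

  # two tight, distant clusters: delta minimal, p at the permutation floor
  pts <- rbind(matrix(rnorm(10, 0, 0.01), 5), matrix(rnorm(10, 50, 0.01), 5))
  rownames(pts) <- sprintf("s%d", 1:10)
  dm <- euclidean_dist(pts, scale = FALSE)
  res2 <- mrpp(dm, rep(c("a", "b"), each = 5), n_perm = 199, seed = 2)
  expect_gt(res2$A, 0)
  # p sits at the permutation floor up to ties from permutations that
  # recreate the same two-set partition
  expect_lte(res2$p_value, 5 / 200)

  # brute-force delta oracle on a small case
  ct <- random_count_table(15, 6, seed = 9)
  dmx <- unclass(bray_curtis(ct))
  grp <- rep(c("a", "b"), each = 3)
  within <- function(idx) mean(dmx[idx, idx][upper.tri(dmx[idx, idx])])
  delta_oracle <- 0.5 * within(1:3) + 0.5 * within(4:6)
  res3 <- mrpp(dist_matrix(dmx), grp, n_perm = 99, seed = 3)
  expect_equal(res3$observed, delta_oracle, tolerance = 1e-12)

  skip_if_not_installed("vegan")
  ref <- vegan::mrpp(as.dist(dmx), grp, permutations = 99)
  expect_equal(res3$observed, ref$delta, tolerance = 1e-12)
})

test_that("Mantel correlation honors rank invariance and the null", {
  ct <- random_count_table(20, 10, seed = 11)
  dm <- bray_curtis(ct)
  expect_equal(mantel(dm, dm, n_perm = 99, seed = 1)$observed, 1)

  # strictly monotone transform leaves Spearman r at 1
  d2 <- unclass(dm)^3 * 2
  expect_equal(mantel(dm, dist_matrix(d2), n_perm = 99, seed = 1)$observed, 1)

  other <- euclidean_dist(matrix(rnorm(20), 10,
                                 dimnames = list(colnames(unclass(ct)), NULL)))
  skip_if_not_installed("vegan")
  expect_equal(mantel(dm, other, n_perm = 99, seed = 5)$observed,
               unname(vegan::mantel(as.dist(unclass(dm)),
                                    as.dist(unclass(other)),
                                    method = "spearman",
                                    permutations = 0)$statistic),
               tolerance = 1e-12)
})

test_that("permutation p-values are calibrated under the null", {
  # independent random matrices: rejection at 0.05 stays near nominal
  set.seed(123)
  rej <- vapply(1:300, function(i) {
    x1 <- matrix(rnorm(16), 8)
    x2 <- matrix(rnorm(16), 8)
    rownames(x1) <- rownames(x2) <- sprintf("s%d", 1:8)
    mantel(euclidean_dist(x1, scale = FALSE),
           euclidean_dist(x2, scale = FALSE),
           n_perm = 99, seed = i)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.10)
})

test_that("one-way ANOVA reduces to the pooled t-test with two groups", {
  set.seed(8)
  v <- c(rnorm(6, 0), rnorm(6, 1))
  g <- rep(c("a", "b"), each = 6)
  res <- anova_tukey(v, g)
  tt <- t.test(v ~ g, var.equal = TRUE)
  expect_equal(res$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)

  # hand-computed 3-group F (textbook MSB/MSW)
  vals <- c(2, 3, 4, 6, 7, 8, 10, 11, 12)
  grp <- rep(c("g1", "g2", "g3"), each = 3)
  msb <- 3 * sum((c(3, 7, 11) - 7)^2) / 2
  msw <- sum((vals - rep(c(3, 7, 11), each = 3))^2) / 6
  expect_equal(anova_tukey(vals, grp)$f, msb / msw, tolerance = 1e-10)
  expect_error(anova_tukey(rep(1, 6), rep(c("a", "b"), 3)), "zero")
})
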