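test_that("PCoA on Euclidean distances reproduces the point cloud", {
  set.seed(5)
  pts <- matrix(rnorm(40), 20, 2, dimnames = list(sprintf("s%d", 1:20), NULL))
  dm <- euclidean_dist(pts, scale = FALSE)
  pc <- pcoa(dm)
  expect_lt(procrustes_error(pc$coordinates[, 1:2], pts), 1e-8)
  expect_equal(pc$negative_eigenvalues, 0)

  skip_if_not_installed("vegan")  # guard not needed, cmdscale is stats; kept symmetric
  cm <- stats::cmdscale(as.dist(unclass(dm)), k = 2, eig = TRUE)
  expect_equal(pc$eigenvalues[1:2], cm$eig[1:2], tolerance = 1e-10)
})

test_that("PCoA forced geometries and the trace identity hold", {
  d <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  pc <- pcoa(dist_matrix(d))
  expect_equal(sort(unname(pc$coordinates[, 1])), c(-1.5, 1.5), tolerance = 1e-12)

  ct <- random_count_table(30, 12, seed = 13)
  dm <- bray_curtis(ct)
  pc2 <- pcoa(dm)
  g_mat <- local({
    d2 <- unclass(dm)^2
    n <- nrow(d2)
    j <- diag(n) - 1 / n
    -0.5 * j %*% d2 %*% j
  })
  g_trace <- sum(diag(g_mat))
  expect_equal(sum(pc2$eigenvalues), g_trace, tolerance = 1e-9)
  expect_lte(sum(pc2$proportion), 1 + 1e-12)
  expect_true(all(diff(pc2$eigenvalues) <= 1e-12))

  # Lingoes correction removes negative eigenvalues
  pc3 <- pcoa(dm, correction = "lingoes")
  expect_lt(abs(min(pc3$eigenvalues[pc3$eigenvalues < 0], 0)),
            1e-8 * max(pc3$eigenvalues))
})

test_that("RDA partitions variance and recognises known constraints", {
  ct <- random_count_table(25, 14, seed = 8)
  y <- hellinger(ct)
  set.seed(1)
  x <- matrix(rnorm(14 * 2), 14, dimnames = list(rownames(y), c("c1", "c2")))
  r <- rda(y, x, n_perm = 99, seed = 1)
  expect_equal(sum(r$constrained_eigenvalues) + sum(r$unconstrained_eigenvalues),
               r$total_inertia, tolerance = 1e-10)
  expect_gte(r$constrained_proportion, 0)
  expect_lte(r$constrained_proportion, 1)

  # constraint equal to the first principal component: RDA1 reproduces it
  yc <- scale(y, scale = FALSE)
  pca <- svd(yc)
  pc1 <- pca$u[, 1] * pca$d[1]
  r1 <- rda(y, matrix(pc1, ncol = 1, dimnames = list(rownames(y), "pc1")),
            n_perm = 0)
  expect_equal(r1$constrained_eigenvalues[1], pca$d[1]^2 / (14 - 1),
               tolerance = 1e-8)
  expect_gt(abs(cor(r1$coordinates[, 1], pc1)), 1 - 1e-10)

  # responses residualized on the constraints leave nothing to explain
  y_orth <- qr.resid(qr(cbind(1, x)), yc)
  rownames(y_orth) <- rownames(y)
  r0 <- rda(y_orth, x, n_perm = 0)
  expect_lt(sum(r0$constrained_eigenvalues), 1e-12)

  expect_error(rda(y, cbind(x, c3 = x[, 1] * 2), n_perm = 0),
               "collinear.*c3")

  skip_if_not_installed("vegan")
  ref <- vegan::rda(y ~ c1 + c2, data = as.data.frame(x))
  expect_equal(unname(r$constrained_eigenvalues),
               unname(ref$CCA$eig), tolerance = 1e-10)
})

test_that("db-RDA on Euclidean distances equals RDA on the raw data", {
  ct <- random_count_table(25, 14, seed = 18)
  y <- hellinger(ct)
  set.seed(2)
  x <- matrix(rnorm(14 * 2), 14, dimnames = list(rownames(y), c("c1", "c2")))
  dm <- euclidean_dist(y, scale = FALSE)
  db <- dbrda(dm, x, n_perm = 0)
  r <- rda(y, x, n_perm = 0)
  expect_equal(unname(db$constrained_eigenvalues),
               unname(r$constrained_eigenvalues), tolerance = 1e-8)
  expect_gte(db$constrained_proportion, 0)
  expect_lte(db$constrained_proportion, 1)

  # group indicators with no group structure explain ~ their df share
  ctb <- random_count_table(30, 16, seed = 19)
  dmb <- bray_curtis(ctb)
  ind <- stats::model.matrix(~g, data.frame(g = rep(c("a", "b"), 8)))[, -1, drop = FALSE]
  rownames(ind) <- rownames(unclass(dmb))
  db0 <- dbrda(dmb, ind, n_perm = 99, seed = 1)
  expect_lt(db0$constrained_proportion, 3 * 1 / (16 - 1))
})

test_that("UPGMA merges forced topologies and reproduces ultrametric input", {
  d <- matrix(10, 3, 3) - diag(10, 3)
  d[1, 2] <- d[2, 1] <- 1
  dimnames(d) <- list(c("A", "B", "C"), c("A", "B", "C"))
  tr <- hclust_average(dist_matrix(d))
  expect_match(tr$newick, "\\(A:0\\.5,B:0\\.5\\)")   # A,B merge first at height 1
  expect_match(tr$newick, "C:5")                     # C joins at the root height 10

  skip_if_not_installed("ape")
  # ultrametric input: cophenetic distances reproduce it exactly
  base <- matrix(8, 4, 4) - diag(8, 4)
  base[1, 2] <- base[2, 1] <- 2
  base[3, 4] <- base[4, 3] <- 4
  dimnames(base) <- list(c("w", "x", "y", "z"), c("w", "x", "y", "z"))
  tru <- hclust_average(dist_matrix(base))
  ph <- ape::read.tree(text = tru$newick)
  cop <- stats::cophenetic(ph)[rownames(base), colnames(base)]
  expect_equal(cop, base, tolerance = 1e-10)

  # input order does not alter the clustering
  ct <- random_count_table(20, 9, seed = 23)
  dm <- unclass(bray_curtis(ct))
  t1 <- hclust_average(dist_matrix(dm))
  ord <- c(4, 9, 1, 3, 7, 2, 8, 5, 6)
  t2 <- hclust_average(dist_matrix(dm[ord, ord]))
  p1 <- ape::read.tree(text = t1$newick)
  p2 <- ape::read.tree(text = t2$newick)
  ids <- rownames(dm)
  expect_equal(stats::cophenetic(p2)[ids, ids],
               stats::cophenetic(p1)[ids, ids], tolerance = 1e-10)
})
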