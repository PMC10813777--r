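#' Principal coordinates analysis (PCoA)
#'
#' Classical metric scaling: eigen-decomposition of the Gower-centered
#' distance matrix. Coordinates are returned for axes with positive
#' eigenvalues; negative eigenvalues (possible for semi-metric
#' dissimilarities such as Bray-Curtis) are reported as-is by default, or
#' removed with the Lingoes additive correction.
#'
#' @param dm a `dist_matrix`.
#' @param correction `"none"` (default) or `"lingoes"`.
#' @return An object of class `ordination`: `eigenvalues` (all, sorted
#'   non-increasing), `coordinates` (samples x positive axes, scaled by
#'   sqrt of eigenvalue), `proportion` (variance share per positive axis),
#'   `negative_eigenvalues` count, `correction`.
#' @export
pcoa <- function(dm, correction = c("none", "lingoes")) {
  correction <- match.arg(correction)
  d <- as_dist_matrix(dm)
  if (correction == "lingoes") {
    g0 <- gower_centre(d)
    lmin <- min(eigen(g0, symmetric = TRUE, only.values = TRUE)$values)
    if (lmin < 0) {
      c_add <- -lmin
      d2 <- d^2 + 2 * c_add
      diag(d2) <- 0
      d <- sqrt(d2)
      dimnames(d) <- dimnames(dm)
      d <- as_dist_matrix((d + t(d)) / 2)
    }
  }
  g <- gower_centre(d)
  eg <- eigen(g, symmetric = TRUE)
  vals <- eg$values
  pos <- which(vals > max(vals) * 1e-12 & vals > 0)
  coords <- eg$vectors[, pos, drop = FALSE] %*% diag(sqrt(vals[pos]), length(pos))
  rownames(coords) <- rownames(d)
  colnames(coords) <- sprintf("PCo%d", seq_along(pos))
  structure(list(
    eigenvalues = vals,
    coordinates = coords,
    proportion = vals[pos] / sum(vals[pos]),
    negative_eigenvalues = sum(vals < -max(abs(vals)) * 1e-8),
    correction = correction,
    total_inertia = sum(diag(g))
  ), class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  kind <- if (!is.null(x$constrained_eigenvalues)) "constrained ordination" else "PCoA"
  cat(sprintf("<%s> %d samples", kind, nrow(x$coordinates)))
  if (!is.null(x$constrained_proportion))
    cat(sprintf(", constrained %.1f%% of inertia", 100 * x$constrained_proportion))
  cat(sprintf("; first axes: %s\n",
              paste(sprintf("%.1f%%", 100 * utils::head(x$proportion, 3)), collapse = ", ")))
  invisible(x)
}

# Check a constraint matrix for collinearity; returns the QR decomposition
# or fails naming a minimal aliased column set.
check_constraints <- function(x) {
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    aliased <- colnames(x)[qrx$pivot[(qrx$rank + 1L):ncol(x)]]
    stop_("collinear constraint(s): %s", paste(aliased, collapse = ", "))
  }
  qrx
}

constraint_matrix <- function(constraints) {
  x <- as.matrix(constraints)
  if (!is.numeric(x)) stop_("constraints must be numeric")
  if (anyNA(x)) stop_("constraints contain missing values")
  if (is.null(colnames(x))) colnames(x) <- sprintf("X%d", seq_len(ncol(x)))
  x
}

#' Redundancy analysis (RDA)
#'
#' Constrained ordination of a response matrix on environmental covariates:
#' each (centered) response column is regressed on the centered constraints;
#' the fitted values are eigen-decomposed into constrained axes and the
#' residuals into unconstrained axes. Inertia is measured as variance
#' (sums of squares / (n - 1)), so constrained plus unconstrained
#' eigenvalues sum to the total variance of the response. Overall
#' significance is a permutation test of the pseudo-F, permuting sample
#' rows.
#'
#' @param abundance samples x taxa matrix, typically transformed counts
#'   (e.g. [hellinger()]).
#' @param constraints samples x covariates numeric matrix or data.frame.
#' @param n_perm permutations for the significance test (0 to skip).
#' @param seed integer seed.
#' @return An `ordination` object with `constrained_eigenvalues`,
#'   `unconstrained_eigenvalues`, `coordinates` (constrained axes),
#'   `biplot` (constraint correlations with the axes),
#'   `constrained_proportion`, `total_inertia`, and `test`
#'   (a `perm_test`, when `n_perm > 0`).
#' @export
rda <- function(abundance, constraints, n_perm = 499L, seed = 1L) {
  y <- as.matrix(abundance)
  x <- constraint_matrix(constraints)
  n <- nrow(y)
  if (nrow(x) != n) stop_("abundance and constraints disagree on samples")
  if (n <= ncol(x) + 1L) stop_("need n_samples > n_covariates + 1")
  yc <- scale(y, center = TRUE, scale = FALSE)
  xc <- scale(x, center = TRUE, scale = FALSE)
  qrx <- check_constraints(xc)
  fit <- qr.fitted(qrx, yc)
  res <- yc - fit
  tot <- sum(yc^2) / (n - 1)
  sv_c <- svd(fit / sqrt(n - 1))
  sv_u <- svd(res / sqrt(n - 1))
  eig_c <- sv_c$d^2
  eig_u <- sv_u$d^2
  keep_c <- eig_c > max(eig_c[1], 0) * 1e-10
  keep_u <- eig_u > max(eig_u[1], 0) * 1e-10
  eig_c <- eig_c[keep_c]
  eig_u <- eig_u[keep_u]
  coords <- sv_c$u[, keep_c, drop = FALSE] %*%
    diag(sv_c$d[keep_c] * sqrt(n - 1), sum(keep_c))
  rownames(coords) <- rownames(y)
  if (length(eig_c)) colnames(coords) <- sprintf("RDA%d", seq_along(eig_c))
  biplot <- if (length(eig_c))
    suppressWarnings(stats::cor(xc, coords)) else NULL
  test <- NULL
  if (n_perm > 0) {
    q <- qrx$rank
    f_of <- function(yy) {
      fitp <- qr.fitted(qrx, yy)
      ssf <- sum(fitp^2)
      ssr <- sum((yy - fitp)^2)
      (ssf / q) / (ssr / (n - q - 1))
    }
    f_obs <- f_of(yc)
    f_perm <- with_seed(derive_seed(seed, 31L), vapply(seq_len(n_perm), function(b) {
      f_of(yc[sample.int(n), , drop = FALSE])
    }, numeric(1)))
    test <- perm_test_result("RDA pseudo-F", f_obs,
                             sum(f_perm >= f_obs - 1e-12), n_perm, seed)
  }
  structure(list(
    eigenvalues = c(eig_c, eig_u),
    constrained_eigenvalues = eig_c,
    unconstrained_eigenvalues = eig_u,
    coordinates = coords,
    biplot = biplot,
    proportion = c(eig_c, eig_u) / tot,
    constrained_proportion = sum(eig_c) / tot,
    total_inertia = tot,
    test = test
  ), class = "ordination")
}

#' Hellinger transformation
#'
#' Square root of relative abundances, the standard pre-transformation that
#' makes RDA on community counts analyse a meaningful (Hellinger) distance.
#'
#' @param table a [count_table()].
#' @return samples x taxa numeric matrix.
#' @export
hellinger <- function(table) {
  rel <- to_relative(table)
  t(sqrt(unclass(rel)))
}

#' Distance-based redundancy analysis (db-RDA / CPCoA)
#'
#' Constrained ordination of an arbitrary dissimilarity matrix: PCoA axes
#' retaining at least 99.9% of the positive inertia are used as the
#' response of an RDA on the constraints. With Euclidean input distances
#' this reproduces RDA on the raw data.
#'
#' @param dm a `dist_matrix`.
#' @param constraints samples x covariates numeric matrix or data.frame.
#' @param n_perm permutations for the significance test (0 to skip).
#' @param seed integer seed.
#' @return An `ordination` object (see [rda()]).
#' @export
dbrda <- function(dm, constraints, n_perm = 499L, seed = 1L) {
  pc <- pcoa(dm)
  cum <- cumsum(pc$proportion)
  n_axes <- which(cum >= 0.999)[1L]
  if (is.na(n_axes)) n_axes <- length(pc$proportion)
  coords <- pc$coordinates[, seq_len(n_axes), drop = FALSE]
  out <- rda(coords, constraints, n_perm = n_perm, seed = seed)
  out$pcoa_axes_used <- n_axes
  out
}
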