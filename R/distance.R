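#' Distance matrices
#'
#' A symmetric dissimilarity matrix with zero diagonal and sample ids on
#' both margins; the common currency of the ordination and permutation
#' statistics.
#'
#' @param m square numeric matrix with matching dimnames.
#' @return A matrix of class `dist_matrix`.
#' @export
dist_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop_("distance matrix must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    stop_("distance matrix needs identical row and column sample ids")
  if (max(abs(m - t(m))) > 1e-12) stop_("distance matrix not symmetric")
  if (any(diag(m) != 0)) stop_("distance matrix diagonal must be 0")
  class(m) <- c("dist_matrix", class(matrix()))
  m
}

as_dist_matrix <- function(x) {
  if (inherits(x, "dist_matrix")) return(unclass(x))
  if (inherits(x, "dist")) {
    m <- as.matrix(x)
    return(unclass(dist_matrix(m)))
  }
  unclass(dist_matrix(x))
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(u, v) = sum |u_i - v_i| / sum (u_i + v_i)`, bounded in `[0, 1]`.
#' Computed on relative abundances by default (robust to unequal depth);
#' `scale = "counts"` uses the abundances as given (e.g. rarefied counts).
#'
#' @param table a [count_table()] or abundance matrix (taxa x samples).
#' @param scale `"relative"` (default) or `"counts"`.
#' @return A `dist_matrix`.
#' @export
bray_curtis <- function(table, scale = c("relative", "counts")) {
  scale <- match.arg(scale)
  m <- if (inherits(table, "count_table")) unclass(table) else as.matrix(table)
  if (ncol(m) < 2L) stop_("need >= 2 samples")
  tot <- colSums(m)
  if (any(tot == 0))
    stop_("zero-total sample(s): %s", paste(colnames(m)[tot == 0], collapse = ", "))
  if (scale == "relative") {
    m <- sweep(m, 2L, tot, "/")
    tot <- rep(1, ncol(m))
  }
  num <- as.matrix(stats::dist(t(m), method = "manhattan"))
  den <- outer(tot, tot, "+")
  d <- num / den
  diag(d) <- 0
  dimnames(d) <- list(colnames(m), colnames(m))
  dist_matrix((d + t(d)) / 2)   # exact symmetry against fp noise
}

# Gower-centered matrix of a distance matrix: G = -1/2 * J A J with
# A = d^2 and J the centering projector. Its trace is the total inertia;
# its eigenstructure drives PCoA, db-RDA and PERMANOVA.
gower_centre <- function(dm) {
  d <- as_dist_matrix(dm)
  a <- -0.5 * d^2
  n <- nrow(a)
  j <- diag(n) - matrix(1 / n, n, n)
  j %*% a %*% j
}

#' Euclidean distances between samples
#'
#' Convenience wrapper producing a `dist_matrix` from sample columns (used
#' for nutrient-factor distance matrices in Mantel tests).
#'
#' @param x matrix or data.frame, samples in rows, variables in columns.
#' @param scale standardize columns first (default TRUE).
#' @return A `dist_matrix`.
#' @export
euclidean_dist <- function(x, scale = TRUE) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) stop_("x needs sample ids as rownames")
  if (scale) {
    sds <- apply(x, 2L, stats::sd)
    keep <- sds > 0
    x <- scale(x[, keep, drop = FALSE])
  }
  d <- as.matrix(stats::dist(x))
  dimnames(d) <- list(rownames(x), rownames(x))
  dist_matrix((d + t(d)) / 2)
}
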