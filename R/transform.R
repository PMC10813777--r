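#' Convert counts to relative abundances
#'
#' Divides every sample (column) by its read total. Relative abundances feed
#' the neutral-model metacommunity estimate and Bray-Curtis distances.
#'
#' @param table a [count_table()].
#' @return A double matrix of class `rel_abundance_table`; every column sums
#'   to 1.
#' @export
to_relative <- function(table) {
  m <- as_count_matrix(table)
  tot <- colSums(m)
  if (any(tot == 0))
    stop_("zero-total sample(s): %s",
          paste(colnames(m)[tot == 0], collapse = ", "))
  rel <- sweep(m, 2L, tot, "/")
  class(rel) <- c("rel_abundance_table", class(matrix()))
  rel
}

#' Rarefy samples to a common depth
#'
#' Subsamples every sample's reads without replacement (hypergeometric
#' draws) to exactly `depth` reads. Each sample's draw is seeded from
#' (`seed`, sample index), so one sample's result does not depend on the
#' draws made for the others.
#'
#' @param table a [count_table()].
#' @param depth target reads per sample; must not exceed any sample total.
#' @param seed integer root seed.
#' @return A [count_table()] with all column totals equal to `depth`.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  m <- as_count_matrix(table)
  depth <- as.integer(depth)
  if (depth < 1L) stop_("depth must be >= 1")
  tot <- colSums(m)
  short <- tot < depth
  if (any(short))
    stop_("depth %d exceeds total reads of sample(s): %s", depth,
          paste(colnames(m)[short], collapse = ", "))
  out <- m
  for (j in seq_len(ncol(m))) {
    if (tot[j] == depth) next
    cnt <- m[, j]
    pool <- rep.int(seq_along(cnt), cnt)
    drawn <- with_seed(derive_seed(seed, j),
                       sample(pool, depth, replace = FALSE))
    out[, j] <- tabulate(drawn, nbins = nrow(m))
  }
  count_table(out)
}

#' Filter low-count / low-prevalence ZOTUs
#'
#' Keeps ZOTUs whose overall read total is at least `min_total` and which
#' are detected (count > 0) in at least a `min_prevalence` fraction of
#' samples. `min_total = 2` reproduces singleton removal. Row order is
#' preserved and the operation is idempotent.
#'
#' @param table a [count_table()].
#' @param min_total minimum total reads across samples.
#' @param min_prevalence minimum detection fraction in `[0, 1]`.
#' @return A filtered [count_table()] (warns when empty).
#' @export
filter_taxa <- function(table, min_total = 0L, min_prevalence = 0) {
  m <- as_count_matrix(table)
  if (min_total < 0 || min_prevalence < 0)
    stop_("thresholds must be >= 0")
  keep <- rowSums(as.matrix(m)) >= min_total &
    rowMeans(m > 0) >= min_prevalence
  if (!any(keep)) {
    warn_("all ZOTUs removed by filtering")
    return(structure(m[keep, , drop = FALSE],
                     class = c("count_table", class(matrix()))))
  }
  count_table(m[keep, , drop = FALSE])
}
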