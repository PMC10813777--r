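#' Alpha diversity per sample
#'
#' Standard within-sample diversity indices computed from counts:
#' `observed` (detected ZOTUs), `shannon` (natural log), `simpson`
#' (Gini-Simpson, `1 - sum p^2`), `chao1` (bias-uncorrected,
#' `S_obs + F1^2 / (2 F2)`, falling back to `F1 (F1 - 1) / 2` when there
#' are no doubletons) and `pielou` (Shannon evenness, `H / ln S_obs`,
#' `NA` for single-taxon samples).
#'
#' @param table a [count_table()].
#' @param metrics subset of
#'   `c("observed", "shannon", "simpson", "chao1", "pielou")`.
#' @return data.frame with `sample_id` and one column per metric.
#' @export
alpha_diversity <- function(table,
                            metrics = c("observed", "shannon", "simpson",
                                        "chao1", "pielou")) {
  known <- c("observed", "shannon", "simpson", "chao1", "pielou")
  bad <- setdiff(metrics, known)
  if (length(bad)) stop_("unknown metric(s): %s", paste(bad, collapse = ", "))
  m <- as_count_matrix(table)
  out <- data.frame(sample_id = colnames(m), stringsAsFactors = FALSE)
  per_sample <- function(fn) apply(m, 2L, fn)
  vals <- list(
    observed = function(v) sum(v > 0),
    shannon = function(v) {
      p <- v[v > 0] / sum(v)
      -sum(p * log(p))
    },
    simpson = function(v) {
      p <- v / sum(v)
      1 - sum(p^2)
    },
    chao1 = function(v) {
      s_obs <- sum(v > 0)
      f1 <- sum(v == 1)
      f2 <- sum(v == 2)
      if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
    },
    pielou = function(v) {
      s_obs <- sum(v > 0)
      if (s_obs < 2) return(NA_real_)
      p <- v[v > 0] / sum(v)
      -sum(p * log(p)) / log(s_obs)
    }
  )
  for (met in metrics) out[[met]] <- unname(per_sample(vals[[met]]))
  out
}
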