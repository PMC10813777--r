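#' Per-OTU per-sample variation degrees
#'
#' For a group of `k` samples, the variation degree of OTU i in sample j is
#' `a_ij = |x_ij - xbar_i| / delta_i`, with `xbar_i` the group mean and
#' `delta_i` the group standard deviation of that OTU's (rarefied)
#' abundance. OTUs with zero variance within the group carry no information
#' about dispersion and are flagged excluded.
#'
#' @param group_table abundance matrix (OTU x sample) of one sample group,
#'   `k >= 2` columns.
#' @param ddof degrees-of-freedom correction of the standard deviation: 1
#'   (sample SD, default) or 0 (population SD).
#' @return `list(a, excluded)`: the degree matrix for retained OTUs and a
#'   named logical of excluded (zero-variance) OTUs.
#' @export
variation_degree <- function(group_table, ddof = 1) {
  x <- if (inherits(group_table, "count_table")) unclass(group_table) else as.matrix(group_table)
  k <- ncol(x)
  if (k < 2L) stop_("need k >= 2 samples in a group")
  if (!ddof %in% c(0, 1)) stop_("ddof must be 0 or 1")
  mu <- rowMeans(x)
  ss <- rowSums((x - mu)^2)
  sd_i <- sqrt(ss / (k - ddof))
  excluded <- sd_i == 0
  a <- abs(x[!excluded, , drop = FALSE] - mu[!excluded]) / sd_i[!excluded]
  list(a = a, excluded = stats::setNames(excluded, rownames(x)))
}

#' Average variation degree (AVD) of a sample group
#'
#' The community-stability index: the mean standardized absolute deviation
#' of OTU abundances within a group, `AVD = sum_ij a_ij / (k * n)` with `k`
#' samples and `n` retained OTUs. Lower AVD indicates a more stable
#' community. AVD is invariant to OTU/sample relabeling and to per-OTU
#' rescaling (the scale cancels in `|x - xbar| / delta`).
#'
#' @inheritParams variation_degree
#' @param zero_variance `"exclude"` (drop zero-variance OTUs from both the
#'   numerator and `n`, default) or `"zero"` (count them as contributing 0).
#' @param group optional group label carried into the result.
#' @return An object of class `avd_result`: `group`, `k`, `n`,
#'   `n_excluded`, `avd`, and the degree matrix `a`.
#' @export
avd <- function(group_table, ddof = 1, zero_variance = c("exclude", "zero"),
                group = NA_character_) {
  zero_variance <- match.arg(zero_variance)
  vd <- variation_degree(group_table, ddof = ddof)
  k <- ncol(vd$a)
  n_excluded <- sum(vd$excluded)
  n <- if (zero_variance == "exclude") nrow(vd$a) else length(vd$excluded)
  if (nrow(vd$a) == 0L) stop_("degenerate group: all OTUs zero-variance")
  structure(list(group = group, k = k, n = n, n_excluded = n_excluded,
                 avd = sum(vd$a) / (k * n), a = vd$a,
                 ddof = ddof, zero_variance = zero_variance),
            class = "avd_result")
}

#' @export
print.avd_result <- function(x, ...) {
  cat(sprintf("AVD %s= %.5f  (k = %d samples, n = %d OTUs, %d zero-variance %s)\n",
              if (is.na(x$group)) "" else sprintf("[%s] ", x$group),
              x$avd, x$k, x$n, x$n_excluded,
              if (x$zero_variance == "exclude") "excluded" else "kept as 0"))
  invisible(x)
}

#' AVD per stratum of the design
#'
#' Rarefies the table to a common depth (the AVD definition uses rarefied
#' abundances), splits samples by the requested strata (default group x
#' lifestyle) and computes one AVD per stratum, plus replicate-level AVD
#' values to support significance testing across strata.
#'
#' The replication unit is configurable because a stratum-level AVD is a
#' single number: `"replicate"` computes one AVD per tank replicate across
#' its time series (default), `"timepoint"` one per sampling day across
#' replicates, `"bootstrap"` resamples the stratum's samples.
#'
#' @param table a [count_table()] covering all strata.
#' @param frame a [sample_frame()] describing the samples.
#' @param strata metadata columns defining strata (default
#'   `c("group", "lifestyle")`).
#' @param rarefy_depth `"auto"` (minimum sample total), a number, or `NULL`
#'   to skip rarefaction (table already rarefied).
#' @param replicate_unit `"replicate"`, `"timepoint"` or `"bootstrap"`.
#' @param n_boot bootstrap replicates when `replicate_unit = "bootstrap"`.
#' @param seed integer seed (rarefaction and bootstrap).
#' @inheritParams avd
#' @return `list(strata, replicates)`: per-stratum summary data.frame
#'   (`stratum`, `k`, `n`, `n_excluded`, `avd`) and a data.frame of
#'   replicate-level values (`stratum`, `unit`, `avd`).
#' @export
avd_by_stratum <- function(table, frame, strata = c("group", "lifestyle"),
                           rarefy_depth = "auto", replicate_unit = c("replicate", "timepoint", "bootstrap"),
                           n_boot = 30L, seed = 1L, ddof = 1,
                           zero_variance = c("exclude", "zero")) {
  replicate_unit <- match.arg(replicate_unit)
  zero_variance <- match.arg(zero_variance)
  frame <- align_frame(table, frame)
  m <- as_count_matrix(table)
  if (!is.null(rarefy_depth)) {
    depth <- if (identical(rarefy_depth, "auto")) min(colSums(m)) else as.integer(rarefy_depth)
    m <- as_count_matrix(rarefy(count_table(m), depth, seed = seed))
  }
  missing_cols <- setdiff(strata, names(frame))
  if (length(missing_cols))
    stop_("strata column(s) not in frame: %s", paste(missing_cols, collapse = ", "))
  stratum <- interaction(frame[strata], drop = TRUE, sep = ".", lex.order = TRUE)
  res <- list(); reps <- list()
  for (s in levels(stratum)) {
    cols <- which(stratum == s)
    if (length(cols) < 2L) {
      warn_("stratum '%s' has < 2 samples; skipped", s)
      next
    }
    r <- avd(m[, cols, drop = FALSE], ddof = ddof,
             zero_variance = zero_variance, group = s)
    res[[s]] <- data.frame(stratum = s, k = r$k, n = r$n,
                           n_excluded = r$n_excluded, avd = r$avd,
                           stringsAsFactors = FALSE)
    units <- switch(replicate_unit,
      replicate = split(cols, frame$replicate[cols]),
      timepoint = split(cols, frame$time[cols]),
      bootstrap = {
        bs <- with_seed(derive_seed(seed, 900L + match(s, levels(stratum))),
                        replicate(n_boot, sample(cols, length(cols), replace = TRUE),
                                  simplify = FALSE))
        stats::setNames(bs, sprintf("boot%d", seq_along(bs)))
      })
    for (u in names(units)) {
      uc <- units[[u]]
      if (length(uc) < 2L) next
      ra <- tryCatch(avd(m[, uc, drop = FALSE], ddof = ddof,
                         zero_variance = zero_variance, group = s),
                     error = function(e) NULL)
      if (is.null(ra)) next
      reps[[paste(s, u)]] <- data.frame(stratum = s, unit = u, avd = ra$avd,
                                        stringsAsFactors = FALSE)
    }
  }
  list(strata = do.call(rbind, c(res, list(make.row.names = FALSE))),
       replicates = do.call(rbind, c(reps, list(make.row.names = FALSE))))
}

#' Compare AVD across groups
#'
#' One-way ANOVA over replicate-level AVD values followed by Tukey HSD and
#' a compact letter display: groups sharing a letter are not significantly
#' different at `alpha`.
#'
#' @param values numeric replicate-level AVD values.
#' @param groups group label per value (>= 2 groups with >= 2 values each;
#'   smaller groups are dropped with a warning).
#' @param alpha significance level for the letters (default 0.05).
#' @return `list(f, p, tukey, letters)`.
#' @export
compare_avd <- function(values, groups, alpha = 0.05) {
  res <- anova_tukey(values, groups, alpha = alpha)
  res
}
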