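#' Neutral-model occurrence frequency
#'
#' Sloan's beta approximation of the neutral community model: a taxon with
#' metacommunity relative abundance `p` has local relative abundance
#' distributed Beta(Nm*p, Nm*(1-p)); its expected occurrence frequency
#' across communities sequenced to `N` reads with detection limit `d` reads
#' is the beta upper tail above the detection threshold,
#' `F(p) = 1 - I_{d/N}(Nm*p, Nm*(1-p))`. Monotone non-decreasing in `p`.
#'
#' @param p relative abundance(s) in `[0, 1]`.
#' @param Nm immigration parameter (> 0).
#' @param N community size in reads (> d).
#' @param d detection limit in reads (default 1).
#' @return Occurrence frequencies in `[0, 1]`.
#' @export
predict_frequency <- function(p, Nm, N, d = 1) {
  if (any(p < 0 | p > 1)) stop_("p must lie in [0, 1]")
  if (Nm <= 0) stop_("Nm must be > 0")
  if (N <= d || d < 1) stop_("need N > d >= 1")
  f <- 1 - stats::pbeta(d / N, Nm * p, Nm * (1 - p))
  f[p == 0] <- 0
  f[p == 1] <- 1
  pmin(pmax(f, 0), 1)
}

# Detection probability under the full count model: the probability that a
# beta-binomial(N, Nm*p, Nm*(1-p)) read count reaches the detection limit d.
# This is the finite-depth analogue of predict_frequency(); the two coincide
# as N grows.
predict_frequency_count <- function(p, Nm, N, d = 1) {
  a <- Nm * p
  b <- Nm * (1 - p)
  N <- round(N)
  below <- matrix(0, nrow = length(p), ncol = d)
  for (c0 in seq_len(d) - 1L) {
    below[, c0 + 1L] <- exp(lchoose(N, c0) + lbeta(a + c0, b + N - c0) - lbeta(a, b))
  }
  f <- 1 - rowSums(below)
  f[p == 0] <- 0
  f[p == 1] <- 1
  pmin(pmax(f, 0), 1)
}

# Numeric slope of a detection curve in p (central difference).
curve_slope <- function(curve, p, Nm, N, d) {
  h <- pmax(p * 1e-3, 1e-9)
  (curve(pmin(p + h, 1), Nm, N, d) - curve(pmax(p - h, 0), Nm, N, d)) / (2 * h)
}

# Wilson score interval for a binomial proportion with success probability
# fhat observed over n trials.
wilson_interval <- function(fhat, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  den <- 1 + z^2 / n
  centre <- fhat + z^2 / (2 * n)
  half <- z * sqrt(fhat * (1 - fhat) / n + z^2 / (4 * n^2))
  cbind(lower = pmax((centre - half) / den, 0),
        upper = pmin((centre + half) / den, 1))
}

#' Fit the neutral community model
#'
#' Estimates the immigration parameter Nm by nonlinear least squares on the
#' occurrence-frequency versus mean-relative-abundance relationship: with
#' `N` the mean reads per sample, `p_i` the mean relative abundance of ZOTU
#' i and `f_obs_i` the fraction of samples where it reaches the detection
#' limit `d`, Nm minimizes `sum_i (f_obs_i - F(p_i))^2` (each ZOTU one
#' unweighted point; Nm optimized on the log scale with multi-start).
#'
#' The fitted detection curve `F` defaults to the beta-binomial detection
#' probability (`detection = "count"`), which accounts for the finite
#' sequencing depth; `detection = "threshold"` uses the classical
#' beta-tail approximation of [predict_frequency()] (the two agree closely
#' for abundant taxa, but the threshold form inflates Nm on count data
#' because taxa just below `d/N` can still be detected). R-squared is
#' `1 - SSE/SST` with SST around the mean observed frequency; it may be
#' negative and is reported as-is.
#'
#' ZOTUs never detected in the fitted samples are excluded (a (0, 0) point
#' is uninformative and degrades SST). The prediction band is a Wilson
#' score interval of a binomial proportion with success probability
#' `F(p_i)` and `n` = number of samples; by default (`band =
#' "propagated"`) the abundance axis' estimation noise is propagated into
#' the band by shrinking the effective `n` per taxon to
#' `F(1-F) / (F(1-F)/n + (dF/dp)^2 var(p_i))` -- without this the band
#' under-covers rare taxa, whose mean abundance is itself noisy.
#' `band = "wilson"` gives the plain interval. ZOTUs above the band are
#' labelled `above`, below it `below`, inside it `neutral`.
#'
#' @param table a [count_table()] of one community group.
#' @param d detection limit in reads.
#' @param ci_level prediction-band level (default 0.95).
#' @param detection `"count"` (beta-binomial, default) or `"threshold"`
#'   (classical beta tail).
#' @param band `"propagated"` (default) or `"wilson"`.
#' @return An object of class `ncm_fit`: `Nm`, `m = Nm/N`, `N`, `d`,
#'   `r_squared`, `ci_level`, `detection`, `n_samples`, `n_excluded`, and
#'   `zotu`, a data.frame with `zotu_id`, `p`, `f_obs`, `f_pred`,
#'   `f_lower`, `f_upper`, `partition`.
#' @export
fit_ncm <- function(table, d = 1, ci_level = 0.95,
                    detection = c("count", "threshold"),
                    band = c("propagated", "wilson")) {
  detection <- match.arg(detection)
  band <- match.arg(band)
  m <- as_count_matrix(table)
  if (ncol(m) < 2L) stop_("need >= 2 samples")
  N <- mean(colSums(m))
  rel <- to_relative(m)
  p_all <- rowMeans(rel)
  f_all <- rowMeans(m >= d)
  keep <- f_all > 0 & p_all > 0
  if (sum(keep) < 10L) stop_("need >= 10 ZOTUs detected in >= 1 sample")
  p <- p_all[keep]
  f_obs <- f_all[keep]
  if (length(unique(f_obs)) == 1L) stop_("degenerate frequency spectrum")

  curve <- if (detection == "count") predict_frequency_count else predict_frequency
  sse <- function(log_nm) {
    fp <- curve(p, exp(log_nm), N, d)
    sum((f_obs - fp)^2)
  }
  starts <- log(c(1, 10, 100, 1000, 10000))
  fits <- lapply(starts, function(s) {
    tryCatch(stats::nlminb(s, sse, lower = log(1e-3), upper = log(1e9)),
             error = function(e) NULL)
  })
  fits <- Filter(function(f) !is.null(f) && is.finite(f$objective), fits)
  if (!length(fits))
    stop_("neutral-model optimizer failed from all starts (n=%d points)",
          length(p))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  Nm <- exp(best$par)
  sse_val <- best$objective
  sst <- sum((f_obs - mean(f_obs))^2)
  r2 <- 1 - sse_val / sst

  f_pred <- curve(p, Nm, N, d)
  k <- ncol(m)
  n_eff <- rep(k, length(p))
  if (band == "propagated") {
    var_p <- apply(rel[keep, , drop = FALSE], 1L, stats::var) / k
    slope <- curve_slope(curve, p, Nm, N, d)
    var_tot <- f_pred * (1 - f_pred) / k + slope^2 * var_p
    n_eff <- ifelse(var_tot > 0,
                    pmax(pmin(f_pred * (1 - f_pred) / var_tot, k), 2), k)
  }
  bnd <- wilson_interval(f_pred, n_eff, ci_level)
  # Union with the exact binomial quantile envelope: the Wilson normal
  # approximation collapses near f = 0 or 1, where e.g. observing a taxon
  # in all samples is the expected outcome, not an excess.
  alpha <- 1 - ci_level
  bnd[, "upper"] <- pmax(bnd[, "upper"],
                         stats::qbinom(1 - alpha / 2, k, f_pred) / k)
  bnd[, "lower"] <- pmin(bnd[, "lower"],
                         stats::qbinom(alpha / 2, k, f_pred) / k)
  partition <- ifelse(f_obs > bnd[, "upper"], "above",
                      ifelse(f_obs < bnd[, "lower"], "below", "neutral"))
  structure(list(
    Nm = Nm, m = Nm / N, N = N, d = d, r_squared = r2,
    ci_level = ci_level, detection = detection, band = band,
    n_samples = ncol(m), n_excluded = sum(!keep),
    zotu = data.frame(zotu_id = names(p), p = unname(p),
                      f_obs = unname(f_obs), f_pred = unname(f_pred),
                      f_lower = unname(bnd[, "lower"]),
                      f_upper = unname(bnd[, "upper"]),
                      partition = unname(partition),
                      stringsAsFactors = FALSE)
  ), class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf("Neutral community model fit (%d ZOTUs, %d samples)\n",
              nrow(x$zotu), x$n_samples))
  cat(sprintf("  Nm = %.1f  (m = %.3g, N = %.1f reads, d = %g)\n",
              x$Nm, x$m, x$N, x$d))
  cat(sprintf("  R2 = %.3f  [SST around mean f_obs]\n", x$r_squared))
  tab <- table(factor(x$zotu$partition, c("above", "neutral", "below")))
  cat(sprintf("  partition: above %d / neutral %d / below %d (%.0f%% band)\n",
              tab["above"], tab["neutral"], tab["below"], 100 * x$ci_level))
  invisible(x)
}

#' Predicted frequency curve of a fitted model
#'
#' @param object an `ncm_fit`.
#' @param p relative abundances at which to evaluate the fitted curve.
#' @param ... unused.
#' @return data.frame with `p`, `f_pred`, `f_lower`, `f_upper`.
#' @export
predict.ncm_fit <- function(object, p, ...) {
  curve <- if (object$detection == "count") predict_frequency_count else predict_frequency
  f <- curve(p, object$Nm, object$N, object$d)
  band <- wilson_interval(f, object$n_samples, object$ci_level)
  data.frame(p = p, f_pred = f,
             f_lower = band[, "lower"], f_upper = band[, "upper"])
}

#' Partition summary by abundance
#'
#' Cumulative mean relative abundance and ZOTU count of the above / neutral
#' / below partitions of a fit. The neutral cumulative abundance is the
#' statistic used to quantify how much of the community is neutrally
#' distributed.
#'
#' @param fit an `ncm_fit`.
#' @param table optional [count_table()] to cross-check ZOTU ids against.
#' @return data.frame with one row per partition: `partition`, `n_zotus`,
#'   `cum_abundance`.
#' @export
partition_abundance <- function(fit, table = NULL) {
  stopifnot(inherits(fit, "ncm_fit"))
  if (!is.null(table)) {
    ids <- rownames(as_count_matrix(table))
    if (!all(fit$zotu$zotu_id %in% ids))
      stop_("fit contains ZOTU ids absent from the table")
  }
  parts <- factor(fit$zotu$partition, levels = c("above", "neutral", "below"))
  data.frame(
    partition = levels(parts),
    n_zotus = as.integer(table(parts)),
    cum_abundance = as.numeric(tapply(fit$zotu$p, parts, sum, default = 0)),
    stringsAsFactors = FALSE
  )
}

#' Family-resolved partition summary
#'
#' ZOTU counts and cumulative abundances per (family, partition), with
#' families sorted by total fitted abundance. ZOTUs missing from the
#' taxonomy fall into the `"Unassigned"` family.
#'
#' @param fit an `ncm_fit`.
#' @param taxonomy a [taxonomy_table()].
#' @return data.frame with `family`, `partition`, `n_zotus`,
#'   `cum_abundance`.
#' @export
partition_by_family <- function(fit, taxonomy) {
  stopifnot(inherits(fit, "ncm_fit"))
  fam <- taxonomy$family[match(fit$zotu$zotu_id, taxonomy$zotu_id)]
  fam[is.na(fam)] <- UNASSIGNED
  parts <- factor(fit$zotu$partition, levels = c("above", "neutral", "below"))
  agg_n <- stats::aggregate(list(n_zotus = fit$zotu$p),
                            by = list(family = fam, partition = parts),
                            FUN = length, drop = TRUE)
  agg_a <- stats::aggregate(list(cum_abundance = fit$zotu$p),
                            by = list(family = fam, partition = parts),
                            FUN = sum, drop = TRUE)
  out <- merge(agg_n, agg_a, by = c("family", "partition"))
  fam_tot <- tapply(out$cum_abundance, out$family, sum)
  out <- out[order(-fam_tot[out$family], out$family, out$partition), ]
  rownames(out) <- NULL
  out$partition <- as.character(out$partition)
  out
}
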