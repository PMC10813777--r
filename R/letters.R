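# Compact letter display by insert-and-absorb: start from one set holding
# all groups; for each significantly different pair, split every set that
# still contains both; finally drop sets that are subsets of others.
# Letters are assigned in order of first group appearance.
compact_letters <- function(groups, sig_pairs) {
  sets <- list(groups)
  for (k in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs[k, 1L]
    b <- sig_pairs[k, 2L]
    for (i in seq_along(sets)) {
      s <- sets[[i]]
      if (all(c(a, b) %in% s)) {
        sets[[i]] <- setdiff(s, a)
        sets[[length(sets) + 1L]] <- setdiff(s, b)
      }
    }
    # absorb: remove sets contained in another set
    keep <- rep(TRUE, length(sets))
    for (i in seq_along(sets)) {
      for (j in seq_along(sets)) {
        if (i != j && keep[j] &&
            all(sets[[i]] %in% sets[[j]]) &&
            (length(sets[[i]]) < length(sets[[j]]) || i > j)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    sets <- sets[keep]
  }
  # order sets by earliest member, label a, b, c, ...
  first_pos <- vapply(sets, function(s) min(match(s, groups)), numeric(1))
  sets <- sets[order(first_pos)]
  out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets)) {
    for (gname in sets[[i]]) out[gname] <- paste0(out[gname], letters[i])
  }
  out
}

#' One-way ANOVA with Tukey HSD and compact letters
#'
#' Classical one-way ANOVA across groups followed by Tukey's honestly
#' significant difference test on all pairs; groups sharing a letter in the
#' compact letter display are not significantly different at `alpha`.
#' Groups with fewer than 2 values are dropped with a warning.
#'
#' @param values numeric response values.
#' @param groups group label per value.
#' @param alpha significance level (default 0.05).
#' @return `list(f, p, tukey, letters, means)`: the ANOVA F and p, the
#'   Tukey table (data.frame with `pair`, `diff`, `lwr`, `upr`, `p_adj`),
#'   letters named by group, and group means.
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  if (length(values) != length(groups)) stop_("values and groups differ in length")
  cnt <- table(groups)
  small <- names(cnt)[cnt < 2L]
  if (length(small)) {
    warn_("group(s) with < 2 values excluded: %s", paste(small, collapse = ", "))
    keep <- !groups %in% small
    values <- values[keep]
    groups <- groups[keep]
  }
  lev <- unique(groups)   # first-appearance order, used for letter ties
  if (length(lev) < 2L) stop_("need >= 2 groups with >= 2 values each")
  gf <- factor(groups, levels = lev)
  if (all(tapply(values, gf, stats::var) == 0))
    stop_("zero within-group variance everywhere: ANOVA undefined")
  fit <- stats::aov(values ~ gf)
  ana <- summary(fit)[[1L]]
  f <- ana[["F value"]][1L]
  p <- ana[["Pr(>F)"]][1L]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$gf
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  rownames(tukey) <- NULL
  sig <- tukey[!is.na(tukey$p_adj) & tukey$p_adj < alpha, , drop = FALSE]
  sig_pairs <- do.call(rbind, strsplit(sig$pair, "-", fixed = TRUE))
  if (is.null(sig_pairs)) sig_pairs <- matrix(character(0), ncol = 2L)
  lets <- compact_letters(lev, sig_pairs)
  list(f = f, p = p, tukey = tukey, letters = lets,
       means = tapply(values, gf, mean))
}
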