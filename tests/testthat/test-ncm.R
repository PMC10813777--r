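test_that("predicted frequency honors limits and monotonicity", {
  expect_equal(predict_frequency(0, 500, 1e4), 0)
  expect_equal(predict_frequency(1, 500, 1e4), 1)
  expect_error(predict_frequency(-0.1, 500, 1e4), "\\[0, 1\\]")
  expect_error(predict_frequency(0.5, -1, 1e4), "Nm")

  p_grid <- sort(c(10^seq(-6, -0.1, length.out = 60), 0.99))
  f <- predict_frequency(p_grid, 300, 1e4)
  expect_true(all(diff(f) >= -1e-12))
  expect_true(all(f >= 0 & f <= 1))

  # as Nm grows the curve approaches a step at p = d/N
  f_lo <- predict_frequency(c(5e-5, 2e-4), 100, 1e4)
  f_hi <- predict_frequency(c(5e-5, 2e-4), 1e6, 1e4)
  expect_lt(f_hi[1], f_lo[1])
  expect_gt(f_hi[2], f_lo[2])
})

test_that("predicted frequency agrees with quadrature of the beta density", {
  # spot grid here; the full 100-point sweep runs in the acceptance suite
  N <- 1e4; d <- 1
  for (Nm in c(50, 500, 5000)) {
    for (p in c(1e-4, 1e-3, 1e-2, 0.2)) {
      quad <- integrate(function(x) dbeta(x, Nm * p, Nm * (1 - p)),
                        lower = d / N, upper = 1,
                        rel.tol = 1e-12, abs.tol = 1e-12)$value
      expect_lt(abs(predict_frequency(p, Nm, N, d) - quad), 1e-8)
    }
  }
})

test_that("the fit recovers the generative immigration parameter", {
  for (s in 1:2) {
    sim <- neutral_sim(600, 40, 8000, 500, seed = s * 7)
    fit <- fit_ncm(sim$table)
    expect_lt(abs(fit$Nm - 500) / 500, 0.15)
    expect_gte(fit$r_squared, 0.6)
    expect_equal(fit$m, fit$Nm / fit$N, tolerance = 1e-12)
  }
})

test_that("fit output satisfies the partition contract", {
  sim <- neutral_sim(400, 30, 5000, 300, seed = 5)
  fit <- fit_ncm(sim$table)
  z <- fit$zotu
  expect_true(all(z$f_lower <= z$f_pred + 1e-12))
  expect_true(all(z$f_pred <= z$f_upper + 1e-12))
  expect_true(all(z$partition %in% c("above", "neutral", "below")))
  expect_identical(z$partition == "above", z$f_obs > z$f_upper)
  expect_identical(z$partition == "below", z$f_obs < z$f_lower)

  # saturation regime: abundant taxa sit at frequency ~1 and are neutral
  sat <- z[z$p > 0.02, ]
  expect_true(all(sat$f_pred > 0.99))
  expect_true(all(sat$partition == "neutral"))

  # widening the band never ejects a neutral taxon
  fit99 <- fit_ncm(sim$table, ci_level = 0.99)
  was_neutral <- z$partition == "neutral"
  expect_true(all(fit99$zotu$partition[was_neutral] == "neutral"))
})

test_that("the fit is invariant to sample and taxon order", {
  sim <- neutral_sim(200, 20, 3000, 400, seed = 12)
  m <- unclass(sim$table)
  perm <- count_table(m[sample(nrow(m)), sample(ncol(m))])
  f1 <- fit_ncm(sim$table)
  f2 <- fit_ncm(perm)
  expect_equal(f2$Nm, f1$Nm, tolerance = 1e-9)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-9)
  z1 <- f1$zotu[order(f1$zotu$zotu_id), ]
  z2 <- f2$zotu[order(f2$zotu$zotu_id), ]
  expect_equal(z2$f_pred, z1$f_pred, tolerance = 1e-9)
  expect_identical(z2$partition, z1$partition)
})

test_that("degenerate inputs are rejected", {
  m <- matrix(5L, 12, 6, dimnames = list(sprintf("z%d", 1:12),
                                         sprintf("s%d", 1:6)))
  expect_error(fit_ncm(count_table(m)), "degenerate frequency spectrum")
  expect_error(fit_ncm(count_table(m[, 1, drop = FALSE])), ">= 2 samples")
  expect_error(fit_ncm(count_table(m[1:3, ])), ">= 10 ZOTUs")
})

test_that("injected non-neutral taxa are recovered by the partition", {
  sim <- neutral_sim(500, 40, 6000, 400, seed = 31)
  inj <- inject_non_neutral(sim$table, sim$truth, 25, 25, seed = 32)
  fit <- fit_ncm(inj$table)
  lab <- setNames(fit$zotu$partition, fit$zotu$zotu_id)
  above <- names(which(inj$truth$labels == "above"))
  below <- names(which(inj$truth$labels == "below"))
  expect_gte(mean(lab[above] == "above", na.rm = TRUE), 0.8)
  expect_gte(mean(lab[below] == "below", na.rm = TRUE), 0.8)
})

test_that("fit R2 is self-consistent under a parametric bootstrap", {
  sim <- neutral_sim(300, 25, 4000, 400, seed = 40)
  fit <- fit_ncm(sim$table)
  p_hat <- setNames(fit$zotu$p / sum(fit$zotu$p), fit$zotu$zotu_id)
  boot <- vapply(1:5, function(b) {
    cfg <- neutral_sim_config(S = length(p_hat), k = fit$n_samples,
                              N = round(fit$N), Nm = fit$Nm, seed = 500 + b)
    fit_ncm(simulate_neutral_counts(p_hat, cfg)$table)$r_squared
  }, numeric(1))
  expect_lt(abs(fit$r_squared - mean(boot)), 3 * sd(boot) + 0.02)
})

test_that("partition summaries add up and aggregate by family", {
  sim <- neutral_sim(300, 25, 4000, 300, seed = 15)
  fit <- fit_ncm(sim$table)
  pa <- partition_abundance(fit, sim$table)
  expect_equal(sum(pa$n_zotus), nrow(fit$zotu))
  expect_lte(sum(pa$cum_abundance), 1 + 1e-9)
  # direct-summation oracle
  for (part in pa$partition) {
    expect_equal(pa$cum_abundance[pa$partition == part],
                 sum(fit$zotu$p[fit$zotu$partition == part]))
  }

  tax <- simulate_taxonomy(fit$zotu$zotu_id, n_families = 20, seed = 3)
  fam <- partition_by_family(fit, tax)
  # independent group-by oracle
  key <- paste(tax$family[match(fit$zotu$zotu_id, tax$zotu_id)],
               fit$zotu$partition)
  oracle <- tapply(fit$zotu$p, key, sum)
  expect_equal(as.numeric(oracle[paste(fam$family, fam$partition)]),
               fam$cum_abundance, tolerance = 1e-12)
  # family marginals add back to the global summary
  for (part in pa$partition) {
    expect_equal(sum(fam$cum_abundance[fam$partition == part]),
                 pa$cum_abundance[pa$partition == part], tolerance = 1e-12)
  }

  # a single shared family reproduces the global summary
  tax1 <- taxonomy_table(data.frame(zotu_id = fit$zotu$zotu_id,
                                    family = "OnlyFamily"))
  fam1 <- partition_by_family(fit, tax1)
  expect_equal(sum(fam1$n_zotus), sum(pa$n_zotus))
  expect_equal(sort(fam1$cum_abundance),
               sort(pa$cum_abundance[pa$cum_abundance > 0]), tolerance = 1e-12)
})
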