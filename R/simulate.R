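#' Simulate a lognormal metacommunity
#'
#' Draws a source-pool relative-abundance vector with a lognormal
#' rank-abundance shape, the canonical abundance distribution of amplicon
#' surveys. `abundance_sigma = 0` degenerates to the uniform pool.
#'
#' @param S number of taxa (>= 2).
#' @param abundance_sigma lognormal shape parameter (sd on the log scale).
#' @param seed integer seed.
#' @return Strictly positive relative abundances summing to 1.
#' @export
simulate_metacommunity <- function(S, abundance_sigma = 1.5, seed = 1L) {
  if (S < 2L) stop_("S must be >= 2")
  if (abundance_sigma < 0) stop_("abundance_sigma must be >= 0")
  w <- with_seed(seed, stats::rlnorm(S, meanlog = 0, sdlog = abundance_sigma))
  p <- w / sum(w)
  names(p) <- sprintf("ZOTU_%d", seq_len(S))
  p
}

#' Configuration for a neutral community simulation
#'
#' @param S taxa in the metacommunity.
#' @param k local communities (samples).
#' @param N sequencing reads per sample.
#' @param Nm immigration parameter: community size times migration rate.
#'   Larger Nm couples local communities more tightly to the metacommunity.
#' @param abundance_sigma lognormal shape of the metacommunity.
#' @param seed integer seed.
#' @return A validated config list of class `neutral_sim_config`.
#' @export
neutral_sim_config <- function(S = 1000L, k = 50L, N = 10000L, Nm = 500,
                               abundance_sigma = 1.5, seed = 1L) {
  if (S < 2L) stop_("S must be >= 2")
  if (k < 2L) stop_("k must be >= 2")
  if (N < 10L) stop_("N must be >= 10")
  if (Nm <= 0) stop_("Nm must be > 0")
  structure(list(S = as.integer(S), k = as.integer(k), N = as.integer(N),
                 Nm = Nm, abundance_sigma = abundance_sigma,
                 seed = as.integer(seed)),
            class = "neutral_sim_config")
}

# One beta/binomial community draw: local relative abundance of taxon i in
# sample j follows Beta(Nm*p_i, Nm*(1-p_i)); its read count is
# Binomial(N, x_ij), per taxon independently (sample totals vary around N
# rather than being renormalized, matching the per-taxon detection model the
# fit assumes). Beta parameters are floored at 1e-8; taxa whose two
# parameters both fall below 1e-6 are treated as absent.
draw_neutral_matrix <- function(p, k, N, Nm) {
  S <- length(p)
  a <- pmax(Nm * p, 1e-8)
  b <- pmax(Nm * (1 - p), 1e-8)
  dead <- (Nm * p < 1e-6 & Nm * (1 - p) < 1e-6) | p <= 0
  x <- matrix(stats::rbeta(S * k, a, b), nrow = S, ncol = k)
  x[dead, ] <- 0
  x[p >= 1, ] <- 1
  counts <- matrix(stats::rbinom(S * k, N, x), nrow = S, ncol = k)
  counts
}

#' Simulate neutral community count data
#'
#' The generative counterpart of the fitted neutral model: each sample is an
#' independent beta draw around the metacommunity, sequenced by binomial
#' subsampling.
#'
#' @param p metacommunity relative abundances (see
#'   [simulate_metacommunity()]); taxa with `p = 0` yield all-zero counts.
#' @param cfg a [neutral_sim_config()].
#' @return `list(table, truth)`: a [count_table()] plus the generative truth
#'   (`Nm`, `p`, `N`, per-taxon `labels`, all `"neutral"` here).
#' @export
simulate_neutral_counts <- function(p, cfg) {
  stopifnot(inherits(cfg, "neutral_sim_config"))
  if (length(p) != cfg$S) stop_("length(p) != cfg$S")
  if (any(p < 0)) stop_("p must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) stop_("p must sum to 1")
  counts <- with_seed(cfg$seed, draw_neutral_matrix(p, cfg$k, cfg$N, cfg$Nm))
  dimnames(counts) <- list(names(p) %||% sprintf("ZOTU_%d", seq_along(p)),
                           sprintf("S%d", seq_len(cfg$k)))
  truth <- list(Nm = cfg$Nm, p = p, N = cfg$N,
                labels = stats::setNames(rep("neutral", length(p)),
                                         rownames(counts)))
  list(table = count_table(counts), truth = truth)
}

#' Inject non-neutrally distributed taxa
#'
#' Creates known violations of neutrality for label-recovery testing:
#' `above` taxa are low-abundance taxa forced to be detected in every sample
#' (occurrence frequency 1 despite low abundance); `below` taxa are
#' high-abundance taxa zeroed out in a majority of samples, their reads
#' reallocated proportionally to the rest of the sample so read totals are
#' conserved.
#'
#' @param table a [count_table()].
#' @param truth truth record from [simulate_neutral_counts()].
#' @param n_above,n_below how many taxa of each class to inject.
#' @param seed integer seed.
#' @param zero_fraction fraction of samples in which each `below` taxon is
#'   zeroed (default 0.8).
#' @return `list(table, truth)` with updated labels.
#' @export
inject_non_neutral <- function(table, truth, n_above, n_below, seed = 1L,
                               zero_fraction = 0.8) {
  m <- as_count_matrix(table)
  S <- nrow(m); k <- ncol(m)
  if (n_above + n_below > S)
    stop_("cannot inject %d taxa into a table of %d", n_above + n_below, S)
  labels <- truth$labels
  p <- truth$p
  ord <- order(p)
  with_seed(seed, {
    below_idx <- integer(0)
    if (n_below > 0) {
      # most abundant taxa, zeroed in a majority of samples
      below_idx <- rev(ord)[seq_len(n_below)]
      n_zero <- max(ceiling(zero_fraction * k), floor(k / 2) + 1L)
      for (i in below_idx) {
        zeroed <- sample.int(k, n_zero)
        for (j in zeroed) {
          r <- m[i, j]
          if (r == 0L) next
          m[i, j] <- 0L
          others <- m[, j]
          others[i] <- 0L
          if (sum(others) == 0L) { m[i, j] <- r; next }
          m[, j] <- m[, j] + as.integer(stats::rmultinom(1L, r, others))
          m[i, j] <- 0L
        }
      }
    }
    above_idx <- integer(0)
    if (n_above > 0) {
      # rarest taxa (positive pool abundance), forced present everywhere;
      # the single donated read comes from the sample's current top taxon
      cand <- setdiff(ord[p[ord] > 0], below_idx)
      above_idx <- cand[seq_len(n_above)]
      for (i in above_idx) {
        for (j in which(m[i, ] == 0L)) {
          donor <- which.max(m[, j])
          if (m[donor, j] <= 1L) next
          m[donor, j] <- m[donor, j] - 1L
          m[i, j] <- 1L
        }
      }
    }
    labels[above_idx] <- "above"
    labels[below_idx] <- "below"
  })
  truth$labels <- labels
  list(table = count_table(m), truth = truth)
}

#' Configuration of the synthetic rearing-water study
#'
#' Defaults emulate the experimental design: 4 treatment groups (C control,
#' N *N. oculata*, T *T. weissflogii*, M mixture) x 3 tank replicates x 8
#' sampling days x 2 bacterial lifestyles (PA/FL) = 192 samples. Per-group
#' immigration parameters make the control community the most neutrally
#' assembled. Nutrient covariates follow group-specific linear trends whose
#' slopes reproduce the observed group mean concentrations (nitrate and
#' phosphate elevated in the microalgae-added groups); both lifestyle
#' fractions of a tank share its water chemistry.
#'
#' @param groups,replicates,timepoints,lifestyles design factors.
#' @param S,N,abundance_sigma community simulation parameters per sample.
#' @param nm named per-group immigration parameter Nm.
#' @param lifestyle_nm_factor named multiplier on Nm per lifestyle
#'   (defaults equal: no assembly difference between PA and FL).
#' @param n_above,n_below injected non-neutral taxa per group.
#' @param nutrient_trends list per covariate: named vectors `intercept`,
#'   `slope` (per group, units mg/L and mg/L/day) and scalar `sd` noise.
#' @param seed integer root seed; all randomness derives from it.
#' @return A config list of class `study_design_config`.
#' @export
study_design_config <- function(groups = GROUP_LEVELS,
                                replicates = 3L,
                                timepoints = c(0L, 5L, 8L, 11L, 15L, 19L, 22L, 29L),
                                lifestyles = LIFESTYLE_LEVELS,
                                S = 1000L, N = 20000L, abundance_sigma = 1.5,
                                nm = c(C = 1500, N = 1000, T = 600, M = 800),
                                lifestyle_nm_factor = c(PA = 1, FL = 1),
                                n_above = 0L, n_below = 0L,
                                nutrient_trends = default_nutrient_trends(),
                                seed = 1L) {
  if (!all(groups %in% names(nm))) stop_("nm must name every group")
  if (!all(lifestyles %in% names(lifestyle_nm_factor)))
    stop_("lifestyle_nm_factor must name every lifestyle")
  structure(list(groups = groups, replicates = as.integer(replicates),
                 timepoints = as.integer(timepoints), lifestyles = lifestyles,
                 S = as.integer(S), N = as.integer(N),
                 abundance_sigma = abundance_sigma, nm = nm,
                 lifestyle_nm_factor = lifestyle_nm_factor,
                 n_above = as.integer(n_above), n_below = as.integer(n_below),
                 nutrient_trends = nutrient_trends, seed = as.integer(seed)),
            class = "study_design_config")
}

# Linear nutrient/biomass trends per group. Intercepts sit near day-0 pond
# water; slopes are back-solved so each group's mean over the 8 sampling
# days lands near the observed group means (nitrate and phosphate rise
# faster under microalgal addition; ammonium and nitrite stay flat).
default_nutrient_trends <- function() {
  list(
    NH4N = list(intercept = c(C = 0.34, N = 0.25, T = 0.24, M = 0.25),
                slope = c(C = 0, N = 0, T = 0, M = 0), sd = 0.08),
    NO2N = list(intercept = c(C = 0.15, N = 0.21, T = 0.16, M = 0.16),
                slope = c(C = 0, N = 0, T = 0, M = 0), sd = 0.05),
    NO3N = list(intercept = c(C = 1.0, N = 1.0, T = 1.0, M = 1.0),
                slope = c(C = 0.054, N = 0.206, T = 0.326, M = 0.216),
                sd = 0.5),
    PO4P = list(intercept = c(C = 0.30, N = 0.30, T = 0.30, M = 0.30),
                slope = c(C = 0.043, N = 0.113, T = 0.134, M = 0.118),
                sd = 0.15),
    n_oculata = list(intercept = c(C = 0, N = 24.4, T = 0, M = 20.1),
                     slope = c(C = 0, N = 0, T = 0, M = 0), sd = 3),
    t_weissflogii = list(intercept = c(C = 0, N = 0, T = 128.7, M = 5.2),
                         slope = c(C = 0, N = 0, T = 0, M = 0), sd = 3)
  )
}

#' Simulate synthetic ranked lineages
#'
#' Assigns each ZOTU a nested synthetic lineage (domain..genus) with a
#' mandatory family rank, for family-resolved partition summaries. Labels
#' are synthetic (`Family_01`, ...), not real taxa.
#'
#' @param zotu_ids character vector of taxon ids.
#' @param n_families number of synthetic families.
#' @param seed integer seed.
#' @return data.frame of class `taxonomy_table` with one row per ZOTU.
#' @export
simulate_taxonomy <- function(zotu_ids, n_families = 25L, seed = 1L) {
  n <- length(zotu_ids)
  with_seed(seed, {
    fam_of_phylum <- sample.int(6L, n_families, replace = TRUE)
    # skewed family sizes, as in real communities
    fam_w <- 1 / seq_len(n_families)
    fam <- sample.int(n_families, n, replace = TRUE, prob = fam_w)
    gen <- fam * 2L - sample(c(0L, 1L), n, replace = TRUE)
    taxonomy_table(data.frame(
      zotu_id = zotu_ids,
      domain = "Bacteria",
      phylum = sprintf("Phylum_%02d", fam_of_phylum[fam]),
      class = sprintf("Class_%02d", fam_of_phylum[fam]),
      order = sprintf("Order_%02d", (fam + 1L) %/% 2L),
      family = sprintf("Family_%02d", fam),
      genus = sprintf("Genus_%02d", gen),
      stringsAsFactors = FALSE
    ))
  })
}

#' Simulate the full study
#'
#' One neutral community per design cell (group x replicate x timepoint x
#' lifestyle), each drawn with the group's (and lifestyle's) Nm from a
#' shared metacommunity, with optional injected non-neutral taxa per group
#' and nutrient covariates following the configured trends. All randomness
#' flows from `cfg$seed`; identical configs give bit-identical output.
#'
#' @param cfg a [study_design_config()].
#' @return `list(counts, samples, taxonomy, truth)`.
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_design_config"))
  design <- expand.grid(lifestyle = cfg$lifestyles, time = cfg$timepoints,
                        replicate = seq_len(cfg$replicates), group = cfg$groups,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("group", "time", "replicate", "lifestyle")]
  design$sample_id <- sprintf("%s%d_%s_d%02d", design$group, design$replicate,
                              design$lifestyle, design$time)
  p <- simulate_metacommunity(cfg$S, cfg$abundance_sigma,
                              derive_seed(cfg$seed, 1L))
  counts <- matrix(0L, nrow = cfg$S, ncol = nrow(design),
                   dimnames = list(names(p), design$sample_id))
  for (i in seq_len(nrow(design))) {
    nm_i <- cfg$nm[[design$group[i]]] *
      cfg$lifestyle_nm_factor[[design$lifestyle[i]]]
    counts[, i] <- with_seed(derive_seed(cfg$seed, 100L + i),
                             draw_neutral_matrix(p, 1L, cfg$N, nm_i))
  }
  truth <- list(p = p, nm = cfg$nm,
                lifestyle_nm_factor = cfg$lifestyle_nm_factor,
                N = cfg$N, labels = list(), config = cfg)
  table <- count_table(counts)
  if (cfg$n_above > 0L || cfg$n_below > 0L) {
    for (g in cfg$groups) {
      cols <- design$sample_id[design$group == g]
      sub <- count_table(counts[, cols, drop = FALSE])
      inj <- inject_non_neutral(sub, list(p = p,
                                          labels = stats::setNames(
                                            rep("neutral", cfg$S), names(p))),
                                cfg$n_above, cfg$n_below,
                                seed = derive_seed(cfg$seed, 7000L + match(g, cfg$groups)))
      counts[, cols] <- as_count_matrix(inj$table)
      truth$labels[[g]] <- inj$truth$labels
    }
    table <- count_table(counts)
  }
  # nutrients are tank-level: one trajectory per (group, replicate, time)
  tanks <- unique(design[, c("group", "replicate", "time")])
  for (nut in names(cfg$nutrient_trends)) {
    tr <- cfg$nutrient_trends[[nut]]
    mu <- tr$intercept[tanks$group] + tr$slope[tanks$group] * tanks$time
    noise <- with_seed(derive_seed(cfg$seed, 5000L + match(nut, names(cfg$nutrient_trends))),
                       stats::rnorm(nrow(tanks), 0, tr$sd))
    val <- pmax(mu + noise, 0)
    key_t <- paste(tanks$group, tanks$replicate, tanks$time)
    key_d <- paste(design$group, design$replicate, design$time)
    design[[nut]] <- val[match(key_d, key_t)]
  }
  samples <- sample_frame(design[, c("sample_id", "group", "time",
                                     "replicate", "lifestyle",
                                     names(cfg$nutrient_trends))])
  taxonomy <- simulate_taxonomy(rownames(counts), seed = derive_seed(cfg$seed, 2L))
  list(counts = table, samples = samples, taxonomy = taxonomy, truth = truth)
}
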