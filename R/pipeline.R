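#' Pipeline configuration
#'
#' Assembles and validates the full analysis configuration: either paths to
#' an existing ZOTU table + metadata (+ taxonomy) or a simulation config,
#' plus the options of every stage. The effective config is persisted
#' verbatim alongside the outputs, and every stochastic stage derives its
#' seed from the single root `seed`.
#'
#' @param counts_path,metadata_path,taxonomy_path input TSVs (optional when
#'   simulating).
#' @param simulation a [study_design_config()] (optional when reading);
#'   its own seed field is overridden from the root seed.
#' @param min_total,min_prevalence ZOTU filtering thresholds
#'   ([filter_taxa()]); the default `min_total = 2` removes singletons.
#' @param rarefy_depth `"auto"` (minimum sample total) or a number; used
#'   for AVD and alpha diversity.
#' @param ncm list: detection limit `d`, band level `ci_level`, `split_by`
#'   metadata column (one fit per level), `detection` model.
#' @param avd list: `strata`, `ddof`, `zero_variance`, `replicate_unit`.
#' @param multivariate list: `n_perm` and PERMANOVA `terms`.
#' @param do_multivariate run the distance-based suite (disable for quick
#'   assembly-only runs).
#' @param seed integer root seed.
#' @param out_dir output directory (created if missing).
#' @return A validated config of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_path = NULL, metadata_path = NULL,
                            taxonomy_path = NULL, simulation = NULL,
                            min_total = 2L, min_prevalence = 0,
                            rarefy_depth = "auto",
                            ncm = list(), avd = list(), multivariate = list(),
                            do_multivariate = TRUE,
                            seed = 1L, out_dir = tempfile("aquastab_run_")) {
  if (is.null(counts_path) && is.null(simulation))
    stop_("config needs either counts_path/metadata_path or a simulation block")
  if (!is.null(counts_path) && is.null(metadata_path))
    stop_("metadata_path required alongside counts_path")
  if (!is.null(simulation) && !inherits(simulation, "study_design_config"))
    stop_("simulation must be a study_design_config")
  ncm <- utils::modifyList(
    list(d = 1, ci_level = 0.95, split_by = "group", detection = "count"), ncm)
  avd <- utils::modifyList(
    list(strata = c("group", "lifestyle"), ddof = 1,
         zero_variance = "exclude", replicate_unit = "replicate"), avd)
  multivariate <- utils::modifyList(
    list(n_perm = 999L,
         terms = c("group", "time", "lifestyle", "group:time",
                   "group:lifestyle", "time:lifestyle",
                   "group:time:lifestyle")), multivariate)
  structure(list(counts_path = counts_path, metadata_path = metadata_path,
                 taxonomy_path = taxonomy_path, simulation = simulation,
                 min_total = as.integer(min_total),
                 min_prevalence = min_prevalence,
                 rarefy_depth = rarefy_depth, ncm = ncm, avd = avd,
                 multivariate = multivariate,
                 do_multivariate = isTRUE(do_multivariate),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

# Serializable echo of the config for the report.
config_echo <- function(config) {
  out <- unclass(config)
  if (!is.null(out$simulation)) out$simulation <- unclass(out$simulation)
  out
}

#' Run the full analysis pipeline
#'
#' Simulate or ingest a ZOTU table, filter and rarefy it, fit the neutral
#' model per community group, compute AVD per stratum with group
#' comparisons, and (optionally) run the distance-based multivariate suite.
#' All stage outputs are written as TSV under `config$out_dir` together
#' with `report.json` summarizing every stage. Deterministic: identical
#' configs (including seed) produce byte-identical reports.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the bundle of fitted objects (`counts`, `samples`,
#'   `fits`, `avd`, `ordination`, `report`, ...).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(schema_version = 1L,
                 package_version = as.character(utils::packageVersion("aquastab")),
                 seed = config$seed,
                 stage_seeds = list(simulate = derive_seed(config$seed, 11L),
                                    rarefy = derive_seed(config$seed, 13L),
                                    multivariate = derive_seed(config$seed, 15L)),
                 config = config_echo(config))

  # --- ingest or simulate -------------------------------------------------
  taxonomy <- NULL
  truth <- NULL
  if (!is.null(config$simulation)) {
    sim_cfg <- config$simulation
    sim_cfg$seed <- report$stage_seeds$simulate
    study <- simulate_study(sim_cfg)
    counts <- study$counts
    samples <- study$samples
    taxonomy <- study$taxonomy
    truth <- study$truth
    write_count_table(counts, file.path(config$out_dir, "counts.tsv"))
    write_sample_frame(samples, file.path(config$out_dir, "metadata.tsv"))
    write_taxonomy_table(taxonomy, file.path(config$out_dir, "taxonomy.tsv"))
  } else {
    counts <- read_count_table(config$counts_path)
    samples <- read_sample_frame(config$metadata_path)
    if (!is.null(config$taxonomy_path))
      taxonomy <- read_taxonomy_table(config$taxonomy_path)
  }
  samples <- align_frame(counts, samples)

  # --- transform ----------------------------------------------------------
  counts <- filter_taxa(counts, config$min_total, config$min_prevalence)
  depth <- if (identical(config$rarefy_depth, "auto"))
    min(colSums(as_count_matrix(counts))) else as.integer(config$rarefy_depth)
  rarefied <- rarefy(counts, depth, seed = report$stage_seeds$rarefy)
  report$data <- list(n_zotus = nrow(counts), n_samples = ncol(counts),
                      rarefy_depth = depth)

  # --- neutral community model -------------------------------------------
  split_col <- config$ncm$split_by
  split_vals <- samples[[split_col]]
  fits <- list()
  report$ncm <- list()
  for (lev in unique(split_vals)) {
    sub <- count_table(as_count_matrix(counts)[, split_vals == lev, drop = FALSE])
    fit <- fit_ncm(sub, d = config$ncm$d, ci_level = config$ncm$ci_level,
                   detection = config$ncm$detection)
    fits[[lev]] <- fit
    pa <- partition_abundance(fit)
    write_tsv_df(fit$zotu, file.path(config$out_dir,
                                     sprintf("ncm_per_zotu_%s.tsv", lev)))
    entry <- list(Nm = fit$Nm, m = fit$m, N = fit$N,
                  r_squared = fit$r_squared,
                  n_zotus = nrow(fit$zotu), n_excluded = fit$n_excluded,
                  partition_counts = stats::setNames(as.list(pa$n_zotus), pa$partition),
                  partition_abundance = stats::setNames(as.list(pa$cum_abundance), pa$partition))
    if (!is.null(taxonomy)) {
      fam <- partition_by_family(fit, taxonomy)
      write_tsv_df(fam, file.path(config$out_dir,
                                  sprintf("ncm_family_%s.tsv", lev)))
    }
    report$ncm[[lev]] <- entry
  }

  # --- AVD ----------------------------------------------------------------
  avd_res <- avd_by_stratum(counts, samples, strata = config$avd$strata,
                            rarefy_depth = config$rarefy_depth,
                            replicate_unit = config$avd$replicate_unit,
                            seed = report$stage_seeds$rarefy,
                            ddof = config$avd$ddof,
                            zero_variance = config$avd$zero_variance)
  write_tsv_df(avd_res$strata, file.path(config$out_dir, "avd.tsv"))
  write_tsv_df(avd_res$replicates, file.path(config$out_dir, "avd_replicates.tsv"))
  report$avd <- list(strata = avd_res$strata)
  avd_letters <- list()
  if ("lifestyle" %in% config$avd$strata && "group" %in% config$avd$strata) {
    rep_df <- avd_res$replicates
    parts <- strsplit(rep_df$stratum, ".", fixed = TRUE)
    rep_df$group <- vapply(parts, `[[`, character(1), 1L)
    rep_df$lifestyle <- vapply(parts, `[[`, character(1), 2L)
    for (ls in unique(rep_df$lifestyle)) {
      sub <- rep_df[rep_df$lifestyle == ls, ]
      cmp <- tryCatch(compare_avd(sub$avd, sub$group), error = function(e) NULL)
      if (!is.null(cmp))
        avd_letters[[ls]] <- list(f = cmp$f, p = cmp$p,
                                  letters = as.list(cmp$letters))
    }
    cmp_ls <- tryCatch(compare_avd(rep_df$avd, rep_df$lifestyle),
                       error = function(e) NULL)
    if (!is.null(cmp_ls))
      avd_letters$lifestyle <- list(f = cmp_ls$f, p = cmp_ls$p,
                                    letters = as.list(cmp_ls$letters))
  }
  report$avd$comparisons <- avd_letters

  # --- alpha diversity ----------------------------------------------------
  alpha <- alpha_diversity(rarefied)
  write_tsv_df(alpha, file.path(config$out_dir, "alpha.tsv"))

  # --- distance-based multivariate suite ---------------------------------
  ord <- NULL
  if (config$do_multivariate) {
    mv_seed <- report$stage_seeds$multivariate
    n_perm <- config$multivariate$n_perm
    samples_mv <- tryCatch(nutrient_change(samples), error = function(e) samples)
    dm <- bray_curtis(counts)
    write_tsv_df(cbind(data.frame(sample_id = rownames(dm)),
                       as.data.frame(unclass(dm))),
                 file.path(config$out_dir, "bray_curtis.tsv"))
    ord <- pcoa(dm)
    coords <- as.data.frame(ord$coordinates[, seq_len(min(4L, ncol(ord$coordinates))), drop = FALSE])
    write_tsv_df(cbind(data.frame(sample_id = rownames(dm)), coords),
                 file.path(config$out_dir, "pcoa.tsv"))
    report$pcoa <- list(proportion = ord$proportion[seq_len(min(4L, length(ord$proportion)))],
                        negative_eigenvalues = ord$negative_eigenvalues)

    pt <- permanova(dm, samples_mv, terms = config$multivariate$terms,
                    n_perm = n_perm, seed = mv_seed,
                    factors = intersect(c("time", "replicate"),
                                        names(samples_mv)))
    write_tsv_df(as.data.frame(pt), file.path(config$out_dir, "permanova.tsv"))
    report$permanova <- as.data.frame(pt)

    an_group <- anosim(dm, samples_mv$group, n_perm = n_perm, seed = mv_seed)
    an_ls <- anosim(dm, samples_mv$lifestyle, n_perm = n_perm, seed = mv_seed)
    mr <- mrpp(dm, samples_mv$group, n_perm = n_perm, seed = mv_seed)
    report$anosim <- list(group = list(R = an_group$observed, p = an_group$p_value),
                          lifestyle = list(R = an_ls$observed, p = an_ls$p_value))
    report$mrpp <- list(group = list(delta = mr$observed, A = mr$A, p = mr$p_value))

    # Mantel per numeric covariate, overall and split by lifestyle
    base_cols <- c("sample_id", "group", "time", "replicate", "lifestyle")
    covars <- setdiff(names(samples_mv), base_cols)
    covars <- covars[vapply(samples_mv[covars], is.numeric, logical(1))]
    mantel_rows <- list()
    for (cv in covars) {
      v <- samples_mv[[cv]]
      if (anyNA(v) || stats::sd(v) == 0) next
      fd <- euclidean_dist(matrix(v, ncol = 1,
                                  dimnames = list(samples_mv$sample_id, cv)))
      mt <- mantel(dm, fd, n_perm = n_perm, seed = mv_seed)
      row <- data.frame(factor = cv, rho = mt$observed, p = mt$p_value,
                        stringsAsFactors = FALSE)
      for (ls in unique(samples_mv$lifestyle)) {
        idx <- samples_mv$lifestyle == ls
        ids <- samples_mv$sample_id[idx]
        mt_ls <- mantel(dist_matrix(unclass(dm)[ids, ids]),
                        dist_matrix(unclass(fd)[ids, ids]),
                        n_perm = n_perm, seed = mv_seed)
        row[[paste0("rho_", ls)]] <- mt_ls$observed
      }
      mantel_rows[[cv]] <- row
    }
    if (length(mantel_rows)) {
      mantel_df <- do.call(rbind, c(mantel_rows, list(make.row.names = FALSE)))
      write_tsv_df(mantel_df, file.path(config$out_dir, "mantel.tsv"))
      report$mantel <- mantel_df
    }

    if (length(covars) >= 1L) {
      keep <- covars[vapply(samples_mv[covars],
                            function(v) !anyNA(v) && stats::sd(v) > 0,
                            logical(1))]
      x <- as.matrix(samples_mv[keep])
      rownames(x) <- samples_mv$sample_id
      db <- tryCatch(dbrda(dm, x, n_perm = n_perm, seed = mv_seed),
                     error = function(e) NULL)
      if (!is.null(db))
        report$dbrda <- list(constrained_proportion = db$constrained_proportion,
                             F = db$test$observed, p = db$test$p_value)
      rd <- tryCatch(rda(hellinger(counts), x, n_perm = n_perm, seed = mv_seed),
                     error = function(e) NULL)
      if (!is.null(rd))
        report$rda <- list(constrained_proportion = rd$constrained_proportion,
                           F = rd$test$observed, p = rd$test$p_value)
    }

    tree <- hclust_average(dm)
    write_newick(tree, file.path(config$out_dir, "tree.nwk"))
  }

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(list(config = config, counts = counts, rarefied = rarefied,
                 samples = samples, taxonomy = taxonomy, truth = truth,
                 fits = fits, avd = avd_res, alpha = alpha,
                 ordination = ord, report = report))
}
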