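#!/usr/bin/env Rscript
# Stage 2: fit the neutral community model per treatment group and
# summarize the above/neutral/below partitions, overall and by family.

suppressPackageStartupMessages(library(aquastab))
dir.create("results/ncm", showWarnings = FALSE, recursive = TRUE)

counts <- filter_taxa(read_count_table("results/data/counts.tsv"), min_total = 2)
samples <- read_sample_frame("results/data/metadata.tsv")
taxonomy <- read_taxonomy_table("results/data/taxonomy.tsv")

summary_rows <- list()
for (g in c("C", "N", "T", "M")) {
  ids <- samples$sample_id[samples$group == g]
  fit <- fit_ncm(count_table(unclass(counts)[, ids]))
  print(fit)
  pa <- partition_abundance(fit)
  write_tsv <- aquastab:::write_tsv_df
  write_tsv(fit$zotu, sprintf("results/ncm/per_zotu_%s.tsv", g))
  write_tsv(partition_by_family(fit, taxonomy),
            sprintf("results/ncm/family_%s.tsv", g))
  summary_rows[[g]] <- data.frame(
    group = g, Nm = fit$Nm, m = fit$m, N = fit$N, r_squared = fit$r_squared,
    neutral_zotus = pa$n_zotus[pa$partition == "neutral"],
    neutral_abundance = pa$cum_abundance[pa$partition == "neutral"])
}
summary <- do.call(rbind, summary_rows)
aquastab:::write_tsv_df(summary, "results/ncm/summary.tsv")
cat("\nfitted Nm ordering:",
    paste(summary$group[order(-summary$Nm)], collapse = " > "), "\n")
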