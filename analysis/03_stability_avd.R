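#!/usr/bin/env Rscript
# Stage 3: community stability via the average variation degree, per
# group x lifestyle stratum, with Tukey letter displays across groups.

suppressPackageStartupMessages(library(aquastab))
dir.create("results/avd", showWarnings = FALSE, recursive = TRUE)

counts <- filter_taxa(read_count_table("results/data/counts.tsv"), min_total = 2)
samples <- read_sample_frame("results/data/metadata.tsv")

res <- avd_by_stratum(counts, samples, seed = 1)
aquastab:::write_tsv_df(res$strata, "results/avd/avd.tsv")
aquastab:::write_tsv_df(res$replicates, "results/avd/avd_replicates.tsv")
print(res$strata)

rep_df <- res$replicates
parts <- strsplit(rep_df$stratum, ".", fixed = TRUE)
rep_df$group <- vapply(parts, `[[`, character(1), 1L)
rep_df$lifestyle <- vapply(parts, `[[`, character(1), 2L)

for (ls in c("PA", "FL")) {
  sub <- rep_df[rep_df$lifestyle == ls, ]
  cmp <- compare_avd(sub$avd, sub$group)
  cat(sprintf("\n%s bacteria: ANOVA F = %.2f, p = %.3g; letters: %s\n",
              ls, cmp$f, cmp$p,
              paste(sprintf("%s=%s", names(cmp$letters), cmp$letters),
                    collapse = " ")))
}
cmp_ls <- compare_avd(rep_df$avd, rep_df$lifestyle)
cat(sprintf("\nPA vs FL: ANOVA F = %.2f, p = %.3g\n", cmp_ls$f, cmp_ls$p))
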