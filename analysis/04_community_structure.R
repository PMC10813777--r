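#!/usr/bin/env Rscript
# Stage 4: distance-based community structure -- alpha diversity,
# Bray-Curtis PCoA, PERMANOVA with interactions, ANOSIM, MRPP, per-factor
# Mantel tests, db-RDA/RDA against nutrient covariates, UPGMA clustering.

suppressPackageStartupMessages(library(aquastab))
dir.create("results/multivariate", showWarnings = FALSE, recursive = TRUE)
out <- function(f) file.path("results/multivariate", f)
tsv <- aquastab:::write_tsv_df

counts <- filter_taxa(read_count_table("results/data/counts.tsv"), min_total = 2)
samples <- nutrient_change(read_sample_frame("results/data/metadata.tsv"))
n_perm <- 999L

tsv(alpha_diversity(rarefy(counts, min(colSums(unclass(counts))), seed = 1)),
    out("alpha.tsv"))

dm <- bray_curtis(counts)
pc <- pcoa(dm)
cat(sprintf("PCoA: first two axes explain %.1f%% + %.1f%% of inertia\n",
            100 * pc$proportion[1], 100 * pc$proportion[2]))

pt <- permanova(dm, samples,
                c("group", "time", "lifestyle", "group:time",
                  "group:lifestyle", "time:lifestyle",
                  "group:time:lifestyle"),
                n_perm = n_perm, seed = 1, factors = "time")
tsv(as.data.frame(pt), out("permanova.tsv"))
print(as.data.frame(pt)[, c("term", "df", "R2", "F", "p")])

an <- anosim(dm, samples$group, n_perm = n_perm, seed = 1)
mr <- mrpp(dm, samples$group, n_perm = n_perm, seed = 1)
cat(sprintf("ANOSIM R = %.4f (p = %.3g); MRPP A = %.4f (p = %.3g)\n",
            an$observed, an$p_value, mr$A, mr$p_value))

covars <- c("NH4N", "NO2N", "NO3N", "PO4P", "n_oculata", "t_weissflogii",
            "NH4N_change", "NO2N_change", "NO3N_change", "PO4P_change")
rows <- lapply(covars, function(cv) {
  fd <- euclidean_dist(matrix(samples[[cv]], ncol = 1,
                              dimnames = list(samples$sample_id, cv)))
  mt <- mantel(dm, fd, n_perm = n_perm, seed = 1)
  data.frame(factor = cv, rho = mt$observed, p = mt$p_value)
})
mantel_df <- do.call(rbind, rows)
tsv(mantel_df, out("mantel.tsv"))
cat("strongest Mantel factor:",
    mantel_df$factor[which.max(mantel_df$rho)], "\n")

x <- as.matrix(samples[covars])
rownames(x) <- samples$sample_id
db <- dbrda(dm, x, n_perm = 199, seed = 1)
cat(sprintf("db-RDA: constraints explain %.1f%% (pseudo-F = %.2f, p = %.3g)\n",
            100 * db$constrained_proportion, db$test$observed, db$test$p_value))

write_newick(hclust_average(dm), out("tree.nwk"))
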