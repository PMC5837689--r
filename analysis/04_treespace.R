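#!/usr/bin/env Rscript

# Stage 4: Robinson-Foulds tree space.
#
# Pairwise RF distances among all analysis trees, within/between marker
# summary statistics, a classical MDS embedding and hexagonal bin counts.
# The question: do nuclear and mitochondrial analyses occupy distinct
# regions of tree space?

suppressPackageStartupMessages(library(cytonuclear))

trees_dir <- "results/trees"
out <- "results/treespace"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

info <- utils::read.delim(file.path(trees_dir, "analysis_trees.tsv"))
trees <- ape::read.tree(file.path(trees_dir, "analysis_trees.nwk"))
ts <- tree_set(trees, group = info$group, ids = info$id, canonical = FALSE)

dm <- pairwise_rf_matrix(ts)
write_distance_tsv(dm, file.path(out, "rf_matrix.tsv"))

gs <- group_summary(dm, cutoff = 0)
jsonlite::write_json(gs, file.path(out, "group_summary.json"),
                     auto_unbox = TRUE, digits = NA, force = TRUE)
cat(sprintf("within-nuclear mean RF %.2f over %d pairs\n",
            gs$within_means[["nuclear"]], gs$pair_counts$within_nuclear))
cat(sprintf("within-mitochondrial mean RF %.2f over %d pairs\n",
            gs$within_means[["mitochondrial"]],
            gs$pair_counts$within_mitochondrial))
cat(sprintf("between-marker mean RF %.2f over %d pairs (minimum %d)\n",
            gs$between_mean, gs$pair_counts$between, gs$min_between))
if (gs$min_between > 0 &&
    gs$between_mean > max(unlist(gs$within_means), na.rm = TRUE)) {
  cat("-> marker classes occupy distinct regions of tree space\n")
}

emb <- embed_cmds(dm, dims = 2)
write_embedding_tsv(emb, file.path(out, "embedding.tsv"))
cat(sprintf("2-D classical MDS: stress %.3f, truncated negative eigenvalue mass %.1f\n",
            emb$stress, emb$negative_eigenvalue_mass))
hex <- hexbin_counts(emb, gridsize = 20)
utils::write.table(hex, file.path(out, "hexbin.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("hexagonal binning: %d occupied cells for %d trees\n",
            nrow(hex), length(ts)))
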