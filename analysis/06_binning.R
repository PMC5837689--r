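#!/usr/bin/env Rscript

# Stage 6: statistical binning.
#
# Estimates bootstrap-supported gene trees for a subset of loci, collapses
# bifurcations at <= 50% support, builds the pairwise incompatibility
# graph, packs loci into balanced compatible bins, concatenates each bin
# into a supergene, re-estimates supergene trees, and reports the weighted
# (bin-size-replicated) and unweighted supergene tree multisets.

suppressPackageStartupMessages(library(cytonuclear))

sim <- "results/sim"
out <- "results/binning"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

loci <- lapply(list.files(file.path(sim, "loci"), full.names = TRUE),
               read_locus_fasta)
loci <- Filter(function(l) l$taxon_count >= 4, loci)[1:60]
names(loci) <- vapply(loci, `[[`, "", "locus_id")

supported <- lapply(loci, function(l)
  bootstrap_gene_tree(l, reps = 50, seed = derive_seed(7, l$locus_id)))
collapsed <- lapply(supported, collapse_low_support, threshold = 50)
mean_splits <- mean(vapply(collapsed, function(t)
  length(cytonuclear:::.splits_keys(t)), 0))
cat(sprintf("collapsed %d gene trees at the 50%% support rule (mean %.1f retained splits)\n",
            length(collapsed), mean_splits))

graph <- build_graph(collapsed)
cat(sprintf("incompatibility graph: %d of %d pairs conflict\n",
            nrow(graph$edges), choose(length(collapsed), 2)))

ba <- balanced_bins(graph, target_size = 7)
write_bin_manifest(ba, file.path(out, "bin_manifest.tsv"))
szs <- table(ba$weights)
cat(sprintf("%d loci packed into %d bins (%s)\n", sum(ba$weights),
            length(ba$bins),
            paste(sprintf("%s of %s", szs, names(szs)), collapse = ", ")))

supergenes <- build_supergenes(ba, loci)
sg_trees <- lapply(names(supergenes), function(b)
  estimate_alignment_tree(supermatrix_to_locus(supergenes[[b]], b)))
names(sg_trees) <- names(supergenes)
ok <- !vapply(sg_trees, is.null, TRUE)
if (!all(ok)) cat(sprintf("dropped %d supergenes with < 4 usable taxa\n", sum(!ok)))
ba_ok <- ba; ba_ok$bins <- ba$bins[ok]; ba_ok$weights <- ba$weights[ok]
weighted <- weight_supergene_trees(sg_trees[ok], ba_ok, weighted = TRUE)
unweighted <- weight_supergene_trees(sg_trees[ok], ba_ok, weighted = FALSE)
write_newick(weighted, file.path(out, "supergene_trees_weighted.nwk"))
write_newick(unweighted, file.path(out, "supergene_trees_unweighted.nwk"))
cat(sprintf("supergene tree multisets: %d weighted (= loci in kept bins), %d unweighted (= kept bins)\n",
            length(weighted), length(unweighted)))

# does binning sharpen the quartet signal?
truth <- jsonlite::read_json(file.path(sim, "truth.json"))
sp_true <- parse_newick(truth$species_newick)
genes_raw <- lapply(supported, canonicalize)
qs_raw <- normalized_quartet_score(sp_true, genes_raw)
qs_bin <- normalized_quartet_score(sp_true, weighted)
cat(sprintf("normalized quartet score vs true species tree: %.3f per-locus, %.3f binned-weighted\n",
            qs_raw$normalized, qs_bin$normalized))
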