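#!/usr/bin/env Rscript

# Stage 3: estimate one analysis tree per matrix regime instance plus a set
# of mitochondrial analysis trees, then census the topologies and build
# majority-rule consensus trees for each marker class.
#
# Nuclear analyses: JC + neighbor joining on each concatenated matrix
# (completeness thresholds, length bins, random subsamples). Mitochondrial
# analyses: the point estimate plus bootstrap re-estimates of the single
# mitochondrial alignment, standing in for the many mitogenome analyses of
# a real study.

suppressPackageStartupMessages(library(cytonuclear))

sim <- "results/sim"
out <- "results/trees"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

loci <- lapply(list.files(file.path(sim, "loci"), full.names = TRUE),
               read_locus_fasta)
truth <- jsonlite::read_json(file.path(sim, "truth.json"))
n_taxa <- truth$n_taxa
full_taxa <- sort(parse_newick(truth$species_newick)$tip.label)
ids <- vapply(loci, `[[`, "", "locus_id")

estimate <- function(sub, id) {
  sm <- concatenate_loci(sub)
  tr <- canonicalize(neighbor_joining(jc_distance(supermatrix_to_locus(sm, id))))
  if (setequal(tr$tip.label, full_taxa)) tr else NULL
}

trees <- list(); labels <- character()
add <- function(tr, id) {
  if (is.null(tr)) return(invisible())
  trees[[length(trees) + 1]] <<- tr
  labels <<- c(labels, id)
}
for (f in c(1, .75, .5, .25)) {
  add(estimate(filter_by_completeness(loci, f, n_taxa),
               sprintf("complete_%02d", 100 * f)),
      sprintf("complete_%02d", 100 * f))
}
bins <- bin_by_length(loci, 5)
for (b in seq_along(bins)) add(estimate(bins[[b]], sprintf("lengthbin_%02d", b)),
                               sprintf("lengthbin_%02d", b))
for (r in names(subs <- random_subsets(loci, k = 30, reps = 30, seed = 77))) {
  add(estimate(loci[match(subs[[r]], ids)], r), paste0("subsample_", r))
}
cat(sprintf("estimated %d nuclear analysis trees\n", length(trees)))

mito <- read_locus_fasta(file.path(sim, "mito.fasta"), "mito")
m <- do.call(rbind, strsplit(mito$seqs, ""))
set.seed(101)
mito_trees <- lapply(seq_len(20), function(r) {
  al <- if (r == 1) mito else
    locus_alignment("mito", apply(m[, sample.int(ncol(m), ncol(m), TRUE)], 1,
                                  paste, collapse = ""))
  canonicalize(neighbor_joining(jc_distance(al)))
})
cat(sprintf("estimated %d mitochondrial analysis trees\n", length(mito_trees)))

ts <- tree_set(c(trees, mito_trees),
               group = rep(c("nuclear", "mitochondrial"),
                           c(length(trees), length(mito_trees))),
               ids = c(labels, sprintf("mito_%03d", seq_along(mito_trees))),
               canonical = FALSE)
write_newick(ts$trees, file.path(out, "analysis_trees.nwk"))
utils::write.table(ts$info, file.path(out, "analysis_trees.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

nuc_ts <- tree_set(trees, group = "nuclear", ids = labels, canonical = FALSE)
mito_ts <- tree_set(mito_trees, group = "mitochondrial",
                    ids = sprintf("mito_%03d", seq_along(mito_trees)),
                    canonical = FALSE)
for (nm in c("nuclear", "mitochondrial")) {
  s <- if (nm == "nuclear") nuc_ts else mito_ts
  cen <- topology_census(s)
  write_census_tsv(cen, file.path(out, sprintf("census_%s.tsv", nm)))
  cons <- majority_consensus(s)
  write_consensus(cons, file.path(out, sprintf("consensus_%s.nwk", nm)),
                  file.path(out, sprintf("consensus_%s_splits.tsv", nm)))
  cat(sprintf("%s: %d analyses, %d unique topologies (modal %d), consensus keeps %d splits\n",
              nm, length(s), nrow(cen$classes), max(cen$classes$count),
              nrow(cons$frequencies)))
}

sp_true <- parse_newick(truth$species_newick)
cons_nuc <- majority_consensus(nuc_ts)
cat(sprintf("nuclear consensus vs true species tree: RF = %d\n",
            rf_distance(cons_nuc$tree, sp_true)))
cat(sprintf("mitochondrial point tree vs species tree: RF = %d (introgression signature)\n",
            rf_distance(mito_trees[[1]], sp_true)))
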