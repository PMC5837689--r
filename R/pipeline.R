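# End-to-end orchestration of the concordance analysis: simulate (or
# ingest) -> matrix regimes -> analysis trees -> census/consensus -> RF tree
# space -> quartet score -> statistical binning, with stage-level logging
# and a machine-readable report whose every number is recomputable from the
# logged configuration and seed.

#' Configuration for a concordance analysis run
#'
#' @param sim a \code{sim_config} describing the synthetic data (ignored in
#'   ingest mode).
#' @param mito_events list of \code{introgression_event} for the
#'   mitochondrial locus, or NULL.
#' @param completeness_fracs completeness regimes to run.
#' @param n_length_bins length-bin regimes (0 disables).
#' @param subsample_k,subsample_reps random-subsample regime (0 reps
#'   disables).
#' @param mito_analyses number of mitochondrial analysis trees (bootstrap
#'   re-estimates of the mitochondrial alignment).
#' @param bootstrap_reps bootstrap replicates for per-locus gene trees.
#' @param binning_threshold support threshold for statistical binning.
#' @param bin_target_size desired loci per bin for automatic binning.
#' @param treespace_cutoff RF cutoff for exceedance counts.
#' @param n_binned_loci number of loci carried into the binning stage (they
#'   need bootstrap supports, the slow step).
#' @param seed master seed.
#' @return list of class \code{concordance_config}.
#' @export
concordance_config <- function(sim = sim_config(n_taxa = 12, n_loci = 150,
                                                rate_scale = 0.02, seed = 1),
                               mito_events = NULL,
                               completeness_fracs = c(1, 0.75, 0.5, 0.25),
                               n_length_bins = 5,
                               subsample_k = 30, subsample_reps = 20,
                               mito_analyses = 28,
                               bootstrap_reps = 50,
                               binning_threshold = 50,
                               bin_target_size = 7,
                               treespace_cutoff = 0,
                               n_binned_loci = 40,
                               seed = 1) {
  cfg <- as.list(environment())
  .assert(all(completeness_fracs > 0 & completeness_fracs <= 1),
          "completeness fractions must be in (0, 1]")
  .assert(length(completeness_fracs) + n_length_bins + subsample_reps >= 1,
          "at least one matrix regime must be enabled")
  structure(cfg, class = "concordance_config")
}

#' Estimate a topology from a (possibly gappy) alignment
#'
#' JC distances + neighbor joining. Taxa with no shared non-missing sites
#' against some partner are pruned greedily (most-missing first) until the
#' distance matrix is complete.
#'
#' @param al a \code{locus_alignment} (often a concatenated supermatrix via
#'   \code{supermatrix_to_locus}).
#' @return an unrooted, metadata-free phylo, or NULL if fewer than 4 taxa
#'   have usable data.
#' @export
estimate_alignment_tree <- function(al) {
  repeat {
    if (al$taxon_count < 4) return(NULL)
    d <- tryCatch(jc_distance(al), error = function(e) NULL)
    if (!is.null(d)) return(canonicalize(neighbor_joining(d)))
    m <- .seq_matrix(al)
    n_missing <- rowSums(matrix(m %in% .MISSING_CHARS, nrow(m)))
    worst <- names(al$seqs)[which.max(n_missing)]
    al <- locus_alignment(al$locus_id, al$seqs[setdiff(names(al$seqs), worst)])
  }
}

# one analysis tree from a set of loci: concatenate and estimate (JC + NJ)
.estimate_matrix_tree <- function(loci, id) {
  sm <- concatenate_loci(loci)
  al <- supermatrix_to_locus(sm, id)
  tr <- estimate_alignment_tree(al)
  .assert(!is.null(tr), "matrix %s: fewer than 4 taxa with usable data", id)
  tr
}

#' Run the full concordance analysis
#'
#' Executes the enabled stages in order on a synthetic data set; returns a
#' report. Rerunning with an identical configuration reproduces every
#' number. If \code{out_dir} is given, intermediate artifacts (trees,
#' distance matrix, embedding, census, consensus, bin manifest, report
#' JSON) are written there.
#'
#' @param cfg a \code{concordance_config}.
#' @param out_dir optional output directory.
#' @param verbose print stage-level progress with counts.
#' @return list of class \code{concordance_report}; see Details.
#' @details The report contains: \code{counts} (per-stage accounting),
#'   \code{census} (unique topologies, modal count), \code{consensus}
#'   (nuclear and mitochondrial), \code{group_summary} (within/between
#'   RF means, min between, exceedance counts), \code{embedding} stress,
#'   \code{quartets} (normalized quartet score of the summary species tree),
#'   \code{binning} (bins, sizes, weighted multiset size), \code{truth}
#'   (generating topologies, for recovery checks), \code{config}.
#' @export
run_concordance <- function(cfg = concordance_config(), out_dir = NULL,
                            verbose = TRUE) {
  .assert(inherits(cfg, "concordance_config"), "cfg must be a concordance_config")
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  say("[simulate] %d taxa, %d nuclear loci", cfg$sim$n_taxa, cfg$sim$n_loci)
  dat <- simulate_dataset(cfg$sim, events = cfg$mito_events)
  loci <- dat$loci
  n_taxa <- cfg$sim$n_taxa

  # --- matrix regimes -> nuclear analysis trees -------------------------
  trees <- list(); ids <- character(0)
  add <- function(tr, id) {
    trees[[length(trees) + 1L]] <<- tr
    ids <<- c(ids, id)
  }
  full_taxa <- sort(dat$species_tree$tip.label)
  for (frac in cfg$completeness_fracs) {
    sub <- filter_by_completeness(loci, frac, n_taxa)
    if (length(sub) == 0) next
    id <- sprintf("complete_%02d", round(100 * frac))
    tr <- .estimate_matrix_tree(sub, id)
    if (setequal(tr$tip.label, full_taxa)) add(tr, id)
  }
  say("[matrices] completeness regimes: %d trees", length(trees))
  if (cfg$n_length_bins > 0 && length(loci) >= cfg$n_length_bins) {
    bins <- bin_by_length(loci, cfg$n_length_bins)
    for (b in seq_along(bins)) {
      id <- sprintf("lengthbin_%02d", b)
      tr <- .estimate_matrix_tree(bins[[b]], id)
      if (setequal(tr$tip.label, full_taxa)) add(tr, id)
    }
  }
  if (cfg$subsample_reps > 0) {
    subs <- random_subsets(loci, k = min(cfg$subsample_k, length(loci)),
                           reps = cfg$subsample_reps,
                           seed = derive_seed(cfg$seed, "subsamples"))
    locus_ids <- vapply(loci, `[[`, "", "locus_id")
    for (r in names(subs)) {
      tr <- .estimate_matrix_tree(loci[match(subs[[r]], locus_ids)],
                                  paste0("subsample_", r))
      if (setequal(tr$tip.label, full_taxa)) add(tr, paste0("subsample_", r))
    }
  }
  n_nuclear <- length(trees)
  say("[matrices] %d nuclear analysis trees", n_nuclear)
  .assert(n_nuclear >= 1, "no nuclear analysis tree spans the full taxon set")

  # --- mitochondrial analysis trees ------------------------------------
  n_mito <- cfg$mito_analyses
  mito_trees <- list()
  m <- .seq_matrix(dat$mito_locus)
  set.seed(derive_seed(cfg$seed, "mito_analyses"))
  for (r in seq_len(n_mito)) {
    al <- if (r == 1) dat$mito_locus else {
      idx <- sample.int(ncol(m), ncol(m), replace = TRUE)
      locus_alignment("mito", apply(m[, idx, drop = FALSE], 1, paste, collapse = ""))
    }
    mito_trees[[r]] <- canonicalize(neighbor_joining(jc_distance(al)))
  }
  say("[mito] %d mitochondrial analysis trees", n_mito)

  ts <- tree_set(c(trees, mito_trees),
                 group = c(rep("nuclear", n_nuclear), rep("mitochondrial", n_mito)),
                 ids = c(ids, sprintf("mito_%03d", seq_len(n_mito))),
                 canonical = FALSE)

  # --- census & consensus ----------------------------------------------
  nuc_ts <- tree_set(trees, group = "nuclear", ids = ids, canonical = FALSE)
  mito_ts <- tree_set(mito_trees, group = "mitochondrial",
                      ids = sprintf("mito_%03d", seq_len(n_mito)), canonical = FALSE)
  census_nuc <- topology_census(nuc_ts)
  census_mito <- topology_census(mito_ts)
  cons_nuc <- majority_consensus(nuc_ts)
  cons_mito <- majority_consensus(mito_ts)
  say("[census] %d unique nuclear topologies (modal %d), %d mitochondrial",
      nrow(census_nuc$classes), max(census_nuc$classes$count),
      nrow(census_mito$classes))

  # --- tree space -------------------------------------------------------
  dm <- pairwise_rf_matrix(ts)
  gs <- group_summary(dm, cutoff = cfg$treespace_cutoff)
  emb <- embed_cmds(dm, dims = 2)
  hex <- hexbin_counts(emb, gridsize = 20)
  say("[treespace] within nuclear %.2f, within mito %.2f, between %.2f (min %s)",
      gs$within_means[["nuclear"]], gs$within_means[["mitochondrial"]],
      gs$between_mean, format(gs$min_between))

  # --- quartet score of the summary species tree ------------------------
  species_hat <- astrid_like(dat$gene_trees)
  qs <- normalized_quartet_score(species_hat, dat$gene_trees)
  say("[quartets] normalized quartet score %.4f", qs$normalized)

  # --- statistical binning ----------------------------------------------
  n_bin_loci <- min(cfg$n_binned_loci, length(loci))
  bin_loci <- loci[seq_len(n_bin_loci)]
  supported <- lapply(seq_along(bin_loci), function(i) {
    l <- bin_loci[[i]]
    if (l$taxon_count < 4) return(NULL)
    bootstrap_gene_tree(l, reps = cfg$bootstrap_reps,
                        seed = derive_seed(cfg$seed, paste0("bs_", l$locus_id)))
  })
  keep <- !vapply(supported, is.null, TRUE)
  supported <- supported[keep]; bin_loci <- bin_loci[keep]
  collapsed <- lapply(supported, collapse_low_support, threshold = cfg$binning_threshold)
  names(collapsed) <- vapply(bin_loci, `[[`, "", "locus_id")
  graph <- build_graph(collapsed)
  ba <- balanced_bins(graph, target_size = cfg$bin_target_size)
  names(bin_loci) <- names(collapsed)
  supergenes <- build_supergenes(ba, bin_loci)
  sg_trees <- lapply(names(supergenes), function(b)
    estimate_alignment_tree(supermatrix_to_locus(supergenes[[b]], b)))
  names(sg_trees) <- names(supergenes)
  ok_sg <- !vapply(sg_trees, is.null, TRUE)
  if (!all(ok_sg)) {
    # bins whose supergene lacks 4 taxa of usable data drop out of the
    # multiset; their loci stay counted in the bin assignment
    sg_trees <- sg_trees[ok_sg]
    ba_trees <- ba; ba_trees$bins <- ba$bins[ok_sg]
    ba_trees$weights <- ba$weights[ok_sg]
  } else ba_trees <- ba
  weighted <- weight_supergene_trees(sg_trees, ba_trees, weighted = TRUE)
  say("[binning] %d loci -> %d bins (graph edges %d), weighted multiset %d",
      sum(ba$weights), length(ba$bins), nrow(graph$edges), length(weighted))

  report <- structure(list(
    counts = list(n_taxa = n_taxa, n_loci_simulated = cfg$sim$n_loci,
                  n_loci_after_masking = length(loci),
                  n_nuclear_analyses = n_nuclear, n_mito_analyses = n_mito,
                  n_binned_loci = sum(ba$weights), n_bins = length(ba$bins)),
    census = list(
      nuclear = list(unique_topologies = nrow(census_nuc$classes),
                     modal_count = max(census_nuc$classes$count)),
      mitochondrial = list(unique_topologies = nrow(census_mito$classes),
                           modal_count = max(census_mito$classes$count))),
    consensus = list(nuclear = write_newick(cons_nuc$tree),
                     mitochondrial = write_newick(cons_mito$tree)),
    group_summary = gs,
    embedding = list(stress = emb$stress,
                     negative_eigenvalue_mass = emb$negative_eigenvalue_mass),
    quartets = list(normalized = qs$normalized, agreeing = qs$agreeing,
                    total_resolved = qs$total_resolved),
    binning = list(n_bins = length(ba$bins), sizes = as.vector(ba$weights),
                   graph_edges = nrow(graph$edges),
                   weighted_multiset = length(weighted),
                   relaxed = ba$relaxed),
    species_tree_estimate = write_newick(species_hat),
    truth = dat$truth,
    config = unclass(cfg)), class = "concordance_report")

  if (!is.null(out_dir)) {
    write_newick(ts$trees, file.path(out_dir, "analysis_trees.nwk"))
    utils::write.table(ts$info, file.path(out_dir, "analysis_trees.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_distance_tsv(dm, file.path(out_dir, "rf_matrix.tsv"))
    write_embedding_tsv(emb, file.path(out_dir, "embedding.tsv"))
    utils::write.table(hex, file.path(out_dir, "hexbin.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_census_tsv(census_nuc, file.path(out_dir, "census_nuclear.tsv"))
    write_census_tsv(census_mito, file.path(out_dir, "census_mitochondrial.tsv"))
    write_consensus(cons_nuc, file.path(out_dir, "consensus_nuclear.nwk"),
                    file.path(out_dir, "consensus_nuclear_splits.tsv"))
    write_consensus(cons_mito, file.path(out_dir, "consensus_mitochondrial.nwk"),
                    file.path(out_dir, "consensus_mitochondrial_splits.tsv"))
    write_bin_manifest(ba, file.path(out_dir, "bin_manifest.tsv"))
    write_report_json(report, file.path(out_dir, "report.json"))
  }
  report
}

#' Serialize a concordance report as JSON
#' @param report a \code{concordance_report}.
#' @param file output path.
#' @export
write_report_json <- function(report, file) {
  x <- unclass(report)
  x$config$sim <- unclass(x$config$sim)
  x$config$mito_events <- lapply(x$config$mito_events %||% list(), unclass)
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(file)
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("concordance report\n")
  cat(sprintf("  analyses: %d nuclear, %d mitochondrial (%d taxa, %d loci)\n",
              x$counts$n_nuclear_analyses, x$counts$n_mito_analyses,
              x$counts$n_taxa, x$counts$n_loci_after_masking))
  cat(sprintf("  census: %d unique nuclear topologies (modal %d), %d mitochondrial\n",
              x$census$nuclear$unique_topologies, x$census$nuclear$modal_count,
              x$census$mitochondrial$unique_topologies))
  cat(sprintf("  RF: within nuclear %.2f, within mito %.2f, between %.2f (min %s)\n",
              x$group_summary$within_means[["nuclear"]],
              x$group_summary$within_means[["mitochondrial"]],
              x$group_summary$between_mean, format(x$group_summary$min_between)))
  cat(sprintf("  quartet score %.4f; binning: %d loci -> %d bins\n",
              x$quartets$normalized, x$counts$n_binned_loci, x$counts$n_bins))
  invisible(x)
}
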