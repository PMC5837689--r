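# Synthetic data with the statistical structure the concordance analysis
# assumes: a species tree, multispecies-coalescent (MSC) gene trees whose
# discordance comes from incomplete lineage sorting, a mitochondrial-like
# locus with reduced effective size and optional introgression, sequences
# whose informativeness matches UCE-scale data, and per-locus taxon
# missingness. Gene trees are simulated directly under the MSC (no
# recombination within loci, free recombination between loci).

#' Simulate a Yule species tree
#'
#' Pure-birth topology with exponential waiting times; branch lengths are
#' interpreted downstream as coalescent units.
#'
#' @param n number of tips (>= 3).
#' @param birth_rate speciation rate, default 1.
#' @param seed optional integer seed.
#' @return a rooted ultrametric phylo with tips \code{t01}, \code{t02}, ...
#' @export
simulate_yule_tree <- function(n, birth_rate = 1, seed = NULL) {
  .assert(n >= 3, "need n >= 3 tips")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n, birth = birth_rate, death = 0)
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr
}

#' Define an introgression event
#'
#' At \code{time} (coalescent units before present), each gene lineage in
#' the recipient branch moves to the donor branch with probability
#' \code{prob}; both branches must be extant at that time.
#'
#' @param donor,recipient tip labels or species-tree node numbers naming the
#'   branch above that node.
#' @param time event time in coalescent units before present.
#' @param prob fraction of lineages rerouted, in (0, 1].
#' @export
introgression_event <- function(donor, recipient, time = NA, prob = 1) {
  .assert(prob > 0 && prob <= 1, "prob must be in (0, 1]")
  .assert(is.na(time) || time >= 0, "time must be >= 0 (or NA for automatic)")
  structure(list(donor = donor, recipient = recipient, time = time, prob = prob),
            class = "introgression_event")
}

# node ages (time before present) of a rooted phylo; tips of an ultrametric
# tree get age 0
.node_ages <- function(phy) {
  depth <- ape::node.depth.edgelength(phy)
  max(depth) - depth
}

#' Simulate one gene tree under the multispecies coalescent
#'
#' Within each species-tree branch, k gene lineages coalesce at rate
#' C(k,2)/\code{ne_scale} per coalescent unit; survivors are passed
#' rootward, and the root population coalesces to completion. Optional
#' introgression events reroute lineages between contemporaneous branches.
#'
#' @param sp rooted species tree (phylo) with branch lengths in coalescent
#'   units.
#' @param seed optional integer seed.
#' @param ne_scale relative effective size (1 = nuclear; ~0.25 for a
#'   haploid, uniparental mitochondrial locus). Smaller values mean faster
#'   coalescence and less incomplete lineage sorting.
#' @param events optional list of \code{introgression_event}.
#' @return a rooted phylo gene tree with branch lengths in coalescent units.
#' @export
simulate_msc_gene_tree <- function(sp, seed = NULL, ne_scale = 1, events = NULL) {
  .assert(inherits(sp, "phylo") && !is.null(sp$edge.length),
          "sp must be a phylo with branch lengths (coalescent units)")
  .assert(ape::is.rooted(sp), "species tree must be rooted")
  .assert(ne_scale > 0, "ne_scale must be > 0")
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(sp$tip.label)
  root <- ntip + 1L
  ages <- .node_ages(sp)
  parent <- rep(NA_integer_, ntip + sp$Nnode)
  parent[sp$edge[, 2]] <- sp$edge[, 1]

  resolve_branch <- function(x) {
    # accept a tip label or node number; the branch is the edge above it
    if (is.character(x)) {
      i <- match(x, sp$tip.label)
      .assert(!is.na(i), "unknown taxon in introgression event: %s", x)
      i
    } else as.integer(x)
  }
  evts <- lapply(events %||% list(), function(e) {
    d <- resolve_branch(e$donor); r <- resolve_branch(e$recipient)
    .assert(d != root && r != root, "introgression cannot involve the root branch")
    lo <- max(ages[c(d, r)]); hi <- min(ages[parent[c(d, r)]])
    tm <- e$time
    if (is.na(tm)) {
      .assert(hi > lo, "donor and recipient branches never coexist")
      tm <- (lo + hi) / 2
    }
    for (b in c(d, r)) {
      .assert(tm >= ages[b] && tm <= ages[parent[b]],
              "branch above node %d not extant at time %g", b, tm)
    }
    list(donor = d, recipient = r, time = tm, prob = e$prob)
  })

  # lineages: pop = species branch (child-node id; root id = root pop),
  # age = height of the lineage's root, nwk = newick fragment
  lineages <- lapply(seq_len(ntip), function(i)
    list(pop = i, age = ages[i], nwk = sp$tip.label[i]))

  coalesce_in_pop <- function(lineages, pop, t_from, t_to) {
    repeat {
      idx <- which(vapply(lineages, function(l) l$pop == pop, TRUE))
      k <- length(idx)
      if (k < 2) return(lineages)
      wait <- stats::rexp(1, rate = choose(k, 2) / ne_scale)
      t_next <- t_from + wait
      if (t_next > t_to) return(lineages)
      pair <- sample(idx, 2)
      a <- lineages[[pair[1]]]; b <- lineages[[pair[2]]]
      merged <- list(pop = pop, age = t_next,
                     nwk = sprintf("(%s:%.10g,%s:%.10g)", a$nwk, t_next - a$age,
                                   b$nwk, t_next - b$age))
      lineages[[pair[1]]] <- merged
      lineages <- lineages[-pair[2]]
      t_from <- t_next
    }
  }

  # event timeline: species nodes (child pops merge into the node's branch)
  # and introgression events, in increasing age
  n_anc <- function(v) {           # ancestors above v; ties process tipward-first
    k <- 0L
    while (!is.na(parent[v])) { v <- parent[v]; k <- k + 1L }
    k
  }
  node_events <- lapply(setdiff(seq_len(ntip + sp$Nnode), seq_len(ntip)),
                        function(v) list(kind = "node", node = v, time = ages[v],
                                         depth = n_anc(v)))
  intro_events <- lapply(evts, function(e) c(kind = "intro", e, depth = Inf))
  timeline <- c(node_events, intro_events)
  timeline <- timeline[order(vapply(timeline, `[[`, 0, "time"),
                             -vapply(timeline, `[[`, 0, "depth"))]

  active <- as.list(seq_len(ntip))                 # active pops
  last_time <- stats::setNames(ages[seq_len(ntip)], seq_len(ntip))

  for (ev in timeline) {
    t_ev <- ev$time
    for (pop in unlist(active)) {
      lineages <- coalesce_in_pop(lineages, pop, last_time[[as.character(pop)]], t_ev)
      last_time[[as.character(pop)]] <- t_ev
    }
    if (ev$kind == "node") {
      kids <- sp$edge[sp$edge[, 1] == ev$node, 2]
      for (l in seq_along(lineages)) {
        if (lineages[[l]]$pop %in% kids) lineages[[l]]$pop <- ev$node
      }
      active <- setdiff(unlist(active), kids)
      active <- as.list(c(active, ev$node))
      last_time[[as.character(ev$node)]] <- t_ev
    } else {
      for (l in seq_along(lineages)) {
        if (lineages[[l]]$pop == ev$recipient && stats::runif(1) < ev$prob) {
          lineages[[l]]$pop <- ev$donor
        }
      }
    }
  }
  # root population: coalesce to completion
  idx <- which(vapply(lineages, function(l) l$pop == root, TRUE))
  stopifnot(length(idx) == length(lineages))
  t_cur <- ages[root]
  while (length(lineages) > 1) {
    k <- length(lineages)
    t_cur <- t_cur + stats::rexp(1, rate = choose(k, 2) / ne_scale)
    pair <- sample(seq_len(k), 2)
    a <- lineages[[pair[1]]]; b <- lineages[[pair[2]]]
    merged <- list(pop = root, age = t_cur,
                   nwk = sprintf("(%s:%.10g,%s:%.10g)", a$nwk, t_cur - a$age,
                                 b$nwk, t_cur - b$age))
    lineages[[pair[1]]] <- merged
    lineages <- lineages[-pair[2]]
  }
  parse_newick(paste0(lineages[[1]]$nwk, ";"))
}

#' Simulate a mitochondrial-like gene tree
#'
#' One non-recombining locus with reduced effective population size (default
#' a quarter of the nuclear size, the expectation for a haploid,
#' uniparentally inherited genome) and optional introgression events whose
#' rerouted history the gene tree tracks.
#'
#' @param sp rooted species tree in coalescent units.
#' @param events list of \code{introgression_event} (or NULL).
#' @param ne_scale relative effective size, default 0.25.
#' @param seed optional integer seed.
#' @return a rooted phylo gene tree.
#' @export
simulate_mito_tree <- function(sp, events = NULL, ne_scale = 0.25, seed = NULL) {
  simulate_msc_gene_tree(sp, seed = seed, ne_scale = ne_scale, events = events)
}

#' Simulate sequences along a tree under Jukes-Cantor (optionally +Gamma)
#'
#' Branch lengths times \code{rate_scale} give expected substitutions per
#' site; the root sequence is uniform. With a gamma shape, site rates follow
#' a discretized gamma with \code{ncat} categories.
#'
#' @param t phylo with branch lengths.
#' @param length alignment columns.
#' @param rate_scale substitutions per site per coalescent unit.
#' @param gamma_shape optional shape for among-site rate variation.
#' @param ncat discrete gamma categories, default 4.
#' @param locus_id id for the returned alignment.
#' @param seed optional integer seed.
#' @return a \code{locus_alignment}.
#' @export
simulate_sequences <- function(t, length, rate_scale = 1, gamma_shape = NULL,
                               ncat = 4, locus_id = "locus", seed = NULL) {
  .assert(!is.null(t$edge.length), "tree must have branch lengths")
  .assert(length >= 1, "length must be >= 1")
  .assert(rate_scale >= 0, "rate_scale must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  sim_block <- function(len, rate) {
    if (rate == 0 || all(t$edge.length * rate == 0)) {
      root <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      m <- matrix(rep(root, each = length(t$tip.label)), nrow = length(t$tip.label))
      rownames(m) <- t$tip.label
      return(m)
    }
    pd <- phangorn::simSeq(t, l = len, type = "DNA", rate = rate)
    m <- as.character(pd)
    m[] <- toupper(m)
    m
  }
  if (is.null(gamma_shape)) {
    m <- sim_block(length, rate_scale)
  } else {
    # discrete gamma: category rates at quantile midpoints, normalized
    qs <- stats::qgamma((seq_len(ncat) - 0.5) / ncat, shape = gamma_shape,
                        rate = gamma_shape)
    qs <- qs / mean(qs)
    cat_of <- sample.int(ncat, length, replace = TRUE)
    m <- NULL
    for (k in seq_len(ncat)) {
      nk <- sum(cat_of == k)
      if (nk == 0) next
      blk <- sim_block(nk, rate_scale * qs[k])
      m <- if (is.null(m)) blk else cbind(m, blk[rownames(m), , drop = FALSE])
    }
  }
  locus_alignment(locus_id, apply(m, 1, paste, collapse = ""))
}

#' Apply per-locus taxon missingness
#'
#' Each taxon is retained independently per locus with the given
#' probability; loci left with fewer than 3 taxa are dropped and reported.
#'
#' @param loci list of \code{locus_alignment}.
#' @param retention scalar or named per-taxon retention probability in
#'   \code{[0, 1]}.
#' @param seed optional integer seed.
#' @return masked locus list; attribute \code{dropped} names removed loci.
#' @export
apply_missingness <- function(loci, retention, seed = NULL) {
  .assert(all(retention >= 0 & retention <= 1), "retention must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  out <- list(); dropped <- character(0)
  for (l in loci) {
    taxa <- names(l$seqs)
    p <- if (length(retention) == 1) rep(retention, length(taxa)) else {
      .assert(all(taxa %in% names(retention)), "retention missing taxa")
      unname(retention[taxa])
    }
    keep <- stats::runif(length(taxa)) < p
    if (sum(keep) < 3) {
      dropped <- c(dropped, l$locus_id)
      next
    }
    out[[length(out) + 1L]] <- locus_alignment(l$locus_id, l$seqs[keep])
  }
  if (length(dropped)) {
    message(sprintf("apply_missingness: dropped %d loci with < 3 taxa", length(dropped)))
  }
  attr(out, "dropped") <- dropped
  out
}

#' Study-scale simulation configuration
#'
#' Defaults emulate a UCE study of a rapid radiation: 37 taxa, 3648 short
#' nuclear loci (~375 bp on average), sequence divergence tuned so a few
#' percent of sites are parsimony-informative, and a single
#' mitochondrial-like locus with reduced effective size.
#'
#' @param n_taxa taxa, default 37.
#' @param n_loci nuclear loci, default 3648.
#' @param locus_length_mean,locus_length_sd lognormal locus-length scale,
#'   defaults 375 / 0.3 (log-sd).
#' @param birth_rate Yule speciation rate (coalescent-unit time), default 1.
#' @param rate_scale substitutions/site per coalescent unit, default 0.0012
#'   (calibrated so a few percent of sites are parsimony-informative at the
#'   default taxon sampling, the UCE-scale signal level).
#' @param gamma_shape among-site rate variation shape (NULL = equal rates).
#' @param retention per-locus taxon retention probability, default 0.9.
#' @param mito_ne_scale relative mitochondrial effective size, default 0.25.
#' @param mito_length mitochondrial alignment length, default 15000.
#' @param seed master seed, default 1.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_taxa = 37, n_loci = 3648, locus_length_mean = 375,
                       locus_length_sd = 0.3, birth_rate = 1, rate_scale = 0.0012,
                       gamma_shape = NULL, retention = 0.9,
                       mito_ne_scale = 0.25, mito_length = 15000, seed = 1) {
  cfg <- as.list(environment())
  .assert(n_taxa >= 4 && n_loci >= 1, "counts must be positive (n_taxa >= 4)")
  structure(cfg, class = "sim_config")
}

#' Simulate a full synthetic data set under a configuration
#'
#' Draws the species tree, one MSC gene tree and sequence alignment per
#' nuclear locus, a mitochondrial-like tree and alignment (optionally
#' introgressed), and applies taxon missingness. All randomness derives from
#' the master seed through named substreams.
#'
#' @param cfg a \code{sim_config}.
#' @param events optional list of \code{introgression_event} for the
#'   mitochondrial locus.
#' @return list: \code{species_tree}, \code{gene_trees} (multiPhylo),
#'   \code{loci} (masked), \code{mito_tree}, \code{mito_locus},
#'   \code{config}, \code{truth} (manifest of seeds and true topologies).
#' @export
simulate_dataset <- function(cfg, events = NULL) {
  .assert(inherits(cfg, "sim_config"), "cfg must be a sim_config")
  sp <- simulate_yule_tree(cfg$n_taxa, cfg$birth_rate,
                           seed = derive_seed(cfg$seed, "species_tree"))
  set.seed(derive_seed(cfg$seed, "locus_lengths"))
  lens <- pmax(100L, as.integer(round(stats::rlnorm(
    cfg$n_loci, log(cfg$locus_length_mean), cfg$locus_length_sd))))
  gene_trees <- vector("list", cfg$n_loci)
  loci <- vector("list", cfg$n_loci)
  for (i in seq_len(cfg$n_loci)) {
    gene_trees[[i]] <- simulate_msc_gene_tree(
      sp, seed = derive_seed(cfg$seed, sprintf("gene_tree_%d", i)))
    loci[[i]] <- simulate_sequences(
      gene_trees[[i]], lens[i], rate_scale = cfg$rate_scale,
      gamma_shape = cfg$gamma_shape, locus_id = sprintf("uce_%04d", i),
      seed = derive_seed(cfg$seed, sprintf("seq_%d", i)))
  }
  class(gene_trees) <- "multiPhylo"
  loci <- apply_missingness(loci, cfg$retention,
                            seed = derive_seed(cfg$seed, "missingness"))
  mito_tree <- simulate_mito_tree(sp, events = events,
                                  ne_scale = cfg$mito_ne_scale,
                                  seed = derive_seed(cfg$seed, "mito_tree"))
  mito_locus <- simulate_sequences(mito_tree, cfg$mito_length,
                                   rate_scale = cfg$rate_scale * 5,
                                   locus_id = "mito",
                                   seed = derive_seed(cfg$seed, "mito_seq"))
  list(species_tree = sp, gene_trees = gene_trees, loci = loci,
       mito_tree = mito_tree, mito_locus = mito_locus, config = cfg,
       truth = list(seed = cfg$seed,
                    species_newick = canonical_newick(sp),
                    mito_newick = canonical_newick(mito_tree),
                    n_loci_after_masking = length(loci)))
}
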