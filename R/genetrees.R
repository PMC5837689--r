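# Desk-scale tree estimation: Jukes-Cantor distances, neighbor joining with
# bootstrap supports, and an average-internode-distance species-tree summary
# (the ASTRID/NJst family: mean topological leaf-to-leaf path lengths over
# gene trees, resolved with a distance method). The estimator is transparent
# and fully in-package; externally computed newick gene trees can be used
# interchangeably wherever gene trees are consumed.

#' Jukes-Cantor pairwise distances for a locus alignment
#'
#' d = -(3/4) log(1 - (4/3) p), with p the mismatch proportion over shared
#' non-missing sites. Pairs with p >= 3/4 (outside the JC domain) are capped
#' at \code{max_distance} and flagged.
#'
#' @param l a \code{locus_alignment} with >= 3 taxa.
#' @param max_distance cap for saturated pairs, default 5.
#' @return symmetric numeric matrix; attribute \code{capped} lists saturated
#'   pairs, if any.
#' @export
jc_distance <- function(l, max_distance = 5) {
  .assert(inherits(l, "locus_alignment"), "l must be a locus_alignment")
  n <- l$taxon_count
  .assert(n >= 3, "need >= 3 taxa for a distance matrix")
  m <- .seq_matrix(l)
  ok <- !(m %in% .MISSING_CHARS)
  dim(ok) <- dim(m)
  taxa <- rownames(m)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  capped <- character(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    both <- ok[i, ] & ok[j, ]
    nn <- sum(both)
    .assert(nn >= 1, "no overlapping non-missing sites for pair (%s, %s)",
            taxa[i], taxa[j])
    p <- sum(m[i, both] != m[j, both]) / nn
    if (p >= 0.75) {
      d[i, j] <- d[j, i] <- max_distance
      capped <- c(capped, paste(taxa[i], taxa[j], sep = ":"))
    } else {
      d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
    }
  }
  attr(d, "capped") <- capped
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (\code{ape::nj}) made deterministic by sorting
#' taxa lexicographically first, with negative branch lengths clamped to
#' zero (and flagged).
#'
#' @param dm symmetric numeric matrix with taxon dimnames, >= 3 taxa.
#' @return a phylo tree; attribute \code{clamped} gives the number of
#'   negative branch lengths set to zero.
#' @export
neighbor_joining <- function(dm) {
  .assert(is.matrix(dm) && nrow(dm) >= 3, "dm must be a matrix with >= 3 taxa")
  .assert(all(is.finite(dm)), "non-finite entries in distance matrix")
  ord <- order(rownames(dm))
  dm <- dm[ord, ord, drop = FALSE]
  tr <- if (nrow(dm) == 3) {
    # the unique unrooted 3-leaf topology, lengths from the three-point formula
    labs <- rownames(dm)
    a <- (dm[1, 2] + dm[1, 3] - dm[2, 3]) / 2
    b <- (dm[1, 2] + dm[2, 3] - dm[1, 3]) / 2
    c <- (dm[1, 3] + dm[2, 3] - dm[1, 2]) / 2
    parse_newick(sprintf("(%s:%g,%s:%g,%s:%g);", labs[1], a, labs[2], b, labs[3], c))
  } else {
    ape::nj(dm)
  }
  neg <- sum(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped") <- neg
  tr
}

#' Estimate a gene tree with nonparametric bootstrap supports
#'
#' Point estimate: JC distances + neighbor joining on the full alignment.
#' Supports: percentage of site-resampled replicates whose re-estimated tree
#' contains each internal split of the point estimate, stored as internal
#' node labels. Alignments with no variable sites yield a star tree with no
#' supports.
#'
#' @param l a \code{locus_alignment} with >= 4 taxa.
#' @param reps bootstrap replicates, default 100.
#' @param seed integer seed.
#' @param max_distance passed to \code{jc_distance}.
#' @return a phylo tree with node labels = integer percent supports and
#'   attribute \code{locus_id}.
#' @export
bootstrap_gene_tree <- function(l, reps = 100, seed = 1, max_distance = 5) {
  .assert(reps >= 1, "reps must be >= 1")
  .assert(l$taxon_count >= 4, "need >= 4 taxa for a supported gene tree")
  m <- .seq_matrix(l)
  nonmiss <- m
  nonmiss[nonmiss %in% .MISSING_CHARS] <- NA
  n_states <- apply(nonmiss, 2, function(col) length(unique(col[!is.na(col)])))
  if (all(n_states < 2)) {
    star <- ape::stree(l$taxon_count, type = "star", tip.label = sort(names(l$seqs)))
    star <- ape::unroot(star)
    attr(star, "locus_id") <- l$locus_id
    return(star)
  }
  point <- ape::unroot(neighbor_joining(jc_distance(l, max_distance)))
  keys <- .splits_keys(point)
  nodes <- attr(keys, "node")
  counts <- stats::setNames(rep(0L, length(keys)), as.character(keys))
  set.seed(seed)
  L <- ncol(m)
  for (r in seq_len(reps)) {
    idx <- sample.int(L, L, replace = TRUE)
    lb <- locus_alignment(l$locus_id, apply(m[, idx, drop = FALSE], 1, paste,
                                            collapse = ""))
    bt <- tryCatch(ape::unroot(neighbor_joining(jc_distance(lb, max_distance))),
                   error = function(e) NULL)
    if (is.null(bt)) next
    bk <- as.character(.splits_keys(bt))
    hit <- as.character(keys) %in% bk
    counts[hit] <- counts[hit] + 1L
  }
  support <- round(100 * counts / reps)
  nlab <- rep(NA_character_, point$Nnode)
  ntip <- length(point$tip.label)
  nlab[nodes - ntip] <- as.character(as.integer(support))
  point$node.label <- nlab
  attr(point, "locus_id") <- l$locus_id
  point
}

#' Mean internode (topological) distance matrix over gene trees
#'
#' For each gene tree, leaf-to-leaf path lengths in edge counts on the
#' unrooted topology; entries are averaged over the gene trees containing
#' both taxa.
#'
#' @param genes list/multiPhylo of phylo gene trees (or a \code{tree_set}).
#' @return list: \code{mean} (matrix, NA where no gene tree supports the
#'   pair), \code{counts} (supporting gene-tree tally), \code{taxa}.
#' @export
internode_distances <- function(genes) {
  trees <- if (inherits(genes, "tree_set")) as.list(genes$trees) else
    if (inherits(genes, "phylo")) list(genes) else as.list(genes)
  taxa <- sort(unique(unlist(lapply(trees, `[[`, "tip.label"))))
  n <- length(taxa)
  s <- matrix(0, n, n, dimnames = list(taxa, taxa))
  cnt <- matrix(0L, n, n, dimnames = list(taxa, taxa))
  for (gt in trees) {
    d <- .topo_dist(gt)
    idx <- match(rownames(d), taxa)
    s[idx, idx] <- s[idx, idx] + d
    cnt[idx, idx] <- cnt[idx, idx] + 1L
  }
  mn <- s / cnt
  mn[cnt == 0L] <- NA
  diag(mn) <- 0
  list(mean = mn, counts = cnt, taxa = taxa)
}

# connected components of the pair-support graph
.pair_components <- function(counts) {
  n <- nrow(counts)
  comp <- rep(0L, n); c_id <- 0L
  for (v in seq_len(n)) {
    if (comp[v] > 0L) next
    c_id <- c_id + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (comp[u] > 0L) next
      comp[u] <- c_id
      nb <- which(counts[u, ] > 0L & comp == 0L)
      queue <- c(queue, nb)
    }
  }
  split(rownames(counts), comp)
}

#' Average-internode-distance species tree (ASTRID-style summary)
#'
#' Builds the mean topological internode distance matrix over the gene trees
#' and resolves it with neighbor joining. Every taxon pair must co-occur in
#' at least one gene tree; a disconnected pair graph is an error listing the
#' unlinked taxon groups.
#'
#' @param genes gene trees (list, multiPhylo or \code{tree_set}).
#' @return an unrooted phylo species topology.
#' @export
astrid_like <- function(genes) {
  ind <- internode_distances(genes)
  comps <- .pair_components(ind$counts)
  .assert(length(comps) == 1,
          "pair graph disconnected; unlinked taxon groups: %s",
          paste(vapply(comps, function(g) paste(g, collapse = ","), ""),
                collapse = " | "))
  miss <- which(is.na(ind$mean) & upper.tri(ind$mean), arr.ind = TRUE)
  .assert(nrow(miss) == 0,
          "no gene tree links taxon pairs: %s",
          paste(apply(miss, 1, function(r) paste(ind$taxa[r], collapse = ":")),
                collapse = ", "))
  ape::unroot(neighbor_joining(ind$mean))
}
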