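# Quartet concordance: induced four-taxon topologies and the normalized
# quartet score of a candidate species tree against a gene-tree set. The
# quartet topology induced by a tree on {a,b,c,d} is read off the four-point
# condition applied to topological (unit-edge) leaf-to-leaf distances: the
# pairing with the strictly smallest distance sum is the induced split, and
# a three-way tie means the restriction is a star.

#' Enumerate all 4-taxon subsets of a taxon set
#'
#' @param taxa character vector of taxon labels (>= 4).
#' @return a C(n,4) x 4 character matrix, rows in lexicographic order.
#' @export
enumerate_quartets <- function(taxa) {
  taxa <- sort(unique(as.character(taxa)))
  .assert(length(taxa) >= 4, "need at least 4 taxa to enumerate quartets")
  t(utils::combn(taxa, 4))
}

# topological leaf-to-leaf distance matrix (every edge counted as 1)
.topo_dist <- function(phy) {
  phy <- if (ape::is.rooted(phy)) ape::unroot(phy) else phy
  phy$edge.length <- rep(1, nrow(phy$edge))
  d <- ape::cophenetic.phylo(phy)
  d[sort(rownames(d)), sort(colnames(d)), drop = FALSE]
}

# pairing codes for quartets given a topological distance matrix.
# quartet rows are indices into rownames(d). codes: 1 = 12|34, 2 = 13|24,
# 3 = 14|23, 0 = unresolved.
.quartet_codes <- function(d, q) {
  s1 <- d[cbind(q[, 1], q[, 2])] + d[cbind(q[, 3], q[, 4])]
  s2 <- d[cbind(q[, 1], q[, 3])] + d[cbind(q[, 2], q[, 4])]
  s3 <- d[cbind(q[, 1], q[, 4])] + d[cbind(q[, 2], q[, 3])]
  c1 <- s1 < s2 & s1 < s3
  c2 <- s2 < s1 & s2 < s3
  c3 <- s3 < s1 & s3 < s2
  as.integer(c1 + 2L * c2 + 3L * c3)
}

#' Induced quartet topology of a tree on four taxa
#'
#' @param phy a phylo tree.
#' @param q character vector of 4 taxon labels, all leaves of \code{phy}.
#' @return object of class \code{quartet_topology}: list with \code{taxa}
#'   (sorted) and \code{pairing} — a string like \code{"a,b|c,d"} with the
#'   pair containing the smallest taxon first, or \code{"unresolved"}.
#' @export
induced_quartet <- function(phy, q) {
  q <- sort(unique(as.character(q)))
  .assert(length(q) == 4, "q must name exactly 4 distinct taxa")
  missing <- setdiff(q, phy$tip.label)
  .assert(length(missing) == 0, "taxa not in tree: %s", paste(missing, collapse = ", "))
  d <- .topo_dist(restrict_tree(phy, q))
  idx <- matrix(match(q, rownames(d)), 1)
  code <- .quartet_codes(d, idx)
  pairing <- if (code == 0L) "unresolved" else {
    mate <- q[c(2, 3, 4)][code]
    rest <- setdiff(q, c(q[1], mate))
    paste0(q[1], ",", mate, "|", rest[1], ",", rest[2])
  }
  structure(list(taxa = q, pairing = pairing), class = "quartet_topology")
}

#' Normalized quartet score of a species tree against gene trees
#'
#' For every gene tree and every 4-taxon subset of the taxa it shares with
#' the species tree, the induced gene-tree quartet is compared with the
#' species-tree quartet. The score is the exact fraction of resolved induced
#' gene-tree quartets that agree with the species tree; unresolved induced
#' quartets (from polytomies) are excluded from both numerator and
#' denominator, so a score of 1 remains attainable for multifurcating gene
#' trees consistent with the species tree. Gene trees with missing taxa
#' contribute only their own C(k,4) quartets.
#'
#' @param species a binary phylo tree.
#' @param genes a \code{tree_set}, multiPhylo or list of phylo gene trees,
#'   each sharing >= 4 taxa with \code{species}.
#' @return object of class \code{quartet_score}: list with \code{agreeing},
#'   \code{total_resolved}, \code{normalized}, and \code{per_gene}
#'   (data.frame: gene, n_taxa, n_quartets, resolved, agreeing).
#' @export
normalized_quartet_score <- function(species, genes) {
  .assert(ape::is.binary(ape::unroot(species)), "species tree must be binary")
  trees <- if (inherits(genes, "tree_set")) as.list(genes$trees) else
    if (inherits(genes, "phylo")) list(genes) else as.list(genes)
  gids <- if (inherits(genes, "tree_set")) genes$info$id else
    sprintf("gene_%03d", seq_along(trees))
  dsp <- .topo_dist(species)
  sp_taxa <- rownames(dsp)
  agree_tot <- 0; res_tot <- 0
  per <- vector("list", length(trees))
  for (g in seq_along(trees)) {
    gt <- trees[[g]]
    shared <- sort(intersect(gt$tip.label, sp_taxa))
    .assert(length(shared) >= 4, "gene tree %s shares fewer than 4 taxa with species tree",
            gids[g])
    dg <- .topo_dist(if (setequal(gt$tip.label, shared)) gt else
      restrict_tree(gt, shared))
    qi <- t(utils::combn(length(shared), 4))
    gcode <- .quartet_codes(dg, qi)
    # map shared indices into the species distance matrix
    spi <- match(shared, sp_taxa)
    qs <- matrix(spi[qi], ncol = 4)
    scode <- .quartet_codes(dsp, qs)
    resolved <- gcode != 0L
    agreeing <- resolved & gcode == scode
    agree_tot <- agree_tot + sum(agreeing)
    res_tot <- res_tot + sum(resolved)
    per[[g]] <- data.frame(gene = gids[g], n_taxa = length(shared),
                           n_quartets = nrow(qi), resolved = sum(resolved),
                           agreeing = sum(agreeing), stringsAsFactors = FALSE)
  }
  .assert(res_tot > 0, "no resolved induced quartets: score undefined")
  structure(list(agreeing = agree_tot, total_resolved = res_tot,
                 normalized = agree_tot / res_tot,
                 per_gene = do.call(rbind, per)),
            class = "quartet_score")
}

#' @export
print.quartet_score <- function(x, ...) {
  cat(sprintf("normalized quartet score: %.4f (%d / %d resolved quartets, %d gene trees)\n",
              x$normalized, x$agreeing, x$total_resolved, nrow(x$per_gene)))
  invisible(x)
}
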