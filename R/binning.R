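# Statistical binning: collapse weakly supported bifurcations, build the
# pairwise incompatibility graph over the collapsed gene trees, color it
# into balanced independent bins ("supergenes"), concatenate each bin's
# alignments, and weight the resulting supergene trees by bin size.

#' Collapse weakly supported bifurcations of a gene tree
#'
#' Internal edges whose bootstrap support is not strictly greater than the
#' threshold are contracted (an edge at exactly the threshold is collapsed).
#'
#' @param g a phylo with internal node labels holding percent supports (as
#'   produced by \code{bootstrap_gene_tree}); missing supports are an error.
#' @param threshold percent support that must be exceeded, default 50.
#' @return a (possibly multifurcating) phylo; attribute \code{threshold}.
#' @export
collapse_low_support <- function(g, threshold = 50) {
  .assert(inherits(g, "phylo"), "g must be a phylo")
  locus <- attr(g, "locus_id")
  g <- if (ape::is.rooted(g)) ape::unroot(g) else g
  keys <- .splits_keys(g)
  nodes <- attr(keys, "node")
  if (length(keys)) {
    .assert(!is.null(g$node.label), "gene tree has no support values")
    sup <- suppressWarnings(as.numeric(g$node.label[nodes - length(g$tip.label)]))
    .assert(!anyNA(sup), "missing support on %d internal edge(s)", sum(is.na(sup)))
    keep <- sup > threshold
  } else {
    keep <- logical(0)
  }
  universe <- sort(g$tip.label)
  out <- if (any(keep)) {
    .tree_from_splits(lapply(as.character(keys[keep]), .key_side), universe)
  } else {
    parse_newick(paste0("(", paste(universe, collapse = ","), ");"))
  }
  attr(out, "threshold") <- threshold
  attr(out, "locus_id") <- locus
  out
}

#' Are two collapsed gene trees incompatible?
#'
#' Both trees are restricted to their shared taxa; they are incompatible iff
#' any retained split of one conflicts with any retained split of the other.
#' Trees sharing fewer than 4 taxa are deemed compatible.
#'
#' @param a,b phylo trees (typically from \code{collapse_low_support}).
#' @return TRUE if incompatible.
#' @export
pair_incompatible <- function(a, b) {
  shared <- intersect(a$tip.label, b$tip.label)
  if (length(shared) < 4) return(FALSE)
  ka <- .restricted_keys(a, shared)
  kb <- .restricted_keys(b, shared)
  if (!length(ka) || !length(kb)) return(FALSE)
  for (x in ka) for (y in kb) {
    if (!.keys_compatible(x, y)) return(TRUE)
  }
  FALSE
}

# split keys of a tree restricted to `shared` taxa (canonical on shared)
.restricted_keys <- function(t, shared) {
  if (setequal(t$tip.label, shared)) {
    as.character(.splits_keys(t, sort(shared)))
  } else {
    if (length(shared) < 4) return(character(0))
    tr <- tryCatch(restrict_tree(t, shared), error = function(e) NULL)
    if (is.null(tr)) return(character(0))
    as.character(.splits_keys(tr, sort(shared)))
  }
}

#' Build the pairwise incompatibility graph over collapsed gene trees
#'
#' @param trees named list of phylo trees (names = locus/gene ids; unnamed
#'   lists use the trees' \code{locus_id} attributes or positional ids).
#' @return object of class \code{incompat_graph}: list with \code{nodes}
#'   (ids) and \code{edges} (2-column character matrix of incompatible
#'   pairs, lexicographic order).
#' @export
build_graph <- function(trees) {
  .assert(length(trees) >= 2, "need >= 2 trees to build a graph")
  ids <- names(trees) %||% vapply(seq_along(trees), function(i)
    attr(trees[[i]], "locus_id") %||% sprintf("locus_%04d", i), "")
  if (is.null(names(trees))) names(trees) <- ids
  .assert(!anyDuplicated(ids), "duplicate tree ids")
  ord <- order(ids)
  ids <- ids[ord]; trees <- trees[ord]
  edges <- list()
  for (i in seq_along(ids)[-length(ids)]) for (j in (i + 1):length(ids)) {
    if (pair_incompatible(trees[[i]], trees[[j]])) {
      edges[[length(edges) + 1L]] <- c(ids[i], ids[j])
    }
  }
  structure(list(nodes = ids,
                 edges = if (length(edges)) do.call(rbind, edges) else
                   matrix(character(0), 0, 2)),
            class = "incompat_graph")
}

#' @export
print.incompat_graph <- function(x, ...) {
  cat(sprintf("incompatibility graph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Balanced independent-set binning of an incompatibility graph
#'
#' Greedy balanced coloring: nodes in descending-degree order (ties by id)
#' are assigned to the currently smallest bin containing no incompatible
#' member. Bin sizes are capped at \code{ceiling(n/n_bins)} so sizes differ
#' by at most one whenever the graph admits it; if a node fits no bin under
#' the cap, the cap is relaxed for that node and a warning recorded. In
#' automatic mode (\code{n_bins = NULL}) the smallest bin count the greedy
#' heuristic satisfies without relaxation is used, starting from
#' \code{ceiling(n/target_size)}.
#'
#' @param g an \code{incompat_graph}.
#' @param n_bins number of bins, or NULL for automatic.
#' @param target_size desired loci per bin for automatic mode, default 7.
#' @return object of class \code{bin_assignment}: list with \code{bins}
#'   (named list bin id -> character vector of node ids), \code{weights}
#'   (bin sizes), \code{relaxed} (TRUE if balance was relaxed).
#' @export
balanced_bins <- function(g, n_bins = NULL, target_size = 7) {
  .assert(inherits(g, "incompat_graph"), "g must be an incompat_graph")
  n <- length(g$nodes)
  adj <- stats::setNames(vector("list", n), g$nodes)
  if (nrow(g$edges)) {
    for (r in seq_len(nrow(g$edges))) {
      a <- g$edges[r, 1]; b <- g$edges[r, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  deg <- lengths(adj)
  ord <- g$nodes[order(-deg, g$nodes)]

  try_assign <- function(k, strict) {
    cap <- ceiling(n / k)
    bins <- vector("list", k)
    assign_of <- stats::setNames(integer(n), g$nodes)
    relaxed <- FALSE
    for (v in ord) {
      bad <- unique(assign_of[adj[[v]]])
      sizes <- lengths(bins)
      valid <- setdiff(which(sizes < cap), bad)
      if (!length(valid)) {
        if (strict) return(NULL)
        valid <- setdiff(seq_len(k), bad)
        if (!length(valid)) return(NULL)
        relaxed <- TRUE
      }
      b <- valid[which.min(sizes[valid])]
      bins[[b]] <- c(bins[[b]], v)
      assign_of[v] <- b
    }
    list(bins = bins, relaxed = relaxed)
  }

  if (is.null(n_bins)) {
    k0 <- max(1L, ceiling(n / target_size))
    res <- NULL
    for (k in k0:n) {
      res <- try_assign(k, strict = TRUE)
      if (!is.null(res)) { n_bins <- k; break }
    }
    .assert(!is.null(res), "no balanced assignment found at any bin count")
  } else {
    res <- try_assign(n_bins, strict = TRUE)
    if (is.null(res)) res <- try_assign(n_bins, strict = FALSE)
    .assert(!is.null(res),
            "no valid assignment with %d bins; minimum feasible is larger (max degree %d)",
            n_bins, max(deg))
    if (res$relaxed) warning("balance constraint relaxed to satisfy independence")
  }
  bins <- res$bins[order(-lengths(res$bins))]
  bins <- lapply(bins, sort)
  names(bins) <- sprintf("bin_%04d", seq_along(bins))
  # post-hoc independence check against the graph
  if (nrow(g$edges)) {
    binof <- stats::setNames(rep(names(bins), lengths(bins)), unlist(bins))
    stopifnot(all(binof[g$edges[, 1]] != binof[g$edges[, 2]]))
  }
  structure(list(bins = bins, weights = lengths(bins), relaxed = res$relaxed),
            class = "bin_assignment")
}

#' @export
print.bin_assignment <- function(x, ...) {
  cat(sprintf("bin assignment: %d loci in %d bins (sizes %s)\n",
              sum(x$weights), length(x$bins),
              paste(sprintf("%dx%d", table(x$weights),
                            as.integer(names(table(x$weights)))), collapse = ", ")))
  invisible(x)
}

#' Concatenate each bin's loci into a supergene alignment
#'
#' @param ba a \code{bin_assignment}.
#' @param loci named list of \code{locus_alignment} (names = locus ids)
#'   covering every binned locus.
#' @return named list of \code{supermatrix}, one per bin, with per-locus
#'   charsets.
#' @export
build_supergenes <- function(ba, loci) {
  ids <- vapply(loci, `[[`, "", "locus_id")
  names(loci) <- ids
  missing <- setdiff(unlist(ba$bins), ids)
  .assert(length(missing) == 0, "loci missing from collection: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  lapply(ba$bins, function(members) concatenate_loci(loci[members]))
}

#' Weighted or unweighted supergene tree multiset
#'
#' Weighted mode replicates each supergene tree by its bin size (a supergene
#' built from six genes contributes six copies); unweighted mode includes
#' each tree once.
#'
#' @param trees named list of phylo, one per bin (names = bin ids).
#' @param ba the \code{bin_assignment}.
#' @param weighted logical.
#' @return multiPhylo; weighted cardinality equals the number of binned loci.
#' @export
weight_supergene_trees <- function(trees, ba, weighted = TRUE) {
  .assert(setequal(names(trees), names(ba$bins)), "need exactly one tree per bin")
  out <- list()
  for (b in names(ba$bins)) {
    reps <- if (weighted) length(ba$bins[[b]]) else 1L
    out <- c(out, rep(list(trees[[b]]), reps))
  }
  class(out) <- "multiPhylo"
  out
}

#' Write a bin manifest TSV (bin_id, locus_id)
#' @param ba a \code{bin_assignment}.
#' @param file output path.
#' @export
write_bin_manifest <- function(ba, file) {
  tab <- data.frame(bin_id = rep(names(ba$bins), lengths(ba$bins)),
                    locus_id = unlist(ba$bins), row.names = NULL)
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
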