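# Bipartition algebra: the machinery behind every topology comparison in the
# package. A bipartition (split) is the two-way division of the taxon set
# induced by an internal edge of the unrooted tree. Splits are canonicalized
# to the side NOT containing the reference taxon (the lexicographically
# smallest label of the universe); under that convention any two compatible
# splits are nested or disjoint, which makes consensus-tree construction a
# simple laminar-family nesting.

#' Construct a bipartition
#'
#' @param side character vector of taxa on one side of the split.
#' @param universe character vector: the full taxon set being partitioned.
#' @return object of class \code{bipartition}: list with canonical
#'   \code{side} (sorted, excluding the reference taxon \code{min(universe)})
#'   and \code{universe} (sorted).
#' @export
bipartition <- function(side, universe) {
  universe <- sort(unique(as.character(universe)))
  side <- sort(unique(as.character(side)))
  .assert(all(side %in% universe), "split side contains taxa outside the universe")
  if (universe[1] %in% side) side <- setdiff(universe, side)
  .assert(length(side) >= 2 && length(side) <= length(universe) - 2,
          "trivial bipartition: side size %d of universe %d", length(side),
          length(universe))
  structure(list(side = side, universe = universe), class = "bipartition")
}

# canonical string key for a split side (assumed canonical already)
.split_key <- function(side) paste(side, collapse = .KSEP)
.key_side <- function(key) strsplit(key, .KSEP, fixed = TRUE)[[1]]

# Nontrivial splits of the unrooted tree, canonicalized against `universe`
# (defaults to the tree's own leaves). Returns a character vector of keys;
# attr "node" maps each split to the child node of its internal edge, attr
# "universe" records the taxon set.
.splits_keys <- function(phy, universe = NULL) {
  phy <- if (ape::is.rooted(phy)) ape::unroot(phy) else phy
  labs <- phy$tip.label
  n <- length(labs)
  universe <- sort(universe %||% labs)
  ref <- universe[1]
  desc <- .tips_below(phy)
  root <- n + 1L
  inner <- setdiff(seq_len(n + phy$Nnode), c(seq_len(n), root))
  keys <- character(0); nodes <- integer(0)
  for (v in inner) {
    side <- sort(labs[desc[[v]]])
    if (ref %in% side) side <- setdiff(universe, side)
    if (length(side) < 2 || length(side) > length(universe) - 2) next
    keys <- c(keys, .split_key(side)); nodes <- c(nodes, v)
  }
  dup <- duplicated(keys)
  keys <- keys[!dup]; nodes <- nodes[!dup]
  structure(keys, node = nodes, universe = universe)
}

#' Extract the nontrivial bipartitions of a tree
#'
#' One bipartition per internal edge of the unrooted tree; a binary n-leaf
#' tree yields exactly n - 3.
#'
#' @param phy a phylo with >= 4 leaves.
#' @return list of \code{bipartition} objects.
#' @export
extract_splits <- function(phy) {
  .assert(length(phy$tip.label) >= 4, "need >= 4 leaves to have nontrivial splits")
  keys <- .splits_keys(phy)
  universe <- attr(keys, "universe")
  lapply(as.character(keys), function(k) bipartition(.key_side(k), universe))
}

#' Are two bipartitions compatible (can they coexist in one tree)?
#'
#' Two splits are compatible iff at least one of the four pairwise side
#' intersections is empty. Splits on different universes are compared on the
#' shared-taxon restriction; restrictions that become trivial are vacuously
#' compatible.
#'
#' @param b1,b2 \code{bipartition} objects.
#' @export
compatible <- function(b1, b2) {
  shared <- intersect(b1$universe, b2$universe)
  if (!setequal(b1$universe, b2$universe)) {
    .assert(length(shared) >= 4, "universes share fewer than 4 taxa")
  }
  a <- intersect(b1$side, shared); b <- intersect(b2$side, shared)
  ca <- setdiff(shared, a); cb <- setdiff(shared, b)
  # trivial after restriction -> compatible with anything
  if (length(a) < 2 || length(ca) < 2 || length(b) < 2 || length(cb) < 2) return(TRUE)
  length(intersect(a, b)) == 0 || length(intersect(a, cb)) == 0 ||
    length(intersect(ca, b)) == 0 || length(intersect(ca, cb)) == 0
}

# key-level compatibility on a shared universe with canonical sides
# (both exclude the reference taxon): compatible iff nested or disjoint
.keys_compatible <- function(k1, k2) {
  s1 <- .key_side(k1); s2 <- .key_side(k2)
  i <- length(intersect(s1, s2))
  i == 0 || i == length(s1) || i == length(s2)
}

#' Unweighted Robinson-Foulds distance between two trees
#'
#' The size of the symmetric difference of the trees' nontrivial split sets,
#' computed on the shared taxon set (both trees are restricted first when
#' their leaf sets differ). Zero iff identical topology; at most 2(n - 3)
#' between binary trees on n shared taxa. Polytomous trees are compared by
#' the same rule, their split sets simply being smaller.
#'
#' @param t1,t2 phylo trees sharing >= 4 taxa.
#' @return non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  .assert(length(shared) >= 4, "trees share fewer than 4 taxa (%d)", length(shared))
  if (!setequal(shared, t1$tip.label)) t1 <- restrict_tree(t1, shared)
  if (!setequal(shared, t2$tip.label)) t2 <- restrict_tree(t2, shared)
  k1 <- as.character(.splits_keys(t1, shared))
  k2 <- as.character(.splits_keys(t2, shared))
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

# Build a phylo from a laminar family of canonical split sides over
# `universe`. Children are ordered by smallest descendant label, so the
# newick emitted is canonical. `labels` (optional, parallel to `sides`)
# become internal node labels.
.tree_from_splits <- function(sides, universe, labels = NULL) {
  universe <- sort(universe)
  if (length(sides)) {
    ord <- order(lengths(sides), vapply(sides, `[`, "", 1))
    sides <- sides[ord]
    if (!is.null(labels)) labels <- labels[ord]
  }
  # parent[i]: index of smallest side strictly containing side i, else 0 (root)
  nsp <- length(sides)
  parent <- integer(nsp)
  if (nsp) {
    for (i in seq_len(nsp)) {
      parent[i] <- 0L
      for (j in seq_len(nsp)) {
        if (j == i) next
        if (length(sides[[j]]) > length(sides[[i]]) &&
            all(sides[[i]] %in% sides[[j]])) {
          if (parent[i] == 0L || length(sides[[j]]) < length(sides[[parent[i]]]))
            parent[i] <- j
        }
      }
    }
  }
  emit <- function(node) {
    # node: 0 for root (set = universe), else split index
    set <- if (node == 0L) universe else sides[[node]]
    kids <- which(parent == node)
    covered <- unlist(sides[kids])
    singles <- setdiff(set, covered)
    if (node != 0L) {
      # taxa in this side not in any child side are direct leaf children
    }
    parts <- c(lapply(kids, emit), as.list(singles))
    first <- vapply(parts, function(p) attr(p, "min") %||% p[[1]], "")
    parts <- parts[order(first)]
    txt <- vapply(parts, function(p) if (is.character(p) && is.null(attr(p, "nwk")))
      p else attr(p, "nwk"), "")
    lab <- if (node != 0L && !is.null(labels)) labels[[node]] else ""
    out <- paste0("(", paste(txt, collapse = ","), ")", lab)
    structure(list(), nwk = out, min = min(c(first)))
  }
  nwk <- paste0(attr(emit(0L), "nwk"), ";")
  parse_newick(nwk)
}

#' Canonical newick string of a topology
#'
#' Metadata-free unrooted canonical form: children are ordered by their
#' smallest descendant label at every node, so two trees have the same
#' canonical newick iff they have the same unrooted topology.
#'
#' @param phy a phylo tree.
#' @export
canonical_newick <- function(phy) {
  phy <- canonicalize(phy)
  if (length(phy$tip.label) < 4) {
    return(paste0("(", paste(sort(phy$tip.label), collapse = ","), ");"))
  }
  keys <- as.character(.splits_keys(phy))
  tr <- .tree_from_splits(lapply(keys, .key_side), sort(phy$tip.label))
  write_newick(tr)
}

#' Majority-rule consensus tree with bipartition frequencies
#'
#' Retains exactly the bipartitions occurring in strictly more than
#' \code{threshold} of the input trees (strict rule, so the retained set is
#' always pairwise compatible for threshold >= 0.5) and assembles them into a
#' possibly multifurcating consensus tree.
#'
#' @param ts a \code{tree_set} (or multiPhylo/list of phylo) on one taxon set.
#' @param threshold retention threshold as a fraction, default 0.5.
#' @return object of class \code{consensus_tree}: list with \code{tree}
#'   (phylo, frequencies as internal node labels), \code{frequencies}
#'   (data.frame: split, frequency, side list-column), \code{n_trees}.
#' @export
majority_consensus <- function(ts, threshold = 0.5) {
  trees <- if (inherits(ts, "tree_set")) ts$trees else ts
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- as.list(trees)
  .assert(length(trees) >= 1, "consensus of an empty tree set is undefined")
  .assert(threshold >= 0.5, "threshold below 0.5 can retain incompatible splits")
  labs <- lapply(trees, `[[`, "tip.label")
  universe <- sort(labs[[1]])
  .assert(all(vapply(labs, function(l) setequal(l, universe), TRUE)),
          "all trees must share one taxon set (restrict first)")
  keysets <- lapply(trees, function(t) as.character(.splits_keys(t, universe)))
  tab <- table(unlist(keysets))
  freq <- as.numeric(tab) / length(trees)
  keep <- freq > threshold
  keys <- names(tab)[keep]; freq <- freq[keep]
  ord <- order(-freq, keys)
  keys <- keys[ord]; freq <- freq[ord]
  sides <- lapply(keys, .key_side)
  tree <- if (length(universe) >= 4) {
    .tree_from_splits(sides, universe, labels = sprintf("%.4g", freq))
  } else {
    parse_newick(paste0("(", paste(universe, collapse = ","), ");"))
  }
  structure(list(tree = tree,
                 frequencies = data.frame(
                   split = vapply(sides, function(s) paste(s, collapse = "|"), ""),
                   frequency = freq, stringsAsFactors = FALSE),
                 sides = sides, n_trees = length(trees)),
            class = "consensus_tree")
}

#' @export
print.consensus_tree <- function(x, ...) {
  cat(sprintf("majority-rule consensus of %d trees: %d retained bipartitions\n",
              x$n_trees, nrow(x$frequencies)))
  invisible(x)
}

#' Census of distinct topologies in a tree set
#'
#' Groups trees into equivalence classes of identical unrooted topology
#' (Robinson-Foulds distance zero). Trees not spanning the full shared taxon
#' set are excluded (and reported), since topology identity is only defined
#' on a common leaf set.
#'
#' @param ts a \code{tree_set}.
#' @return object of class \code{topology_census}: list with \code{classes}
#'   (data.frame: class_id, count, newick, member_ids list-column, ordered by
#'   decreasing count), \code{n_trees} (censused), \code{excluded} (ids).
#' @export
topology_census <- function(ts) {
  .assert(inherits(ts, "tree_set"), "ts must be a tree_set")
  universe <- tree_set_taxa(ts)
  full <- vapply(ts$trees, function(t) setequal(t$tip.label, universe), TRUE)
  excluded <- ts$info$id[!full]
  trees <- as.list(ts$trees)[full]
  ids <- ts$info$id[full]
  .assert(length(trees) >= 1, "no trees span the full taxon set")
  keys <- vapply(trees, function(t) {
    if (length(t$tip.label) < 4) return("")
    paste(sort(as.character(.splits_keys(t, universe))), collapse = ";")
  }, "")
  by_key <- split(ids, keys)
  counts <- lengths(by_key)
  ord <- order(-counts, vapply(by_key, `[`, "", 1))
  by_key <- by_key[ord]; counts <- counts[ord]
  reps <- match(vapply(by_key, `[`, "", 1), ids)
  classes <- data.frame(class_id = sprintf("T%03d", seq_along(by_key)),
                        count = as.integer(counts),
                        newick = vapply(trees[reps], canonical_newick, ""),
                        stringsAsFactors = FALSE)
  classes$member_ids <- unname(by_key)
  stopifnot(sum(classes$count) == length(trees))
  structure(list(classes = classes, n_trees = length(trees),
                 excluded = excluded),
            class = "topology_census")
}

#' @export
print.topology_census <- function(x, ...) {
  cat(sprintf("topology census: %d trees, %d distinct topologies, modal count %d\n",
              x$n_trees, nrow(x$classes), max(x$classes$count)))
  invisible(x)
}

#' Write a topology census as TSV
#' @param census a \code{topology_census}.
#' @param file output path.
#' @export
write_census_tsv <- function(census, file) {
  tab <- census$classes
  tab$member_ids <- vapply(tab$member_ids, paste, "", collapse = ",")
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a consensus tree (frequencies as internal labels) and its split table
#' @param cons a \code{consensus_tree}.
#' @param tree_file newick output path.
#' @param table_file optional TSV path for the bipartition frequency table.
#' @export
write_consensus <- function(cons, tree_file, table_file = NULL) {
  write_newick(cons$tree, tree_file)
  if (!is.null(table_file)) {
    utils::write.table(cons$frequencies, table_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(tree_file)
}
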