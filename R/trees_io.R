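#' Parse a newick string into a validated phylo tree
#'
#' Thin, validating wrapper around \code{ape::read.tree}. Internal node
#' labels that are numeric and fall in [0, 100] are interpreted downstream as
#' bootstrap-style support values (the convention of RAxML and most consensus
#' writers); other labels are kept as names. Negative branch lengths are
#' rejected; zero lengths are allowed.
#'
#' @param text a single newick string, terminated by a semicolon.
#' @param taxa optional character vector of allowed taxon labels; leaves
#'   outside it trigger an error.
#' @return an object of class \code{phylo}.
#' @export
parse_newick <- function(text, taxa = NULL) {
  .assert(is.character(text) && length(text) == 1, "text must be a single string")
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      .assert(depth >= 0L, "malformed newick: unbalanced ')' at character %d", i)
    }
  }
  .assert(depth == 0L, "malformed newick: %d unclosed '(' at end of string", depth)
  .assert(grepl(";\\s*$", text), "malformed newick: missing terminal ';' at character %d",
          nchar(text))
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("malformed newick: ", conditionMessage(e),
                                           call. = FALSE))
  .assert(inherits(phy, "phylo"), "malformed newick: no tree parsed")
  .assert(!anyDuplicated(phy$tip.label), "duplicate leaf label: %s",
          paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  if (!is.null(phy$edge.length)) {
    .assert(all(phy$edge.length >= 0), "negative branch length in newick input")
  }
  if (!is.null(taxa)) {
    extra <- setdiff(phy$tip.label, taxa)
    .assert(length(extra) == 0, "leaf labels outside taxon namespace: %s",
            paste(extra, collapse = ", "))
  }
  phy
}

#' Write a tree (or multiPhylo) as newick
#' @param phy phylo or multiPhylo.
#' @param file path, or \code{""} to return the string(s).
#' @export
write_newick <- function(phy, file = "") {
  ape::write.tree(phy, file = file)
}

#' Remove branch lengths and support values from a tree
#'
#' Cross-analysis topology comparisons mix trees whose branch lengths carry
#' different meanings (substitutions, coalescent units, none at all), so all
#' metadata is stripped before any distance is computed.
#'
#' @param phy a phylo tree.
#' @return the same topology with no edge lengths, node labels or root edge.
#' @export
strip_metadata <- function(phy) {
  phy$edge.length <- NULL
  phy$node.label <- NULL
  phy$root.edge <- NULL
  phy
}

#' Unroot a tree, suppressing the degree-2 root
#' @param phy a phylo with >= 3 leaves.
#' @export
unroot_tree <- function(phy) {
  .assert(length(phy$tip.label) >= 3, "cannot unroot a tree with fewer than 3 leaves")
  ape::unroot(phy)
}

#' Restrict a tree to a subset of its taxa
#'
#' Leaves outside \code{keep} are pruned and resulting degree-2 nodes are
#' suppressed, with branch lengths summed across suppressed nodes.
#'
#' @param phy a phylo tree.
#' @param keep character vector of taxon labels to retain.
#' @export
restrict_tree <- function(phy, keep) {
  keep <- intersect(phy$tip.label, keep)
  .assert(length(keep) >= 3, "fewer than 3 taxa would survive restriction (%d)",
          length(keep))
  if (setequal(keep, phy$tip.label)) return(phy)
  ape::keep.tip(phy, keep)
}

#' Canonical unrooted form used for all cross-tree comparisons
#'
#' Strips metadata and unroots; the result depends only on the topology.
#' @param phy a phylo tree.
#' @export
canonicalize <- function(phy) {
  phy <- strip_metadata(phy)
  if (ape::is.rooted(phy) && length(phy$tip.label) >= 3) phy <- unroot_tree(phy)
  phy
}

#' A tree set: trees on a shared taxon namespace with provenance labels
#'
#' @param trees a multiPhylo or list of phylo trees.
#' @param group character, one marker/group label per tree (recycled if 1).
#' @param ids optional analysis identifiers, one per tree.
#' @param canonical canonicalize (unroot + strip) every tree on construction.
#' @return object of class \code{tree_set}: list with \code{trees}
#'   (multiPhylo), \code{info} (data.frame: id, group).
#' @export
tree_set <- function(trees, group = "all", ids = NULL, canonical = TRUE) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unname(as.list(trees))
  .assert(length(trees) >= 1, "tree set must contain at least one tree")
  .assert(all(vapply(trees, inherits, TRUE, "phylo")), "all elements must be phylo trees")
  if (canonical) trees <- lapply(trees, canonicalize)
  group <- as.character(group)
  if (length(group) == 1) group <- rep(group, length(trees))
  .assert(length(group) == length(trees), "one group label per tree required")
  .assert(all(nzchar(group)), "group labels must be non-empty")
  if (is.null(ids)) ids <- sprintf("tree_%03d", seq_along(trees))
  .assert(!anyDuplicated(ids), "analysis ids must be unique")
  class(trees) <- "multiPhylo"
  structure(list(trees = trees,
                 info = data.frame(id = as.character(ids), group = group,
                                   stringsAsFactors = FALSE)),
            class = "tree_set")
}

#' @export
print.tree_set <- function(x, ...) {
  cat(sprintf("tree_set: %d trees, groups: %s\n", length(x$trees),
              paste(sprintf("%s (%d)", names(table(x$info$group)),
                            table(x$info$group)), collapse = ", ")))
  invisible(x)
}

#' Number of trees in a tree set
#' @param x a tree_set.
#' @export
length.tree_set <- function(x) length(x$trees)

#' All taxon labels used across a tree set, sorted
#' @param ts a tree_set.
#' @export
tree_set_taxa <- function(ts) {
  sort(unique(unlist(lapply(ts$trees, `[[`, "tip.label"))))
}

#' Combine tree sets
#' @param ... tree_set objects.
#' @export
combine_tree_sets <- function(...) {
  sets <- list(...)
  trees <- do.call(c, lapply(sets, function(s) as.list(s$trees)))
  info <- do.call(rbind, lapply(sets, `[[`, "info"))
  .assert(!anyDuplicated(info$id), "duplicate analysis ids across combined sets")
  tree_set(trees, group = info$group, ids = info$id, canonical = FALSE)
}

#' Read tree sets from a manifest file
#'
#' The manifest is a TSV with columns \code{path}, \code{group_label},
#' \code{analysis_id}. Each path may hold one or more newick trees; multiple
#' trees in one file get the analysis id suffixed with \code{.1}, \code{.2},
#' ... All trees are canonicalized (unrooted, metadata stripped).
#'
#' @param manifest path to the TSV manifest; relative tree paths are resolved
#'   against the manifest's directory.
#' @return a \code{tree_set}.
#' @export
ingest_tree_sets <- function(manifest) {
  .assert(file.exists(manifest), "manifest not found: %s", manifest)
  tab <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  .assert(nrow(tab) >= 1, "empty manifest: %s", manifest)
  .assert(all(c("path", "group_label", "analysis_id") %in% names(tab)),
          "manifest must have columns path, group_label, analysis_id")
  base <- dirname(manifest)
  trees <- list(); groups <- character(); ids <- character()
  for (r in seq_len(nrow(tab))) {
    p <- tab$path[r]
    if (!file.exists(p)) p <- file.path(base, tab$path[r])
    .assert(file.exists(p), "manifest row %d: file not found: %s", r, tab$path[r])
    tr <- tryCatch(ape::read.tree(p),
                   error = function(e) stop(sprintf(
                     "manifest row %d: cannot parse %s: %s", r, tab$path[r],
                     conditionMessage(e)), call. = FALSE))
    if (inherits(tr, "phylo")) tr <- list(tr)
    .assert(length(tr) >= 1, "manifest row %d: no trees in %s", r, tab$path[r])
    sub_ids <- if (length(tr) == 1) tab$analysis_id[r] else
      paste(tab$analysis_id[r], seq_along(tr), sep = ".")
    trees <- c(trees, as.list(tr))
    groups <- c(groups, rep(tab$group_label[r], length(tr)))
    ids <- c(ids, sub_ids)
  }
  tree_set(trees, group = groups, ids = ids, canonical = TRUE)
}
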