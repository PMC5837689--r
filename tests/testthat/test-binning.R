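# helper: attach supports to every internal edge of a binary tree
supported_tree <- function(newick, supports) {
  tr <- parse_newick(newick)
  tr <- if (ape::is.rooted(tr)) ape::unroot(tr) else tr
  keys <- cytonuclear:::.splits_keys(tr)
  nodes <- attr(keys, "node")
  nlab <- rep(NA_character_, tr$Nnode)
  nlab[nodes - length(tr$tip.label)] <- as.character(supports)
  tr$node.label <- nlab
  tr
}

test_that("low-support bifurcations are contracted with a strict rule", {
  tr <- supported_tree("((a,b),(c,d),e);", 100)
  expect_equal(rf_distance(collapse_low_support(tr, 50), tr), 0)
  # an edge at exactly the threshold is contracted (strictly-greater rule)
  tr2 <- supported_tree("((a,b),(c,d),e);", c(50, 90))
  col2 <- collapse_low_support(tr2, 50)
  expect_length(extract_splits(col2), 1)
  # mixed supports on a 5-taxon tree: only the strong split survives
  tr3 <- supported_tree("(((a,b),c),(d,e));", c(90, 40))
  col3 <- collapse_low_support(tr3, 50)
  expect_length(extract_splits(col3), 1)
  expect_error(collapse_low_support(strip_metadata(tr3), 50), "support")
})

test_that("pairwise incompatibility detects conflict on shared taxa", {
  a <- collapse_low_support(supported_tree("((a,b),(c,d),e);", 99), 50)
  b <- collapse_low_support(supported_tree("((a,c),(b,d),e);", 99), 50)
  expect_false(pair_incompatible(a, a))
  expect_true(pair_incompatible(a, b))
  star <- parse_newick("(a,b,c,d,e);")
  expect_false(pair_incompatible(a, star))
  # fewer than 4 shared taxa -> vacuously compatible
  c <- parse_newick("((a,b),(x,y),z);")
  expect_false(pair_incompatible(a, c))
})

test_that("incompatibility graph edges are exactly the conflicting pairs", {
  t_ab <- parse_newick("((a,b),(c,d),e);")
  t_ac <- parse_newick("((a,c),(b,d),e);")
  t_ad <- parse_newick("((a,d),(b,c),e);")
  g0 <- build_graph(list(x = t_ab, y = t_ab, z = t_ab))
  expect_equal(nrow(g0$edges), 0)
  g3 <- build_graph(list(x = t_ab, y = t_ac, z = t_ad))
  expect_equal(nrow(g3$edges), 3)          # triangle
  # random collapsed trees: edge iff pair_incompatible, verified pairwise
  set.seed(191)
  trees <- lapply(1:12, function(i) {
    tr <- random_binary_tree(letters[1:6])
    keep <- sample(letters[1:6], 5)
    restrict_tree(tr, keep)
  })
  names(trees) <- sprintf("g%02d", 1:12)
  g <- build_graph(trees)
  edges <- apply(g$edges, 1, paste, collapse = "|")
  for (i in 1:11) for (j in (i + 1):12) {
    ids <- sort(c(names(trees)[i], names(trees)[j]))
    expect_equal(paste(ids, collapse = "|") %in% edges,
                 pair_incompatible(trees[[i]], trees[[j]]))
  }
})

test_that("balanced binning respects independence and balance", {
  # triangle -> three singleton bins
  t_ab <- parse_newick("((a,b),(c,d),e);")
  t_ac <- parse_newick("((a,c),(b,d),e);")
  t_ad <- parse_newick("((a,d),(b,c),e);")
  g3 <- build_graph(list(x = t_ab, y = t_ac, z = t_ad))
  ba3 <- balanced_bins(g3, n_bins = 3)
  expect_equal(sort(unname(ba3$weights)), c(1L, 1L, 1L))
  expect_error(balanced_bins(g3, n_bins = 2), "no valid assignment")
  # path of 4 nodes into 2 alternating bins of 2
  path_graph <- structure(list(nodes = c("n1", "n2", "n3", "n4"),
                               edges = rbind(c("n1", "n2"), c("n2", "n3"),
                                             c("n3", "n4"))),
                          class = "incompat_graph")
  ba2 <- balanced_bins(path_graph, n_bins = 2)
  expect_equal(sort(unname(ba2$weights)), c(2L, 2L))
  binof <- stats::setNames(rep(names(ba2$bins), lengths(ba2$bins)),
                           unlist(ba2$bins))
  expect_false(binof[["n1"]] == binof[["n2"]])
  expect_false(binof[["n2"]] == binof[["n3"]])
  expect_false(binof[["n3"]] == binof[["n4"]])
})

test_that("an edgeless 3648-locus graph fills 528 bins as 480x7 + 48x6", {
  g <- structure(list(nodes = sprintf("l%04d", 1:3648),
                      edges = matrix(character(0), 0, 2)),
                 class = "incompat_graph")
  ba <- balanced_bins(g, n_bins = 528)
  expect_equal(length(ba$bins), 528)
  tab <- table(ba$weights)
  expect_equal(unname(tab[["7"]]), 480)
  expect_equal(unname(tab[["6"]]), 48)
  expect_equal(sum(ba$weights), 3648)
})

test_that("binning invariants hold on random inputs", {
  set.seed(197)
  for (rep in 1:10) {
    trees <- lapply(1:10, function(i) random_binary_tree(letters[1:6]))
    names(trees) <- sprintf("g%02d", 1:10)
    g <- build_graph(trees)
    ba <- tryCatch(balanced_bins(g, target_size = 3),
                   warning = function(w) suppressWarnings(
                     balanced_bins(g, target_size = 3)))
    # no bin contains an incompatible pair
    for (b in ba$bins) {
      if (length(b) < 2) next
      for (i in 1:(length(b) - 1)) for (j in (i + 1):length(b)) {
        expect_false(pair_incompatible(trees[[b[i]]], trees[[b[j]]]))
      }
    }
    expect_equal(sum(ba$weights), 10)
  }
})

test_that("refinements of one topology bin without conflict at target size", {
  base <- parse_newick("((a,b),(c,d),(e,f));")
  trees <- replicate(9, base, simplify = FALSE)
  names(trees) <- sprintf("g%02d", 1:9)
  g <- build_graph(trees)
  expect_equal(nrow(g$edges), 0)
  ba <- balanced_bins(g, target_size = 3)
  expect_equal(length(ba$bins), ceiling(9 / 3))
})

test_that("supergenes concatenate bin members with per-locus charsets", {
  loci <- list(
    locus_alignment("l1", c(a = strrep("A", 100), b = strrep("C", 100))),
    locus_alignment("l2", c(a = strrep("G", 200), b = strrep("T", 200))),
    locus_alignment("l3", c(a = strrep("A", 300), b = strrep("G", 300))))
  ba <- structure(list(bins = list(bin_0001 = c("l1", "l2", "l3")),
                       weights = c(bin_0001 = 3L), relaxed = FALSE),
                  class = "bin_assignment")
  sg <- build_supergenes(ba, loci)
  expect_equal(sg$bin_0001$length, 600)
  expect_equal(nrow(sg$bin_0001$charsets), 3)
  ba_bad <- structure(list(bins = list(b = c("l1", "nope"))),
                      class = "bin_assignment")
  expect_error(build_supergenes(ba_bad, loci), "missing")
  # bin of one locus: supergene equals the locus
  ba1 <- structure(list(bins = list(b1 = "l2")), class = "bin_assignment")
  expect_equal(build_supergenes(ba1, loci)$b1$seqs, loci[[2]]$seqs)
})

test_that("weighted multisets replicate supergene trees by bin size", {
  tr <- parse_newick("((a,b),(c,d));")
  ba <- structure(list(bins = list(bin_a = sprintf("x%d", 1:7),
                                   bin_b = sprintf("y%d", 1:6)),
                       weights = c(bin_a = 7L, bin_b = 6L), relaxed = FALSE),
                  class = "bin_assignment")
  trees <- list(bin_a = tr, bin_b = tr)
  expect_length(weight_supergene_trees(trees, ba, weighted = TRUE), 13)
  expect_length(weight_supergene_trees(trees, ba, weighted = FALSE), 2)
  # conservation at the published scale: 528 bins sized 7/6 -> 3648 trees
  bins528 <- c(lapply(1:480, function(i) sprintf("a%d_%d", i, 1:7)),
               lapply(1:48, function(i) sprintf("b%d_%d", i, 1:6)))
  names(bins528) <- sprintf("bin_%04d", 1:528)
  ba528 <- structure(list(bins = bins528, weights = lengths(bins528),
                          relaxed = FALSE), class = "bin_assignment")
  trees528 <- stats::setNames(rep(list(tr), 528), names(bins528))
  expect_length(weight_supergene_trees(trees528, ba528, weighted = TRUE), 3648)
})
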