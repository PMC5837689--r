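test_that("split extraction matches hand enumeration", {
  expect_length(extract_splits(parse_newick("((a,b),(c,d));")), 1)
  star <- ape::stree(5, type = "star")
  star$tip.label <- letters[1:5]
  expect_length(extract_splits(star), 0)
  cat6 <- parse_newick("(((((a,b),c),d),e),f);")
  # canonical sides exclude the reference taxon "a"
  sides <- vapply(extract_splits(cat6), function(b) paste(b$side, collapse = ""), "")
  expect_setequal(sides, c("cdef", "def", "ef"))
  # binary n-leaf tree yields exactly n-3 splits
  set.seed(5)
  for (n in 5:9) {
    tr <- random_binary_tree(sprintf("s%02d", 1:n))
    expect_length(extract_splits(tr), n - 3)
  }
})

test_that("split extraction agrees with brute-force monophyly oracle", {
  set.seed(21)
  for (i in 1:20) {
    tr <- random_binary_tree(letters[1:7])
    mine <- sort(vapply(extract_splits(tr), function(b)
      paste(b$side, collapse = "|"), ""))
    oracle <- sort(vapply(oracle_splits(tr), paste, "", collapse = "|"))
    expect_equal(mine, oracle)
  }
})

test_that("bipartition compatibility follows the four-intersection rule", {
  u <- letters[1:5]
  b_ab <- bipartition(c("a", "b"), u)
  b_abc <- bipartition(c("a", "b", "c"), u)
  expect_true(compatible(b_ab, b_abc))        # nested
  u4 <- letters[1:4]
  expect_false(compatible(bipartition(c("a", "b"), u4),
                          bipartition(c("a", "c"), u4)))  # classic conflict
  expect_true(compatible(b_ab, b_ab))          # identity
  expect_error(bipartition("a", u), "trivial")
})

test_that("RF distance equals split symmetric difference and is a metric", {
  t1 <- parse_newick("((a,b),(c,d));")
  t2 <- parse_newick("((a,c),(b,d));")
  expect_equal(rf_distance(t1, t1), 0)
  expect_equal(rf_distance(t1, t2), 2)
  t3 <- parse_newick("((a,b),(c,d),(e,f));")
  t4 <- parse_newick("((a,c),(b,d),(e,f));")
  expect_equal(rf_distance(t3, t4), 4)
  expect_error(rf_distance(t1, parse_newick("((a,b),(x,y));")), "fewer than 4")

  set.seed(31)
  labels <- sprintf("s%02d", 1:8)
  trees <- replicate(12, random_binary_tree(labels), simplify = FALSE)
  # symmetry, identity, triangle inequality on random triples
  for (i in 1:20) {
    tri <- sample(12, 3)
    a <- trees[[tri[1]]]; b <- trees[[tri[2]]]; c <- trees[[tri[3]]]
    expect_equal(rf_distance(a, b), rf_distance(b, a))
    expect_lte(rf_distance(a, c), rf_distance(a, b) + rf_distance(b, c))
  }
  # oracle equivalence, brute-force naive enumeration
  for (i in 1:15) {
    a <- trees[[sample(12, 1)]]; b <- trees[[sample(12, 1)]]
    expect_equal(rf_distance(a, b), oracle_rf(a, b))
  }
  # independent library cross-check over many pairs
  mp <- structure(trees, class = "multiPhylo")
  lib <- as.matrix(phangorn::RF.dist(mp))
  mine <- pairwise_rf_matrix(tree_set(trees, group = "g"))
  expect_true(all(mine == lib))
})

test_that("RF range bound holds and caterpillar reversal attains it at n = 6", {
  labels <- letters[1:6]
  cat_fwd <- parse_newick("(((((a,b),c),d),e),f);")
  cat_rev <- parse_newick("(((((f,e),d),c),b),a);")
  # reversed caterpillar shares the same splits read from the other end;
  # maximum is attained by a caterpillar against a tree with disjoint splits
  dmax <- 2 * (6 - 3)
  set.seed(77)
  best <- 0
  for (i in 1:200) {
    tr <- random_binary_tree(labels)
    best <- max(best, rf_distance(cat_fwd, tr))
    expect_lte(rf_distance(cat_fwd, tr), dmax)
  }
  expect_equal(best, dmax)
})

test_that("majority consensus retains exactly the >threshold splits", {
  t1 <- parse_newick("((a,b),(c,d));")
  t2 <- parse_newick("((a,c),(b,d));")
  cons <- majority_consensus(list(t1, t1, t2))
  expect_equal(nrow(cons$frequencies), 1)
  expect_equal(cons$frequencies$frequency, 2 / 3)
  expect_equal(cons$frequencies$split, "c|d")

  # unanimity: consensus equals the input tree with frequency 1
  set.seed(41)
  tr <- random_binary_tree(letters[1:7])
  cons1 <- majority_consensus(list(tr, tr, tr))
  expect_equal(rf_distance(cons1$tree, tr), 0)
  expect_true(all(cons1$frequencies$frequency == 1))

  # three mutually conflicting quartets -> star
  t3 <- parse_newick("((a,d),(b,c));")
  cons2 <- majority_consensus(list(t1, t2, t3))
  expect_equal(nrow(cons2$frequencies), 0)
  expect_length(extract_splits(cons2$tree), 0)

  expect_error(majority_consensus(list()), "empty|at least one")
})

test_that("consensus soundness: recount over inputs and pairwise compatibility", {
  set.seed(51)
  labels <- sprintf("s%02d", 1:7)
  for (rep in 1:25) {
    trees <- replicate(sample(3:9, 1), random_binary_tree(labels),
                       simplify = FALSE)
    cons <- majority_consensus(trees)
    u <- sort(labels)
    # independent recount via ape::prop.part bipartition frequencies
    pp <- ape::prop.part(structure(lapply(trees, function(t)
      ape::root(t, outgroup = u[1], resolve.root = TRUE)), class = "multiPhylo"))
    ppl <- attr(pp, "labels")
    key_of <- function(tips) {
      side <- sort(tips)
      if (u[1] %in% side) side <- setdiff(u, side)
      paste(side, collapse = "|")
    }
    counts <- integer(0)
    for (k in seq_along(pp)) {
      tips <- ppl[pp[[k]]]
      if (length(tips) < 2 || length(tips) > length(u) - 2) next
      counts[key_of(tips)] <- attr(pp, "number")[k]
    }
    for (r in seq_len(nrow(cons$frequencies))) {
      expect_equal(cons$frequencies$frequency[r],
                   counts[[cons$frequencies$split[r]]] / length(trees))
      expect_gt(cons$frequencies$frequency[r], 0.5)
    }
    sides <- cons$sides
    if (length(sides) >= 2) {
      for (i in 1:(length(sides) - 1)) for (j in (i + 1):length(sides)) {
        expect_true(compatible(bipartition(sides[[i]], u),
                               bipartition(sides[[j]], u)))
      }
    }
  }
})

test_that("topology census groups trees iff RF distance is zero", {
  t1 <- parse_newick("((a,b),(c,d),e);")
  t2 <- parse_newick("((a,c),(b,d),e);")
  ts <- tree_set(list(t1, t1, t1, t2), group = "g",
                 ids = c("x1", "x2", "x3", "y1"))
  cen <- topology_census(ts)
  expect_equal(nrow(cen$classes), 2)
  expect_equal(cen$classes$count, c(3L, 1L))
  expect_setequal(cen$classes$member_ids[[1]], c("x1", "x2", "x3"))
  expect_equal(sum(cen$classes$count), 4)

  # census key identity equals RF = 0, across random trees
  set.seed(61)
  labels <- sprintf("s%02d", 1:6)
  trees <- replicate(12, random_binary_tree(labels), simplify = FALSE)
  ts2 <- tree_set(trees, group = "g")
  cen2 <- topology_census(ts2)
  id_class <- stats::setNames(rep(seq_len(nrow(cen2$classes)),
                                  lengths(cen2$classes$member_ids)),
                              unlist(cen2$classes$member_ids))
  for (i in 1:11) for (j in (i + 1):12) {
    same <- rf_distance(trees[[i]], trees[[j]]) == 0
    expect_equal(id_class[[ts2$info$id[i]]] == id_class[[ts2$info$id[j]]], same)
  }
  # trees missing taxa are excluded, not censused
  mixed <- tree_set(c(trees[1:3], list(restrict_tree(trees[[4]], labels[1:5]))),
                    group = "g")
  cen3 <- topology_census(mixed)
  expect_equal(cen3$n_trees, 3)
  expect_length(cen3$excluded, 1)
})

test_that("canonical newick is invariant to representation", {
  set.seed(71)
  for (i in 1:10) {
    tr <- random_binary_tree(letters[1:7])
    rot <- ape::rotateConstr(tr, sample(tr$tip.label))
    rerooted <- ape::root(tr, outgroup = sample(tr$tip.label, 1),
                          resolve.root = TRUE)
    expect_equal(canonical_newick(tr), canonical_newick(rot))
    expect_equal(canonical_newick(tr), canonical_newick(rerooted))
    back <- parse_newick(canonical_newick(tr))
    expect_equal(rf_distance(tr, back), 0)
  }
})
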