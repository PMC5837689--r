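test_that("Yule trees are reproducible with the requested shape", {
  t1 <- simulate_yule_tree(8, seed = 5)
  t2 <- simulate_yule_tree(8, seed = 5)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_equal(length(t1$tip.label), 8)
  expect_equal(t1$Nnode, 7)                    # rooted: n - 1 internal nodes
  expect_true(ape::is.ultrametric(t1))
  expect_error(simulate_yule_tree(2), "n >= 3")
})

test_that("named substreams give independent reproducible seeds", {
  expect_equal(derive_seed(42, "a"), derive_seed(42, "a"))
  expect_false(derive_seed(42, "a") == derive_seed(42, "b"))
  expect_false(derive_seed(42, "a") == derive_seed(43, "a"))
  s <- vapply(1:200, function(i) derive_seed(i, "gene"), 0L)
  expect_true(all(s >= 1 & s < 2^31))
})

test_that("deep species-tree branches force gene-tree concordance", {
  sp <- simulate_yule_tree(7, seed = 13)
  sp$edge.length <- sp$edge.length * 0 + 50
  for (i in 1:5) {
    gt <- simulate_msc_gene_tree(sp, seed = 100 + i)
    expect_equal(rf_distance(gt, sp), 0)
  }
})

test_that("3-taxon MSC concordance matches 1 - (2/3)exp(-T)", {
  reps <- 3000
  for (T_len in c(0.5, 2)) {
    spt <- parse_newick(sprintf("((a:1,b:1):%g,c:%g);", T_len, 1 + T_len))
    set.seed(211 + round(10 * T_len))
    hits <- 0
    for (i in seq_len(reps)) {
      gt <- simulate_msc_gene_tree(spt)
      d <- ape::cophenetic.phylo(gt)
      if (d["a", "b"] < d["a", "c"] && d["a", "b"] < d["b", "c"]) hits <- hits + 1
    }
    p_hat <- hits / reps
    p_theory <- 1 - (2 / 3) * exp(-T_len)
    se <- sqrt(p_theory * (1 - p_theory) / reps)
    expect_lt(abs(p_hat - p_theory), 3 * se)
  }
})

test_that("a star species tree gives each 3-taxon topology 1/3 of the time", {
  spt <- parse_newick("((a:1,b:1):0,c:1);")
  set.seed(223)
  reps <- 2000; hits <- 0
  for (i in seq_len(reps)) {
    gt <- simulate_msc_gene_tree(spt)
    d <- ape::cophenetic.phylo(gt)
    if (d["a", "b"] < d["a", "c"] && d["a", "b"] < d["b", "c"]) hits <- hits + 1
  }
  expect_lt(abs(hits / reps - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / reps))
})

test_that("certain introgression reroutes the mitochondrial history", {
  sp <- simulate_yule_tree(8, seed = 11)
  sp$edge.length <- sp$edge.length / max(ape::node.depth.edgelength(sp)) * 3
  # no events, tiny effective size -> mito equals the species topology
  m0 <- simulate_mito_tree(sp, ne_scale = 1e-4, seed = 3)
  expect_equal(rf_distance(m0, sp), 0)
  # a certain transfer into a distant recipient moves it next to the donor
  ev <- introgression_event(donor = "t01", recipient = "t08", prob = 1)
  hits <- 0
  for (i in 1:10) {
    m1 <- simulate_mito_tree(sp, events = list(ev), ne_scale = 1e-3,
                             seed = 400 + i)
    expect_gt(rf_distance(m1, sp), 0)
    d <- cytonuclear:::.topo_dist(m1)
    if (d["t01", "t08"] == min(d["t08", colnames(d) != "t08"])) hits <- hits + 1
  }
  expect_equal(hits, 10)
  # invalid event timing errors
  bad <- introgression_event(donor = "t01", recipient = "t08", time = 1e6)
  expect_error(simulate_mito_tree(sp, events = list(bad)), "extant")
})

test_that("sequence simulation follows the JC expectation", {
  # rate 0 -> identical sequences
  sp <- simulate_yule_tree(5, seed = 17)
  al0 <- simulate_sequences(sp, 100, rate_scale = 0, seed = 1)
  expect_equal(length(unique(al0$seqs)), 1)
  # two taxa at JC distance d: observed mismatch ~ (3/4)(1 - exp(-4d/3))
  two <- parse_newick("(x:0.1,y:0.1);")
  al <- simulate_sequences(two, 20000, rate_scale = 1, seed = 23)
  p_obs <- mean(strsplit(al$seqs[["x"]], "")[[1]] != strsplit(al$seqs[["y"]], "")[[1]])
  p_exp <- 0.75 * (1 - exp(-4 * 0.2 / 3))
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 20000))
  expect_error(simulate_sequences(strip_metadata(sp), 10), "branch lengths")
})

test_that("default divergence yields a few percent informative sites", {
  cfg <- sim_config(n_loci = 20, seed = 31, retention = 1)
  dat <- simulate_dataset(cfg)
  frac <- vapply(dat$loci, function(l) {
    st <- locus_stats(l); st$informative / st$length
  }, 0)
  expect_gt(mean(frac), 0.005)
  expect_lt(mean(frac), 0.05)
})

test_that("missingness masks taxa at the requested rate and drops thin loci", {
  sp <- simulate_yule_tree(20, seed = 41)
  loci <- lapply(1:100, function(i)
    simulate_sequences(sp, 30, rate_scale = 0.01, locus_id = sprintf("l%03d", i),
                       seed = 500 + i))
  kept <- apply_missingness(loci, retention = 1, seed = 1)
  expect_equal(length(kept), 100)
  expect_equal(kept[[1]]$taxon_count, 20)
  masked <- apply_missingness(loci, retention = 0.5, seed = 2)
  mean_taxa <- mean(vapply(masked, `[[`, 0, "taxon_count"))
  expect_lt(abs(mean_taxa - 10), 3 * sqrt(20 * 0.25) / sqrt(100) + 0.5)
  # nestedness of completeness filters on masked loci
  counts <- vapply(c(0.9, 0.6, 0.3), function(f)
    length(filter_by_completeness(masked, f, 20)), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("simulated datasets are reproducible end to end", {
  cfg <- sim_config(n_taxa = 8, n_loci = 10, seed = 77, mito_length = 500)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$loci[[3]]$seqs, d2$loci[[3]]$seqs)
  expect_identical(write_newick(d1$mito_tree), write_newick(d2$mito_tree))
})
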