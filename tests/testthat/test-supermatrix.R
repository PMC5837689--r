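test_that("locus construction validates shape", {
  expect_error(locus_alignment("x", c(a = "ACGT", b = "ACG")), "unequal")
  expect_error(locus_alignment("x", c("ACGT", "ACGT")), "named")
  l <- locus_alignment("x", c(a = "acgt", b = "ACGT"))
  expect_equal(unname(l$seqs[1]), "ACGT")
  expect_equal(l$length, 4)
  expect_equal(l$taxon_count, 2)
})

test_that("variable and informative site definitions are exact", {
  # columns: AATT (informative), AAAT (variable only), AAAA (constant),
  # A-NT (one non-missing state pair -> variable, not informative)
  l <- locus_alignment("s", c(t1 = "AAAA", t2 = "AAA-", t3 = "TAAN",
                              t4 = "TTAT"))
  st <- locus_stats(l)
  expect_equal(st$length, 4)
  expect_equal(st$variable, 3)
  expect_equal(st$informative, 1)
  expect_equal(st$constant + st$variable, st$length)
  # exhaustive column check on a toy alignment
  l2 <- locus_alignment("s2", c(a = "AAT", b = "AAT", c = "ATA", d = "ATA"))
  st2 <- locus_stats(l2)
  expect_equal(st2$variable, 2)
  expect_equal(st2$informative, 2)
  expect_error(locus_stats(locus_alignment("s3", c(a = "ACGT"))), "fewer than 2")
})

test_that("completeness thresholds reproduce the published 37-taxon spectrum", {
  fracs <- c(1, .95, .85, .75, .65, .55, .45, .35, .25, .15)
  mins <- c(37, 35, 31, 27, 24, 20, 16, 12, 9, 5)
  taxa <- sprintf("sp%02d", 1:37)
  set.seed(151)
  loci <- lapply(1:80, function(i) {
    k <- sample(3:37, 1)
    locus_alignment(sprintf("l%03d", i),
                    stats::setNames(rep(strrep("A", 10), k), sample(taxa, k)))
  })
  for (i in seq_along(fracs)) {
    sub <- filter_by_completeness(loci, fracs[i], 37)
    expect_equal(attr(sub, "min_taxa"), mins[i])
    expect_true(all(vapply(sub, `[[`, 0, "taxon_count") >= mins[i]))
  }
  # nestedness: stricter thresholds select subsets of looser ones
  for (i in seq_along(fracs)[-1]) {
    strict <- vapply(filter_by_completeness(loci, fracs[i - 1], 37), `[[`, "",
                     "locus_id")
    loose <- vapply(filter_by_completeness(loci, fracs[i], 37), `[[`, "",
                    "locus_id")
    expect_true(all(strict %in% loose))
  }
})

test_that("length bins are contiguous, balanced and deterministic", {
  set.seed(157)
  loci <- lapply(1:25, function(i)
    locus_alignment(sprintf("l%03d", i),
                    c(a = strrep("A", 10 + i), b = strrep("C", 10 + i))))
  bins <- bin_by_length(sample(loci), 10)
  sizes <- lengths(bins)
  expect_equal(sum(sizes), 25)
  expect_lte(max(sizes) - min(sizes), 1)
  lens <- lapply(bins, function(b) vapply(b, `[[`, 0, "length"))
  expect_true(all(diff(unlist(lens)) >= 0))     # ascending across bins
  # 10 loci, 10 bins -> one each
  expect_true(all(lengths(bin_by_length(loci[1:10], 10)) == 1))
  # ties broken by id: deterministic under input permutation
  tied <- lapply(1:6, function(i)
    locus_alignment(sprintf("t%d", i), c(a = "AAAA", b = "CCCC")))
  b1 <- bin_by_length(tied, 3)
  b2 <- bin_by_length(rev(tied), 3)
  ids <- function(b) lapply(b, function(g) vapply(g, `[[`, "", "locus_id"))
  expect_equal(ids(b1), ids(b2))
})

test_that("random subsets are reproducible uniform draws without replacement", {
  ids <- sprintf("l%04d", 1:200)
  s1 <- random_subsets(ids, k = 30, reps = 10, seed = 5)
  s2 <- random_subsets(ids, k = 30, reps = 10, seed = 5)
  expect_identical(s1, s2)
  expect_true(all(vapply(s1, function(x) length(unique(x)) == 30, TRUE)))
  full <- random_subsets(ids, k = 200, reps = 3, seed = 5)
  expect_true(all(vapply(full, setequal, TRUE, ids)))
  expect_error(random_subsets(ids, k = 201, reps = 1, seed = 5), "exceeds")
})

test_that("concatenation pads missing taxa and records charsets", {
  l1 <- locus_alignment("loc1", c(a = strrep("A", 100), b = strrep("C", 100)))
  l2 <- locus_alignment("loc2", c(a = strrep("G", 250), c = strrep("T", 250)))
  sm <- concatenate_loci(list(l1, l2))
  expect_equal(sm$length, 350)
  expect_equal(sm$charsets$start, c(1L, 101L))
  expect_equal(sm$charsets$end, c(100L, 350L))
  expect_equal(substr(sm$seqs[["b"]], 101, 350), strrep("?", 250))
  expect_equal(substr(sm$seqs[["c"]], 1, 100), strrep("?", 100))
  expect_error(concatenate_loci(list(l1, l1)), "duplicate")
  # single locus: supermatrix identical to the locus
  sm1 <- concatenate_loci(list(l1))
  expect_equal(sm1$seqs, l1$seqs)
  expect_equal(nrow(sm1$charsets), 1)
})

test_that("alignment writers emit parseable files", {
  l1 <- locus_alignment("loc1", c(a = "ACGTAC", b = "ACGTAA", c = "ACCTAA",
                                  d = "AGGTAA"))
  sm <- concatenate_loci(list(l1))
  dir <- withr::local_tempdir()
  write_phylip(sm, file.path(dir, "m.phy"))
  first <- readLines(file.path(dir, "m.phy"))[1]
  expect_equal(first, "4 6")
  write_raxml_partitions(sm, file.path(dir, "m.part"))
  expect_match(readLines(file.path(dir, "m.part")), "DNA, loc1 = 1-6")
  write_nexus(sm, file.path(dir, "m.nex"))
  expect_true(any(grepl("CHARSET loc1 = 1-6;", readLines(file.path(dir, "m.nex")))))
  write_locus_fasta(l1, file.path(dir, "l.fa"))
  back <- read_locus_fasta(file.path(dir, "l.fa"))
  expect_equal(back$seqs, l1$seqs)
})
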