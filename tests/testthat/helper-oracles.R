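# fixtures and independent oracles used across the suite

# random binary unrooted tree on the given labels
random_binary_tree <- function(labels) {
  tr <- ape::rtree(length(labels), rooted = FALSE, br = NULL)
  tr$tip.label <- sample(labels)
  tr
}

# brute-force split enumeration: for every subset S of the taxa with
# 2 <= |S| <= n-2, test whether some edge of the tree separates S from its
# complement by checking that both S and its complement are connected in the
# tree minus one edge -- implemented by checking monophyly of S or of its
# complement on the rooted tree (root at taxon 1), which is equivalent for
# unrooted split containment.
oracle_splits <- function(phy) {
  taxa <- sort(phy$tip.label)
  ref <- taxa[1]
  rooted <- ape::root(phy, outgroup = ref, resolve.root = TRUE)
  n <- length(taxa)
  sides <- list()
  others <- setdiff(taxa, ref)
  for (k in 2:(n - 2)) {
    for (idx in utils::combn(length(others), k, simplify = FALSE)) {
      S <- others[idx]
      if (ape::is.monophyletic(rooted, S)) sides[[length(sides) + 1]] <- sort(S)
    }
  }
  sides
}

oracle_rf <- function(t1, t2) {
  s1 <- vapply(oracle_splits(t1), paste, "", collapse = "|")
  s2 <- vapply(oracle_splits(t2), paste, "", collapse = "|")
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# quartet pairing by explicit restriction and split extraction (independent
# of the four-point-condition engine)
oracle_quartet_pairing <- function(phy, q) {
  q <- sort(q)
  r <- restrict_tree(phy, q)
  sp <- tryCatch(extract_splits(ape::unroot(r)), error = function(e) list())
  if (length(sp) == 0) return("unresolved")
  side <- sp[[1]]$side
  other <- setdiff(q, side)
  a <- sort(if (q[1] %in% side) side else other)
  b <- sort(setdiff(q, a))
  paste0(a[1], ",", a[2], "|", b[1], ",", b[2])
}

oracle_quartet_score <- function(species, genes) {
  agree <- 0; resolved <- 0
  for (gt in genes) {
    shared <- sort(intersect(gt$tip.label, species$tip.label))
    for (idx in utils::combn(length(shared), 4, simplify = FALSE)) {
      q <- shared[idx]
      pg <- oracle_quartet_pairing(gt, q)
      if (pg == "unresolved") next
      resolved <- resolved + 1
      if (pg == oracle_quartet_pairing(species, q)) agree <- agree + 1
    }
  }
  list(agreeing = agree, total_resolved = resolved,
       normalized = agree / resolved)
}

# Procrustes root-mean-square misfit after centering and optimal rotation
# (no scaling)
procrustes_rms <- function(X, Y) {
  X <- scale(X, scale = FALSE); Y <- scale(Y, scale = FALSE)
  s <- svd(crossprod(X, Y))
  R <- s$u %*% t(s$v)
  sqrt(mean((X %*% R - Y)^2))
}

# quick locus fixture
toy_locus <- function(id = "loc1", seqs = c(a = "ACGTACGT", b = "ACGTACGA",
                                            c = "ACGAACGA", d = "ACGAACGT")) {
  locus_alignment(id, seqs)
}

# simulated alignment on a fixed tree with signal
signal_locus <- function(n_taxa = 6, len = 500, rate = 0.1, seed = 42) {
  sp <- simulate_yule_tree(n_taxa, seed = seed)
  simulate_sequences(sp, len, rate_scale = rate, locus_id = "sig",
                     seed = seed + 1)
}
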