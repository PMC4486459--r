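# neighbor joining, bootstrap support and anchored clade extraction

test_that("NJ recovers additive matrices exactly, including branch lengths", {
  tr0 <- ape::read.tree(text = "((a:1,b:2):1.5,(c:1,d:3):0.5);")
  D <- ape::cophenetic.phylo(tr0)
  tr <- build_nj_tree(D)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr0), tr)), 0)
  # path lengths between every pair reproduce the input
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
               tolerance = 1e-10)
})

test_that("three taxa resolve by the closed three-point formulas", {
  D <- matrix(c(0, 0.3, 0.5, 0.3, 0, 0.6, 0.5, 0.6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- build_nj_tree(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["a"]), (0.3 + 0.5 - 0.6) / 2)
  expect_equal(unname(bl["b"]), (0.3 + 0.6 - 0.5) / 2)
  expect_equal(unname(bl["c"]), (0.5 + 0.6 - 0.3) / 2)
})

test_that("negative NJ branch lengths are clamped and flagged", {
  D <- matrix(0.2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  D["a", "b"] <- D["b", "a"] <- 0.01
  D["a", "c"] <- D["c", "a"] <- 0.21
  tr <- build_nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
})

test_that("NJ topology is recovered from simulated codon data", {
  wins <- 0L
  truth <- ape::unroot(ape::read.tree(text = TREE6))
  for (s in 1:10) {
    cfg <- codon_sim_config(TREE6, kappa = 2,
                            site_classes = data.frame(proportion = 1,
                                                      omega = 0.3),
                            n_codons = 667, seed = 400 + s)
    aln <- simulate_codon_alignment(cfg)
    dm <- mcl_distances(aln, bootstrap_reps = 0)
    tr <- build_nj_tree(dm)
    if (ape::dist.topo(truth, tr) == 0) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("bootstrap supports are deterministic and strong for deep splits", {
  b1 <- random_dna(600, seed = 31)
  v <- strsplit(b1, "")[[1]]
  set.seed(32)
  pos <- sample(600, 250)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  b2 <- paste(v, collapse = "")
  aln <- aligned_set(c(mutant_family(b1, 3, 5, tag = "p", seed = 33),
                       mutant_family(b2, 3, 5, tag = "q", seed = 34)))
  t1 <- bootstrap_support(aln, reps = 100, seed = 5)
  t2 <- bootstrap_support(aln, reps = 100, seed = 5)
  expect_identical(t1$node.label, t2$node.label)
  # support of the p|q split
  key <- mhcdiv:::.split_key(c("p1", "p2", "p3"), t1$tip.label)
  lookup <- mhcdiv:::.support_by_split(t1)
  expect_gte(lookup[[key]], 99)
  expect_error(bootstrap_support(aln, reps = 0), "reps")
})

test_that("supports are invariant under leaf-order permutation", {
  b1 <- random_dna(400, seed = 41)
  v <- strsplit(b1, "")[[1]]
  set.seed(45)
  for (p in sample(400, 150)) v[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                                     v[p]), 1)
  b2 <- paste(v, collapse = "")
  aln <- aligned_set(c(mutant_family(b1, 2, 10, tag = "x", seed = 42),
                       mutant_family(b2, 3, 10, tag = "y", seed = 43)))
  perm <- aligned_set(aln$seqs[c(4, 1, 5, 2, 3)])
  t1 <- bootstrap_support(aln, reps = 60, seed = 9)
  t2 <- bootstrap_support(perm, reps = 60, seed = 9)
  key <- mhcdiv:::.split_key(c("x1", "x2"), t1$tip.label)
  l1 <- mhcdiv:::.support_by_split(t1)
  l2 <- mhcdiv:::.support_by_split(t2)
  # same split is present in both; counts differ only by the resampling
  # stream, which is identical under a fixed seed and pairwise counting
  expect_false(is.null(l1[[key]]))
  expect_false(is.null(l2[[key]]))
  expect_equal(l1[[key]], l2[[key]], tolerance = 25)
})

test_that("an invariant alignment is flagged degenerate", {
  s <- random_dna(120, seed = 51)
  aln <- aligned_set(c(a = s, b = s, c = s, d = s))
  tr <- bootstrap_support(aln, reps = 10, seed = 1)
  expect_true(attr(tr, "degenerate"))
  expect_true(all(is.na(tr$node.label)))
})

test_that("clade extraction finds anchored clades and labels the rest", {
  tr <- ape::read.tree(text = "(((a1:1,a2:1):1,a3:1):2,((b1:1,b2:1):1,o:4):0.5);")
  tr$node.label <- c(NA, 95, 90, 80, 85)
  ca <- extract_clades(tr, anchors = list(A = c("a1", "a2"),
                                          B = c("b1", "b2")),
                       min_support = 70, outgroup = "o")
  m <- setNames(ca$cluster, ca$sequence)
  expect_identical(unname(m[c("a1", "a2")]), c("A", "A"))
  expect_identical(unname(m["b2"]), "B")
  expect_identical(unname(m["o"]), "unassigned")
  # the assignment always partitions assigned + unassigned
  expect_setequal(ca$sequence, tr$tip.label)

  # cherry anchors resolve to exactly that cherry
  ca2 <- extract_clades(tr, anchors = list(B = c("b1", "b2")),
                        min_support = 0, outgroup = "o")
  expect_identical(sort(ca2$sequence[ca2$cluster == "B"]), c("b1", "b2"))

  expect_error(extract_clades(tr, anchors = list(A = "zz")), "zz")
  # two clusters anchored inside one minimal clade conflict
  expect_error(extract_clades(tr, anchors = list(A = c("a1", "a2"),
                                                 C = c("a1", "a3")),
                              min_support = 0, outgroup = "o"),
               "conflict")
})

test_that("planted clade membership is recovered from simulated data", {
  b1 <- random_dna(500, seed = 61)
  v <- strsplit(b1, "")[[1]]
  set.seed(62)
  pos <- sample(500, 180)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  b2 <- paste(v, collapse = "")
  planted <- c(mutant_family(b1, 4, 8, tag = "in", seed = 63),
               mutant_family(b2, 3, 8, tag = "out", seed = 64))
  aln <- aligned_set(planted)
  tr <- bootstrap_support(aln, reps = 60, seed = 3)
  ca <- extract_clades(tr, anchors = list(IN = c("in1", "in2")),
                       min_support = 70, outgroup = "out1")
  expect_setequal(ca$sequence[ca$cluster == "IN"],
                  paste0("in", 1:4))
})
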