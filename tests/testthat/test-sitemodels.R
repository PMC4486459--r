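# codon site models: likelihood oracle equivalence, nesting, LRT
# mechanics, posteriors and the consensus site caller

test_that("pruning likelihood equals brute-force ancestral summation", {
  # 3 sequences x 5 codons
  cfg <- codon_sim_config("(a:0.3,b:0.2,c:0.4);", kappa = 2,
                          site_classes = data.frame(proportion = 1,
                                                    omega = 0.6),
                          n_codons = 5, seed = 71)
  aln <- simulate_codon_alignment(cfg)
  tr <- cfg$tree
  pi <- f3x4_frequencies(aln)
  for (pars in list(c(2, 0.6), c(1.3, 1.8))) {
    Q <- mhcdiv:::codon_rate_matrix(pars[1], pars[2], pi)
    dec <- mhcdiv:::codon_eigen(Q / mhcdiv:::codon_mean_rate(Q, pi), pi)
    tr2 <- ape::reorder.phylo(tr, "postorder")
    st <- mhcdiv:::encode_codon_states(aln)[tr2$tip.label, , drop = FALSE]
    kernel <- sum(mhcdiv:::codon_class_loglik(
      matrix(dec$lambda), array(dec$U, c(61, 61, 1)),
      array(dec$Uinv, c(61, 61, 1)), tr2$edge, tr2$edge.length, st, pi,
      length(tr2$tip.label) + tr2$Nnode))
    oracle <- brute_force_codon_lnl(aln, tr, pars[1], pars[2])
    expect_equal(kernel, oracle, tolerance = 1e-8)
  }
})

test_that("invariant alignments give a degenerate fit at the multinomial constant", {
  s <- paste(rep("ATGGCC", 10), collapse = "")
  aln <- aligned_set(c(a = s, b = s, c = s))
  tr <- ape::read.tree(text = "(a:0.1,b:0.1,c:0.1);")
  fit <- fit_site_model(aln, tr, "M0")
  expect_true(fit$degenerate)
  pi <- f3x4_frequencies(aln)
  st <- mhcdiv:::encode_codon_states(aln)
  expect_equal(fit$lnL, sum(log(pi[st[1, ]])))
})

test_that("internal stop codons are rejected with sequence and position", {
  aln_ok <- c(a = "ATGTAAGCC")   # TAA at codon 2 of 3
  expect_error(fit_site_model(aligned_set(aln_ok),
                              ape::read.tree(text = "(a:1,b:1,c:1);")),
               "internal stop codon in sequence 'a' at codon position\\(s\\) 2")
})

test_that("alternative models dominate their nulls and posteriors are proper", {
  cfg <- codon_sim_config(TREE6, kappa = 2,
                          site_classes = data.frame(
                            proportion = c(0.6, 0.3, 0.1),
                            omega = c(0.1, 1, 4)),
                          n_codons = 200, seed = 81)
  aln <- simulate_codon_alignment(cfg)
  tr <- cfg$tree
  f0 <- fit_site_model(aln, tr, "M0")
  f1 <- fit_site_model(aln, tr, "M1a")
  f2 <- fit_site_model(aln, tr, "M2a")
  f3 <- fit_site_model(aln, tr, "M3")
  expect_gte(f2$lnL, f1$lnL - 1e-6)
  expect_gte(f3$lnL, f0$lnL - 1e-6)
  # posterior rows sum to 1
  expect_equal(rowSums(f2$per_site_posterior),
               rep(1, 200), tolerance = 1e-9)
  # M1a respects its constraints
  expect_lte(f1$class_params$omega[1], 1)
  expect_equal(f1$class_params$omega[2], 1)
  expect_gte(f2$class_params$omega[3], 1)
})

test_that("LRT mechanics follow the chi-square df = 2 contract", {
  f1 <- structure(list(model_id = "M1a", lnL = -100), class = "site_model_fit")
  f2 <- structure(list(model_id = "M2a", lnL = -100), class = "site_model_fit")
  r <- lrt(f1, f2)
  expect_equal(r$stat, 0)
  expect_equal(r$p_value, 1)
  # chi-square quantile identity
  f3 <- structure(list(model_id = "M2a", lnL = -100 + 5.991 / 2),
                  class = "site_model_fit")
  expect_equal(lrt(f1, f3)$p_value, 0.05, tolerance = 1e-3)
  # clamped when the alternative lands below the null
  f4 <- structure(list(model_id = "M2a", lnL = -101), class = "site_model_fit")
  expect_equal(lrt(f1, f4)$stat, 0)
  # non-nested pairs refused
  f0 <- structure(list(model_id = "M0", lnL = -90), class = "site_model_fit")
  expect_error(lrt(f0, f2), "nested")
})

test_that("consensus site caller is empty under purifying selection", {
  cfg <- codon_sim_config(TREE6, kappa = 2,
                          site_classes = data.frame(proportion = 1,
                                                    omega = 0.2),
                          n_codons = 200, seed = 91)
  aln <- simulate_codon_alignment(cfg)
  fits <- list(M2a = fit_site_model(aln, cfg$tree, "M2a"),
               M3 = fit_site_model(aln, cfg$tree, "M3"))
  sel <- selected_sites(fits, threshold = 0.9, min_models = 2)
  expect_equal(sum(sel$selected), 0)
  expect_error(selected_sites(list(M2a = fits$M2a, bogus = fits$M3)),
               "named")
})

test_that("selected_sites enforces matching alignment lengths", {
  fA <- structure(list(model_id = "M2a", n_sites = 10,
                       p_positive = rep(0, 10)), class = "site_model_fit")
  fB <- structure(list(model_id = "M3", n_sites = 12,
                       p_positive = rep(0, 12)), class = "site_model_fit")
  expect_error(selected_sites(list(M2a = fA, M3 = fB)), "different lengths")
})

test_that("planted selected sites are recovered by the 2-of-3 consensus at MHC-scale divergence", {
  # 12 taxa, 500 codons, 10% of sites at omega = 4, total tree length
  # ~3.3 expected substitutions/codon (the divergence regime of the
  # expanded MHC class I lineages this package targets)
  tr12txt <- paste0("(((a:0.2,b:0.24):0.1,(c:0.16,d:0.2):0.12):0.08,",
                    "((e:0.2,f:0.18):0.1,(g:0.22,h:0.2):0.08):0.1,",
                    "((i:0.2,j:0.16):0.12,(k:0.18,l:0.24):0.1):0.08);")
  tr12 <- ape::read.tree(text = tr12txt)
  cfg <- codon_sim_config(tr12txt, kappa = 2,
    site_classes = data.frame(proportion = c(0.6, 0.3, 0.1),
                              omega = c(0.1, 1, 4)),
    n_codons = 500, seed = 4001)
  aln <- simulate_codon_alignment(cfg)
  fits <- list(M2a = fit_site_model(aln, tr12, "M2a"),
               M3 = fit_site_model(aln, tr12, "M3"),
               M8 = fit_site_model(aln, tr12, "M8"))
  sel <- selected_sites(fits)
  truth <- which(attr(aln, "site_omega") > 1)
  called <- sel$site[sel$selected]
  sens <- length(intersect(called, truth)) / length(truth)
  fpr <- length(setdiff(called, truth)) / (500 - length(truth))
  expect_gte(sens, 0.5)
  expect_lte(fpr, 0.05)
})
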