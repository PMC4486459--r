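# translation to mature numbering and PBR variability tabulation

# build an aligned_set of coding sequences from residue specs:
# residues[[lineage]][[seq]] = named vector position -> amino acid
codon_for <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
               Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
               L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
               S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

make_protein_alignment <- function(seq_residues, n_positions = 160,
                                   offset = 0) {
  seqs <- vapply(seq_residues, function(res) {
    aa <- rep("A", n_positions + offset)
    if (length(res)) aa[as.integer(names(res)) + offset] <- res
    paste(codon_for[aa], collapse = "")
  }, "")
  aligned_set(seqs)
}

test_that("translation arithmetic and mature renumbering are correct", {
  # a 1041-bp cDNA: 347 codons = 346 residues + terminal stop
  s <- paste0(paste(rep("GCT", 346), collapse = ""), "TAA")
  expect_equal(nchar(s), 1041)
  m <- translate_and_number(aligned_set(c(x = s)), numbering_offset = 24)
  expect_equal(ncol(m), 346)
  expect_equal(colnames(m)[1], "-23")
  expect_equal(colnames(m)[25], "1")      # first mature residue
  expect_equal(colnames(m)[346], "322")

  # offset 0 keeps identity numbering
  m0 <- translate_and_number(aligned_set(c(x = s)), numbering_offset = 0)
  expect_equal(colnames(m0)[1], "1")

  # reverse complement lands stops internally and trips the frame check
  fwd <- paste0("GCTTTA", paste(rep("GCT", 344), collapse = ""), "TAA")
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(fwd, "")[[1]]),
                                     collapse = ""))
  expect_error(translate_and_number(aligned_set(c(x = rc))),
               "internal stop")
  expect_error(translate_and_number(aligned_set(c(x = "ATGCC"))),
               "divisible")
})

test_that("single sequences have no variable positions", {
  aln <- make_protein_alignment(list(s1 = c("9" = "K", "24" = "F")))
  prot <- translate_and_number(aln, numbering_offset = 0)
  tab <- tabulate_variability(prot, c(s1 = "L1"), peptide_contact_map(),
                              numbering_offset = 0)
  expect_equal(sum(tab$variable), 0)
  expect_true(all(tab$covered))
})

test_that("variability, sharing and selection flags follow the construction", {
  # two lineages; position 24 variable and disjoint between lineages,
  # position 9 variable with a shared residue, position 62 invariant
  aln <- make_protein_alignment(list(
    a1 = c("24" = "F", "9" = "K"),
    a2 = c("24" = "Y", "9" = "R"),
    b1 = c("24" = "L", "9" = "K"),
    b2 = c("24" = "I", "9" = "R")))
  prot <- translate_and_number(aln, numbering_offset = 0)
  lin <- c(a1 = "GA", a2 = "GA", b1 = "GB", b2 = "GB")
  sel <- data.frame(site = c(24, 150), selected = TRUE)
  tab <- tabulate_variability(prot, lin, peptide_contact_map(),
                              selected = sel, numbering_offset = 0)
  r24 <- tab[tab$position == 24, ]
  expect_true(r24$variable)
  expect_equal(r24$n_shared, 0)
  expect_true(r24$selected)
  r9 <- tab[tab$position == 9, ]
  expect_true(r9$variable)
  expect_equal(r9$n_shared, 2)     # K and R both occur in both lineages
  r62 <- tab[tab$position == 62, ]
  expect_false(r62$variable)
  expect_false(r62$selected)

  # shared residue counts by hand: variable positions are 9 (shared) and
  # 24 (disjoint)
  expect_equal(shared_residue_counts(tab, c("GA", "GB")), 1L)
  # identical lineages: every variable position the lineage covers
  expect_equal(shared_residue_counts(tab, c("GA", "GA")), 2L)
  expect_error(shared_residue_counts(tab, c("GA", "nope")), "unknown")
})

test_that("positions missing from the alignment are listed, not dropped", {
  aln <- make_protein_alignment(list(s1 = c("9" = "K"), s2 = c("9" = "R")),
                                n_positions = 100)  # map runs to 156
  prot <- translate_and_number(aln, numbering_offset = 0)
  tab <- tabulate_variability(prot, c(s1 = "L1", s2 = "L1"),
                              peptide_contact_map(), numbering_offset = 0)
  unc <- attr(tab, "uncovered")
  expect_true(all(unc > 100))
  expect_equal(nrow(tab) + length(unc), nrow(peptide_contact_map()))
})

test_that("shipped contact maps satisfy their documented structure", {
  cmap <- peptide_contact_map()
  expect_equal(nrow(cmap), 35)
  expect_true(all(cmap$mhc_pos >= 1 & cmap$mhc_pos <= 182))
  expect_true(all(unlist(cmap$peptide_positions) %in% 1:9))
  kir <- kir_contact_set()
  expect_equal(nrow(kir), 14)
  expect_setequal(kir$mhc_pos[kir$critical], c(80, 83, 142, 146, 149))
  expect_true(all(kir$mhc_pos[kir$critical] %in% kir$mhc_pos))
})
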