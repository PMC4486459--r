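# mhcdiv

Diversification analysis of expanded MHC class I multigene families.

Expanded MHC class I gene families — such as the MHC-G-like and MHC-B
lineages of New World monkeys — evolve by birth-and-death: loci arise
by duplication, diverge under diversifying selection concentrated on
the peptide-binding region (PBR), and are lost from some haplotypes.
Working from cloned full-length cDNA sets in a diploid population,
`mhcdiv` provides the complete analysis chain:

* **Distances** — maximum composite likelihood pairwise distances under
  a Tamura–Nei model with rate parameters shared across all pairs, and
  site-resampling bootstrap standard errors (`mcl_distances()`,
  `group_distance()`).
* **Trees** — neighbor joining, bipartition-keyed bootstrap support,
  and anchored clade extraction (`build_nj_tree()`,
  `bootstrap_support()`, `extract_clades()`).
* **Locus assignment & copy number** — the coarsest tree-consistent
  grouping of alleles compatible with diploidy (≤ 2 alleles per
  individual per locus), and detection of haplotype gene-content
  variation (`assign_loci()`, `detect_cnv()`).
* **Positive selection** — maximum likelihood codon site models M0,
  M1a, M2a, M3 and M8 (GY94 rate matrix, F3X4 frequencies, compiled
  pruning kernel), likelihood ratio tests, and empirical Bayes
  identification of positively selected sites under a 2-of-3 model
  consensus (`fit_site_model()`, `lrt()`, `selected_sites()`).
* **PBR variability** — translation to mature-protein numbering and
  per-position variability tables against structure-derived peptide and
  KIR contact maps (`translate_and_number()`,
  `tabulate_variability()`).
* **MHC:KIR scoring** — interface hydrogen-bond detection, atomic
  contact desolvation energy, the interaction index
  `I = k·h / ln|dG|`, and threshold calibration on labeled pairs
  (`detect_interface_hbonds()`, `desolvation_energy()`,
  `interaction_index()`, `calibrate_and_classify()`).
* **Simulators with known truth** for every stage, and an end-to-end,
  cached, deterministic `run_pipeline()`.

## Worked example

Simulate a 12-individual population carrying four loci with variable
gene content, then recover the structure:

```r
library(mhcdiv)

cfg <- population_sim_config(
  n_individuals = 12,
  loci = data.frame(locus_name = paste0("locus", 1:4),
                    allele_pool_size = 6, presence_probability = 0.7),
  seed = 5017)
sim <- simulate_population_alleles(cfg)
aln <- aligned_set(sim$sequences)

dm <- mcl_distances(aln, bootstrap_reps = 200, seed = 1)
dm
#> mcl_dist: 20 sequences; mean pairwise d = 0.2546
#>   shared rates: k1 = 0.9938  k2 = 1.009

round(group_distance(dm, list(dm$labels), mode = "within"), 4)
#>   mean     se
#> 0.2546 0.0103

tree <- bootstrap_support(aln, reps = 100, seed = 2)
part <- assign_loci(tree, sim$genotypes)
part
#> locus_partition: 4 group(s); valid
#>   L1 : 4 sequence(s)
#>   L2 : 6 sequence(s)
#>   L3 : 5 sequence(s)
#>   L4 : 5 sequence(s)

detect_cnv(part, sim$genotypes)
#> cnv_report: haplotypic gene-content variation DETECTED
#>   groups with absent carriers: L1, L2, L3

inferred <- rep(names(part$groups), lengths(part$groups))
names(inferred) <- unlist(part$groups)
adjusted_rand_index(sim$locus_of[names(inferred)], inferred)
#> [1] 1
```

Scan for positive selection on a simulated alignment with 10% of sites
at ω = 4:

```r
scfg <- codon_sim_config(
  "((a:0.15,b:0.2):0.1,(c:0.12,d:0.18):0.08,(e:0.2,f:0.1):0.12);",
  kappa = 2,
  site_classes = data.frame(proportion = c(0.6, 0.3, 0.1),
                            omega = c(0.1, 1, 4)),
  n_codons = 300, seed = 11)
saln <- simulate_codon_alignment(scfg)

f2 <- fit_site_model(saln, scfg$tree, "M2a")
f2
#> Codon site model M2a
#>   lnL = -2752.9389   kappa = 2.349   tree scale = 0.9373
#>   site classes:
#>   proportion  omega
#> 1     0.5334 0.0760
#> 2     0.4205 1.0000
#> 3     0.0460 4.4937

lrt(fit_site_model(saln, scfg$tree, "M1a"), f2)
#> LRT M1a vs M2a: 2dL = 13.8960, df = 2, p = 0.0009606
```

The test rejects neutrality decisively, and every site called by the
2-of-3 consensus (`selected_sites()`) on this alignment is a planted
ω = 4 site. Per-site recall depends strongly on divergence: at this
shallow 6-taxon tree only the strongest sites exceed posterior 0.9,
while at MHC-scale divergence (12 taxa, total tree length ≈ 3.3
substitutions/codon, 500 codons) the same consensus recovers 30 sites
— all planted — out of 47 (sensitivity 0.64, zero false positives).

Score a toy MHC:KIR complex with planted interface hydrogen bonds:

```r
s <- generate_toy_complex(complex_sim_config(8, n_decoy_atoms = 100,
                                             seed = 5))
hb <- detect_interface_hbonds(s)
hb
#> hbond_list: 8 interface hydrogen bond(s) (heavy-atom proxy geometry)

interaction_index(hb, desolvation_energy(s), k = 5)
#> interaction_score: h = 8, dG = 2.800 kcal/mol, k = 5.00, I = 38.8493
```

## Analysing the reference cDNA sets

The package's reference inputs are public GenBank records — the
*Cebus albifrons* population set of 29 MHC-G-like plus 22 MHC-B unique
cDNAs (KM219732–KM219782) and a nine-species panel (KM219682–KM219731);
`genbank_accessions()` lists them. They are fetched once by the user
(this repository ships no sequence data), aligned with any standard
aligner, and loaded with `load_population_cdnas()`; all analyses above
then apply directly. The acceptance tests in
`tests/testthat/test-acceptance.R` encode the expected reference
results (mean lineage distances, cluster sizes, locus counts, selected
PBR positions) and fail with an actionable message until the file
`tests/testthat/data/cebus_population.fasta` exists.

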