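---
title: "Methods: diversification analysis of expanded MHC class I families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversification analysis of expanded MHC class I families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhcdiv)
```

This vignette documents the statistical methods behind each stage of the
package, the default parameter choices and why they were made, and the
known limitations. The intended workflow is the analysis of cloned
full-length MHC class I cDNA sets from a diploid population: pairwise
distances and a clustered tree, allele-to-locus assignment with
haplotype gene-content (copy-number) inference, detection of positive
selection at codon sites, tabulation of peptide-binding-region (PBR)
variability against a structural contact map, and a structure-based
score for MHC:KIR receptor pairings.

## 1. Pairwise distances: composite likelihood under Tamura–Nei

`mcl_distances()` estimates all pairwise distances under a Tamura–Nei
(TN93) substitution model in which the base frequencies $\pi$ and the
two transition/transversion rate ratios $\kappa_1$ (A$\leftrightarrow$G)
and $\kappa_2$ (C$\leftrightarrow$T) are **shared across every pair**,
while each pair $ij$ keeps its own divergence $t_{ij}$. The estimator
maximizes the composite likelihood

$$\ell(\kappa_1, \kappa_2, \{t_{ij}\}) =
  \sum_{i<j} \sum_{x,y} F^{(ij)}_{xy} \,
  \log\!\big[\pi_x \, P_{xy}(t_{ij}; \kappa_1, \kappa_2, \pi)\big],$$

where $F^{(ij)}$ is the symmetrized site-pattern count matrix of the
pair. This is the "Maximum Composite Likelihood" distance familiar from
standard phylogenetic software; sharing the rate parameters stabilizes
them when individual pairs are short or closely related. The
maximization alternates between the shared rates (BFGS on log scale,
bounded to $e^{\pm 10}$, beyond which the ratios are unidentifiable)
and the per-pair divergences (1-D likelihood maximization), initialized
from the closed-form TN93 inversion (`tn93_closed_form()`).

Choices and conventions:

* **Gaps and ambiguous bases** are removed by *pairwise deletion*: a
  column is dropped only for the pairs in which it is not A/C/G/T.
* **Saturated pairs**, where the closed-form inversion diverges, are
  reported as `NaN` and flagged in `$saturated`; they are never capped
  at an arbitrary large value.
* **Standard errors** come from a site-resampling bootstrap (default
  1000 replicates). The shared rate parameters are held at their
  full-data estimates across replicates; re-estimating them on every
  replicate changes the SEs negligibly at these sequence lengths and
  costs an order of magnitude more time.
* `group_distance()` averages the relevant matrix cells (within or
  between groups of labels) and propagates the bootstrap replicates of
  the *mean*, which correctly accounts for the correlation between
  pair distances that share sequences.

## 2. Trees: neighbor joining, bootstrap support, clade extraction

`build_nj_tree()` applies Saitou–Nei neighbor joining (via `ape::nj`,
an exact implementation of a standard algorithm) to the distance
matrix; NJ is exact on additive matrices. Negative branch lengths, an
NJ artifact on noisy input, are clamped to zero and flagged.

`bootstrap_support()` resamples alignment columns, rebuilds the
distance matrix and NJ tree per replicate with the same pipeline, and
reports the percentage of replicates containing each bipartition of the
full-data tree. Supports are keyed by the *bipartition* (canonical
split of the tip set), not by node numbers, so they are invariant to
tip order and rerooting. A fixed seed gives byte-identical results.

`extract_clades()` assigns sequences to named clusters by climbing from
user-supplied anchor sequences to the smallest clade that contains all
anchors of a cluster and has bootstrap support at or above
`min_support` (default 70, the conventional "well supported"
threshold). Sequences captured by no anchored clade are reported as
`"unassigned"` rather than forced into a cluster; two clusters whose
minimal clades overlap are an error, not a silent merge.

## 3. Locus assignment and haplotype gene content

In a diploid individual, one locus contributes at most two alleles.
`assign_loci()` exploits this: given the tree and a presence matrix
(individuals × sequences), it finds the **coarsest partition of the
tips into tree-consistent groups (clades)** such that no individual
carries more than `max_alleles` (default 2) sequences of any group.
The search descends from the root, splitting a clade only when it
violates the constraint, so the result is the unique maximal antichain
of valid clades. If even single tips violate the constraint (more than
two identical cDNAs in one individual), the partition is returned with
`valid = FALSE` and downstream steps refuse to run.

`detect_cnv()` then reports haplotype gene-content variation: an
individual that carries **no** allele of a locus group that other
individuals do carry lacks that locus on both chromosomes. This is the
operational signature of birth-and-death evolution (locus presence
varying between haplotypes) accessible from cDNA data alone; it cannot
distinguish true absence from non-expression, which is a documented
limitation of expression-based genotyping.

## 4. Positive selection: codon site models

`fit_site_model()` implements maximum-likelihood codon models in the
Goldman–Yang (GY94) family. The instantaneous rate of codon $u \to v$
differing at one position is

$$q_{uv} = \begin{cases}
  \pi_v & \text{synonymous transversion} \\
  \kappa\,\pi_v & \text{synonymous transition} \\
  \omega\,\pi_v & \text{nonsynonymous transversion} \\
  \omega\kappa\,\pi_v & \text{nonsynonymous transition,}
\end{cases}$$

over the 61 sense codons with target frequencies $\pi$ estimated from
the data by F3X4. The supported site models are M0 (one $\omega$), M1a
(nearly neutral: $\omega_0 < 1$, $\omega_1 = 1$), M2a (M1a plus
$\omega_2 \ge 1$), M3 (three free discrete classes), and M8 (a
10-category discretized beta for $\omega \in (0,1)$ — equal-probability
categories represented by their medians, the standard discretization —
plus a selection class $\omega_s \ge 1$). The mixture likelihood is
computed by Felsenstein pruning over site patterns and $\omega$
classes (compiled kernel), with the rate matrix rescaled so branch
lengths are expected substitutions per codon under the fitted mixture;
a free scale parameter multiplies the guide-tree branch lengths, so
only the guide topology (from the distance tree) is taken as fixed.

Constraints are enforced through unconstrained reparameterizations
(log, logit, softmax, $1 + e^x$ for $\omega \ge 1$ classes), optimized
by BFGS from multiple starting points. The beta shapes of M8 are
bounded to $[0.005, 99]$, the conventional identifiable range.

Inference follows the standard recipe:

* **LRTs** (`lrt()`): M1a vs M2a, M1a vs M8, M0 vs M3, statistic
  $2\Delta\ell$ clamped at 0 and referred to $\chi^2_2$. This is the
  common df = 2 convention; it is conservative for M1a vs M2a where the
  null lies on a boundary.
* **Site identification** (`selected_sites()`): *naive empirical
  Bayes* (NEB) posterior probabilities that each site belongs to an
  $\omega > 1$ class, with a consensus rule — a site is called
  positively selected when **at least 2 of the 3** alternative models
  (M2a, M3, M8) give it posterior $> 0.9$. NEB rather than BEB is a
  deliberate simplification: BEB integrates over parameter uncertainty
  and differs mainly in small or weakly informative alignments. The
  consensus-across-models rule absorbs much of the difference; the
  acceptance contract for reproducing reference analyses therefore
  allows a $\pm 2$ position margin.

Power characteristics (from this package's own seeded studies, see
`tests/testthat/test-acceptance.R`): with 6 sequences and 500 codons
the M1a-vs-M2a LRT rejects in 20/20 simulated positive-selection data
sets and in 1/20 null data sets; per-site NEB recovery of planted
$\omega = 4$ sites reaches sensitivity $\approx 0.64$ at false positive
rate $< 0.01$ at MHC-scale divergence (12 sequences, total tree length
$\approx 3.3$ substitutions/codon). At substantially lower divergence
per-site power drops well below 0.5 — site detection needs signal, and
users should check their tree length before interpreting an empty site
list as absence of selection.

## 5. PBR variability tables

`translate_and_number()` translates cDNAs and renumbers columns to the
mature protein. The default `numbering_offset = 24` corresponds to the
24-residue signal peptide of classical MHC class I precursors, so
column "1" is the first residue of the mature chain — the numbering
used throughout the MHC structural literature. `tabulate_variability()`
then reports, for each position of a structure-derived contact map,
whether it is variable (≥ 2 residues observed), which residues each
lineage carries, how many residues are shared between lineages, and
whether the position was called positively selected.

Two contact maps ship as editable TSVs under `inst/extdata/`:
`peptide_contacts.tsv` (35 peptide-contacting PBR positions with the
peptide positions they touch) and `kir_contacts.tsv` (14 KIR-contacting
positions, 5 of them critical for docking: 80, 83, 142, 146, 149).
Both files are approximate transcriptions completed with canonical
class I groove/footprint positions and are flagged as such in their
headers; users with better structural assignments should swap the
files via the `path` argument of the loaders.

## 6. Structure-based MHC:KIR interaction index

For a two-chain complex (`read_complex_pdb()`), three quantities are
computed:

* **Interface hydrogen bonds** (`detect_interface_hbonds()`): N/O
  donor–acceptor pairs across the interface with heavy-atom distance
  ≤ 3.5 Å and, when no hydrogens are present (the usual case for
  models), an antecedent-carbon angle proxy ≥ 90°; with explicit
  hydrogens, D–H…A ≥ 120°. These are standard geometric criteria; each
  donor–acceptor pair counts once.
* **Desolvation energy** (`desolvation_energy()`): sum of atomic
  contact energies over all cross-interface heavy-atom pairs within
  6 Å, using an 18-type atomic contact potential shipped as a TSV
  (`contact_energy_synthetic.tsv`). The shipped table is a synthetic,
  internally consistent potential (the literature table behind the
  published contact-energy approach is not reproducible from public
  text); every structural property of the package is table-agnostic,
  and the table is swappable via `table_path`.
* **Interaction index** (`interaction_index()`):
  $I = k\,h / \ln|\Delta G|$ with $k$ = average hydrogen-bond energy,
  default **5 kcal/mol** (mid-range literature value; $k$ rescales $I$
  linearly and cannot change a calibrated classification). The
  logarithm uses $|\Delta G|$, and $|\Delta G| \le 1$ is reported as
  *indeterminate* rather than produce a sign flip or division blow-up;
  $h = 0$ gives $I = 0$.

`calibrate_and_classify()` picks the score threshold minimizing total
misclassification on labeled pairs (ties broken toward the midpoint
between class means) and reports FP/FN/total error. On separated
classes the error is 0; on overlapping unit-variance Gaussians one
mean apart the empirical error lands within a fraction of a point of
the Bayes error $\Phi(-1/2) \approx 0.309$.

## 7. Simulators and the pipeline

Every stage has a seeded generator with a known truth:
`simulate_codon_alignment()` (GY94 mixture evolution along a tree,
recording each site's $\omega$ class), `simulate_population_alleles()`
(multilocus diploid population with allele pools per locus and
per-haplotype locus presence, recording the true locus of every allele
and the true gene content of every individual), and
`generate_toy_complex()` (two-chain atom sets with geometrically
guaranteed planted hydrogen bonds and unreachable decoys).

`run_pipeline()` chains the stages through plain files (FASTA, Newick,
TSV, JSON) under an output directory, caches each stage keyed on a
hash of its config block, and writes a deterministic `report.json`:
identical config and seed give an identical report body.

## Known limitations

* NEB (not BEB) site posteriors; mitigated by the 2-of-3 consensus and
  the documented ±2-position margin.
* The guide topology is fixed during site-model fitting (branch
  lengths are rescaled by one free factor, not re-fit individually).
* cDNA-based genotyping cannot distinguish locus absence from
  non-expression.
* The contact-energy table and both contact maps are approximate,
  clearly flagged, and swappable.
* The composite-likelihood distance SEs condition on the shared rate
  estimates.
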