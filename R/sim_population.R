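#' Configuration for the diploid multilocus population simulator
#'
#' Emulates a population of cloned cDNAs from a multigene family: several
#' loci that diverged from a common ancestor (a star phylogeny of locus
#' founders), polymorphic allele pools within each locus, and haplotypes
#' that may lack a locus entirely (gene-content variation).
#'
#' @param n_individuals number of diploid individuals.
#' @param loci data.frame with columns `locus_name`, `allele_pool_size`,
#'   `presence_probability` (per haplotype). Default: 4 loci, pool size 6,
#'   presence 0.8 each.
#' @param divergence_between_loci expected substitutions/site separating
#'   each locus founder from the common ancestor (default 0.12, matching
#'   the ~10-20 percent between-cluster distances typical of expanded MHC
#'   class I families).
#' @param polymorphism_within_locus expected substitutions/site separating
#'   alleles of one locus from their founder (default 0.03, giving ~5-6
#'   percent within-group allele distances).
#' @param seq_length nucleotide sequence length (default 900).
#' @param seed integer seed.
#' @return object of class `population_sim_config`.
#' @export
population_sim_config <- function(n_individuals = 12L,
                                  loci = NULL,
                                  divergence_between_loci = 0.12,
                                  polymorphism_within_locus = 0.03,
                                  seq_length = 900L, seed = 1L) {
  if (is.null(loci))
    loci <- data.frame(locus_name = paste0("locus", 1:4),
                       allele_pool_size = 6L,
                       presence_probability = 0.8)
  loci <- as.data.frame(loci)
  if (any(loci$allele_pool_size < 1L)) stop("allele_pool_size must be >= 1")
  if (any(loci$presence_probability < 0 | loci$presence_probability > 1))
    stop("presence_probability must be in [0, 1]")
  if (divergence_between_loci <= polymorphism_within_locus)
    stop("loci must be separable: divergence_between_loci must exceed ",
         "polymorphism_within_locus")
  structure(list(n_individuals = as.integer(n_individuals), loci = loci,
                 divergence_between_loci = divergence_between_loci,
                 polymorphism_within_locus = polymorphism_within_locus,
                 seq_length = as.integer(seq_length),
                 seed = as.integer(seed)),
            class = "population_sim_config")
}

.mutate_seq <- function(s, rate) {
  L <- length(s)
  nmut <- stats::rpois(1L, rate * L)
  if (nmut == 0L) return(s)
  pos <- sample.int(L, min(nmut, L))
  for (p in pos) s[p] <- sample(setdiff(.DNT, s[p]), 1L)
  s
}

#' Simulate a diploid population carrying a multilocus allele family
#'
#' Each locus founder is the common ancestral sequence mutated at the
#' between-locus divergence scale (star tree); each allele is its founder
#' mutated at the within-locus polymorphism scale. Every individual draws
#' two haplotypes; a haplotype carries a given locus with the configured
#' presence probability and, if so, one allele from its pool. At most two
#' alleles per locus per individual can therefore occur, and haplotype
#' gene-content variation arises whenever presence probability < 1.
#'
#' @param config a [population_sim_config].
#' @return list with `sequences` (named character vector of realized unique
#'   alleles), `genotypes` (individuals x sequences 0/1 matrix),
#'   `locus_of` (truth: sequence -> locus), `carries` (truth:
#'   individuals x loci logical, FALSE = planted deletion on both
#'   haplotypes), and `config`.
#' @export
simulate_population_alleles <- function(config) {
  stopifnot(inherits(config, "population_sim_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  L <- config$seq_length
  anc <- sample(.DNT, L, replace = TRUE)
  loci <- config$loci
  nl <- nrow(loci)

  alleles <- list()  # [[locus]][[allele]] character vector
  for (l in seq_len(nl)) {
    founder <- .mutate_seq(anc, config$divergence_between_loci)
    pool <- list()
    for (a in seq_len(loci$allele_pool_size[l])) {
      repeat {
        cand <- .mutate_seq(founder, config$polymorphism_within_locus)
        key <- paste0(cand, collapse = "")
        if (!key %in% vapply(pool, paste0, "", collapse = "")) break
      }
      pool[[a]] <- cand
    }
    alleles[[loci$locus_name[l]]] <- pool
  }

  n <- config$n_individuals
  ind <- paste0("ind", formatC(seq_len(n), width = 2, flag = "0"))
  hap_draw <- matrix(list(), n, nl, dimnames = list(ind, loci$locus_name))
  carries <- matrix(FALSE, n, nl, dimnames = list(ind, loci$locus_name))
  for (i in seq_len(n)) for (l in seq_len(nl)) {
    got <- integer(0)
    for (h in 1:2)
      if (stats::runif(1) < loci$presence_probability[l])
        got <- c(got, sample.int(loci$allele_pool_size[l], 1L))
    hap_draw[[i, l]] <- got
    carries[i, l] <- length(got) > 0L
  }

  # realized unique alleles only
  seqs <- character(0); locus_of <- character(0)
  allele_name <- function(l, a) paste0(loci$locus_name[l], "_a", a)
  for (l in seq_len(nl)) {
    used <- sort(unique(unlist(hap_draw[, l])))
    for (a in used) {
      nm <- allele_name(l, a)
      seqs[nm] <- paste0(alleles[[l]][[a]], collapse = "")
      locus_of[nm] <- loci$locus_name[l]
    }
  }
  gm <- matrix(0L, n, length(seqs), dimnames = list(ind, names(seqs)))
  for (i in seq_len(n)) for (l in seq_len(nl))
    for (a in unique(hap_draw[[i, l]]))
      gm[i, allele_name(l, a)] <- 1L

  # an individual could in principle end up with no sequence at all
  empty <- rowSums(gm) == 0L
  if (any(empty)) {
    gm <- gm[!empty, , drop = FALSE]
    carries <- carries[!empty, , drop = FALSE]
  }
  keep <- colSums(gm) > 0L
  list(sequences = seqs[keep],
       genotypes = gm[, keep, drop = FALSE],
       locus_of = locus_of[keep],
       carries = carries,
       config = config)
}
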