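# End-to-end orchestration: population chain (distances -> tree -> loci ->
# copy-number report), selection chain (site models -> LRTs -> selected
# sites), and optional structural KIR scoring, with plain-file artifacts,
# per-stage caching keyed on a config hash, and a deterministic report.

# small deterministic string hash (djb2); no cryptographic needs here
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

.stage_cached <- function(outdir, stage, hash) {
  hf <- file.path(outdir, paste0(".", stage, ".hash"))
  rf <- file.path(outdir, paste0(".", stage, ".rds"))
  if (file.exists(hf) && file.exists(rf) &&
      identical(readLines(hf, warn = FALSE), hash))
    readRDS(rf)
  else NULL
}

.stage_store <- function(outdir, stage, hash, value) {
  writeLines(hash, file.path(outdir, paste0(".", stage, ".hash")))
  saveRDS(value, file.path(outdir, paste0(".", stage, ".rds")))
  value
}

#' Run the full diversification analysis pipeline
#'
#' Executes the configured stages in dependency order, writing each stage's
#' artifact files under `outdir` and returning (and writing) a machine-
#' readable report. Stages are cached: a rerun with an unchanged config
#' block reuses the stage output, and any parameter change invalidates the
#' affected stage.
#'
#' @param config a list, or path to a YAML file, with optional blocks:
#'   \describe{
#'     \item{population}{either `simulate` (arguments of
#'       [population_sim_config()], with `n_loci`/`presence_probability`
#'       shortcuts) or `alignment_fasta` + `genotypes_tsv`; options
#'       `bootstrap_reps` (default 200) and `max_alleles` (default 2).}
#'     \item{selection}{either `simulate` (arguments of
#'       [codon_sim_config()]) or `alignment_fasta` + `tree_newick`;
#'       option `models` (default M0, M1a, M2a, M3, M8), `threshold`
#'       (0.9), `min_models` (2).}
#'     \item{kir}{`complexes`: list of `(id, pdb, mhc_chain, kir_chain,
#'       label)`; options `k` (5), `d_cutoff` (3.5), `contact_radius`
#'       (6).}
#'   }
#'   plus top-level `seed` and `outdir`.
#' @param outdir overrides `config$outdir`.
#' @return object of class `run_report` (nested list of per-stage
#'   summaries), also written as `report.json`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  outdir <- outdir %||% config$outdir %||% stop("outdir required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  report <- list(seed = seed,
                 package_version = as.character(utils::packageVersion("mhcdiv")),
                 config_hash = .config_hash(
                   config[setdiff(names(config), "outdir")]))

  if (!is.null(config$population)) {
    pc <- config$population
    hash <- .config_hash(list(pc, seed))
    pop <- .stage_cached(outdir, "population", hash)
    if (is.null(pop)) {
      pop <- .run_population_stage(pc, seed, outdir)
      .stage_store(outdir, "population", hash, pop)
    }
    report$population <- pop$summary
  }

  if (!is.null(config$selection)) {
    sc <- config$selection
    hash <- .config_hash(list(sc, seed))
    sel <- .stage_cached(outdir, "selection", hash)
    if (is.null(sel)) {
      sel <- .run_selection_stage(sc, seed, outdir)
      .stage_store(outdir, "selection", hash, sel)
    }
    report$selection <- sel$summary
  }

  if (!is.null(config$kir)) {
    kc <- config$kir
    hash <- .config_hash(list(kc, seed))
    kir <- .stage_cached(outdir, "kir", hash)
    if (is.null(kir)) {
      kir <- .run_kir_stage(kc, outdir)
      .stage_store(outdir, "kir", hash, kir)
    }
    report$kir <- kir$summary
  }

  class(report) <- "run_report"
  jsonlite::write_json(unclass(report),
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (seed", x$seed, ", config", x$config_hash, ")\n")
  for (st in intersect(c("population", "selection", "kir"), names(x))) {
    cat("--", st, "--\n")
    utils::str(x[[st]], max.level = 1, give.attr = FALSE)
  }
  invisible(x)
}

.run_population_stage <- function(pc, seed, outdir) {
  if (!is.null(pc$simulate)) {
    s <- pc$simulate
    loci <- data.frame(
      locus_name = paste0("locus", seq_len(s$n_loci %||% 4)),
      allele_pool_size = s$allele_pool_size %||% 6L,
      presence_probability = s$presence_probability %||% 0.8)
    cfg <- population_sim_config(
      n_individuals = s$n_individuals %||% 12L, loci = loci,
      divergence_between_loci = s$divergence_between_loci %||% 0.12,
      polymorphism_within_locus = s$polymorphism_within_locus %||% 0.03,
      seq_length = s$seq_length %||% 900L, seed = seed)
    sim <- simulate_population_alleles(cfg)
    aln <- aligned_set(sim$sequences, source = "simulate_population_alleles")
    gm <- sim$genotypes
    truth <- sim[c("locus_of", "carries")]
  } else {
    aln <- read_alignment(pc$alignment_fasta)
    gm <- as.matrix(utils::read.delim(pc$genotypes_tsv, row.names = 1,
                                      check.names = FALSE))
    truth <- NULL
  }
  write_alignment(aln, file.path(outdir, "population_alleles.fasta"))

  dm <- mcl_distances(aln, bootstrap_reps = pc$bootstrap_reps %||% 200L,
                      seed = seed)
  utils::write.table(round(dm$d, 6), file.path(outdir, "distances.tsv"),
                     sep = "\t", quote = FALSE)
  tr <- bootstrap_support(aln, reps = pc$tree_bootstrap %||% 100L,
                          seed = seed)
  ape::write.tree(tr, file.path(outdir, "tree.nwk"))
  part <- assign_loci(tr, gm, max_alleles = pc$max_alleles %||% 2L)
  ptab <- data.frame(
    sequence = unlist(part$groups),
    group = rep(names(part$groups), lengths(part$groups)))
  utils::write.table(ptab, file.path(outdir, "locus_partition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cnv <- detect_cnv(part, gm)
  utils::write.table(cnv$carries_locus * 1L,
                     file.path(outdir, "locus_presence.tsv"),
                     sep = "\t", quote = FALSE)

  off <- dm$d[upper.tri(dm$d)]
  summary <- list(
    n_sequences = length(aln), n_individuals = nrow(gm),
    mean_distance = mean(off, na.rm = TRUE),
    mean_distance_se = {
      gd <- group_distance(dm, list(dm$labels), "within"); unname(gd["se"])
    },
    n_locus_groups = length(part$groups),
    partition_valid = part$valid,
    haplotypic_variation = cnv$haplotypic_variation)
  if (!is.null(truth)) {
    inferred <- rep(names(part$groups), lengths(part$groups))
    names(inferred) <- unlist(part$groups)
    summary$ari_vs_truth <-
      adjusted_rand_index(truth$locus_of[names(inferred)], inferred)
  }
  list(summary = summary, partition = part, cnv = cnv, dm = dm,
       tree = tr, truth = truth)
}

.run_selection_stage <- function(sc, seed, outdir) {
  if (!is.null(sc$simulate)) {
    s <- sc$simulate
    classes <- if (!is.null(s$site_classes)) as.data.frame(s$site_classes)
      else data.frame(proportion = c(0.7, 0.2, 0.1), omega = c(0.1, 1, 4))
    cfg <- codon_sim_config(
      s$tree %||%
        "((a:0.15,b:0.2):0.1,(c:0.12,d:0.18):0.08,(e:0.2,f:0.1):0.12);",
      kappa = s$kappa %||% 2, site_classes = classes,
      n_codons = s$n_codons %||% 300L, seed = seed)
    aln <- simulate_codon_alignment(cfg)
    truth_sites <- which(attr(aln, "site_omega") > 1)
    tr <- cfg$tree
  } else {
    aln <- read_alignment(sc$alignment_fasta)
    tr <- ape::read.tree(sc$tree_newick)
    truth_sites <- NULL
  }
  write_alignment(aln, file.path(outdir, "selection_alignment.fasta"))
  models <- sc$models %||% c("M0", "M1a", "M2a", "M3", "M8")
  fits <- lapply(models, function(m) fit_site_model(aln, tr, m))
  names(fits) <- models
  ptab <- do.call(rbind, lapply(fits, function(f) data.frame(
    model = f$model_id, lnL = f$lnL, kappa = f$kappa,
    scale = f$scale,
    classes = if (is.null(f$class_params)) "" else
      paste(sprintf("%.3f:%.3f", f$class_params$proportion,
                    f$class_params$omega), collapse = ";"))))
  utils::write.table(ptab, file.path(outdir, "site_models.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  lrts <- list()
  for (pair in .NESTED_PAIRS)
    if (all(pair %in% models))
      lrts[[paste(pair, collapse = "_vs_")]] <- lrt(fits[[pair[1]]],
                                                    fits[[pair[2]]])
  ltab <- do.call(rbind, lapply(lrts, function(l) data.frame(
    null = l$null, alt = l$alt, stat = l$stat, df = l$df,
    p_value = l$p_value)))
  if (!is.null(ltab))
    utils::write.table(ltab, file.path(outdir, "lrt.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

  sel <- NULL
  selm <- intersect(c("M2a", "M3", "M8"), models)
  if (length(selm) >= (sc$min_models %||% 2L)) {
    sel <- selected_sites(fits[selm], threshold = sc$threshold %||% 0.9,
                          min_models = sc$min_models %||% 2L)
    utils::write.table(sel, file.path(outdir, "selected_sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary <- list(
    n_sequences = length(aln), n_codons = aln$length / 3,
    lnL = stats::setNames(vapply(fits, function(f) f$lnL, 0), models),
    lrt_p = if (is.null(ltab)) NULL else
      stats::setNames(ltab$p_value, rownames(ltab)),
    n_selected_sites = if (is.null(sel)) NA_integer_ else
      sum(sel$selected),
    selected_sites = if (is.null(sel)) NULL else sel$site[sel$selected])
  if (!is.null(truth_sites) && !is.null(sel)) {
    called <- sel$site[sel$selected]
    summary$planted_sites <- truth_sites
    summary$sensitivity <- if (length(truth_sites))
      length(intersect(called, truth_sites)) / length(truth_sites) else NA
  }
  list(summary = summary, fits = fits, lrts = lrts, selected = sel)
}

.run_kir_stage <- function(kc, outdir) {
  rows <- list(); scores <- numeric(0); labels <- character(0)
  for (cx in kc$complexes) {
    s <- read_complex_pdb(cx$pdb, cx$mhc_chain, cx$kir_chain)
    hb <- detect_interface_hbonds(s, d_cutoff = kc$d_cutoff %||% 3.5)
    dG <- desolvation_energy(s, contact_radius = kc$contact_radius %||% 6)
    sc <- interaction_index(hb, dG, k = kc$k %||% 5)
    rows[[cx$id]] <- data.frame(pair = cx$id, h = sc$h, dG = sc$dG,
                                I = sc$I,
                                label = cx$label %||% NA_character_)
    if (!is.null(cx$label)) {
      scores[cx$id] <- sc$I; labels[cx$id] <- cx$label
    }
  }
  tab <- do.call(rbind, rows)
  utils::write.table(tab, file.path(outdir, "kir_scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summary <- list(n_pairs = nrow(tab),
                  mean_h = mean(tab$h), mean_I = mean(tab$I, na.rm = TRUE))
  if (length(unique(labels[!is.na(labels)])) == 2) {
    cal <- calibrate_and_classify(scores, labels)
    summary$calibration <- list(threshold = cal$threshold,
                                fp_rate = cal$fp_rate,
                                fn_rate = cal$fn_rate)
  }
  list(summary = summary, scores = tab)
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b label vectors of equal length (names are ignored; order
#'   aligns them).
#' @return ARI in `[-1, 1]`; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab)); sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}
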