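# Peptide-binding-region variability: translation to mature class I
# numbering, tabulation of observed residues per position and lineage
# against the structure-derived contact maps, and shared-residue summaries
# between lineages.

#' Load the shipped peptide-contact map
#'
#' 35 mature-numbering MHC class I positions predicted to contact the bound
#' peptide within 4.0 Angstrom, with the peptide residue(s) (1-9) each
#' contacts. Positions whose peptide assignment is an approximate
#' transcription are flagged in the `approx` column.
#'
#' @param path optional alternative TSV (`mhc_pos`, `peptide_positions`).
#' @return data.frame with `mhc_pos` (integer) and `peptide_positions`
#'   (list of integers).
#' @export
peptide_contact_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "peptide_contacts.tsv",
                        package = "mhcdiv")
  df <- utils::read.delim(path, comment.char = "#")
  stopifnot(all(df$mhc_pos >= 1 & df$mhc_pos <= 182))
  pp <- lapply(strsplit(as.character(df$peptide_positions), ","),
               as.integer)
  stopifnot(all(unlist(pp) %in% 1:9))
  data.frame(mhc_pos = as.integer(df$mhc_pos),
             peptide_positions = I(pp),
             approx = if ("approx" %in% names(df)) df$approx == "yes"
                      else FALSE)
}

#' Load the shipped KIR-contact position set
#'
#' @param path optional alternative TSV (`mhc_pos`, `critical`).
#' @return data.frame with `mhc_pos` and logical `critical` (the positions
#'   whose substitution strongly shifts KIR3DL1 affinity).
#' @export
kir_contact_set <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "kir_contacts.tsv", package = "mhcdiv")
  df <- utils::read.delim(path, comment.char = "#")
  out <- data.frame(mhc_pos = as.integer(df$mhc_pos),
                    critical = df$critical == "yes")
  stopifnot(any(out$critical))
  out
}

#' Translate cDNAs and renumber to the mature protein
#'
#' Translates each aligned cDNA in frame 1 and shifts numbering so that
#' position 1 is the first residue of the mature protein (the
#' `numbering_offset` leader residues removed; default 24, the canonical
#' MHC class I leader length). A terminal stop codon is dropped; internal
#' stops are an error naming the sequence and codon.
#'
#' @param aln an [aligned_set] (length divisible by 3, frame 1).
#' @param numbering_offset leader length in residues (default 24; 0 keeps
#'   precursor numbering).
#' @return character matrix (sequences x positions) of one-letter residues
#'   with column names = mature position numbers (leader columns get
#'   numbers <= 0).
#' @export
translate_and_number <- function(aln, numbering_offset = 24L) {
  seqs <- aln_sequences(aln)
  if (nchar(seqs[1]) %% 3L != 0L)
    stop("alignment length not divisible by 3")
  prot <- lapply(seqs, translate_codons)
  nres <- length(prot[[1]])
  for (nm in names(prot)) {
    stops <- which(prot[[nm]] == "*")
    if (any(stops < nres))
      stop("internal stop codon in '", nm, "' at codon ",
           paste(stops[stops < nres], collapse = ", "))
  }
  m <- do.call(rbind, prot)
  rownames(m) <- names(seqs)
  # drop a trailing all-stop column
  if (all(m[, nres] %in% c("*", "-", "X")) && any(m[, nres] == "*"))
    m <- m[, -nres, drop = FALSE]
  colnames(m) <- seq_len(ncol(m)) - as.integer(numbering_offset)
  m
}

#' Tabulate residue variability at peptide-contacting positions
#'
#' For every position of the contact map, collects the observed amino-acid
#' set per lineage, flags variability (two or more residues observed across
#' the whole set), attaches selection calls, and classifies residues as
#' shared between lineages or unique to one.
#'
#' @param proteins matrix from [translate_and_number()].
#' @param lineages named vector or [extract_clades()] result mapping
#'   sequence names to lineage labels; sequences labeled `"unassigned"`
#'   are dropped.
#' @param cmap contact map from [peptide_contact_map()] (or any data.frame
#'   with `mhc_pos`).
#' @param selected optional [selected_sites()] result; its `site` numbers
#'   are codon positions of the alignment that produced `proteins`, and are
#'   shifted by the same numbering offset.
#' @param numbering_offset the offset used in [translate_and_number()]
#'   (needed to place `selected` sites; default 24).
#' @return object of class `variability_table`: data.frame with one row
#'   per contact-map position (`position`, `covered`, `variable`,
#'   `selected`, per-lineage residue strings, `n_shared` residues common to
#'   all covering lineages), plus an `uncovered` attribute listing map
#'   positions absent from the alignment.
#' @export
tabulate_variability <- function(proteins, lineages, cmap,
                                 selected = NULL, numbering_offset = 24L) {
  if (inherits(lineages, "clade_assignment"))
    lineages <- stats::setNames(lineages$cluster, lineages$sequence)
  lineages <- lineages[names(lineages) %in% rownames(proteins)]
  lineages <- lineages[lineages != "unassigned"]
  if (!length(lineages)) stop("no sequences with lineage labels")
  if (!all(rownames(proteins) %in% names(lineages)))
    proteins <- proteins[rownames(proteins) %in% names(lineages), ,
                         drop = FALSE]
  lin_levels <- sort(unique(lineages))
  posnum <- as.integer(colnames(proteins))
  sel_positions <- integer(0)
  if (!is.null(selected))
    sel_positions <- selected$site[selected$selected] -
      as.integer(numbering_offset)

  rows <- list(); uncovered <- integer(0)
  for (p in cmap$mhc_pos) {
    ci <- match(p, posnum)
    if (is.na(ci)) { uncovered <- c(uncovered, p); next }
    col <- stats::setNames(proteins[, ci], rownames(proteins))
    per_lin <- lapply(lin_levels, function(l) {
      r <- unique(col[names(col) %in% names(lineages)[lineages == l]])
      sort(setdiff(r, c("-", "X")))
    })
    names(per_lin) <- lin_levels
    all_res <- sort(unique(unlist(per_lin)))
    covering <- per_lin[vapply(per_lin, length, 0L) > 0]
    shared <- if (length(covering) > 1) Reduce(intersect, covering)
              else character(0)
    rows[[length(rows) + 1L]] <- data.frame(
      position = p, covered = length(all_res) > 0,
      variable = length(all_res) >= 2,
      selected = p %in% sel_positions,
      n_shared = length(shared),
      t(vapply(per_lin, paste0, "", collapse = "")),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  names(out)[-(1:5)] <- paste0("res_", lin_levels)
  attr(out, "uncovered") <- uncovered
  attr(out, "lineages") <- lin_levels
  class(out) <- c("variability_table", "data.frame")
  out
}

#' @export
print.variability_table <- function(x, ...) {
  cat("variability_table:", nrow(x), "contact positions;",
      sum(x$variable), "variable;", sum(x$selected),
      "positively selected\n")
  if (length(attr(x, "uncovered")))
    cat("  uncovered map positions:",
        paste(attr(x, "uncovered"), collapse = ", "), "\n")
  NextMethod()
}

#' Count variable contact positions sharing residues between two lineages
#'
#' Over the variable positions of a [tabulate_variability()] table, counts
#' those where the two lineages have at least one amino acid in common
#' (both lineages must cover the position).
#'
#' @param table a `variability_table`.
#' @param pair character vector of two lineage labels (identical labels
#'   count the variable positions the lineage covers).
#' @return integer count.
#' @export
shared_residue_counts <- function(table, pair) {
  stopifnot(length(pair) == 2)
  lins <- attr(table, "lineages")
  miss <- setdiff(pair, lins)
  if (length(miss)) stop("unknown lineage(s): ", paste(miss, collapse = ", "))
  c1 <- table[[paste0("res_", pair[1])]]
  c2 <- table[[paste0("res_", pair[2])]]
  n <- 0L
  for (i in which(table$variable)) {
    r1 <- strsplit(c1[i], "")[[1]]; r2 <- strsplit(c2[i], "")[[1]]
    if (length(r1) && length(r2) && length(intersect(r1, r2))) n <- n + 1L
  }
  n
}
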