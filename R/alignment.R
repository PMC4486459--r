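#' Aligned sequence set
#'
#' A light container for a nucleotide alignment with optional per-sequence
#' individual identifiers and lineage labels, the common currency of the
#' distance, tree and selection stages.
#'
#' @param seqs named character vector of equal-length nucleotide strings
#'   (alphabet `A C G T - N`, case-insensitive).
#' @param individual optional character vector of individual ids, recycled
#'   or named like `seqs`.
#' @param lineage optional character vector of lineage/clade labels.
#' @param source free-text provenance note (e.g. the aligner used), kept in
#'   the object's metadata.
#' @return an object of class `aligned_set`.
#' @export
aligned_set <- function(seqs, individual = NULL, lineage = NULL,
                        source = "unspecified") {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  seqs <- toupper(seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences are not aligned (unequal lengths)")
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    stop("invalid characters in sequence(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  x <- list(seqs = seqs, length = L,
            individual = .expand_meta(individual, seqs),
            lineage = .expand_meta(lineage, seqs),
            source = source)
  class(x) <- "aligned_set"
  x
}

.expand_meta <- function(v, seqs) {
  if (is.null(v)) return(NULL)
  if (!is.null(names(v))) return(v[names(seqs)])
  stats::setNames(rep_len(as.character(v), length(seqs)), names(seqs))
}

#' @export
print.aligned_set <- function(x, ...) {
  cat("aligned_set:", length(x$seqs), "sequences x", x$length, "columns\n")
  if (!is.null(x$individual))
    cat("  individuals:", length(unique(x$individual)), "\n")
  cat("  source:", x$source, "\n")
  invisible(x)
}

#' @export
length.aligned_set <- function(x) length(x$seqs)

aln_sequences <- function(aln) {
  if (inherits(aln, "aligned_set")) return(aln$seqs)
  if (is.character(aln) && !is.null(names(aln))) return(toupper(aln))
  stop("expected an aligned_set or named character vector")
}

# alignment as a character matrix (rows = sequences)
aln_matrix <- function(aln) {
  seqs <- aln_sequences(aln)
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(seqs)
  m
}

# column-subset an aligned_set (bootstrap resampling etc.)
aln_subset_columns <- function(aln, idx) {
  m <- aln_matrix(aln)[, idx, drop = FALSE]
  seqs <- apply(m, 1L, paste0, collapse = "")
  aligned_set(stats::setNames(seqs, rownames(m)),
              individual = aln$individual, lineage = aln$lineage,
              source = aln$source)
}

#' Read an aligned FASTA file
#'
#' Sequence names of the form `name|individual` populate the individual
#' field; otherwise individuals are `NA`.
#'
#' @param path FASTA file of equal-length nucleotide sequences.
#' @param source provenance note stored in the object (default
#'   `"external"`, i.e. aligned outside this package).
#' @return an [aligned_set].
#' @export
read_alignment <- function(path, source = "external") {
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna), paste0, "", collapse = "")
  nm <- names(seqs)
  ind <- NULL
  if (any(grepl("|", nm, fixed = TRUE))) {
    parts <- strsplit(nm, "|", fixed = TRUE)
    nm <- vapply(parts, `[`, "", 1L)
    ind <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, "")
  }
  names(seqs) <- nm
  aligned_set(seqs, individual = if (!is.null(ind)) stats::setNames(ind, nm),
              source = source)
}

#' Write an aligned_set to FASTA
#'
#' @param aln an [aligned_set].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqs <- aln_sequences(aln)
  nm <- names(seqs)
  if (!is.null(aln$individual))
    nm <- ifelse(is.na(aln$individual), nm,
                 paste0(nm, "|", aln$individual))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", nm[i]), seqs[[i]]), con)
  invisible(path)
}
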