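# The population cDNA sets analysed with this package are public GenBank
# records; they are inputs the user fetches once, not package data.

#' GenBank accession ranges of the reference cDNA sets
#'
#' The cross-species MHC class I cDNA panel and the 12-individual
#' *Cebus albifrons* population set (29 MHC-G-like plus 22 MHC-B unique
#' cDNAs) used as the package's reference inputs.
#'
#' @return data.frame with `set`, `first_accession`, `last_accession`,
#'   `description`.
#' @export
genbank_accessions <- function() {
  data.frame(
    set = c("cross_species", "cebus_population"),
    first_accession = c("KM219682", "KM219732"),
    last_accession = c("KM219731", "KM219782"),
    description = c(
      "MHC-G-like and MHC-B cDNAs cloned from nine platyrrhine species",
      paste("MHC-G-like (29) and MHC-B (22) unique cDNAs from 12",
            "Cebus albifrons individuals")),
    stringsAsFactors = FALSE)
}

#' Load a downloaded population cDNA FASTA
#'
#' Thin wrapper over [read_alignment()] that gives an actionable error when
#' the file has not been fetched yet. Sequence names of the form
#' `name|individual` carry the individual tags needed by the locus caller.
#'
#' @param path path to the aligned FASTA of population cDNAs.
#' @return an [aligned_set].
#' @export
load_population_cdnas <- function(path) {
  if (!file.exists(path))
    stop("cDNA file not found: ", path,
         "\nFetch the GenBank records first (see genbank_accessions()); ",
         "e.g. accessions KM219732-KM219782 for the Cebus albifrons ",
         "population set, aligned with any standard aligner.")
  read_alignment(path, source = "downloaded GenBank set")
}
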