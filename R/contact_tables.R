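# 18-type atom alphabet for the contact-potential desolvation term, and
# access to the shipped (synthetic, swappable) pairwise energy table.

.CONTACT_TYPES <- c("N_bb", "N_pro", "CA", "C_bb", "O_bb", "C_aliph",
                    "C_arom", "C_polar", "C_charged_arm", "O_carboxyl",
                    "O_amide", "O_hydroxyl", "N_amide", "N_pos", "N_arom",
                    "S_thiol", "S_thioether", "O_terminal")

# side-chain atom classifications; backbone handled by rule
.SC_TYPE <- list(
  C_arom = c("PHE:CG", "PHE:CD1", "PHE:CD2", "PHE:CE1", "PHE:CE2",
             "PHE:CZ", "TYR:CG", "TYR:CD1", "TYR:CD2", "TYR:CE1",
             "TYR:CE2", "TRP:CG", "TRP:CD1", "TRP:CD2", "TRP:CE2",
             "TRP:CE3", "TRP:CZ2", "TRP:CZ3", "TRP:CH2", "HIS:CG",
             "HIS:CD2", "HIS:CE1"),
  C_polar = c("SER:CB", "THR:CB", "CYS:CB", "TYR:CZ", "ASP:CG", "GLU:CD",
              "ASN:CG", "GLN:CD", "ARG:CZ"),
  C_charged_arm = c("LYS:CE", "ARG:CD"),
  O_carboxyl = c("ASP:OD1", "ASP:OD2", "GLU:OE1", "GLU:OE2"),
  O_amide = c("ASN:OD1", "GLN:OE1"),
  O_hydroxyl = c("SER:OG", "THR:OG1", "TYR:OH"),
  N_amide = c("ASN:ND2", "GLN:NE2"),
  N_pos = c("LYS:NZ", "ARG:NE", "ARG:NH1", "ARG:NH2"),
  N_arom = c("HIS:ND1", "HIS:NE2", "TRP:NE1"),
  S_thiol = c("CYS:SG"),
  S_thioether = c("MET:SD"))

.contact_env <- new.env(parent = emptyenv())

.sc_lookup <- function() {
  if (is.null(.contact_env$sc)) {
    v <- character(0)
    for (ty in names(.SC_TYPE)) v[.SC_TYPE[[ty]]] <- ty
    .contact_env$sc <- v
  }
  .contact_env$sc
}

#' Type atoms into the 18-type contact-potential alphabet
#'
#' Backbone atoms follow fixed rules (N, CA, C, O, OXT); side-chain N, O
#' and S atoms follow a residue/atom lookup; remaining side-chain carbons
#' are aliphatic. Hydrogens and unrecognized atoms get `NA`.
#'
#' @param resname,atom,element vectors of PDB residue names, atom names
#'   and element symbols.
#' @return integer vector of type indices into the energy table (rows of
#'   [contact_energy_table()]), `NA` for untypable atoms.
#' @export
atom_contact_type <- function(resname, atom, element) {
  resname <- toupper(trimws(resname)); atom <- toupper(trimws(atom))
  element <- toupper(trimws(element))
  n <- length(atom)
  ty <- rep(NA_character_, n)
  aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")
  std <- resname %in% aa3
  ty[std & atom == "N"] <- ifelse(resname[std & atom == "N"] == "PRO",
                                  "N_pro", "N_bb")
  ty[std & atom == "CA"] <- "CA"
  ty[std & atom == "C"] <- "C_bb"
  ty[std & atom == "O"] <- "O_bb"
  ty[std & atom == "OXT"] <- "O_terminal"
  sc <- .sc_lookup()
  key <- paste0(resname, ":", atom)
  hit <- std & is.na(ty) & key %in% names(sc)
  ty[hit] <- sc[key[hit]]
  # remaining side-chain carbons are aliphatic
  ty[std & is.na(ty) & element == "C"] <- "C_aliph"
  ty[element == "H"] <- NA_character_
  match(ty, .CONTACT_TYPES)
}

#' The pairwise atomic contact energy table
#'
#' Returns the 18x18 symmetric energy matrix (kcal/mol per contact) used by
#' [desolvation_energy()]. The shipped default is a constructed potential:
#' each type carries a transfer-free-energy-like parameter (hydrophobic
#' types favorable/negative, polar and charged types unfavorable/positive)
#' and pair energies are the parameter sums. It is labeled synthetic and
#' can be replaced by any table with the same layout.
#'
#' @param path optional TSV path (first column = type names, remaining
#'   columns the matrix).
#' @return numeric 18x18 matrix with type names as dimnames.
#' @export
contact_energy_table <- function(path = NULL) {
  .contact_energy_table(path)
}

.contact_energy_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.contact_env$table)) return(.contact_env$table)
    path <- system.file("extdata", "contact_energy_synthetic.tsv",
                        package = "mhcdiv")
    cache <- TRUE
  } else cache <- FALSE
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (!identical(rownames(m), colnames(m)))
    stop("contact energy table must be square with matching names")
  if (max(abs(m - t(m))) > 1e-9) stop("contact energy table must be symmetric")
  if (cache) .contact_env$table <- m
  m
}
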