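#' Configuration for the toy two-chain complex generator
#'
#' @param n_planted_hbonds number of donor-acceptor pairs planted across
#'   the interface (>= 0).
#' @param n_decoy_atoms decoy atoms scattered on the two chains, placed so
#'   that no decoy can satisfy the hydrogen-bond criteria across the
#'   interface.
#' @param chain_separation depth (Angstrom) of each decoy cloud behind its
#'   chain's interface plane (default 12).
#' @param jitter uniform coordinate noise (Angstrom) applied to planted
#'   atoms; must leave the planted geometry inside the detector's criteria
#'   with margin (jitter <= 0.25 for the 2.9 A / 3.5 A defaults).
#' @param seed integer seed.
#' @return object of class `complex_sim_config`.
#' @export
complex_sim_config <- function(n_planted_hbonds, n_decoy_atoms = 0L,
                               chain_separation = 12, jitter = 0.05,
                               seed = 1L) {
  if (n_planted_hbonds < 0L) stop("n_planted_hbonds must be >= 0")
  if (jitter > 0.25)
    stop("jitter too large to guarantee planted bonds stay detectable ",
         "(2.9 + 2*jitter must stay below the 3.5 A cutoff with margin)")
  structure(list(n_planted_hbonds = as.integer(n_planted_hbonds),
                 n_decoy_atoms = as.integer(n_decoy_atoms),
                 chain_separation = chain_separation, jitter = jitter,
                 seed = as.integer(seed)),
            class = "complex_sim_config")
}

#' Generate a toy two-chain complex with planted hydrogen bonds
#'
#' Chain A (MHC role) and chain B (KIR role) face each other across the
#' x = 1.45 plane. Each planted bond is an N donor on chain A at 2.9 A
#' from an O acceptor on chain B, with a carbon antecedent placed so the
#' antecedent-donor-acceptor angle is ~180 degrees; consecutive plantings
#' are 10 A apart so they cannot cross-pair. Decoy atoms (70% C, 30% N/O)
#' are placed at least `chain_separation/2 + 3` A behind each chain's
#' interface so no decoy pair can fall inside the 3.5 A criterion.
#'
#' @param config a [complex_sim_config].
#' @return a [complex_structure] with attribute `manifest`: data.frame of
#'   the planted donor/acceptor atom row indices.
#' @export
generate_toy_complex <- function(config) {
  stopifnot(inherits(config, "complex_sim_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  jit <- function(n) matrix(stats::runif(3 * n, -1, 1), n, 3) *
    config$jitter / sqrt(3)
  rows <- list(); manifest <- NULL
  add <- function(chain, resno, resname, atom, element, xyz) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = chain, resno = resno, resname = resname, atom = atom,
      element = element, x = xyz[1], y = xyz[2], z = xyz[3],
      stringsAsFactors = FALSE)
    length(rows)
  }

  np <- config$n_planted_hbonds
  if (np > 0) {
    jd <- jit(np); ja <- jit(np); jc <- jit(np)
    for (i in seq_len(np)) {
      y <- 10 * (i - 1)
      ci <- add("A", i, "ALA", "C", "C", c(-1.4, y, 0) + jc[i, ])
      di <- add("A", i, "ALA", "N", "N", c(0, y, 0) + jd[i, ])
      ai <- add("B", i, "ALA", "O", "O", c(2.9, y, 0) + ja[i, ])
      manifest <- rbind(manifest,
                        data.frame(bond = i, donor = di, acceptor = ai,
                                   antecedent = ci))
    }
  }

  nd <- config$n_decoy_atoms
  if (nd > 0) {
    span <- max(10 * np, 20)
    half <- config$chain_separation / 2 + 3
    elem <- sample(c("C", "N", "O"), nd, replace = TRUE,
                   prob = c(0.7, 0.15, 0.15))
    side <- rep_len(c("A", "B"), nd)
    for (i in seq_len(nd)) {
      x <- stats::runif(1, half, half + config$chain_separation)
      pos <- c(if (side[i] == "A") -x else 2.9 + x,
               stats::runif(1, -5, span + 5), stats::runif(1, -8, 8))
      nm <- switch(elem[i], C = "CB", N = "N", O = "O")
      add(side[i], np + i, "ALA", nm, elem[i], pos)
    }
  }
  if (!length(rows)) {
    # degenerate but well-formed: one faraway atom per chain
    add("A", 1, "ALA", "CB", "C", c(-20, 0, 0))
    add("B", 2, "ALA", "CB", "C", c(20, 0, 0))
  }
  atoms <- do.call(rbind, rows)
  s <- complex_structure(atoms, mhc_chain = "A", kir_chain = "B")
  attr(s, "manifest") <- manifest
  s
}
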