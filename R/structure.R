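# Structure-based MHC:KIR interaction scoring: a two-chain atomic structure
# container, geometric interface hydrogen-bond enumeration, a table-driven
# atomic-contact desolvation energy, the interaction index I = k h / ln dG,
# and threshold calibration against labeled pairs.

#' Two-chain complex structure container
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resname`,
#'   `atom` (PDB atom name), `element`, `x`, `y`, `z` (Angstrom).
#' @param mhc_chain,kir_chain chain identifiers taking the MHC and KIR
#'   roles.
#' @return object of class `complex_structure`.
#' @export
complex_structure <- function(atoms, mhc_chain, kir_chain) {
  need <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  atoms$role <- ifelse(atoms$chain %in% mhc_chain, "MHC",
                       ifelse(atoms$chain %in% kir_chain, "KIR", NA))
  structure(list(atoms = atoms, mhc_chain = mhc_chain,
                 kir_chain = kir_chain),
            class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  cat("complex_structure:", nrow(x$atoms), "atoms; MHC chain(s)",
      paste(x$mhc_chain, collapse = ","), "/ KIR chain(s)",
      paste(x$kir_chain, collapse = ","), "\n")
  invisible(x)
}

#' Read a complex from a PDB file
#'
#' @param path PDB file.
#' @param mhc_chain,kir_chain chain ids of the MHC and KIR molecules.
#' @return a [complex_structure].
#' @export
read_complex_pdb <- function(path, mhc_chain, kir_chain) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(gsub("[^A-Za-z].*", "", a$elety), 1, 1)
  atoms <- data.frame(chain = a$chain, resno = a$resno, resname = a$resid,
                      atom = a$elety, element = toupper(trimws(elem)),
                      x = a$x, y = a$y, z = a$z,
                      stringsAsFactors = FALSE)
  complex_structure(atoms, mhc_chain, kir_chain)
}

#' Write a complex_structure to a PDB file
#'
#' @param s a [complex_structure].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_complex_pdb <- function(s, path) {
  a <- s$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(a))) {
    writeLines(sprintf(
      "ATOM  %5d  %-4s%3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      i, substr(a$atom[i], 1, 4), a$resname[i],
      a$chain[i], a$resno[i], a$x[i], a$y[i], a$z[i], a$element[i]), con)
  }
  writeLines("END", con)
  invisible(path)
}

.cross_pairs <- function(s, cutoff) {
  a <- s$atoms
  A <- which(a$role == "MHC"); B <- which(a$role == "KIR")
  if (!length(A) || !length(B))
    stop("both an MHC-role and a KIR-role chain are required")
  xyzA <- as.matrix(a[A, c("x", "y", "z")])
  xyzB <- as.matrix(a[B, c("x", "y", "z")])
  d2 <- outer(rowSums(xyzA^2), rowSums(xyzB^2), "+") -
    2 * tcrossprod(xyzA, xyzB)
  hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
  data.frame(i = A[hit[, 1]], j = B[hit[, 2]],
             dist = sqrt(pmax(d2[hit], 0)))
}

.angle_deg <- function(p, q, r) {
  # angle at q formed by p-q-r
  v1 <- p - q; v2 <- r - q
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Detect interface hydrogen bonds
#'
#' Enumerates donor-acceptor pairs across the MHC/KIR interface. Donors and
#' acceptors are N and O heavy atoms. A pair is a hydrogen bond when the
#' donor-acceptor distance is at most `d_cutoff` and the geometry is
#' plausible: if the structure carries hydrogens, some donor-bound H gives a
#' D-H...A angle of at least `h_angle_cutoff`; otherwise the angle at the
#' donor formed with its covalently bonded heavy-atom antecedent must be at
#' least `angle_cutoff` (pairs whose donor has no resolvable antecedent are
#' accepted on distance alone). Either atom of the pair may act as the
#' donor; each cross-interface pair is counted once.
#'
#' @param s a [complex_structure].
#' @param d_cutoff donor-acceptor heavy-atom distance cutoff, Angstrom
#'   (default 3.5).
#' @param angle_cutoff antecedent-donor-acceptor angle cutoff, degrees,
#'   used when no hydrogens are present (default 90).
#' @param h_angle_cutoff D-H...A angle cutoff, degrees, used when hydrogens
#'   are present (default 120).
#' @return object of class `hbond_list`: data.frame of bonds (donor and
#'   acceptor atom indices, distance, angle) with `h = nrow` the bond
#'   count.
#' @export
detect_interface_hbonds <- function(s, d_cutoff = 3.5, angle_cutoff = 90,
                                    h_angle_cutoff = 120) {
  a <- s$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  polar <- a$element %in% c("N", "O")
  has_h <- any(a$element == "H")

  cand <- .cross_pairs(s, d_cutoff)
  cand <- cand[polar[cand$i] & polar[cand$j], , drop = FALSE]

  neighbours <- function(idx, elements, maxd) {
    same <- which(a$chain == a$chain[idx])
    d <- sqrt(rowSums((xyz[same, , drop = FALSE] -
                         matrix(xyz[idx, ], length(same), 3,
                                byrow = TRUE))^2))
    same[d > 1e-6 & d <= maxd & a$element[same] %in% elements]
  }
  donor_ok <- function(d_idx, a_idx) {
    if (has_h) {
      hs <- neighbours(d_idx, "H", 1.25)
      if (!length(hs)) return(FALSE)
      angs <- vapply(hs, function(h)
        .angle_deg(xyz[d_idx, ], xyz[h, ], xyz[a_idx, ]), 0)
      return(any(angs >= h_angle_cutoff))
    }
    ante <- neighbours(d_idx, "C", 1.8)
    if (!length(ante)) return(TRUE)
    angs <- vapply(ante, function(cc)
      .angle_deg(xyz[cc, ], xyz[d_idx, ], xyz[a_idx, ]), 0)
    any(angs >= angle_cutoff)
  }

  keep <- logical(nrow(cand)); ang <- rep(NA_real_, nrow(cand))
  dono <- integer(nrow(cand)); acce <- integer(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (donor_ok(i, j)) {
      keep[r] <- TRUE; dono[r] <- i; acce[r] <- j
    } else if (donor_ok(j, i)) {
      keep[r] <- TRUE; dono[r] <- j; acce[r] <- i
    }
  }
  bonds <- data.frame(donor = dono[keep], acceptor = acce[keep],
                      dist = cand$dist[keep])
  structure(list(bonds = bonds, h = nrow(bonds),
                 d_cutoff = d_cutoff, angle_cutoff = angle_cutoff,
                 used_hydrogens = has_h),
            class = "hbond_list")
}

#' @export
print.hbond_list <- function(x, ...) {
  cat("hbond_list:", x$h, "interface hydrogen bond(s)",
      if (x$used_hydrogens) "(explicit-H geometry)" else
        "(heavy-atom proxy geometry)", "\n")
  invisible(x)
}

#' Desolvation energy from an atomic contact potential
#'
#' Sums a tabulated contact energy over all cross-interface heavy-atom
#' pairs within `contact_radius`. Atoms are typed into an 18-type alphabet
#' by residue/atom rules; the shipped energy table
#' (`contact_energy_synthetic.tsv`) is a constructed potential with
#' transfer-free-energy-like magnitudes, versioned with the package and
#' swappable via `table_path`. Untypable atoms (hydrogens, hetero atoms,
#' unknown names) are excluded with a warning listing them.
#'
#' @param s a [complex_structure].
#' @param contact_radius contact cutoff in Angstrom (default 6.0).
#' @param table_path optional path to an alternative 18x18 energy TSV.
#' @return numeric dG (kcal/mol) with attribute `n_contacts`.
#' @export
desolvation_energy <- function(s, contact_radius = 6.0, table_path = NULL) {
  tab <- .contact_energy_table(table_path)
  a <- s$atoms
  types <- atom_contact_type(a$resname, a$atom, a$element)
  unty <- is.na(types) & a$element != "H"
  if (any(unty))
    warning("excluded ", sum(unty), " untypable atom(s): ",
            paste(utils::head(unique(paste0(a$resname[unty], "/",
                                            a$atom[unty])), 10),
                  collapse = ", "))
  pairs <- .cross_pairs(s, contact_radius)
  ok <- !is.na(types[pairs$i]) & !is.na(types[pairs$j])
  pairs <- pairs[ok, , drop = FALSE]
  dG <- sum(tab[cbind(types[pairs$i], types[pairs$j])])
  attr(dG, "n_contacts") <- nrow(pairs)
  dG
}

#' Interaction index for an MHC:KIR pair
#'
#' Computes `I = k * h / ln(|dG|)`: `k` the average hydrogen-bond energy
#' (kcal/mol), `h` the interface hydrogen-bond count, `dG` the desolvation
#' energy. The logarithm is taken on the magnitude of `dG`; pairs with
#' `|dG| <= 1` (logarithm near or below zero) are marked indeterminate
#' rather than producing infinities. `h = 0` gives `I = 0`.
#'
#' @param h hydrogen-bond count (or an `hbond_list`).
#' @param dG desolvation energy, kcal/mol.
#' @param k average hydrogen-bond energy, kcal/mol (default 5; rescaling
#'   `k` rescales `I` linearly and does not change classifications).
#' @return object of class `interaction_score` with fields `h`, `dG`, `k`,
#'   `I`, `call` (`"indeterminate"` or `NA` pending calibration).
#' @export
interaction_index <- function(h, dG, k = 5) {
  if (inherits(h, "hbond_list")) h <- h$h
  stopifnot(h >= 0)
  dG <- as.numeric(dG)
  degenerate <- abs(dG) <= 1 + 1e-6
  I <- if (h == 0) 0 else if (degenerate) NA_real_ else
    k * h / log(abs(dG))
  structure(list(h = as.integer(h), dG = dG, k = k, I = I,
                 call = if (degenerate) "indeterminate" else NA_character_),
            class = "interaction_score")
}

#' @export
print.interaction_score <- function(x, ...) {
  cat(sprintf("interaction_score: h = %d, dG = %.3f kcal/mol, k = %.2f, I = %s%s\n",
              x$h, x$dG, x$k,
              if (is.na(x$I)) "NA" else format(x$I, digits = 6),
              if (identical(x$call, "indeterminate")) " [indeterminate]"
              else ""))
  invisible(x)
}

#' Calibrate the interaction index against labeled pairs
#'
#' Chooses the score threshold minimizing total misclassification
#' (positives score at or above the threshold); among tied thresholds the
#' one closest to the midpoint of the class means is used, so two single
#' scores calibrate to their midpoint. Reports false-positive and
#' false-negative rates and per-pair calls.
#'
#' @param scores numeric index values, or a list of `interaction_score`s.
#' @param labels character/factor vector of `"positive"` / `"negative"`.
#' @return object of class `kir_calibration`: `threshold`, `fp_rate`,
#'   `fn_rate`, `error_rate`, `calls`.
#' @export
calibrate_and_classify <- function(scores, labels) {
  if (is.list(scores) && all(vapply(scores, inherits, TRUE,
                                    "interaction_score")))
    scores <- vapply(scores, function(s) s$I, 0)
  labels <- as.character(labels)
  if (!all(labels %in% c("positive", "negative")))
    stop("labels must be 'positive' or 'negative'")
  pos <- scores[labels == "positive"]; neg <- scores[labels == "negative"]
  if (!length(pos) || !length(neg))
    stop("need at least one score in each class")
  mid <- (mean(pos) + mean(neg)) / 2
  # cut-point errors via cumulative counts over the sorted unique scores
  su <- sort(unique(scores))
  npos_at <- vapply(su, function(v) sum(pos == v), 0)
  nneg_at <- vapply(su, function(v) sum(neg == v), 0)
  if (length(su) > 20) {  # tally by match for large inputs
    npos_at <- tabulate(match(pos, su), length(su))
    nneg_at <- tabulate(match(neg, su), length(su))
  }
  cum_pos <- cumsum(npos_at)
  cum_neg <- cumsum(nneg_at)
  cand <- if (length(su) > 1) (su[-1] + su[-length(su)]) / 2 else numeric(0)
  err <- cum_pos[-length(su)] + (length(neg) - cum_neg[-length(su)])
  cand <- c(cand, mid)
  err <- c(err, sum(pos < mid) + sum(neg >= mid))
  best <- cand[err == min(err)]
  threshold <- best[which.min(abs(best - mid))]
  calls <- ifelse(scores >= threshold, "interacting", "non-interacting")
  structure(list(threshold = threshold,
                 fp_rate = sum(neg >= threshold) / length(neg),
                 fn_rate = sum(pos < threshold) / length(pos),
                 error_rate = (sum(neg >= threshold) + sum(pos < threshold)) /
                   length(scores),
                 calls = calls, n_positive = length(pos),
                 n_negative = length(neg)),
            class = "kir_calibration")
}

#' @export
print.kir_calibration <- function(x, ...) {
  cat(sprintf(
    "kir_calibration: threshold = %.4g; FP = %.1f%%, FN = %.1f%% (n+ = %d, n- = %d)\n",
    x$threshold, 100 * x$fp_rate, 100 * x$fn_rate, x$n_positive,
    x$n_negative))
  invisible(x)
}
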