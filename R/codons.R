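# Codon-level machinery shared by the simulator and the site-model fitter:
# the universal genetic code over the 61 sense codons, F3X4 frequency
# estimation, and the GY94-style 61x61 rate matrix with its spectral
# decomposition (reversible, so symmetrizable).

.NT <- c("T", "C", "A", "G")

# universal code, codons ordered base1/base2/base3 each T,C,A,G
.AA64 <- strsplit("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
                  "")[[1]]

.codon_env <- new.env(parent = emptyenv())

codon_space <- function() {
  if (!is.null(.codon_env$codons)) return(as.list(.codon_env))
  cod64 <- character(64)
  k <- 0
  for (n1 in .NT) for (n2 in .NT) for (n3 in .NT) {
    k <- k + 1
    cod64[k] <- paste0(n1, n2, n3)
  }
  sense <- .AA64 != "*"
  codons <- cod64[sense]
  aa <- .AA64[sense]
  n <- length(codons)                       # 61
  cmat <- do.call(rbind, strsplit(codons, ""))

  # single-nucleotide neighbour structure for the rate matrix
  from <- integer(0); to <- integer(0)
  pos <- integer(0); ts <- logical(0); syn <- logical(0)
  is_transition <- function(x, y) {
    (x %in% c("A", "G") && y %in% c("A", "G")) ||
      (x %in% c("C", "T") && y %in% c("C", "T"))
  }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    diff <- which(cmat[i, ] != cmat[j, ])
    if (length(diff) == 1L) {
      from <- c(from, i); to <- c(to, j); pos <- c(pos, diff)
      ts <- c(ts, is_transition(cmat[i, diff], cmat[j, diff]))
      syn <- c(syn, aa[i] == aa[j])
    }
  }
  .codon_env$codons <- codons
  .codon_env$aa <- aa
  .codon_env$cmat <- cmat
  .codon_env$nbr <- data.frame(from = from, to = to, pos = pos,
                               transition = ts, synonymous = syn)
  as.list(.codon_env)
}

#' Translate a nucleotide string to amino acids
#'
#' Uses the universal genetic code. Codons containing gaps or ambiguity
#' characters translate to `"X"` (or `"-"` for all-gap codons); stop codons
#' translate to `"*"`.
#'
#' @param seq single nucleotide string, length divisible by 3.
#' @return character vector of one-letter residues.
#' @export
translate_codons <- function(seq) {
  seq <- toupper(gsub("U", "T", seq))
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3: ", n)
  cs <- codon_space()
  cods <- substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
  map <- c(stats::setNames(cs$aa, cs$codons),
           stats::setNames(rep("*", 3), c("TAA", "TAG", "TGA")))
  out <- map[cods]
  out[is.na(out)] <- ifelse(cods[is.na(out)] == "---", "-", "X")
  unname(out)
}

#' F3X4 codon frequencies from an alignment
#'
#' Positional nucleotide frequencies are estimated from codon positions 1-3
#' of the whole alignment; sense-codon frequencies are the products,
#' renormalized after excluding stop codons. A small pseudo-frequency keeps
#' every sense codon strictly positive.
#'
#' @param aln an [aligned_set] (codon-aware, length divisible by 3).
#' @return numeric vector of 61 frequencies summing to 1, named by codon.
#' @export
f3x4_frequencies <- function(aln) {
  seqs <- aln_sequences(aln)
  L <- nchar(seqs[1])
  if (L %% 3L != 0L) stop("alignment length not divisible by 3")
  chars <- do.call(rbind, strsplit(toupper(seqs), ""))
  posfreq <- matrix(0, 3, 4, dimnames = list(NULL, .NT))
  for (p in 1:3) {
    cols <- seq(p, L, by = 3L)
    tab <- table(factor(chars[, cols], levels = .NT))
    posfreq[p, ] <- (tab + 1e-6) / sum(tab + 1e-6)
  }
  cs <- codon_space()
  f <- posfreq[1, cs$cmat[, 1]] * posfreq[2, cs$cmat[, 2]] *
    posfreq[3, cs$cmat[, 3]]
  f <- f / sum(f)
  stats::setNames(f, cs$codons)
}

# GY94-style instantaneous rate matrix over sense codons.
# q_ij = pi_j * kappa^[transition] * omega^[nonsynonymous] for single-nt
# changes, 0 otherwise; unscaled (caller scales to expected subs/codon).
codon_rate_matrix <- function(kappa, omega, pi) {
  cs <- codon_space()
  n <- length(cs$codons)
  Q <- matrix(0, n, n)
  nbr <- cs$nbr
  rate <- ifelse(nbr$transition, kappa, 1) * ifelse(nbr$synonymous, 1, omega)
  Q[cbind(nbr$from, nbr$to)] <- rate * pi[nbr$to]
  Q[cbind(nbr$to, nbr$from)] <- rate * pi[nbr$from]
  diag(Q) <- -rowSums(Q)
  Q
}

# mean substitution rate under pi (positive scalar)
codon_mean_rate <- function(Q, pi) -sum(pi * diag(Q))

# Spectral decomposition of a reversible Q via symmetrization.
# Returns U, Uinv, lambda with P(t) = U %*% diag(exp(lambda t)) %*% Uinv.
codon_eigen <- function(Q, pi) {
  d <- sqrt(pi)
  S <- Q * (d %o% (1 / d))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(U = e$vectors / d, Uinv = t(e$vectors) * rep(d, each = nrow(Q)),
       lambda = e$values)
}

codon_pmat <- function(dec, t) {
  P <- dec$U %*% (exp(dec$lambda * t) * dec$Uinv)
  P[P < 0] <- 0
  P
}
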