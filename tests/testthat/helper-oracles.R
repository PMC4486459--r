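# Independent oracles: these reimplement the checked quantities by a
# different route (brute-force enumeration, closed forms, dense matrix
# exponentials) and never call the code paths they verify.

# Brute-force codon likelihood: explicit summation over all ancestral
# state assignments, with transition probabilities from Matrix::expm.
brute_force_codon_lnl <- function(aln, tree, kappa, omega, scale = 1) {
  pi <- f3x4_frequencies(aln)
  Q <- mhcdiv:::codon_rate_matrix(kappa, omega, pi)
  Q <- Q / mhcdiv:::codon_mean_rate(Q, pi)
  tr <- ape::reorder.phylo(tree, "postorder")
  Ps <- lapply(seq_len(nrow(tr$edge)), function(e)
    as.matrix(Matrix::expm(Q * tr$edge.length[e] * scale)))
  states <- mhcdiv:::encode_codon_states(aln)[tr$tip.label, , drop = FALSE]
  ntip <- nrow(states)
  root <- tr$edge[nrow(tr$edge), 1]
  internals <- sort(unique(tr$edge[, 1]))
  grid <- as.matrix(expand.grid(rep(list(1:61), length(internals))))
  lnl <- 0
  for (s in seq_len(ncol(states))) {
    tot <- 0
    stv <- integer(max(internals))
    stv[seq_len(ntip)] <- states[, s]
    for (g in seq_len(nrow(grid))) {
      stv[internals] <- grid[g, ]
      p <- pi[stv[root]]
      for (e in seq_len(nrow(tr$edge)))
        p <- p * Ps[[e]][stv[tr$edge[e, 1]], stv[tr$edge[e, 2]]]
      tot <- tot + p
    }
    lnl <- lnl + log(tot)
  }
  unname(lnl)
}

# Closed-form TN93 distance written out independently of the package's
# composite estimator.
oracle_tn93 <- function(seq1, seq2) {
  a <- strsplit(seq1, "")[[1]]; b <- strsplit(seq2, "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  f <- table(factor(c(a, b), levels = c("A", "C", "G", "T"))) / (2 * n)
  piA <- f[["A"]]; piC <- f[["C"]]; piG <- f[["G"]]; piT <- f[["T"]]
  piR <- piA + piG; piY <- piC + piT
  P1 <- mean((a == "A" & b == "G") | (a == "G" & b == "A"))
  P2 <- mean((a == "C" & b == "T") | (a == "T" & b == "C"))
  Q <- mean(a != b) - P1 - P2
  k1 <- 2 * piA * piG / piR
  k2 <- 2 * piC * piT / piY
  k3 <- 2 * (piR * piY - piA * piG * piY / piR - piC * piT * piR / piY)
  w1 <- 1 - P1 / k1 - Q / (2 * piR)
  w2 <- 1 - P2 / k2 - Q / (2 * piY)
  w3 <- 1 - Q / (2 * piR * piY)
  -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
}

# simulate one sequence pair at true TN93 distance d (dense expm route)
simulate_tn93_pair <- function(L, d, k1 = 3, k2 = 4,
                               pi = c(0.3, 0.2, 0.25, 0.25), seed = 1) {
  set.seed(seed)
  Q <- matrix(1, 4, 4)
  Q[1, 3] <- Q[3, 1] <- k1
  Q[2, 4] <- Q[4, 2] <- k2
  Q <- sweep(Q, 2, pi, "*"); diag(Q) <- 0; diag(Q) <- -rowSums(Q)
  Q <- Q / -sum(pi * diag(Q))
  P <- as.matrix(Matrix::expm(Q * d))
  nt <- c("A", "C", "G", "T")
  anc <- sample.int(4, L, replace = TRUE, prob = pi)
  der <- vapply(anc, function(s) sample.int(4, 1, prob = P[s, ]), 0L)
  c(x = paste(nt[anc], collapse = ""), y = paste(nt[der], collapse = ""))
}

# Brute-force interface hydrogen-bond count: plain triple loop over all
# atom pairs with the same geometric definition as the detector's contract.
brute_force_hbonds <- function(s, d_cutoff = 3.5, angle_cutoff = 90,
                               h_angle_cutoff = 120) {
  a <- s$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  has_h <- any(a$element == "H")
  dist <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  ang <- function(p, q, r) {
    v1 <- xyz[p, ] - xyz[q, ]; v2 <- xyz[r, ] - xyz[q, ]
    acos(min(max(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) *
      180 / pi
  }
  donor_ok <- function(d_i, a_i) {
    same <- which(a$chain == a$chain[d_i])
    if (has_h) {
      hs <- same[a$element[same] == "H" &
                   vapply(same, dist, 0, j = d_i) <= 1.25 &
                   vapply(same, dist, 0, j = d_i) > 1e-6]
      if (!length(hs)) return(FALSE)
      return(any(vapply(hs, function(h) ang(d_i, h, a_i), 0) >=
                   h_angle_cutoff))
    }
    cc <- same[a$element[same] == "C"]
    cc <- cc[vapply(cc, dist, 0, j = d_i) <= 1.8 &
               vapply(cc, dist, 0, j = d_i) > 1e-6]
    if (!length(cc)) return(TRUE)
    any(vapply(cc, function(x) ang(x, d_i, a_i), 0) >= angle_cutoff)
  }
  count <- 0L
  A <- which(a$role == "MHC" & a$element %in% c("N", "O"))
  B <- which(a$role == "KIR" & a$element %in% c("N", "O"))
  for (i in A) for (j in B) {
    if (dist(i, j) > d_cutoff) next
    if (donor_ok(i, j) || donor_ok(j, i)) count <- count + 1L
  }
  count
}

# assemble an aligned_set of k mutated copies of a base sequence
mutant_family <- function(base, k, n_mut, tag = "s", seed = 1) {
  set.seed(seed)
  nt <- c("A", "C", "G", "T")
  out <- character(0)
  v0 <- strsplit(base, "")[[1]]
  for (i in seq_len(k)) {
    v <- v0
    pos <- sample(length(v), n_mut)
    for (p in pos) v[p] <- sample(setdiff(nt, v[p]), 1)
    out[paste0(tag, i)] <- paste(v, collapse = "")
  }
  out
}

random_dna <- function(L, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

TREE6 <- "((a:0.15,b:0.2):0.1,(c:0.12,d:0.18):0.08,(e:0.2,f:0.1):0.12);"
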