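# Maximum composite likelihood pairwise distances in the Tamura-Nei family:
# base frequencies and the two transition/transversion rate ratios are
# shared across all pairs (estimated by maximizing the summed pair
# likelihoods), while each pair keeps its own divergence. Standard errors
# come from a site-resampling bootstrap. Gap/N columns are handled by
# pairwise deletion.

.DNT <- c("A", "C", "G", "T")   # purines 1,3; pyrimidines 2,4

.encode_nt <- function(aln) {
  m <- aln_matrix(aln)
  s <- matrix(match(m, .DNT), nrow(m), ncol(m), dimnames = dimnames(m))
  s
}

# TN93 rate matrix (transversions 1, A<->G k1, C<->T k2), scaled to mean
# rate 1, with its spectral decomposition
.tn93_machine <- function(k1, k2, pi) {
  Q <- matrix(1, 4, 4)
  Q[1, 3] <- Q[3, 1] <- k1
  Q[2, 4] <- Q[4, 2] <- k2
  Q <- sweep(Q, 2L, pi, "*")
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q <- Q / -sum(pi * diag(Q))
  d <- sqrt(pi)
  S <- (Q * (d %o% (1 / d)) + t(Q * (d %o% (1 / d)))) / 2
  e <- eigen(S, symmetric = TRUE)
  list(U = e$vectors / d, Vt = t(e$vectors) * rep(d, each = 4),
       lambda = e$values, pi = pi)
}

.tn93_pmat <- function(mach, t) {
  P <- mach$U %*% (exp(mach$lambda * t) * mach$Vt)
  P[P < 0] <- 0
  P
}

# log composite likelihood of one pair's symmetrized 4x4 count matrix
.pair_loglik <- function(F, mach, t) {
  P <- .tn93_pmat(mach, t)
  M <- mach$pi * P
  sel <- F > 0
  sum(F[sel] * log(pmax(M[sel], 1e-300)))
}

.pair_mle_t <- function(F, mach, upper = 15) {
  if (sum(F) == 0) return(NA_real_)
  off <- sum(F) - sum(diag(F))
  if (off == 0) return(0)
  stats::optimize(function(t) -.pair_loglik(F, mach, t),
                  interval = c(1e-9, upper), tol = 1e-9)$minimum
}

#' Closed-form Tamura-Nei (TN93) distance for one pair
#'
#' The classical method-of-moments/ML inversion from the two transition
#' proportions and the transversion proportion, with supplied (or pooled)
#' base frequencies. Returns `NaN` when the estimator diverges (saturated
#' pair).
#'
#' @param p1 proportion of sites with an A/G difference.
#' @param p2 proportion of sites with a C/T difference.
#' @param q proportion of sites with a transversion difference.
#' @param pi base frequencies in A, C, G, T order.
#' @return distance in substitutions per site.
#' @export
tn93_closed_form <- function(p1, p2, q, pi) {
  piR <- pi[1] + pi[3]; piY <- pi[2] + pi[4]
  k1 <- 2 * pi[1] * pi[3] / piR
  k2 <- 2 * pi[2] * pi[4] / piY
  k3 <- 2 * (piR * piY - pi[1] * pi[3] * piY / piR -
               pi[2] * pi[4] * piR / piY)
  w1 <- 1 - p1 / k1 - q / (2 * piR)
  w2 <- 1 - p2 / k2 - q / (2 * piY)
  w3 <- 1 - q / (2 * piR * piY)
  if (any(c(w1, w2, w3) <= 0)) return(NaN)
  unname(-k1 * log(w1) - k2 * log(w2) - k3 * log(w3))
}

# per-pair 16-category column classification; rows indexed by pair
.pair_categories <- function(s) {
  n <- nrow(s); L <- ncol(s)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  C <- matrix(NA_integer_, nrow(pairs), L)
  for (p in seq_len(nrow(pairs))) {
    a <- s[pairs[p, 1], ]; b <- s[pairs[p, 2], ]
    C[p, ] <- (a - 1L) * 4L + b
  }
  list(C = C, pairs = pairs)
}

.counts_from_cat <- function(catrow) {
  F <- matrix(tabulate(catrow, 16L), 4, 4, byrow = TRUE)
  (F + t(F)) / 2
}

#' Maximum composite likelihood distance matrix
#'
#' Estimates all pairwise distances under a Tamura-Nei model whose base
#' frequencies and two transition/transversion rate ratios are shared by
#' every pair (the composite-likelihood estimator behind "Maximum Composite
#' Likelihood" distances), with per-pair divergences maximized numerically.
#' Standard errors are from a site-resampling bootstrap; the shared rate
#' parameters are held at their full-data estimates across replicates.
#' Gaps and Ns are removed pairwise. Pairs for which the estimator diverges
#' are flagged as saturated (`NaN`), never silently capped.
#'
#' @param aln an [aligned_set] with at least 2 sequences.
#' @param bootstrap_reps number of bootstrap replicates for standard errors
#'   (default 1000; 0 disables the bootstrap).
#' @param seed seed for the bootstrap resampling.
#' @return object of class `mcl_dist`: `d` and `se` matrices
#'   (substitutions/site), `labels`, `params` (shared `k1`, `k2`, `pi`),
#'   `saturated` logical matrix, and the replicate pair distances needed by
#'   [group_distance()].
#' @export
mcl_distances <- function(aln, bootstrap_reps = 1000L, seed = 1L) {
  s <- .encode_nt(aln)
  n <- nrow(s)
  if (n < 2L) stop("need at least 2 sequences")
  labels <- rownames(s)
  tab <- tabulate(s, 4L)
  pi <- (tab + 1e-9) / sum(tab + 1e-9)

  pc <- .pair_categories(s)
  np <- nrow(pc$pairs)
  Fs <- lapply(seq_len(np), function(p) .counts_from_cat(pc$C[p, ]))

  # shared k1, k2 by alternating maximization (2 rounds is ample)
  est_t <- function(mach) vapply(Fs, .pair_mle_t, 0, mach = mach)
  kpar <- c(lk1 = log(2), lk2 = log(2))
  mach <- .tn93_machine(2, 2, pi)
  tcur <- est_t(mach)
  for (round in 1:2) {
    obj <- function(lk) {
      lk <- pmin(pmax(lk, -10), 10)   # rate ratios unidentifiable beyond this
      m <- .tn93_machine(exp(lk[1]), exp(lk[2]), pi)
      -sum(vapply(seq_len(np), function(p) {
        t <- tcur[p]
        if (!is.finite(t)) return(0)
        .pair_loglik(Fs[[p]], m, max(t, 1e-9))
      }, 0))
    }
    kpar <- stats::optim(kpar, obj, method = "BFGS")$par
    kpar <- pmin(pmax(kpar, -10), 10)
    mach <- .tn93_machine(exp(kpar[1]), exp(kpar[2]), pi)
    tcur <- est_t(mach)
  }

  # saturation check through the closed-form inversion on pooled freqs
  sat <- vapply(seq_len(np), function(p) {
    F <- Fs[[p]]; tot <- sum(F)
    if (tot == 0) return(TRUE)
    p1 <- 2 * F[1, 3] / tot; p2 <- 2 * F[2, 4] / tot
    q <- (2 * (F[1, 2] + F[1, 4] + F[2, 3] + F[3, 4])) / tot
    !is.finite(tn93_closed_form(p1, p2, q, pi)) && (p1 + p2 + q) > 0
  }, TRUE)
  tcur[sat] <- NaN

  D <- matrix(0, n, n, dimnames = list(labels, labels))
  SAT <- matrix(FALSE, n, n, dimnames = list(labels, labels))
  D[pc$pairs] <- tcur; D[pc$pairs[, c(2, 1)]] <- tcur
  SAT[pc$pairs] <- sat; SAT[pc$pairs[, c(2, 1)]] <- sat

  SE <- matrix(0, n, n, dimnames = list(labels, labels))
  reps <- NULL
  if (bootstrap_reps > 0L) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    L <- ncol(s)
    reps <- matrix(NA_real_, np, bootstrap_reps)
    for (r in seq_len(bootstrap_reps)) {
      idx <- sample.int(L, L, replace = TRUE)
      for (p in seq_len(np)) {
        F <- .counts_from_cat(pc$C[p, idx])
        reps[p, r] <- .pair_mle_t(F, mach)
      }
    }
    sev <- apply(reps, 1L, stats::sd, na.rm = TRUE)
    sev[vapply(seq_len(np), function(p) sum(Fs[[p]]) > 0 &&
                 sum(Fs[[p]]) == sum(diag(Fs[[p]])), TRUE)] <- 0
    SE[pc$pairs] <- sev; SE[pc$pairs[, c(2, 1)]] <- sev
  }

  structure(list(d = D, se = SE, labels = labels,
                 params = list(k1 = exp(kpar[["lk1"]]),
                               k2 = exp(kpar[["lk2"]]), pi = pi),
                 saturated = SAT, pair_index = pc$pairs,
                 replicates = reps),
            class = "mcl_dist")
}

#' @export
print.mcl_dist <- function(x, ...) {
  off <- x$d[upper.tri(x$d)]
  cat("mcl_dist:", length(x$labels), "sequences;",
      "mean pairwise d =", format(mean(off, na.rm = TRUE), digits = 4))
  if (any(x$saturated)) cat(" [", sum(x$saturated[upper.tri(x$saturated)]),
                            "saturated pair(s) ]")
  cat("\n  shared rates: k1 =", format(x$params$k1, digits = 4),
      " k2 =", format(x$params$k2, digits = 4), "\n")
  invisible(x)
}

#' Mean distance within or between sequence groups
#'
#' Arithmetic mean of the relevant distance-matrix cells, with a standard
#' error propagated from the stored bootstrap replicates of the full
#' matrix (the same resamples that produced the per-pair SEs).
#'
#' @param dm an [mcl_distances()] result.
#' @param groups for `mode = "within"` a character vector of labels (one
#'   group, >= 2 members) or a list of such vectors (cells pooled);
#'   for `mode = "between"` a list of exactly two label vectors.
#' @param mode `"within"` or `"between"`.
#' @return named numeric vector `c(mean, se)` (se `NA` without bootstrap).
#' @export
group_distance <- function(dm, groups, mode = c("within", "between")) {
  mode <- match.arg(mode)
  if (is.character(groups)) groups <- list(groups)
  for (g in groups) {
    if (!length(g)) stop("empty group")
    miss <- setdiff(g, dm$labels)
    if (length(miss)) stop("labels not in matrix: ",
                           paste(miss, collapse = ", "))
  }
  idx <- function(v) match(v, dm$labels)
  cells <- NULL
  if (mode == "within") {
    for (g in groups) {
      if (length(g) < 2L) stop("within-group mode needs >= 2 members")
      ii <- idx(g)
      cmb <- t(utils::combn(sort(ii), 2L))
      cells <- rbind(cells, cmb)
    }
  } else {
    if (length(groups) != 2L)
      stop("between mode needs a list of exactly two groups")
    gr <- expand.grid(idx(groups[[1]]), idx(groups[[2]]))
    cells <- cbind(pmin(gr[, 1], gr[, 2]), pmax(gr[, 1], gr[, 2]))
    if (any(cells[, 1] == cells[, 2]))
      stop("groups overlap")
  }
  dvals <- dm$d[cells]
  m <- mean(dvals)
  se <- NA_real_
  if (!is.null(dm$replicates)) {
    pid <- match(paste(cells[, 1], cells[, 2]),
                 paste(dm$pair_index[, 1], dm$pair_index[, 2]))
    se <- stats::sd(colMeans(dm$replicates[pid, , drop = FALSE],
                             na.rm = TRUE), na.rm = TRUE)
  }
  c(mean = m, se = se)
}
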