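# Maximum likelihood codon site models (M0, M1a, M2a, M3, M8) in the GY94
# family, with F3X4 codon frequencies estimated from the data, a free
# branch-length scale on a fixed guide-tree topology, naive empirical Bayes
# site posteriors, likelihood ratio tests, and the two-of-three consensus
# rule for calling positively selected sites.

.SITE_MODELS <- c("M0", "M1a", "M2a", "M3", "M8")
.M8_NCAT <- 10L

# integer codon states per sequence; 0 = gap/ambiguous; errors on internal
# stop codons, masks a terminal stop column
encode_codon_states <- function(aln) {
  seqs <- aln_sequences(aln)
  L <- nchar(seqs[1])
  if (L %% 3L != 0L) stop("alignment length not divisible by 3")
  nc <- L %/% 3L
  cs <- codon_space()
  idx <- stats::setNames(seq_len(61), cs$codons)
  stops <- c("TAA", "TAG", "TGA")
  out <- matrix(0L, length(seqs), nc, dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs)) {
    cods <- substring(seqs[i], seq(1L, L, 3L), seq(3L, L, 3L))
    st <- unname(idx[cods])
    st[is.na(st)] <- 0L
    is_stop <- cods %in% stops
    if (any(is_stop)) {
      internal <- which(is_stop & seq_len(nc) < nc)
      if (length(internal))
        stop("internal stop codon in sequence '", names(seqs)[i],
             "' at codon position(s) ", paste(internal, collapse = ", "))
      st[nc] <- 0L
    }
    out[i, ] <- st
  }
  out
}

# collapse identical codon columns into patterns
compress_patterns <- function(states) {
  key <- apply(states, 2L, paste0, collapse = ",")
  u <- !duplicated(key)
  list(patterns = states[, u, drop = FALSE],
       weights = as.vector(table(factor(key, levels = key[u]))),
       map = match(key, key[u]))
}

# (proportions, omegas) of the discrete site classes for a parameter vector
# on the unconstrained scale
.class_structure <- function(model, par) {
  plogis_ <- stats::plogis
  switch(model,
    M0 = list(prop = 1, omega = exp(par[["lw"]])),
    M1a = {
      p0 <- plogis_(par[["a0"]])
      list(prop = c(p0, 1 - p0), omega = c(plogis_(par[["lw0"]]), 1))
    },
    M2a = {
      ea <- exp(c(par[["a0"]], par[["a1"]], 0))
      p <- ea / sum(ea)
      list(prop = p,
           omega = c(plogis_(par[["lw0"]]), 1, 1 + exp(par[["lw2"]])))
    },
    M3 = {
      ea <- exp(c(par[["a0"]], par[["a1"]], 0))
      list(prop = ea / sum(ea),
           omega = exp(c(par[["lw0"]], par[["lw1"]], par[["lw2"]])))
    },
    M8 = {
      p0 <- plogis_(par[["a0"]])
      # bound the beta shapes to the conventional identifiable range
      # (0.005, 99]; outside it qbeta is numerically meaningless
      p <- min(max(exp(par[["lp"]]), 0.005), 99)
      q <- min(max(exp(par[["lq"]]), 0.005), 99)
      K <- .M8_NCAT
      # qbeta emits precision warnings for near-degenerate shapes the
      # optimizer passes through; the category medians remain usable
      cats <- suppressWarnings(
        stats::qbeta((2 * seq_len(K) - 1) / (2 * K), p, q))
      list(prop = c(rep(p0 / K, K), 1 - p0),
           omega = c(cats, 1 + exp(par[["lws"]])))
    },
    stop("unknown model: ", model))
}

.start_params <- function(model) {
  base <- list(ls = log(1), lk = log(2))
  extra <- switch(model,
    M0 = list(lw = log(0.4)),
    M1a = list(a0 = stats::qlogis(0.7), lw0 = stats::qlogis(0.2)),
    M2a = list(a0 = log(0.7 / 0.1), a1 = log(0.2 / 0.1),
               lw0 = stats::qlogis(0.2), lw2 = log(2 - 1)),
    M3 = list(a0 = 0, a1 = 0, lw0 = log(0.05), lw1 = log(0.4),
              lw2 = log(1.5)),
    M8 = list(a0 = stats::qlogis(0.9), lp = log(0.5), lq = log(1.5),
              lws = log(2 - 1)))
  unlist(c(base, extra))
}

# per-pattern per-class log-likelihood matrix for given parameters
.pattern_class_loglik <- function(par, model, pi, tr, tips, nnode) {
  cls <- .class_structure(model, par)
  kappa <- exp(par[["lk"]]); s <- exp(par[["ls"]])
  uo <- unique(cls$omega)
  Qs <- lapply(uo, function(w) codon_rate_matrix(kappa, w, pi))
  names(Qs) <- as.character(uo)
  rates <- vapply(Qs, codon_mean_rate, 0, pi = pi)
  mean_rate <- sum(cls$prop * rates[as.character(cls$omega)])
  decs <- lapply(Qs, function(Q) codon_eigen(Q / mean_rate, pi))
  K <- length(cls$omega)
  lambda <- matrix(0, 61, K); U <- array(0, c(61, 61, K))
  Uinv <- array(0, c(61, 61, K))
  for (k in seq_len(K)) {
    d <- decs[[as.character(cls$omega[k])]]
    lambda[, k] <- d$lambda; U[, , k] <- d$U; Uinv[, , k] <- d$Uinv
  }
  ll <- codon_class_loglik(lambda, U, Uinv, tr$edge, tr$edge.length * s,
                           tips, pi, nnode)
  list(loglik = ll, cls = cls)
}

.mixture_lnl <- function(pcl, weights) {
  lp <- sweep(pcl$loglik, 2L, log(pcl$cls$prop), "+")
  m <- apply(lp, 1L, max)
  sum(weights * (m + log(rowSums(exp(lp - m)))))
}

#' Fit a codon site model by maximum likelihood
#'
#' Fits one of the GY94-family site models M0 (one ratio), M1a (nearly
#' neutral), M2a (positive selection), M3 (discrete, 3 classes) or M8
#' (beta plus omega_s >= 1, 10 equal-probability beta categories) on a fixed
#' tree topology. The log-likelihood is maximized over kappa, the class
#' parameters and a single branch-length scale; codon frequencies are F3X4,
#' estimated from the alignment. Optimization is multi-start BFGS on an
#' unconstrained reparameterization with deterministic perturbed restarts.
#'
#' @param aln an [aligned_set]; length divisible by 3, no internal stop
#'   codons, sequence names matching the tree's tip labels.
#' @param tree a `phylo` guide tree with branch lengths (any overall scale;
#'   a free scale factor is estimated), typically the neighbor-joining tree.
#' @param model_id one of `"M0"`, `"M1a"`, `"M2a"`, `"M3"`, `"M8"`.
#' @param n_starts number of deterministic optimizer restarts (default 2).
#' @return object of class `site_model_fit` with elements `lnL`, `kappa`,
#'   `class_params` (`proportion`, `omega` per class, plus beta `p`, `q` for
#'   M8), `scale`, `per_site_posterior` (sites x classes, naive empirical
#'   Bayes at the MLE), `p_positive` (per-site posterior mass on classes
#'   with omega > 1), `converged`, and `degenerate`.
#' @export
fit_site_model <- function(aln, tree, model_id = "M0", n_starts = 2L) {
  model_id <- match.arg(model_id, .SITE_MODELS)
  states <- encode_codon_states(aln)
  if (!setequal(rownames(states), tree$tip.label))
    stop("tree tip labels do not match sequence names")
  tr <- ape::reorder.phylo(tree, "postorder")
  if (any(tr$edge.length < 0)) tr$edge.length[tr$edge.length < 0] <- 0
  states <- states[tr$tip.label, , drop = FALSE]
  nsite <- ncol(states)
  pi <- f3x4_frequencies(aln)

  # invariant data: omega unidentifiable; likelihood is the multinomial
  # constant of the stationary frequencies
  varying <- apply(states, 2L, function(col) {
    obs <- col[col > 0L]
    length(unique(obs)) > 1L
  })
  if (!any(varying)) {
    lnL <- sum(vapply(seq_len(nsite), function(j) {
      obs <- states[states[, j] > 0L, j]
      if (!length(obs)) 0 else log(pi[obs[1]])
    }, 0))
    fit <- list(model_id = model_id, lnL = lnL, kappa = NA_real_,
                class_params = NULL, scale = 0,
                per_site_posterior = NULL,
                p_positive = rep(0, nsite), n_sites = nsite,
                converged = TRUE, degenerate = TRUE, frequencies = pi)
    class(fit) <- "site_model_fit"
    return(fit)
  }

  cp <- compress_patterns(states)
  nnode <- length(tr$tip.label) + tr$Nnode
  negll <- function(par) {
    names(par) <- names(p0)
    pcl <- try(.pattern_class_loglik(par, model_id, pi, tr, cp$patterns,
                                     nnode), silent = TRUE)
    if (inherits(pcl, "try-error")) return(1e10)
    v <- -.mixture_lnl(pcl, cp$weights)
    if (!is.finite(v)) 1e10 else v
  }

  p0 <- .start_params(model_id)
  perturb <- list(numeric(length(p0)),
                  rep(0.5, length(p0)) * rep_len(c(1, -1), length(p0)),
                  rep_len(c(-1, 0.5), length(p0)))
  best <- NULL
  for (i in seq_len(max(1L, n_starts))) {
    st <- p0 + perturb[[((i - 1L) %% 3L) + 1L]]
    opt <- stats::optim(st, negll, method = "BFGS",
                        control = list(maxit = 400, reltol = 1e-10))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  par <- best$par; names(par) <- names(p0)
  pcl <- .pattern_class_loglik(par, model_id, pi, tr, cp$patterns, nnode)
  cls <- pcl$cls

  # naive empirical Bayes: class posteriors at the MLE, per site
  lp <- sweep(pcl$loglik, 2L, log(cls$prop), "+")
  m <- apply(lp, 1L, max)
  post_pat <- exp(lp - m) / rowSums(exp(lp - m))
  post <- post_pat[cp$map, , drop = FALSE]
  p_pos <- as.vector(post %*% as.numeric(cls$omega > 1))

  class_params <- data.frame(proportion = cls$prop, omega = cls$omega)
  if (model_id == "M8")
    attr(class_params, "beta") <- c(
      p = min(max(exp(par[["lp"]]), 0.005), 99),
      q = min(max(exp(par[["lq"]]), 0.005), 99))
  fit <- list(model_id = model_id, lnL = -best$value,
              kappa = exp(par[["lk"]]), class_params = class_params,
              scale = exp(par[["ls"]]), per_site_posterior = post,
              p_positive = p_pos, n_sites = nsite,
              converged = best$convergence == 0, degenerate = FALSE,
              frequencies = pi, par = par)
  class(fit) <- "site_model_fit"
  fit
}

#' @export
print.site_model_fit <- function(x, ...) {
  cat("Codon site model", x$model_id, "\n")
  if (x$degenerate) {
    cat("  degenerate fit (no variable sites); lnL =", format(x$lnL), "\n")
    return(invisible(x))
  }
  cat("  lnL =", format(x$lnL, digits = 8), "  kappa =",
      format(x$kappa, digits = 4), "  tree scale =",
      format(x$scale, digits = 4), "\n")
  cat("  site classes:\n")
  print(round(x$class_params, 4))
  if (!x$converged) cat("  [optimizer did not report convergence]\n")
  invisible(x)
}

#' @export
logLik.site_model_fit <- function(object, ...) {
  structure(object$lnL, class = "logLik",
            df = length(object$par) %||% 0, nobs = object$n_sites)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
coef.site_model_fit <- function(object, ...) {
  c(kappa = object$kappa, scale = object$scale,
    omega = if (object$model_id == "M0") object$class_params$omega[1])
}

.NESTED_PAIRS <- list(c("M1a", "M2a"), c("M1a", "M8"), c("M0", "M3"))

#' Likelihood ratio test between nested site models
#'
#' Supported pairs: M1a vs M2a, M1a vs M8, M0 vs M3. The statistic is
#' `2 * (lnL_alt - lnL_null)`, clamped at zero, and the p-value is from a
#' chi-square distribution with two degrees of freedom.
#'
#' @param null_fit,alt_fit fitted [fit_site_model] objects.
#' @return list with `stat`, `df`, `p_value`, and the model pair.
#' @export
lrt <- function(null_fit, alt_fit) {
  pair <- c(null_fit$model_id, alt_fit$model_id)
  ok <- any(vapply(.NESTED_PAIRS, identical, TRUE, y = pair))
  if (!ok)
    stop("not a supported nested pair: ", pair[1], " vs ", pair[2])
  stat <- max(0, 2 * (alt_fit$lnL - null_fit$lnL))
  structure(list(null = pair[1], alt = pair[2], stat = stat, df = 2L,
                 p_value = stats::pchisq(stat, df = 2, lower.tail = FALSE)),
            class = "site_lrt")
}

#' @export
print.site_lrt <- function(x, ...) {
  cat(sprintf("LRT %s vs %s: 2dL = %.4f, df = %d, p = %.4g\n",
              x$null, x$alt, x$stat, x$df, x$p_value))
  invisible(x)
}

#' Positively selected sites by the two-of-three consensus rule
#'
#' A codon site is called positively selected when its empirical Bayes
#' posterior probability of belonging to an omega > 1 class exceeds
#' `threshold` in at least `min_models` of the supplied selection-capable
#' fits (M2a, M3, M8).
#'
#' @param fits named list of [fit_site_model] objects (names among
#'   `"M2a"`, `"M3"`, `"M8"`), all fitted to the same alignment.
#' @param threshold posterior probability cutoff (default 0.9).
#' @param min_models minimum number of supporting models (default 2).
#' @return data.frame with one row per alignment codon position: per-model
#'   posteriors, `n_supporting`, and logical `selected`.
#' @export
selected_sites <- function(fits, threshold = 0.9, min_models = 2L) {
  if (is.null(names(fits)) || !all(names(fits) %in% c("M2a", "M3", "M8")))
    stop("fits must be a named list with names among M2a, M3, M8")
  ns <- vapply(fits, function(f) as.integer(f$n_sites), 0L)
  if (length(unique(ns)) != 1L)
    stop("fits were made on alignments of different lengths")
  pp <- vapply(fits, function(f) f$p_positive, numeric(ns[1]))
  if (is.null(dim(pp))) pp <- matrix(pp, nrow = 1)
  colnames(pp) <- paste0("p_", names(fits))
  n_sup <- rowSums(pp > threshold)
  out <- data.frame(site = seq_len(ns[1]), pp, n_supporting = n_sup,
                    selected = n_sup >= min_models)
  attr(out, "threshold") <- threshold
  attr(out, "min_models") <- min_models
  out
}
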