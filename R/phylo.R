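# Neighbor-joining trees from composite-likelihood distances, bootstrap
# clade support, and extraction of named clusters from anchored reference
# sequences.

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via ape). Negative branch lengths are
#' clamped to zero and flagged in the `clamped_edges` attribute. Non-finite
#' distances (saturated pairs) are an error naming the offending pairs.
#'
#' @param dm an [mcl_distances()] result, a `dist`, or a square matrix.
#' @return a `phylo` tree.
#' @export
build_nj_tree <- function(dm) {
  D <- if (inherits(dm, "mcl_dist")) dm$d else as.matrix(dm)
  if (nrow(D) < 3L) stop("need at least 3 labels")
  bad <- which(!is.finite(D) & upper.tri(D), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite distance(s) for pair(s): ",
         paste(rownames(D)[bad[, 1]], colnames(D)[bad[, 2]],
               sep = " vs ", collapse = "; "))
  tr <- ape::nj(stats::as.dist(D))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    tr$edge.length[neg] <- 0
    attr(tr, "clamped_edges") <- which(neg)
  }
  tr
}

#' Neighbor-joining tree with bootstrap clade support
#'
#' Resamples alignment columns, rebuilds the composite-likelihood distance
#' matrix and the NJ tree for each replicate, and annotates each internal
#' edge of the full-data tree with the percentage of replicate trees
#' containing the corresponding bipartition (stored in `node.label`).
#'
#' @param aln an [aligned_set].
#' @param reps number of bootstrap replicates (>= 1).
#' @param seed RNG seed; fixed seed gives identical supports.
#' @return `phylo` tree with numeric `node.label` supports in `[0, 100]`
#'   (`NA` at the root). Attribute `degenerate` is `TRUE` when the
#'   alignment carries no variation at all.
#' @export
bootstrap_support <- function(aln, reps = 1000L, seed = 1L) {
  if (reps < 1L) stop("reps must be >= 1")
  full <- mcl_distances(aln, bootstrap_reps = 0L)
  tr <- build_nj_tree(full)
  degenerate <- all(full$d[upper.tri(full$d)] == 0)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  L <- aln$length
  btrees <- vector("list", reps)
  for (r in seq_len(reps)) {
    sub <- aln_subset_columns(aln, sample.int(L, L, replace = TRUE))
    bd <- mcl_distances(sub, bootstrap_reps = 0L)
    btrees[[r]] <- build_nj_tree(bd)
  }
  counts <- ape::prop.clades(tr, btrees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supp <- 100 * counts / reps
  supp[1] <- NA  # root pseudo-node of an unrooted tree
  if (degenerate) supp[] <- NA
  tr$node.label <- supp
  attr(tr, "degenerate") <- degenerate
  attr(tr, "bootstrap_reps") <- reps
  tr
}

.rooted_tree <- function(tree, outgroup = NULL) {
  if (!is.null(outgroup)) return(ape::root(tree, outgroup, resolve.root = TRUE))
  if (ape::is.rooted(tree)) return(tree)
  phangorn::midpoint(tree)
}

# canonical key of the bipartition induced by a tip set (side containing
# the alphabetically first tip)
.split_key <- function(tips, all_tips) {
  side <- sort(tips)
  other <- sort(setdiff(all_tips, tips))
  if (length(other) && other[1] < side[1]) side <- other
  paste(side, collapse = "\r")
}

# map bipartition key -> numeric support from a tree's node.label
.support_by_split <- function(tree) {
  out <- list()
  if (is.null(tree$node.label)) return(out)
  ntip <- length(tree$tip.label)
  for (n in seq_len(tree$Nnode)) {
    s <- suppressWarnings(as.numeric(tree$node.label[n]))
    if (is.na(s)) next
    tips <- ape::extract.clade(tree, ntip + n)$tip.label
    out[[.split_key(tips, tree$tip.label)]] <- s
  }
  out
}

#' Assign sequences to named clusters from anchor sequences
#'
#' For each cluster label, the cluster is the smallest well-supported clade
#' (support >= `min_support`, unlabeled edges treated as supported) of the
#' rooted tree that contains all of that cluster's anchor sequences.
#' Leaves outside every cluster are labeled `"unassigned"`.
#'
#' @param tree a `phylo`, ideally with bootstrap `node.label` supports.
#' @param anchors named list: cluster label -> character vector of anchor
#'   tip names present in the tree.
#' @param min_support minimum bootstrap percentage for a defining edge
#'   (default 70).
#' @param outgroup optional tip name(s) used to root the tree; midpoint
#'   rooting is used when absent.
#' @return data.frame (`sequence`, `cluster`, `support`) covering every
#'   tip; class `clade_assignment`.
#' @export
extract_clades <- function(tree, anchors, min_support = 70,
                           outgroup = NULL) {
  stopifnot(is.list(anchors), !is.null(names(anchors)))
  for (cl in names(anchors)) {
    miss <- setdiff(anchors[[cl]], tree$tip.label)
    if (length(miss))
      stop("anchor(s) not in tree for cluster ", cl, ": ",
           paste(miss, collapse = ", "))
  }
  # support is keyed by bipartition (rooting permutes node labels)
  lookup <- .support_by_split(tree)
  rt <- .rooted_tree(tree, outgroup)
  ntip <- length(rt$tip.label)
  root <- ntip + 1L
  supp_of <- function(node) {
    if (node <= ntip) return(NA_real_)
    tips <- ape::extract.clade(rt, node)$tip.label
    key <- .split_key(tips, rt$tip.label)
    if (!is.null(lookup[[key]])) lookup[[key]] else NA_real_
  }
  parent_of <- function(node) {
    e <- which(rt$edge[, 2] == node)
    if (!length(e)) NA_integer_ else rt$edge[e, 1]
  }
  members <- list(); defsup <- numeric(0)
  for (cl in names(anchors)) {
    a <- anchors[[cl]]
    node <- if (length(a) == 1L) match(a, rt$tip.label) else
      ape::getMRCA(rt, a)
    if (node != root) {
      s <- supp_of(node)
      while (!is.na(s) && s < min_support && node != root) {
        node <- parent_of(node)
        s <- supp_of(node)
      }
    }
    tips <- if (node <= ntip) rt$tip.label[node] else
      ape::extract.clade(rt, node)$tip.label
    members[[cl]] <- tips
    defsup[cl] <- if (node == root) NA_real_ else supp_of(node)
  }
  for (i in seq_along(members)) for (j in seq_len(i - 1L)) {
    ov <- intersect(members[[i]], members[[j]])
    if (length(ov))
      stop("cluster conflict: '", names(members)[i], "' and '",
           names(members)[j], "' resolve to overlapping clades (",
           length(ov), " shared tips)")
  }
  cluster <- rep("unassigned", ntip)
  support <- rep(NA_real_, ntip)
  names(cluster) <- names(support) <- rt$tip.label
  for (cl in names(members)) {
    cluster[members[[cl]]] <- cl
    support[members[[cl]]] <- defsup[cl]
  }
  out <- data.frame(sequence = rt$tip.label, cluster = unname(cluster),
                    support = unname(support), row.names = NULL)
  class(out) <- c("clade_assignment", "data.frame")
  out
}

#' @export
print.clade_assignment <- function(x, ...) {
  tab <- table(x$cluster)
  cat("clade_assignment:", nrow(x), "sequences in",
      sum(names(tab) != "unassigned"), "cluster(s)\n")
  print(tab)
  invisible(x)
}
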