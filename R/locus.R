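# Allele-to-locus assignment for a diploid population of cloned cDNAs.
# Rule: locus groups are clades of the guide tree, and no individual may
# carry more than max_alleles unique sequences of one group. The coarsest
# tree-consistent partition satisfying this is found by top-down splitting:
# a clade that violates the constraint is replaced by its child clades,
# recursively. The result is the unique maximal antichain of valid nodes,
# so it is deterministic and provably coarsest.

#' Assign unique sequences to putative loci
#'
#' @param tree `phylo` guide tree whose tips include every genotype-matrix
#'   column; rooted trees are used as-is, unrooted trees are midpoint
#'   rooted.
#' @param gm genotype matrix: individuals x unique sequences, 0/1 presence
#'   (counts are also accepted).
#' @param max_alleles maximum sequences per individual per locus group
#'   (default 2, diploidy).
#' @param outgroup optional tip name(s) for rooting.
#' @return object of class `locus_partition`: `groups` (named list of
#'   sequence sets, in tree order), `per_individual_counts`
#'   (individuals x groups), and `valid` (`FALSE` if even single-sequence
#'   groups violate the constraint).
#' @export
assign_loci <- function(tree, gm, max_alleles = 2L, outgroup = NULL) {
  gm <- as.matrix(gm)
  if (is.null(colnames(gm)) || is.null(rownames(gm)))
    stop("genotype matrix needs individual row names and sequence column names")
  miss <- setdiff(colnames(gm), tree$tip.label)
  if (length(miss))
    stop("sequences absent from tree: ", paste(miss, collapse = ", "))
  if (any(colSums(gm) == 0))
    stop("genotype matrix has all-absent sequence column(s)")

  rt <- .rooted_tree(tree, outgroup)
  keep <- intersect(rt$tip.label, colnames(gm))
  if (length(keep) < length(rt$tip.label))
    rt <- ape::keep.tip(rt, keep)
  ntip <- length(rt$tip.label)

  children_of <- split(rt$edge[, 2], rt$edge[, 1])
  clade_tips <- function(node) {
    if (node <= ntip) return(rt$tip.label[node])
    unlist(lapply(children_of[[as.character(node)]], clade_tips),
           use.names = FALSE)
  }
  ok <- function(tips) {
    cnt <- rowSums(gm[, tips, drop = FALSE])
    all(cnt <= max_alleles)
  }
  groups <- list()
  valid <- TRUE
  descend <- function(node) {
    tips <- clade_tips(node)
    if (ok(tips)) {
      groups[[length(groups) + 1L]] <<- tips
    } else if (node <= ntip) {
      groups[[length(groups) + 1L]] <<- tips
      valid <<- FALSE
    } else {
      for (ch in children_of[[as.character(node)]]) descend(ch)
    }
  }
  descend(ntip + 1L)

  names(groups) <- paste0("L", seq_along(groups))
  counts <- vapply(groups, function(g)
    rowSums(gm[, g, drop = FALSE]), numeric(nrow(gm)))
  if (is.null(dim(counts)))
    counts <- matrix(counts, nrow = nrow(gm),
                     dimnames = list(rownames(gm), names(groups)))
  structure(list(groups = groups, per_individual_counts = counts,
                 valid = valid, max_alleles = max_alleles, tree = rt),
            class = "locus_partition")
}

#' @export
print.locus_partition <- function(x, ...) {
  cat("locus_partition:", length(x$groups), "group(s);",
      if (x$valid) "valid" else "INVALID (constraint unsatisfiable)", "\n")
  for (g in names(x$groups))
    cat(" ", g, ":", length(x$groups[[g]]), "sequence(s)\n")
  invisible(x)
}

#' Haplotype gene-content (copy number) variation report
#'
#' An individual "carries" a locus group when it has at least one sequence
#' of that group. Haplotypic gene-content variation is flagged when some
#' individual lacks a group that another individual carries.
#'
#' @param part a [assign_loci()] result.
#' @param gm the genotype matrix used for the partition.
#' @return list with `carries_locus` (logical individuals x groups matrix),
#'   `haplotypic_variation` flag, and per-group lists of lacking
#'   individuals.
#' @export
detect_cnv <- function(part, gm) {
  stopifnot(inherits(part, "locus_partition"))
  if (!part$valid) stop("partition is not valid under the allele constraint")
  gm <- as.matrix(gm)
  counts <- vapply(part$groups, function(g)
    rowSums(gm[, g, drop = FALSE]), numeric(nrow(gm)))
  if (is.null(dim(counts)))
    counts <- matrix(counts, nrow = nrow(gm),
                     dimnames = list(rownames(gm), names(part$groups)))
  carries <- counts > 0
  variable_groups <- colnames(carries)[apply(carries, 2L, function(v)
    any(v) && !all(v))]
  lacking <- lapply(part$groups[variable_groups], function(g)
    rownames(gm)[rowSums(gm[, g, drop = FALSE]) == 0])
  structure(list(carries_locus = carries,
                 haplotypic_variation = length(variable_groups) > 0,
                 variable_groups = variable_groups,
                 lacking_individuals = lacking),
            class = "cnv_report")
}

#' @export
print.cnv_report <- function(x, ...) {
  cat("cnv_report: haplotypic gene-content variation",
      if (x$haplotypic_variation) "DETECTED" else "not detected", "\n")
  if (x$haplotypic_variation)
    cat("  groups with absent carriers:",
        paste(x$variable_groups, collapse = ", "), "\n")
  invisible(x)
}
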