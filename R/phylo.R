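#' Homolog-count shortcut for candidate validation
#'
#' Candidates with more than five prokaryotic homologs and no eukaryotic
#' homolog in the reference search are accepted without a tree; candidates
#' with homologs in both domains require the tree-placement test; candidates
#' with five or fewer prokaryote-only homologs are left unsupported.
#'
#' @param prok_homologs,euk_homologs Non-negative integer vectors (recycled
#'   to a common length).
#' @return Character vector over `HGT_NO_TREE`, `NEEDS_TREE`, `UNSUPPORTED`.
#' @export
homolog_count_rule <- function(prok_homologs, euk_homologs) {
  if (any(prok_homologs < 0) || any(euk_homologs < 0))
    stopf("homolog counts must be non-negative")
  n <- max(length(prok_homologs), length(euk_homologs))
  prok <- rep_len(prok_homologs, n)
  euk <- rep_len(euk_homologs, n)
  ifelse(euk >= 1L, "NEEDS_TREE",
         ifelse(prok > 5L, "HGT_NO_TREE", "UNSUPPORTED"))
}

# descendant tip sets for every edge of a phylo object (postorder pass)
edge_tip_sets <- function(tree) {
  nt <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- i
  e <- tree$edge
  for (i in seq_len(nrow(e)))
    desc[[e[i, 1L]]] <- c(desc[[e[i, 1L]]], desc[[e[i, 2L]]])
  lapply(seq_len(nrow(e)), function(i) desc[[e[i, 2L]]])
}

#' Gene-tree placement test for a horizontal-transfer candidate
#'
#' Operationalizes "the query clusters in a prokaryotic clade that has a
#' eukaryotic outgroup" on the unrooted topology: the verdict is
#' `HGT_TREE_SUPPORTED` iff some bipartition of the tree splits the tips
#' into sides (A, B) such that A contains every `QUERY` tip, A minus the
#' queries is non-empty and entirely `PROKARYOTE`, and B contains at least
#' one `EUKARYOTE` tip. Both orientations of every edge are examined in the
#' tree's edge order; the first qualifying split is returned as the witness.
#' Because the test is a function of the bipartition set only, it is
#' invariant under rerooting and tip-order permutation.
#'
#' @param gtree A [gene_tree()] with at least one tip of each class.
#' @return Object of class `placement_result`: list with `verdict`
#'   (`HGT_TREE_SUPPORTED` or `REJECTED`) and `witness` (list with
#'   `clade_side` and `outgroup_side` tip labels, or `NULL`).
#' @export
tree_placement_test <- function(gtree) {
  stopifnot(inherits(gtree, "gene_tree"))
  tree <- gtree$tree
  cls <- gtree$tip_class[tree$tip.label]
  need <- c("QUERY", "PROKARYOTE", "EUKARYOTE")
  absent <- setdiff(need, unique(cls))
  if (length(absent))
    stopf("gene tree lacks tips of class: %s", paste(absent, collapse = ", "))
  nq <- sum(cls == "QUERY"); np <- sum(cls == "PROKARYOTE")
  ne <- sum(cls == "EUKARYOTE"); nt <- length(cls)
  sides <- edge_tip_sets(tree)
  for (s in sides) {
    cs <- cls[s]
    q_in <- sum(cs == "QUERY"); p_in <- sum(cs == "PROKARYOTE")
    e_in <- sum(cs == "EUKARYOTE")
    # orientation 1: A = descendant side, B = complement
    if (q_in == nq && length(s) > nq && p_in == length(s) - nq && ne - e_in >= 1L) {
      return(placement_result("HGT_TREE_SUPPORTED",
                              witness = list(
                                clade_side = tree$tip.label[s],
                                outgroup_side = tree$tip.label[-s])))
    }
    # orientation 2: A = complement, B = descendant side
    nc <- nt - length(s)
    if (nq - q_in == nq && nc > nq && np - p_in == nc - nq && e_in >= 1L) {
      return(placement_result("HGT_TREE_SUPPORTED",
                              witness = list(
                                clade_side = tree$tip.label[-s],
                                outgroup_side = tree$tip.label[s])))
    }
  }
  placement_result("REJECTED")
}

placement_result <- function(verdict, witness = NULL) {
  stopifnot(xor(verdict != "HGT_TREE_SUPPORTED", !is.null(witness)))
  structure(list(verdict = verdict, witness = witness),
            class = "placement_result")
}

#' @export
print.placement_result <- function(x, ...) {
  cat("tree placement:", x$verdict, "\n")
  if (!is.null(x$witness))
    cat(sprintf("  prokaryotic clade: {%s}\n  outgroup side: {%s}\n",
                paste(x$witness$clade_side, collapse = ", "),
                paste(x$witness$outgroup_side, collapse = ", ")))
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Thin validated wrapper around classical NJ agglomeration, used to build
#' test and simulation trees (maximum-likelihood inference is out of scope
#' here; trees are otherwise consumed, not estimated). Additive distance
#' matrices are recovered exactly.
#'
#' @param d Symmetric numeric matrix with zero diagonal, non-negative
#'   entries, at least 3 taxa, and row/column names.
#' @return An `ape` `phylo` object.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || nrow(d) < 3L)
    stopf("distance matrix must be square with >= 3 taxa")
  if (any(d < 0)) stopf("distance matrix has a negative entry")
  if (!isTRUE(all.equal(d, t(d), check.attributes = FALSE)))
    stopf("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stopf("distance matrix diagonal must be zero")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  ape::nj(d)
}

#' Phylogenetic validation of screened candidates
#'
#' Applies [homolog_count_rule()] to every screened candidate and, where a
#' tree is required, [tree_placement_test()]. The final status is `HGT` iff
#' the gene passed the hit-profile screen and the contamination filter and
#' its verdict is `HGT_NO_TREE` or `HGT_TREE_SUPPORTED`. Non-candidates are
#' marked `UNSUPPORTED` and `NOT_HGT` without tree evaluation.
#'
#' @param calls An `hgt_calls` data.frame from [screen_genome()].
#' @param homolog_counts Data.frame with columns `gene_id`, `prok_homologs`,
#'   `euk_homologs` (reference-database homolog counts per candidate).
#' @param trees Named list of [gene_tree()] objects, keyed by gene id; every
#'   candidate routed to the tree test must have one.
#' @return `calls` with `phylo_verdict` and `final_status` filled.
#' @export
validate_candidates <- function(calls, homolog_counts, trees = list()) {
  stopifnot(inherits(calls, "hgt_calls"))
  idx <- match(calls$gene_id, homolog_counts$gene_id)
  verdict <- rep("UNSUPPORTED", nrow(calls))
  for (i in which(calls$candidate)) {
    if (is.na(idx[i]))
      stopf("candidate '%s' has no homolog counts", calls$gene_id[i])
    rule <- homolog_count_rule(homolog_counts$prok_homologs[idx[i]],
                               homolog_counts$euk_homologs[idx[i]])
    if (rule == "NEEDS_TREE") {
      g <- calls$gene_id[i]
      if (is.null(trees[[g]]))
        stopf("candidate '%s' requires a gene tree but none was supplied", g)
      verdict[i] <- tree_placement_test(trees[[g]])$verdict
    } else {
      verdict[i] <- rule
    }
  }
  calls$phylo_verdict <- verdict
  calls$final_status <- ifelse(
    calls$candidate & verdict %in% c("HGT_NO_TREE", "HGT_TREE_SUPPORTED"),
    "HGT", "NOT_HGT")
  calls
}
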