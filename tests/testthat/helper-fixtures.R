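# shared fixture builders and independent oracles

# quick hit-table rows
make_hits <- function(n, superkingdom, evalue = NULL, bitscore = NULL,
                      genus = NULL, qseqid = "g1") {
  superkingdom <- rep_len(superkingdom, n)
  genus_default <- ifelse(superkingdom == "Eukaryota", "Oxytricha", "Escherichia")
  data.frame(
    qseqid = qseqid,
    sseqid = sprintf("s%02d", seq_len(n)),
    pident = 50,
    evalue = if (is.null(evalue)) 10^-(40 - seq_len(n)) else rep_len(evalue, n),
    bitscore = if (is.null(bitscore)) 200 - seq_len(n) else rep_len(bitscore, n),
    superkingdom = superkingdom,
    phylum = ifelse(superkingdom == "Eukaryota", "Ciliophora", "Pseudomonadota"),
    genus = if (is.null(genus)) genus_default else rep_len(genus, n),
    species = "spp",
    stringsAsFactors = FALSE)
}

tree_from_text <- function(nwk, classes = NULL) {
  tr <- ape::read.tree(text = nwk)
  if (is.null(classes)) {
    cls <- rep(NA_character_, length(tr$tip.label))
    cls[startsWith(tr$tip.label, "QUERY_")] <- "QUERY"
    cls[startsWith(tr$tip.label, "PROK_")] <- "PROKARYOTE"
    cls[startsWith(tr$tip.label, "EUK_")] <- "EUKARYOTE"
    names(cls) <- tr$tip.label
    classes <- cls
  }
  gene_tree(tr, classes)
}

# independent placement oracle: split the tree graph at every edge by
# breadth-first traversal and ask, for each resulting rooted side, whether
# it is a prokaryotic clade containing all queries with a eukaryotic tip
# outside it
placement_oracle <- function(gtree) {
  tree <- gtree$tree
  cls <- gtree$tip_class[tree$tip.label]
  e <- tree$edge
  nn <- max(e)
  nt <- length(tree$tip.label)
  adj <- vector("list", nn)
  for (i in seq_len(nrow(e))) {
    adj[[e[i, 1L]]] <- c(adj[[e[i, 1L]]], e[i, 2L])
    adj[[e[i, 2L]]] <- c(adj[[e[i, 2L]]], e[i, 1L])
  }
  qset <- which(cls == "QUERY")
  is_clade_hgt <- function(inside) {
    out <- setdiff(seq_len(nt), inside)
    all(qset %in% inside) &&
      length(setdiff(inside, qset)) > 0 &&
      all(cls[setdiff(inside, qset)] == "PROKARYOTE") &&
      any(cls[out] == "EUKARYOTE")
  }
  for (i in seq_len(nrow(e))) {
    seen <- rep(FALSE, nn)
    queue <- e[i, 2L]
    seen[queue] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (v == e[i, 2L] && w == e[i, 1L]) next  # severed edge
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    side <- which(seen[seq_len(nt)])
    if (is_clade_hgt(side) || is_clade_hgt(setdiff(seq_len(nt), side)))
      return("HGT_TREE_SUPPORTED")
  }
  "REJECTED"
}

# exact rank-sum p by full enumeration over C(n+m, n) group assignments
wilcoxon_perm_oracle <- function(x, y) {
  n <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  sums <- utils::combn(seq_along(pooled), n,
                       FUN = function(ix) sum(r[ix]))
  obs <- sum(r[seq_len(n)])
  min(1, 2 * min(mean(sums <= obs + 1e-9), mean(sums >= obs - 1e-9)))
}

# hypergeometric upper tail by enumerating every possible study draw
hyper_enum_oracle <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # term genes are 1..K
  mean(hits >= k)
}

# step-up BH by its definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  pmin(1, q_sorted)[order(o)]
}
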