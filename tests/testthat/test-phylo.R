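test_that("homolog-count shortcut honours the 'more than five' boundary", {
  expect_equal(homolog_count_rule(6, 0), "HGT_NO_TREE")
  expect_equal(homolog_count_rule(5, 0), "UNSUPPORTED")
  expect_equal(homolog_count_rule(10, 3), "NEEDS_TREE")
  expect_equal(homolog_count_rule(0, 0), "UNSUPPORTED")
  expect_equal(homolog_count_rule(c(6, 5, 10), c(0, 0, 3)),
               c("HGT_NO_TREE", "UNSUPPORTED", "NEEDS_TREE"))
  expect_error(homolog_count_rule(-1, 0), "non-negative")
})

test_that("placement test accepts prokaryote-nested queries and rejects others", {
  sup <- tree_placement_test(tree_from_text(
    "(((QUERY_g,PROK_p1),PROK_p2),(EUK_e1,EUK_e2));"))
  expect_equal(sup$verdict, "HGT_TREE_SUPPORTED")
  expect_true(all(c("QUERY_g", "PROK_p1") %in% sup$witness$clade_side))
  expect_true(any(startsWith(sup$witness$outgroup_side, "EUK_")))

  rej <- tree_placement_test(tree_from_text(
    "(((QUERY_g,EUK_e1),PROK_p1),(PROK_p2,EUK_e2));"))
  expect_equal(rej$verdict, "REJECTED")
  expect_null(rej$witness)

  # a query-only clade is not a prokaryotic clade: both paralogs must sit
  # inside one prokaryote-containing split
  lone <- tree_placement_test(tree_from_text(
    "((QUERY_g1,QUERY_g2),EUK_e1,(EUK_e2,PROK_p1));"))
  expect_equal(lone$verdict, "REJECTED")
  # ... but the same paralog cherry nested among prokaryotes is accepted
  par2 <- tree_placement_test(tree_from_text(
    "(((QUERY_g1,QUERY_g2),PROK_p1),PROK_p2,(EUK_e1,EUK_e2));"))
  expect_equal(par2$verdict, "HGT_TREE_SUPPORTED")

  expect_error(tree_placement_test(tree_from_text("((QUERY_g,PROK_a),PROK_b);")),
               "EUKARYOTE")
})

test_that("placement test is invariant under rerooting and tip permutation", {
  set.seed(9)
  for (i in 1:20) {
    gt <- sim_gene_tree(sprintf("g%d", i), n_prok = sample(2:5, 1),
                        n_euk = sample(2:4, 1),
                        supported = i %% 2 == 0)
    base <- tree_placement_test(gt)$verdict
    for (tip in sample(gt$tree$tip.label, 2)) {
      rerooted <- gene_tree(ape::root(gt$tree, outgroup = tip,
                                      resolve.root = TRUE), gt$tip_class)
      expect_equal(tree_placement_test(rerooted)$verdict, base)
    }
    perm <- ape::read.tree(text = ape::write.tree(gt$tree))
    expect_equal(tree_placement_test(gene_tree(perm, gt$tip_class))$verdict,
                 base)
  }
})

test_that("adding a prokaryote tip inside a witnessing clade keeps support", {
  set.seed(13)
  for (i in 1:10) {
    gt <- sim_gene_tree(sprintf("g%d", i), n_prok = sample(2:4, 1),
                        n_euk = sample(2:3, 1), supported = TRUE)
    res <- tree_placement_test(gt)
    expect_equal(res$verdict, "HGT_TREE_SUPPORTED")
    # graft a new prokaryote onto an edge inside the witnessing clade
    inside <- setdiff(res$witness$clade_side,
                      names(gt$tip_class)[gt$tip_class == "QUERY"])[1]
    tr <- suppressWarnings(
      ape::bind.tree(gt$tree, ape::read.tree(text = "(PROK_new:1);"),
                     where = which(gt$tree$tip.label == inside)))
    gt2 <- gene_tree(tr, c(gt$tip_class, PROK_new = "PROKARYOTE"))
    expect_equal(tree_placement_test(gt2)$verdict, "HGT_TREE_SUPPORTED")
  }
})

test_that("edge-scan verdicts match the exhaustive split oracle on random trees", {
  set.seed(21)
  for (i in 1:40) {
    nt <- sample(5:9, 1)
    tr <- ape::rtree(nt)
    cls <- sample(c("PROKARYOTE", "EUKARYOTE"), nt, TRUE)
    cls[sample(nt, 1)] <- "QUERY"
    if (!any(cls == "PROKARYOTE")) cls[which(cls != "QUERY")[1]] <- "PROKARYOTE"
    if (!any(cls == "EUKARYOTE")) cls[which(cls == "PROKARYOTE")[1]] <- "EUKARYOTE"
    if (sum(cls == "PROKARYOTE") == 0 || sum(cls == "EUKARYOTE") == 0) next
    names(cls) <- tr$tip.label
    gt <- gene_tree(tr, cls)
    expect_equal(tree_placement_test(gt)$verdict, placement_oracle(gt))
  }
})

test_that("neighbor joining recovers additive distances", {
  tr <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:4):2);")
  d <- ape::cophenetic.phylo(tr)
  nj <- neighbor_joining(d)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(nj), ape::unroot(tr))), 0)
  expect_equal(ape::cophenetic.phylo(nj)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)

  # three taxa resolve to the unique unrooted star
  d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(length(neighbor_joining(d3)$tip.label), 3L)

  expect_error(neighbor_joining(matrix(c(0, -1, 2, -1, 0, 3, 2, 3, 0), 3)),
               "negative")
  dd <- d; dd[1, 2] <- 99
  expect_error(neighbor_joining(dd), "symmetric")
})

test_that("candidate validation combines shortcut, tree test and screen flags", {
  sim <- simulate_dataset(sim_config(seed = 5, n_native = 10, n_hgt = 4,
                                     n_contaminant = 2))
  calls <- screen_genome(sim$contigs, sim$genes, sim$hit_tables)

  # shortcut: many prokaryote-only homologs, no tree needed
  hc <- sim$homolog_counts
  done <- validate_candidates(calls, hc, sim$trees)
  hgt <- done$gene_id[done$final_status == "HGT"]
  expect_setequal(hgt, names(sim$truth$gene_labels)[
    sim$truth$gene_labels == "HGT"])
  no_tree <- done$phylo_verdict[done$candidate &
                                  !done$gene_id %in% names(sim$trees)]
  expect_true(all(no_tree == "HGT_NO_TREE"))

  # a rejected placement demotes the candidate
  victim <- names(sim$trees)[1]
  trees2 <- sim$trees
  trees2[[victim]] <- sim_gene_tree(victim, n_prok = 3, n_euk = 3,
                                    supported = FALSE)
  done2 <- validate_candidates(calls, hc, trees2)
  expect_equal(done2$phylo_verdict[done2$gene_id == victim], "REJECTED")
  expect_equal(done2$final_status[done2$gene_id == victim], "NOT_HGT")

  # a tree-routed candidate without a tree is an error naming the gene
  expect_error(validate_candidates(calls, hc, sim$trees[-1]), victim)
})
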