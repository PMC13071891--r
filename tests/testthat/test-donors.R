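test_that("donor attribution takes the best retained prokaryotic hit", {
  hits <- make_hits(4, "Bacteria")
  hits$species <- c("Escherichia coli", "Bacillus subtilis", "x", "y")
  hits$genus <- c("Escherichia", "Bacillus", "g", "h")
  hits$phylum <- c("Pseudomonadota", "Bacillota", "p", "q")
  d <- assign_donor("g1", hits)
  expect_equal(d$donor_genus, "Escherichia")
  expect_equal(d$donor_phylum, "Pseudomonadota")
  expect_equal(d$best_hit_id, "s01")

  # E-value ties resolved by bitscore then subject id
  tied <- make_hits(3, "Bacteria", evalue = 1e-40, bitscore = c(100, 250, 250))
  tied$species <- c("a", "b", "c")
  expect_equal(assign_donor("g1", tied)$best_hit_id, "s02")

  expect_error(assign_donor("g1", make_hits(3, "Eukaryota")), "prokaryotic")
})

test_that("phylum spectra are per-species proportions summing to one", {
  asg <- data.frame(gene_id = paste0("g", 1:4),
                    donor_phylum = c("Pseudomonadota", "Pseudomonadota",
                                     "Bacteroidota", "Bacillota"))
  sp <- phylum_spectrum(asg)
  expect_equal(sort(as.numeric(sp), decreasing = TRUE), c(0.5, 0.25, 0.25))
  expect_equal(unname(rowSums(sp)), 1)

  one <- phylum_spectrum(data.frame(gene_id = "g", donor_phylum = "Bacillota"))
  expect_equal(as.numeric(one), 1)
})

test_that("endosymbiont flags use case-folded genus matching", {
  genera <- c("Polynucleobacter", "Candidatus Bandiella")
  asg <- data.frame(donor_genus = c("Polynucleobacter", "Escherichia",
                                    "polynucleobacter", "Bandiella",
                                    "Candidatus Bandiella"))
  expect_equal(flag_endosymbiont_derived(asg, genera),
               c(TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_error(flag_endosymbiont_derived(asg, character(0)), "empty")
})

test_that("family clustering joins mutual best hits above the ratio threshold", {
  sp <- paste0("sp", 1:5)
  proteins <- data.frame(species_id = sp, gene_id = "gA")
  pairs <- expand.grid(a = 1:5, b = 1:5)
  pairs <- pairs[pairs$a != pairs$b, ]
  scores <- rbind(
    data.frame(species_a = sp, gene_a = "gA", species_b = sp, gene_b = "gA",
               bitscore = 100),
    data.frame(species_a = sp[pairs$a], gene_a = "gA",
               species_b = sp[pairs$b], gene_b = "gA", bitscore = 80))
  fam <- cluster_families(proteins, scores, link_threshold = 0.5)
  expect_equal(length(unique(fam$family_id)), 1L)
  expect_setequal(fam$species_id, sp)

  # below-threshold mutual best hits stay apart
  fam2 <- cluster_families(proteins, scores, link_threshold = 0.9)
  expect_equal(length(unique(fam2$family_id)), 5L)
})

test_that("two disjoint cliques become two families", {
  proteins <- data.frame(species_id = rep(c("s1", "s2"), 2),
                         gene_id = c("a1", "a2", "b1", "b2"))
  scores <- rbind(
    data.frame(species_a = c("s1", "s2", "s1", "s2"),
               gene_a = c("a1", "a2", "b1", "b2"),
               species_b = c("s1", "s2", "s1", "s2"),
               gene_b = c("a1", "a2", "b1", "b2"), bitscore = 100),
    data.frame(species_a = c("s1", "s2"), gene_a = c("a1", "a2"),
               species_b = c("s2", "s1"), gene_b = c("a2", "a1"),
               bitscore = 90),
    data.frame(species_a = c("s1", "s2"), gene_a = c("b1", "b2"),
               species_b = c("s2", "s1"), gene_b = c("b2", "b1"),
               bitscore = 85))
  fam <- cluster_families(proteins, scores)
  expect_equal(length(unique(fam$family_id)), 2L)
  expect_equal(sort(table(fam$family_id), decreasing = TRUE),
               sort(c(2L, 2L)), ignore_attr = TRUE)
})

test_that("components match a naive transitive-closure oracle", {
  set.seed(41)
  for (rep in 1:5) {
    ns <- 4
    sp <- paste0("sp", 1:ns)
    genes <- expand.grid(species_id = sp, i = 1:5, stringsAsFactors = FALSE)
    genes$gene_id <- paste0("g", genes$i)
    proteins <- genes[, c("species_id", "gene_id")]
    # random mutual links among same-index genes
    links <- NULL
    for (i in 1:5) for (a in 1:(ns - 1)) for (b in (a + 1):ns) {
      if (runif(1) < 0.4) {
        links <- rbind(links,
          data.frame(species_a = sp[a], gene_a = paste0("g", i),
                     species_b = sp[b], gene_b = paste0("g", i),
                     bitscore = 90),
          data.frame(species_a = sp[b], gene_a = paste0("g", i),
                     species_b = sp[a], gene_b = paste0("g", i),
                     bitscore = 90))
      }
    }
    selfs <- data.frame(species_a = proteins$species_id,
                        gene_a = proteins$gene_id,
                        species_b = proteins$species_id,
                        gene_b = proteins$gene_id, bitscore = 100)
    scores <- rbind(selfs, links)
    fam <- cluster_families(proteins, scores)
    # oracle: iterate merging over the undirected link list
    node <- paste(proteins$species_id, proteins$gene_id, sep = ":")
    comp <- seq_along(node)
    names(comp) <- node
    if (!is.null(links)) {
      repeat {
        changed <- FALSE
        for (j in seq_len(nrow(links))) {
          u <- paste(links$species_a[j], links$gene_a[j], sep = ":")
          v <- paste(links$species_b[j], links$gene_b[j], sep = ":")
          if (comp[u] != comp[v]) {
            comp[comp == comp[v]] <- comp[u]
            changed <- TRUE
          }
        }
        if (!changed) break
      }
    }
    fam_of <- structure(fam$family_id,
                        names = paste(fam$species_id, fam$gene_id, sep = ":"))
    # same partition: pairwise co-membership agrees
    for (i in seq_along(node)) for (j in seq_len(i - 1)) {
      expect_equal(fam_of[[node[i]]] == fam_of[[node[j]]],
                   comp[[node[i]]] == comp[[node[j]]])
    }
    # every gene in exactly one family
    expect_setequal(names(fam_of), node)
  }
})

test_that("shared-family counts partition families by species subset", {
  fam <- data.frame(
    family_id = c("f1", "f1", "f2", "f2", "f2", "f2", "f2", "f3"),
    species_id = c("A", "B", "A", "B", "C", "D", "E", "C"),
    gene_id = paste0("g", 1:8))
  class(fam) <- c("hgt_families", "data.frame")
  res <- shared_family_counts(fam, LETTERS[1:5])
  expect_equal(res$core_count, 1L)
  expect_equal(res$n_families, 3L)
  expect_equal(sum(res$cells$n_families), 3L)

  singles <- data.frame(family_id = c("f1", "f2"), species_id = c("A", "B"),
                        gene_id = c("x", "y"))
  class(singles) <- c("hgt_families", "data.frame")
  expect_equal(shared_family_counts(singles, LETTERS[1:5])$core_count, 0L)
})

test_that("simulated donors and families are recovered exactly", {
  sim <- simulate_dataset(sim_config(seed = 1))
  run <- run_hgt_pipeline(sim)
  truth <- sim$truth$donors
  got <- run$donors[match(truth$gene_id, run$donors$gene_id), ]
  expect_equal(got$donor_species, truth$donor_species)
  expect_equal(got$donor_phylum, truth$donor_phylum)

  # phylum spectrum equals the planted donor distribution
  planted <- table(truth$donor_phylum) / nrow(truth)
  sp <- run$phylum_spectrum
  expect_equal(sort(as.numeric(sp[1, names(planted)])),
               sort(as.numeric(planted)))

  expect_equal(run$shared_families$core_count, sim$cfg$n_core_families)
  # planted family partition is recovered
  truth_fam <- sim$truth$family_assignments
  fam_of <- structure(run$families$family_id,
                      names = paste(run$families$species_id,
                                    run$families$gene_id, sep = ":"))
  key <- paste(truth_fam$species_id, truth_fam$gene_id, sep = ":")
  expect_equal(length(unique(fam_of[key[truth_fam$true_family == "core01"]])), 1L)
  expect_equal(length(unique(run$families$family_id)),
               length(unique(truth_fam$true_family)))
})
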