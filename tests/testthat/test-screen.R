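cfg <- screen_config()

test_that("telomere detection counts tandem units at both ends", {
  core <- paste(rep("A", 60), collapse = "")
  ctg <- nanochromosomes("t1", paste0("CCCCAAAACCCCAAAA",
                                      "GATTACAGATTACAGATTACAGATTACA",
                                      "GGGGTTTTGGGGTTTT"))
  d <- detect_telomeres(ctg, cfg)
  expect_equal(d$left_telomere_units, 2L)
  expect_equal(d$right_telomere_units, 2L)
  expect_true(has_telomere(d, cfg))

  none <- detect_telomeres(nanochromosomes("t2", paste(
    rep("GATC", 25), collapse = "")), cfg)
  expect_equal(none$left_telomere_units, 0L)
  expect_equal(none$right_telomere_units, 0L)
  expect_false(has_telomere(none, cfg))

  # a single telomere suffices
  one <- detect_telomeres(nanochromosomes("t3", paste0(
    strrep("CCCCAAAA", 3), core)), cfg)
  expect_equal(one$left_telomere_units, 3L)
  expect_true(has_telomere(one, cfg))
})

test_that("telomere scan tolerates ragged starts within the window", {
  # partial leading unit: run starts 4 nt into the contig
  ragged <- detect_telomeres(nanochromosomes("r1", paste0(
    "AAAA", strrep("CCCCAAAA", 3), strrep("GATC", 20))), cfg)
  expect_equal(ragged$left_telomere_units, 3L)

  # run starting beyond the window is not a telomere
  far <- detect_telomeres(nanochromosomes("r2", paste0(
    strrep("GATC", 20), strrep("CCCCAAAA", 3), strrep("GATC", 20))), cfg)
  expect_equal(far$left_telomere_units, 0L)
})

test_that("telomere detection is strand-symmetric", {
  set.seed(11)
  for (i in 1:15) {
    seqs <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
    if (i %% 3 == 0) seqs <- paste0(strrep("CCCCAAAA", 2), seqs)
    if (i %% 4 == 0) seqs <- paste0(seqs, strrep("GGGGTTTT", 3))
    fwd <- detect_telomeres(nanochromosomes("x", seqs), cfg)
    rev <- detect_telomeres(nanochromosomes(
      "x", ciliateHGT:::revcomp(seqs)), cfg)
    expect_equal(fwd$left_telomere_units, rev$right_telomere_units)
    expect_equal(fwd$right_telomere_units, rev$left_telomere_units)
  }
})

test_that("hit profile applies best-hit and strict majority rules", {
  # 10 hits, best is Bacteria, 6 prokaryotic -> pass with fraction 0.6
  p <- evaluate_hit_profile(make_hits(10, c(rep("Bacteria", 6),
                                            rep("Eukaryota", 4))), cfg)
  expect_true(p$screen_pass)
  expect_equal(p$prokaryote_hit_fraction, 0.6)

  # best hit eukaryotic fails even at 9/10 prokaryote
  p2 <- evaluate_hit_profile(make_hits(10, c("Eukaryota",
                                             rep("Bacteria", 9))), cfg)
  expect_false(p2$screen_pass)
  expect_true(p2$passed_evalue)

  # exactly 50% is not a strict majority
  p3 <- evaluate_hit_profile(make_hits(10, rep(c("Bacteria", "Eukaryota"),
                                               each = 5)), cfg)
  expect_equal(p3$prokaryote_hit_fraction, 0.5)
  expect_false(p3$screen_pass)

  # empty profiles fail with fraction reported as 0
  p4 <- evaluate_hit_profile(NULL, cfg)
  expect_false(p4$screen_pass)
  expect_equal(p4$prokaryote_hit_fraction, 0)
})

test_that("hit profile filters E-value failures and self-hits first", {
  hits <- rbind(make_hits(4, "Bacteria"),
                make_hits(4, "Eukaryota", evalue = 1e-3),  # above cutoff
                make_hits(2, "Eukaryota", evalue = 1e-60, bitscore = 500,
                          genus = "Euplotes"))              # self-hits
  p <- evaluate_hit_profile(hits, cfg)
  expect_equal(p$n_retained, 4L)
  expect_equal(p$prokaryote_hit_fraction, 1)
  expect_true(p$screen_pass)
})

test_that("hit profile is invariant to row order and deterministic on ties", {
  hits <- make_hits(9, c(rep("Bacteria", 5), rep("Eukaryota", 4)))
  p_ref <- evaluate_hit_profile(hits, cfg)
  set.seed(5)
  for (i in 1:10) {
    p <- evaluate_hit_profile(hits[sample(nrow(hits)), ], cfg)
    expect_equal(p$prokaryote_hit_fraction, p_ref$prokaryote_hit_fraction)
    expect_equal(p$best_hit$sseqid, p_ref$best_hit$sseqid)
  }
  # tie on E-value: bitscore then subject id decide
  tied <- make_hits(3, "Bacteria", evalue = 1e-30,
                    bitscore = c(100, 300, 300))
  expect_equal(evaluate_hit_profile(tied, cfg)$best_hit$sseqid, "s02")
})

test_that("raising the E-value cutoff never shrinks the retained set", {
  set.seed(7)
  hits <- make_hits(30, sample(c("Bacteria", "Eukaryota"), 30, TRUE),
                    evalue = 10^-runif(30, 0, 40))
  cuts <- sort(10^-runif(8, 0, 40))
  retained <- vapply(cuts, function(ct)
    evaluate_hit_profile(hits, screen_config(evalue_cutoff = ct))$n_retained,
    integer(1))
  expect_true(all(diff(retained) >= 0))
})

test_that("contamination filter requires a telomere or an intron", {
  expect_true(contamination_filter(TRUE, 0L))
  expect_true(contamination_filter(FALSE, 2L))
  expect_false(contamination_filter(FALSE, 0L))
  expect_equal(contamination_filter(c(TRUE, FALSE), c(0L, 1L)), c(TRUE, TRUE))
})

test_that("genome screening recovers exactly the planted transfers", {
  sim <- simulate_dataset(sim_config(seed = 1))
  calls <- screen_genome(sim$contigs, sim$genes, sim$hit_tables, cfg)
  planted <- names(sim$truth$gene_labels)[sim$truth$gene_labels == "HGT"]
  expect_setequal(calls$gene_id[calls$candidate], planted)

  # contaminants pass the taxonomic screen but fail the nanochromosome filter
  contam <- names(sim$truth$gene_labels)[sim$truth$gene_labels == "CONTAMINANT"]
  crows <- calls[match(contam, calls$gene_id), ]
  expect_true(all(crows$screen_pass))
  expect_false(any(crows$contamination_pass))
})

test_that("all-native genomes yield no candidates", {
  sim <- simulate_dataset(sim_config(seed = 2, n_native = 25, n_hgt = 0,
                                     n_contaminant = 0))
  calls <- screen_genome(sim$contigs, sim$genes, sim$hit_tables, cfg)
  expect_equal(sum(calls$candidate), 0L)
})

test_that("screening a gene on a missing contig is an error", {
  sim <- simulate_dataset(sim_config(seed = 4, n_native = 4, n_hgt = 1,
                                     n_contaminant = 0))
  expect_error(
    screen_genome(sim$contigs[-1, ], sim$genes, sim$hit_tables, cfg),
    "missing contig")
})
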