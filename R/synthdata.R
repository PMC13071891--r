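# built-in donor/taxon pools used by the simulator ------------------------

prok_donor_pool <- function() {
  data.frame(
    species = c("Escherichia coli", "Pseudomonas fluorescens",
                "Caulobacter vibrioides", "Flavobacterium johnsoniae",
                "Bacteroides fragilis", "Bacillus subtilis",
                "Lactococcus lactis", "Synechococcus elongatus",
                "Nostoc punctiforme", "Sulfolobus acidocaldarius"),
    genus = c("Escherichia", "Pseudomonas", "Caulobacter", "Flavobacterium",
              "Bacteroides", "Bacillus", "Lactococcus", "Synechococcus",
              "Nostoc", "Sulfolobus"),
    phylum = c("Pseudomonadota", "Pseudomonadota", "Pseudomonadota",
               "Bacteroidota", "Bacteroidota", "Bacillota", "Bacillota",
               "Cyanobacteriota", "Cyanobacteriota", "Thermoproteota"),
    superkingdom = c(rep("Bacteria", 9), "Archaea"),
    stringsAsFactors = FALSE)
}

endosymbiont_donor_pool <- function() {
  data.frame(
    species = c("Polynucleobacter necessarius",
                "Candidatus Bandiella woodruffii",
                "Candidatus Cyrtobacter comes",
                "Candidatus Protistobacter heckmanni"),
    genus = c("Polynucleobacter", "Candidatus Bandiella",
              "Candidatus Cyrtobacter", "Candidatus Protistobacter"),
    phylum = rep("Pseudomonadota", 4),
    superkingdom = rep("Bacteria", 4),
    stringsAsFactors = FALSE)
}

euk_hit_pool <- function() {
  data.frame(
    species = c("Oxytricha trifallax", "Tetrahymena thermophila",
                "Stylonychia lemnae", "Paramecium tetraurelia",
                "Saccharomyces cerevisiae", "Homo sapiens"),
    genus = c("Oxytricha", "Tetrahymena", "Stylonychia", "Paramecium",
              "Saccharomyces", "Homo"),
    phylum = c("Ciliophora", "Ciliophora", "Ciliophora", "Ciliophora",
               "Ascomycota", "Chordata"),
    superkingdom = rep("Eukaryota", 6),
    stringsAsFactors = FALSE)
}

#' Known endosymbiont genera shipped with the simulator
#'
#' A synthetic stand-in list of bacterial genera with endosymbiotic
#' representatives in Euplotes-like hosts, used as the default
#' endosymbiont-derived-gene reference.
#' @return Character vector of genus names.
#' @export
default_endosymbiont_genera <- function() {
  c("Polynucleobacter", "Candidatus Bandiella", "Candidatus Cyrtobacter",
    "Candidatus Protistobacter", "Candidatus Nebulobacter",
    "Candidatus Fokinia", "Candidatus Midichloria",
    "Candidatus Euplotechlamydia")
}

#' Simulation configuration
#'
#' Defines the study conditions the simulator emulates: gene-sized
#' telomere-capped nanochromosomes for host genes, tiny (26 bp) spliceosomal
#' introns shared at equal rates by transferred and native genes, planted
#' transferred genes with prokaryote-dominated hit profiles and
#' prokaryote-nested tree placements, bacterial contaminant contigs lacking
#' both telomeres and introns, and lower expression of transferred genes.
#'
#' @param seed Integer RNG seed; a fixed seed yields byte-identical outputs.
#' @param n_native,n_hgt,n_contaminant Gene counts per class.
#' @param gc_native,gc_hgt Per-class GC of generated sequence (defaults
#'   equal at 0.35, emulating ancient, host-ameliorated acquisitions).
#' @param intron_prob Probability that a host gene carries one intron
#'   (shared by native and transferred classes; default 0.3).
#' @param intron_length_bp Intron length (default 26).
#' @param hits_per_gene Informative homology hits simulated per gene.
#' @param prok_fraction_hgt Prokaryote fraction of transferred-gene hit
#'   profiles (must exceed 0.5).
#' @param prok_fraction_native Prokaryote fraction of native-gene profiles
#'   (must be below 0.5).
#' @param hgt_expression_multiplier Ratio of transferred-gene to native-gene
#'   mean expression, in (0, 1]; 1 gives the null (no effect).
#' @param expression_mean Native-class negative-binomial mean count.
#' @param expression_dispersion Negative-binomial dispersion (0 = counts
#'   equal to class means).
#' @param n_core_families Gene families planted across every species.
#' @param n_species Number of species in the family simulation.
#' @param endosymbiont_donor_prob Probability that a transferred gene's
#'   donor is drawn from the endosymbiont genus pool.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_native = 200L, n_hgt = 20L,
                       n_contaminant = 10L, gc_native = 0.35, gc_hgt = 0.35,
                       intron_prob = 0.3, intron_length_bp = 26L,
                       hits_per_gene = 20L, prok_fraction_hgt = 0.8,
                       prok_fraction_native = 0.2,
                       hgt_expression_multiplier = 0.3,
                       expression_mean = 200, expression_dispersion = 0.3,
                       n_core_families = 7L, n_species = 5L,
                       endosymbiont_donor_prob = 0.15) {
  if (any(c(n_native, n_hgt, n_contaminant) < 0))
    stopf("gene counts must be non-negative")
  if (prok_fraction_hgt <= 0.5)
    stopf("prok_fraction_hgt must exceed 0.5, otherwise planted transfers cannot pass the majority rule")
  if (prok_fraction_native >= 0.5)
    stopf("prok_fraction_native must be below 0.5")
  if (!(hgt_expression_multiplier > 0 && hgt_expression_multiplier <= 1))
    stopf("hgt_expression_multiplier must lie in (0, 1]")
  if (!(gc_native > 0 && gc_native < 1 && gc_hgt > 0 && gc_hgt < 1))
    stopf("GC fractions must lie in (0, 1)")
  if (hits_per_gene < 2L) stopf("hits_per_gene must be >= 2")
  structure(list(seed = as.integer(seed), n_native = as.integer(n_native),
                 n_hgt = as.integer(n_hgt),
                 n_contaminant = as.integer(n_contaminant),
                 gc_native = gc_native, gc_hgt = gc_hgt,
                 intron_prob = intron_prob,
                 intron_length_bp = as.integer(intron_length_bp),
                 hits_per_gene = as.integer(hits_per_gene),
                 prok_fraction_hgt = prok_fraction_hgt,
                 prok_fraction_native = prok_fraction_native,
                 hgt_expression_multiplier = hgt_expression_multiplier,
                 expression_mean = expression_mean,
                 expression_dispersion = expression_dispersion,
                 n_core_families = as.integer(n_core_families),
                 n_species = as.integer(n_species),
                 endosymbiont_donor_prob = endosymbiont_donor_prob),
            class = "sim_config")
}

random_dna <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# one telomere-capped (or bare, for contaminants) contig carrying one gene
sim_nanochromosome <- function(gene_id, class, cfg) {
  gc <- switch(class, HGT = cfg$gc_hgt, NATIVE = cfg$gc_native, 0.5)
  capped <- class != "CONTAMINANT"
  tel_l <- if (capped) strrep("CCCCAAAA", sample(2:4, 1)) else ""
  tel_r <- if (capped) strrep("GGGGTTTT", sample(2:4, 1)) else ""
  pad5 <- random_dna(sample(15:40, 1), gc)
  pad3 <- random_dna(sample(15:40, 1), gc)
  n_codons <- max(100L, min(800L, round(exp(stats::rnorm(1, log(300), 0.35)))))
  cds <- random_dna(3L * n_codons, gc)
  with_intron <- capped && stats::runif(1) < cfg$intron_prob
  off <- nchar(tel_l) + nchar(pad5)
  if (with_intron) {
    cut <- 3L * sample(seq_len(n_codons - 1L), 1)
    ilen <- cfg$intron_length_bp
    intron <- paste0("GT", random_dna(ilen - 4L, gc), "AG")
    seqs <- paste0(tel_l, pad5, substr(cds, 1L, cut), intron,
                   substr(cds, cut + 1L, nchar(cds)), pad3, tel_r)
    exons <- cbind(start = c(off + 1L, off + cut + ilen + 1L),
                   end = c(off + cut, off + nchar(cds) + ilen))
  } else {
    seqs <- paste0(tel_l, pad5, cds, pad3, tel_r)
    exons <- cbind(start = off + 1L, end = off + nchar(cds))
  }
  list(contig_id = paste0("ctg_", gene_id), sequence = seqs,
       gene = list(gene_id = gene_id, contig_id = paste0("ctg_", gene_id),
                   strand = "+", exons = exons),
       cds = cds)
}

sample_pool <- function(pool, n) pool[sample(nrow(pool), n, replace = TRUE), , drop = FALSE]

# taxonomy-annotated hit profile for one gene; the retained (informative)
# rows realise the class's prokaryote fraction exactly, and extra rows that
# must be filtered out (E-value failures, self-hits) are appended
sim_hit_table <- function(gene_id, class, cfg, donor) {
  n <- cfg$hits_per_gene
  frac <- if (class == "NATIVE") cfg$prok_fraction_native else cfg$prok_fraction_hgt
  n_prok <- if (class == "NATIVE") floor(frac * n) else ceiling(frac * n)
  if (class != "NATIVE" && n_prok / n <= 0.5) n_prok <- floor(n / 2) + 1L
  n_euk <- n - n_prok
  prok <- sample_pool(prok_donor_pool(), max(0L, n_prok - 1L))
  euk <- sample_pool(euk_hit_pool(), max(0L, n_euk - 1L))
  if (class == "NATIVE") {
    best <- sample_pool(euk_hit_pool(), 1L)
    prok <- sample_pool(prok_donor_pool(), n_prok)
  } else {
    best <- donor
    euk <- sample_pool(euk_hit_pool(), n_euk)
  }
  tax <- rbind(best, prok, euk)[seq_len(n), , drop = FALSE]
  ev <- c(10^-stats::runif(1, 40, 80), sort(10^-stats::runif(n - 1L, 6, 35)))
  bs <- c(round(stats::runif(1, 400, 600)),
          round(sort(stats::runif(n - 1L, 60, 390), decreasing = TRUE)))
  hits <- data.frame(
    qseqid = gene_id,
    sseqid = sprintf("%s_ref_%02d", gene_id, seq_len(n)),
    pident = round(stats::runif(n, 30, 95), 1),
    evalue = ev, bitscore = bs,
    superkingdom = tax$superkingdom, phylum = tax$phylum,
    genus = tax$genus, species = tax$species,
    stringsAsFactors = FALSE)
  # rows the screen must discard: two above the E-value cutoff, one self-hit
  junk <- data.frame(
    qseqid = gene_id,
    sseqid = sprintf("%s_junk_%d", gene_id, 1:3),
    pident = round(stats::runif(3, 25, 60), 1),
    evalue = c(1e-3, 1e-2, 1e-40),
    bitscore = c(40, 35, 300),
    superkingdom = c("Bacteria", "Eukaryota", "Eukaryota"),
    phylum = c("Pseudomonadota", "Ciliophora", "Ciliophora"),
    genus = c("Escherichia", "Oxytricha", "Euplotes"),
    species = c("Escherichia coli", "Oxytricha trifallax",
                "Euplotes octocarinatus"),
    stringsAsFactors = FALSE)
  rbind(hits, junk)
}

# random binary nesting of a label set into a Newick subtree string
rand_clade <- function(labels) {
  if (length(labels) == 1L) return(labels)
  k <- sample(seq_len(length(labels) - 1L), 1)
  pick <- sample(labels)
  paste0("(", rand_clade(pick[seq_len(k)]), ",",
         rand_clade(pick[-seq_len(k)]), ")")
}

#' Simulate a gene tree with a planted placement
#'
#' `supported = TRUE` nests the query inside a prokaryotic clade with a
#' eukaryotic outgroup; `supported = FALSE` pairs the query with a eukaryote
#' so that no prokaryotic clade containing it exists (requires
#' `n_euk >= 2`).
#'
#' @param gene_id Query gene id.
#' @param n_prok,n_euk Numbers of prokaryote/eukaryote reference tips.
#' @param supported Logical.
#' @return A [gene_tree()].
#' @export
sim_gene_tree <- function(gene_id, n_prok = 4L, n_euk = 3L,
                          supported = TRUE) {
  if (n_prok < 1L || n_euk < 1L) stopf("need at least one tip per class")
  q <- paste0("QUERY_", gene_id)
  pr <- sprintf("PROK_p%d", seq_len(n_prok))
  eu <- sprintf("EUK_e%d", seq_len(n_euk))
  if (supported) {
    nwk <- paste0("(", rand_clade(c(q, pr)), ",", rand_clade(eu), ");")
  } else {
    if (n_euk < 2L) stopf("a rejected placement needs n_euk >= 2")
    nwk <- paste0("(", rand_clade(pr), ",",
                  rand_clade(c(paste0("(", q, ",", eu[1L], ")"), eu[-1L])),
                  ");")
  }
  tr <- ape::read.tree(text = nwk)
  cls <- c(stats::setNames("QUERY", q),
           stats::setNames(rep("PROKARYOTE", n_prok), pr),
           stats::setNames(rep("EUKARYOTE", n_euk), eu))
  gene_tree(tr, cls)
}

#' Simulate expression counts for labelled genes
#'
#' Counts are negative-binomial with class means `expression_mean` (native,
#' contaminant) and `hgt_expression_multiplier * expression_mean`
#' (transferred). Zero dispersion degenerates to counts equal to the class
#' means.
#'
#' @param cfg A [sim_config()].
#' @param labels Named character vector gene id -> class
#'   (`NATIVE`/`HGT`/`CONTAMINANT`).
#' @param lengths_bp Named effective lengths (default 1000 for all genes).
#' @return Data.frame `gene_id`, `count`, `effective_length`.
#' @export
simulate_expression <- function(cfg, labels, lengths_bp = NULL) {
  ids <- names(labels)
  if (is.null(lengths_bp)) lengths_bp <- stats::setNames(rep(1000, length(ids)), ids)
  mu <- ifelse(labels == "HGT",
               cfg$hgt_expression_multiplier * cfg$expression_mean,
               cfg$expression_mean)
  counts <- if (cfg$expression_dispersion == 0) round(mu)
            else stats::rnbinom(length(ids), mu = mu,
                                size = 1 / cfg$expression_dispersion)
  data.frame(gene_id = ids, count = as.numeric(counts),
             effective_length = as.numeric(lengths_bp[ids]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate a complete benchmark dataset with truth labels
#'
#' Generates contigs, gene models, taxonomy-annotated hit tables, homolog
#' counts, gene trees for candidates routed to the tree test, expression
#' counts, functional annotations, a germline scaffold map, an endosymbiont
#' genus list, and a cross-species family benchmark — together with the
#' truth labels needed to score the pipeline. Generated data are
#' self-validated against the class definitions (every planted transfer
#' passes the hit-profile screen, every contaminant fails the contamination
#' filter) before being returned.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional directory; when given, all files are also written via
#'   [write_dataset()].
#' @return Object of class `hgt_sim`: list with elements `contigs`, `genes`,
#'   `hit_tables`, `homolog_counts`, `trees`, `expression`, `annotations`,
#'   `mic_map`, `endosymbiont_genera`, `family_proteins`, `family_scores`,
#'   `truth`, `cfg`.
#' @export
simulate_dataset <- function(cfg = sim_config(), dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  sim <- with_seed(cfg$seed, simulate_dataset_impl(cfg))
  if (!is.null(dir)) write_dataset(sim, dir)
  sim
}

simulate_dataset_impl <- function(cfg) {
  ids <- c(sprintf("native_%03d", seq_len(cfg$n_native)),
           sprintf("hgt_%03d", seq_len(cfg$n_hgt)),
           sprintf("contam_%03d", seq_len(cfg$n_contaminant)))
  labels <- stats::setNames(
    rep(c("NATIVE", "HGT", "CONTAMINANT"),
        c(cfg$n_native, cfg$n_hgt, cfg$n_contaminant)), ids)

  nanos <- lapply(ids, function(g) sim_nanochromosome(g, labels[[g]], cfg))
  contigs <- nanochromosomes(vapply(nanos, `[[`, character(1), "contig_id"),
                             vapply(nanos, `[[`, character(1), "sequence"))
  genes <- gene_models(lapply(nanos, `[[`, "gene"))

  # donors: a planted draw per transferred gene (endosymbiont pool with
  # configured probability); contaminants draw environmental donors only
  endo <- endosymbiont_donor_pool()
  donors <- lapply(ids, function(g) {
    if (labels[[g]] == "HGT" && stats::runif(1) < cfg$endosymbiont_donor_prob)
      sample_pool(endo, 1L)
    else sample_pool(prok_donor_pool()[prok_donor_pool()$superkingdom ==
                                         "Bacteria", ], 1L)
  })
  names(donors) <- ids
  hit_tables <- lapply(ids, function(g)
    sim_hit_table(g, labels[[g]], cfg, donors[[g]]))
  names(hit_tables) <- ids

  # homolog counts: alternate transferred genes between the no-tree
  # shortcut (prokaryote-only homologs) and the tree-test route
  hgt_ids <- ids[labels == "HGT"]
  needs_tree <- rep(c(FALSE, TRUE), length.out = length(hgt_ids))
  homolog_counts <- data.frame(
    gene_id = ids,
    prok_homologs = ifelse(labels == "NATIVE", sample(0:3, length(ids), TRUE),
                           sample(6:30, length(ids), TRUE)),
    euk_homologs = ifelse(labels == "NATIVE", sample(10:50, length(ids), TRUE),
                          0L),
    stringsAsFactors = FALSE)
  homolog_counts$euk_homologs[match(hgt_ids[needs_tree],
                                    homolog_counts$gene_id)] <-
    sample(1:5, sum(needs_tree), TRUE)
  trees <- lapply(hgt_ids[needs_tree], function(g)
    sim_gene_tree(g, n_prok = sample(3:6, 1), n_euk = sample(2:4, 1),
                  supported = TRUE))
  names(trees) <- hgt_ids[needs_tree]

  lens <- stats::setNames(genes$cds_length_bp, genes$gene_id)
  expression <- simulate_expression(cfg, labels, lens)

  # annotations: a planted term enriched among transferred genes over a
  # background of generic terms; universe = host (non-contaminant) genes
  host_ids <- ids[labels != "CONTAMINANT"]
  bg_terms <- sprintf("GO:background_%02d", 1:10)
  ann <- do.call(rbind, lapply(host_ids, function(g) {
    terms <- sample(bg_terms, sample(0:2, 1))
    if (labels[[g]] == "HGT" && stats::runif(1) < 0.8)
      terms <- c(terms, "GO:mannosidase_activity")
    else if (stats::runif(1) < 0.02)
      terms <- c(terms, "GO:mannosidase_activity")
    if (length(terms))
      data.frame(gene_id = g, term = terms, stringsAsFactors = FALSE)
  }))

  # germline scaffold map: most transferred genes on distinct scaffolds,
  # one shared pair when enough genes exist
  mapped <- hgt_ids[seq_len(ceiling(0.7 * length(hgt_ids)))]
  scaf <- sprintf("mic_scaffold_%03d", seq_along(mapped))
  if (length(mapped) >= 4L) scaf[length(mapped)] <- scaf[1L]
  mic_map <- data.frame(gene_id = mapped, scaffold_id = scaf,
                        stringsAsFactors = FALSE)

  fam <- sim_families(cfg)

  truth <- list(
    gene_labels = labels,
    donors = data.frame(
      gene_id = hgt_ids,
      donor_species = vapply(donors[hgt_ids], `[[`, character(1), "species"),
      donor_genus = vapply(donors[hgt_ids], `[[`, character(1), "genus"),
      donor_phylum = vapply(donors[hgt_ids], `[[`, character(1), "phylum"),
      stringsAsFactors = FALSE),
    mic = list(n_genes_mapped = length(mapped),
               n_scaffolds = length(unique(scaf)),
               max_genes_per_scaffold = if (length(mapped) >= 4L) 2L else 1L),
    enriched_term = "GO:mannosidase_activity",
    family_assignments = fam$truth,
    n_core_families = cfg$n_core_families)

  sim <- structure(list(contigs = contigs, genes = genes,
                        hit_tables = hit_tables,
                        homolog_counts = homolog_counts, trees = trees,
                        expression = expression, annotations = ann,
                        mic_map = mic_map,
                        endosymbiont_genera = default_endosymbiont_genera(),
                        family_proteins = fam$proteins,
                        family_scores = fam$scores,
                        truth = truth, cfg = cfg),
                   class = "hgt_sim")
  validate_sim(sim)
  sim
}

# cross-species family benchmark: core families present in every species
# plus per-species private genes that must remain singletons
sim_families <- function(cfg) {
  sp <- sprintf("sp%d", seq_len(cfg$n_species))
  core <- expand.grid(species_id = sp,
                      fam = seq_len(cfg$n_core_families),
                      stringsAsFactors = FALSE)
  core$gene_id <- sprintf("core%02d_%s", core$fam, core$species_id)
  priv <- expand.grid(species_id = sp, i = 1:3, stringsAsFactors = FALSE)
  priv$gene_id <- sprintf("priv%d_%s", priv$i, priv$species_id)
  proteins <- rbind(core[, c("species_id", "gene_id")],
                    priv[, c("species_id", "gene_id")])
  selfs <- data.frame(species_a = proteins$species_id,
                      gene_a = proteins$gene_id,
                      species_b = proteins$species_id,
                      gene_b = proteins$gene_id,
                      bitscore = 400, stringsAsFactors = FALSE)
  cross <- NULL
  if (cfg$n_core_families > 0L && cfg$n_species > 1L) {
    pairs <- expand.grid(a = seq_along(sp), b = seq_along(sp),
                         fam = seq_len(cfg$n_core_families))
    pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
    cross <- data.frame(
      species_a = sp[pairs$a],
      gene_a = sprintf("core%02d_%s", pairs$fam, sp[pairs$a]),
      species_b = sp[pairs$b],
      gene_b = sprintf("core%02d_%s", pairs$fam, sp[pairs$b]),
      bitscore = 300, stringsAsFactors = FALSE)
    # weak off-family noise edges that must fall below the ratio threshold
    noise <- data.frame(
      species_a = sp[1L], gene_a = sprintf("priv1_%s", sp[1L]),
      species_b = sp[-1L], gene_b = sprintf("priv1_%s", sp[-1L]),
      bitscore = 100, stringsAsFactors = FALSE)
    cross <- rbind(cross, noise)
  }
  scores <- rbind(selfs, cross)
  truth <- rbind(
    data.frame(gene_id = core$gene_id, species_id = core$species_id,
               true_family = sprintf("core%02d", core$fam),
               stringsAsFactors = FALSE),
    data.frame(gene_id = priv$gene_id, species_id = priv$species_id,
               true_family = priv$gene_id, stringsAsFactors = FALSE))
  list(proteins = proteins, scores = scores, truth = truth)
}

# generated data must satisfy their own class definitions
validate_sim <- function(sim) {
  cfg <- sim$cfg
  scfg <- screen_config()
  labels <- sim$truth$gene_labels
  contigs <- detect_telomeres(sim$contigs, scfg)
  tel <- stats::setNames(has_telomere(contigs, scfg), contigs$contig_id)
  for (g in names(labels)) {
    prof <- evaluate_hit_profile(sim$hit_tables[[g]], scfg)
    gene <- sim$genes[sim$genes$gene_id == g, ]
    cpass <- contamination_filter(tel[[gene$contig_id]], gene$n_introns)
    ok <- switch(labels[[g]],
                 HGT = prof$screen_pass && cpass,
                 NATIVE = !prof$screen_pass && cpass,
                 CONTAMINANT = prof$screen_pass && !cpass)
    if (!ok)
      stopf("simulator self-validation failed for %s gene '%s'",
            labels[[g]], g)
  }
  for (g in names(sim$trees))
    if (tree_placement_test(sim$trees[[g]])$verdict != "HGT_TREE_SUPPORTED")
      stopf("simulator self-validation failed: tree for '%s' is not supported", g)
  invisible(sim)
}

#' @export
print.hgt_sim <- function(x, ...) {
  tab <- table(x$truth$gene_labels)
  cat(sprintf("synthetic nanochromosome dataset (seed %d): %d native, %d transferred, %d contaminant genes; %d gene trees; %d-species family benchmark\n",
              x$cfg$seed, tab[["NATIVE"]], tab[["HGT"]], tab[["CONTAMINANT"]],
              length(x$trees), x$cfg$n_species))
  invisible(x)
}
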