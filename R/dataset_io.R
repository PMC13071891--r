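write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stopf("required input file not found: %s", path)
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Write gene models as GFF3
#'
#' Emits gene/mRNA/exon rows with ID/Parent attributes, 1-based closed
#' coordinates.
#'
#' @param genes A `gene_models` data.frame.
#' @param path Output path.
#' @export
write_gff_genes <- function(genes, path) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes$gene_id[i]
    ex <- genes$exons[[i]]
    n <- nrow(ex)
    list(seqnames = rep(genes$contig_id[i], n + 2L),
         start = c(min(ex[, "start"]), min(ex[, "start"]), ex[, "start"]),
         end = c(max(ex[, "end"]), max(ex[, "end"]), ex[, "end"]),
         strand = rep(genes$strand[i], n + 2L),
         type = c("gene", "mRNA", rep("exon", n)),
         ID = c(g, paste0(g, ".t1"), sprintf("%s.exon%d", g, seq_len(n))),
         Parent = c(list(character(0)), list(g),
                    rep(list(paste0(g, ".t1")), n)))
  })
  take <- function(f) unlist(lapply(rows, `[[`, f), use.names = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = take("seqnames"),
    ranges = IRanges::IRanges(start = take("start"), end = take("end")),
    strand = take("strand"),
    type = take("type"), ID = take("ID"),
    Parent = IRanges::CharacterList(
      do.call(c, lapply(rows, `[[`, "Parent"))))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a simulated dataset to a directory
#'
#' Files: `genome.fasta`, `genes.gff3`, `hits.tsv`, `homolog_counts.tsv`,
#' `trees/<gene>.nwk`, `expression.tsv`, `annotations.tsv`, `mic_map.tsv`,
#' `endosymbionts.tsv`, `family_proteins.tsv`, `family_scores.tsv`,
#' `truth_labels.tsv`.
#'
#' @param sim An `hgt_sim` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_fasta(sim$contigs, p("genome.fasta"))
  write_gff_genes(sim$genes, p("genes.gff3"))
  write_hit_table(sim$hit_tables, p("hits.tsv"))
  write_tsv(sim$homolog_counts, p("homolog_counts.tsv"))
  dir.create(p("trees"), showWarnings = FALSE)
  for (g in names(sim$trees)) write_newick(sim$trees[[g]],
                                           p("trees", paste0(g, ".nwk")))
  write_tsv(sim$expression, p("expression.tsv"))
  write_tsv(sim$annotations, p("annotations.tsv"))
  write_tsv(sim$mic_map, p("mic_map.tsv"))
  writeLines(c("# endosymbiont genera (one per line)",
               sim$endosymbiont_genera), p("endosymbionts.tsv"))
  write_tsv(sim$family_proteins, p("family_proteins.tsv"))
  write_tsv(sim$family_scores, p("family_scores.tsv"))
  write_tsv(data.frame(gene_id = names(sim$truth$gene_labels),
                       label = unname(sim$truth$gene_labels)),
            p("truth_labels.tsv"))
  invisible(dir)
}

#' Read a dataset directory back into memory
#'
#' Inverse of [write_dataset()]; truth labels are loaded when present but
#' are never consumed by the analysis stages.
#'
#' @param dir Dataset directory.
#' @return List with the same analysis-facing elements as an `hgt_sim`.
#' @export
read_dataset <- function(dir) {
  p <- function(...) file.path(dir, ...)
  contigs <- read_fasta(p("genome.fasta"))
  lens <- stats::setNames(nchar(contigs$sequence), contigs$contig_id)
  genes <- read_gff_genes(p("genes.gff3"), contig_lengths = lens)
  trees <- list()
  if (dir.exists(p("trees"))) {
    files <- sort(list.files(p("trees"), pattern = "\\.nwk$",
                             full.names = TRUE))
    trees <- lapply(files, read_newick)
    names(trees) <- sub("\\.nwk$", "", basename(files))
  }
  truth <- NULL
  if (file.exists(p("truth_labels.tsv"))) {
    tl <- read_tsv(p("truth_labels.tsv"))
    truth <- list(gene_labels = stats::setNames(tl$label, tl$gene_id))
  }
  list(contigs = contigs, genes = genes,
       hit_tables = read_hit_table(p("hits.tsv")),
       homolog_counts = read_tsv(p("homolog_counts.tsv")),
       trees = trees,
       expression = read_tsv(p("expression.tsv")),
       annotations = read_tsv(p("annotations.tsv")),
       mic_map = if (file.exists(p("mic_map.tsv"))) read_tsv(p("mic_map.tsv")),
       endosymbiont_genera = read_genus_list(p("endosymbionts.tsv")),
       family_proteins = read_tsv(p("family_proteins.tsv")),
       family_scores = read_tsv(p("family_scores.tsv")),
       truth = truth)
}
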