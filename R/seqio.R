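#' Read macronuclear contigs (nanochromosomes) from FASTA
#'
#' Each FASTA record becomes one nanochromosome. Sequences are uppercased and
#' wrapped lines are joined; only the DNA alphabet `A`, `C`, `G`, `T`, `N` is
#' accepted (RNA `U` is rejected). The contig id is the first whitespace-
#' delimited token of the header.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame of class `nanochromosomes` with columns `contig_id`,
#'   `sequence`, `left_telomere_units`, `right_telomere_units` (unit counts
#'   are 0 until [detect_telomeres()] is run).
#' @seealso [detect_telomeres()], [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  if (anyDuplicated(ids))
    stopf("duplicate contig_id in %s: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(nchar(seqs) == 0L))
    stopf("empty sequence for contig '%s'", ids[nchar(seqs) == 0L][1L])
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    ch <- regmatches(seqs[bad][1L], regexpr("[^ACGTN]", seqs[bad][1L]))
    stopf("non-IUPAC DNA character '%s' in contig '%s' (alphabet is A/C/G/T/N)",
          ch, ids[bad][1L])
  }
  nanochromosomes(ids, seqs)
}

#' @rdname read_fasta
#' @param contig_id,sequence Character vectors defining records directly.
#' @export
nanochromosomes <- function(contig_id, sequence) {
  stopifnot(length(contig_id) == length(sequence))
  out <- data.frame(contig_id = as.character(contig_id),
                    sequence = toupper(as.character(sequence)),
                    left_telomere_units = 0L,
                    right_telomere_units = 0L,
                    stringsAsFactors = FALSE)
  class(out) <- c("nanochromosomes", "data.frame")
  out
}

#' Write nanochromosomes to FASTA
#'
#' @param contigs A `nanochromosomes` data.frame.
#' @param path Output path.
#' @export
write_fasta <- function(contigs, path) {
  set <- Biostrings::BStringSet(contigs$sequence)
  names(set) <- contigs$contig_id
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Consumes the gene/mRNA/exon subset of GFF3 (1-based, closed coordinates).
#' Exons are grouped under their gene (via `Parent` chains through mRNA rows,
#' or directly), sorted by start. The coding length is the sum of exon
#' lengths and intron `i` spans `[exon_i end + 1, exon_(i+1) start - 1]`.
#'
#' @param path Path to a GFF3 file.
#' @param contig_lengths Optional named integer vector of contig lengths;
#'   when supplied, exons extending beyond their contig raise an error.
#' @return A data.frame of class `gene_models` with columns `gene_id`,
#'   `contig_id`, `strand`, `cds_length_bp`, `n_introns` and a list column
#'   `exons` (two-column start/end matrices).
#' @export
read_gff_genes <- function(path, contig_lengths = NULL) {
  if (!file.exists(path)) stopf("GFF3 file not found: %s", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   stopf("invalid interval (end < start) or malformed GFF3 in %s: %s",
                         path, conditionMessage(e)))
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p)[1L] else NA_character_, character(1))
  if (any(df$end < df$start))
    stopf("invalid interval (end < start) for feature '%s' in %s",
          df$ID[df$end < df$start][1L], path)
  # map transcript -> gene so exon Parents resolve either way
  tx <- df[df$type %in% c("mRNA", "transcript"), ]
  tx2gene <- structure(tx$Parent, names = tx$ID)
  ex <- df[df$type == "exon", ]
  if (nrow(ex) == 0L) stopf("no exon features in %s", path)
  gene_of <- ifelse(ex$Parent %in% names(tx2gene),
                    unname(tx2gene[ex$Parent]), ex$Parent)
  if (anyNA(gene_of)) stopf("exon without Parent attribute in %s", path)
  genes <- df[df$type == "gene", ]
  gids <- if (nrow(genes)) genes$ID else unique(gene_of)
  recs <- lapply(gids, function(g) {
    e <- ex[gene_of == g, , drop = FALSE]
    if (nrow(e) == 0L) stopf("gene '%s' has no exons in %s", g, path)
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1L && any(e$start[-1L] <= e$end[-nrow(e)]))
      stopf("overlapping exons within gene '%s'", g)
    ctg <- as.character(e$seqnames[1L])
    if (!is.null(contig_lengths)) {
      if (!ctg %in% names(contig_lengths))
        stopf("gene '%s' lies on unknown contig '%s'", g, ctg)
      if (e$start[1L] < 1L || max(e$end) > contig_lengths[[ctg]])
        stopf("exon of gene '%s' outside contig '%s' bounds", g, ctg)
    }
    list(gene_id = g, contig_id = ctg,
         strand = if (as.character(e$strand[1L]) == "-") "-" else "+",
         exons = cbind(start = e$start, end = e$end))
  })
  gene_models(recs)
}

#' @rdname read_gff_genes
#' @param records List of lists with fields `gene_id`, `contig_id`, `strand`,
#'   `exons` (start/end matrix).
#' @export
gene_models <- function(records) {
  out <- data.frame(
    gene_id = vapply(records, `[[`, character(1), "gene_id"),
    contig_id = vapply(records, `[[`, character(1), "contig_id"),
    strand = vapply(records, `[[`, character(1), "strand"),
    stringsAsFactors = FALSE)
  out$exons <- lapply(records, `[[`, "exons")
  out$cds_length_bp <- vapply(out$exons, function(e)
    sum(e[, "end"] - e[, "start"] + 1L), numeric(1))
  out$n_introns <- vapply(out$exons, nrow, integer(1)) - 1L
  if (anyDuplicated(out$gene_id))
    stopf("duplicate gene_id: %s", out$gene_id[duplicated(out$gene_id)][1L])
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Intron intervals of one gene model
#'
#' @param exons A start/end matrix of sorted, non-overlapping exons.
#' @return Matrix of intron `[start, end]` intervals (0 rows for a
#'   single-exon gene).
#' @export
intron_intervals <- function(exons) {
  n <- nrow(exons)
  if (n < 2L) return(cbind(start = integer(0), end = integer(0)))
  cbind(start = exons[-n, "end"] + 1L, end = exons[-1L, "start"] - 1L)
}

HIT_COLS <- c("qseqid", "sseqid", "pident", "evalue", "bitscore",
              "superkingdom", "phylum", "genus", "species")

#' Read a taxonomy-annotated homology hit table
#'
#' The table is tab-separated with exactly the columns `qseqid`, `sseqid`,
#' `pident`, `evalue`, `bitscore`, `superkingdom`, `phylum`, `genus`,
#' `species` (tabular protein-search output plus four taxonomy columns).
#' Lines starting with `#` are ignored; a header line is optional. The
#' superkingdom must be one of Bacteria, Archaea or Eukaryota — anything else
#' (viruses, unclassified entries) is a parse error rather than being
#' silently binned, since the downstream rules are a strict
#' prokaryote/eukaryote dichotomy.
#'
#' @param path Path to the TSV.
#' @return Named list mapping each query gene id to a data.frame of its hits
#'   in file order.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stopf("hit table not found: %s", path)
  raw <- readLines(path)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lineno <- which(keep)
  rows <- raw[keep]
  if (length(rows) && startsWith(rows[1L], "qseqid")) {
    rows <- rows[-1L]; lineno <- lineno[-1L]
  }
  if (!length(rows)) return(structure(list(), names = character(0)))
  parts <- strsplit(rows, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 9L))
    stopf("line %d of %s: expected 9 tab-separated fields, found %d",
          lineno[nf != 9L][1L], path, nf[nf != 9L][1L])
  m <- do.call(rbind, parts)
  colnames(m) <- HIT_COLS
  hits <- as.data.frame(m, stringsAsFactors = FALSE)
  for (col in c("pident", "evalue", "bitscore")) {
    v <- suppressWarnings(as.numeric(hits[[col]]))
    bad <- is.na(v) | !is.finite(v)
    if (any(bad))
      stopf("line %d of %s: malformed numeric in column '%s': '%s'",
            lineno[bad][1L], path, col, hits[[col]][bad][1L])
    hits[[col]] <- v
  }
  bad_sk <- !hits$superkingdom %in% c("Bacteria", "Archaea", "Eukaryota")
  if (any(bad_sk))
    stopf("line %d of %s: unknown superkingdom '%s' (supported: Bacteria, Archaea, Eukaryota)",
          lineno[bad_sk][1L], path, hits$superkingdom[bad_sk][1L])
  empty_tax <- !nzchar(hits$phylum) | !nzchar(hits$genus) | !nzchar(hits$species)
  if (any(empty_tax))
    stopf("line %d of %s: empty taxonomy field", lineno[empty_tax][1L], path)
  split(hits, factor(hits$qseqid, levels = unique(hits$qseqid)))
}

#' Write a hit-table list back to TSV
#' @param hit_tables Named list of hit data.frames (as from
#'   [read_hit_table()]).
#' @param path Output path.
#' @export
write_hit_table <- function(hit_tables, path) {
  all <- do.call(rbind, c(unname(hit_tables), list(make.row.names = FALSE)))
  if (is.null(all)) all <- as.data.frame(setNames(rep(list(character(0)), 9), HIT_COLS))
  utils::write.table(all, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a classified gene tree
#'
#' @param tree An `ape` `phylo` object with unique, non-empty tip labels.
#' @param tip_class Named character vector mapping every tip label to one of
#'   `QUERY`, `PROKARYOTE`, `EUKARYOTE`.
#' @return Object of class `gene_tree`.
#' @export
gene_tree <- function(tree, tip_class) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (any(is.na(tips) | !nzchar(tips))) stopf("tree contains an unlabeled tip")
  if (anyDuplicated(tips))
    stopf("duplicate tip label: %s", tips[duplicated(tips)][1L])
  missing <- setdiff(tips, names(tip_class))
  if (length(missing))
    stopf("tip '%s' has no class mapping", missing[1L])
  cls <- tip_class[tips]
  bad <- !cls %in% c("QUERY", "PROKARYOTE", "EUKARYOTE")
  if (any(bad))
    stopf("tip '%s' has unknown class '%s'", tips[bad][1L], cls[bad][1L])
  if (!any(cls == "QUERY")) stopf("gene tree has no QUERY tip")
  structure(list(tree = tree, tip_class = cls), class = "gene_tree")
}

#' Read a gene tree from Newick, with tip classes
#'
#' Tip classes come from a companion two-column TSV (`tip_id<TAB>class`) or,
#' when `classes` is `NULL`, from tip-name prefixes `QUERY_`, `PROK_`,
#' `EUK_`.
#'
#' @param path Path to a Newick file containing one tree.
#' @param classes `NULL` (use prefixes), a path to a tip-class TSV, or a
#'   named character vector.
#' @return A `gene_tree`.
#' @export
read_newick <- function(path, classes = NULL) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  if (is.null(tr)) stopf("could not parse Newick file: %s", path)
  tips <- tr$tip.label
  if (is.null(classes)) {
    cls <- rep(NA_character_, length(tips))
    cls[startsWith(tips, "QUERY_")] <- "QUERY"
    cls[startsWith(tips, "PROK_")] <- "PROKARYOTE"
    cls[startsWith(tips, "EUK_")] <- "EUKARYOTE"
    if (anyNA(cls))
      stopf("tip '%s' has no class mapping (expected QUERY_/PROK_/EUK_ prefix or a class table)",
            tips[is.na(cls)][1L])
    names(cls) <- tips
  } else if (is.character(classes) && is.null(names(classes)) &&
             length(classes) == 1L) {
    tab <- utils::read.table(classes, sep = "\t", header = FALSE,
                             col.names = c("tip_id", "class"),
                             comment.char = "#", stringsAsFactors = FALSE)
    cls <- structure(tab$class, names = tab$tip_id)
  } else {
    cls <- classes
  }
  gene_tree(tr, cls)
}

#' Write a gene tree to Newick
#' @param gtree A `gene_tree`.
#' @param path Output path.
#' @export
write_newick <- function(gtree, path) {
  ape::write.tree(gtree$tree, file = path)
  invisible(path)
}

#' Write the per-gene HGT call report
#'
#' One row per gene with every evidence field of the call table.
#'
#' @param calls An `hgt_calls` data.frame (see [screen_genome()]).
#' @param path Output TSV path.
#' @export
write_report <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
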