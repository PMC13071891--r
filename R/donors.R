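#' Attribute a donor taxon to a validated HGT gene
#'
#' The donor is the taxonomy of the gene's best retained hit, with the same
#' retention filters and tie-breaking (E-value, then bitscore, then subject
#' id) as the screening stage. Donor phylum nomenclature follows the hit
#' table verbatim; no synonym resolution is attempted.
#'
#' @param gene_id Gene identifier.
#' @param hits Hit data.frame for the gene.
#' @param cfg A [screen_config()].
#' @return One-row data.frame with `gene_id`, `donor_species`,
#'   `donor_genus`, `donor_phylum`, `best_hit_id`.
#' @export
assign_donor <- function(gene_id, hits, cfg = screen_config()) {
  prof <- evaluate_hit_profile(hits, cfg)
  if (is.null(prof$best_hit) || !prof$best_hit_prokaryotic)
    stopf("gene '%s' has no retained prokaryotic best hit; donor undefined",
          gene_id)
  b <- prof$best_hit
  data.frame(gene_id = gene_id, donor_species = b$species,
             donor_genus = b$genus, donor_phylum = b$phylum,
             best_hit_id = b$sseqid, stringsAsFactors = FALSE)
}

#' @rdname assign_donor
#' @param gene_ids Character vector of validated genes.
#' @param hit_tables Named list of hit data.frames.
#' @param species_id Optional species label attached to every row.
#' @export
assign_donors <- function(gene_ids, hit_tables, cfg = screen_config(),
                          species_id = NULL) {
  rows <- lapply(gene_ids, function(g) assign_donor(g, hit_tables[[g]], cfg))
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(gene_id = character(0), donor_species = character(0),
                      donor_genus = character(0), donor_phylum = character(0),
                      best_hit_id = character(0))
  if (!is.null(species_id)) out$species_id <- species_id
  out
}

#' Donor phylum spectrum per species
#'
#' @param assignments Data.frame from [assign_donors()]; a `species_id`
#'   column groups rows (absent = one unnamed species).
#' @return Matrix of proportions (species rows, donor-phylum columns); each
#'   row sums to 1.
#' @export
phylum_spectrum <- function(assignments) {
  if (nrow(assignments) == 0L) stopf("no donor assignments")
  sp <- if ("species_id" %in% names(assignments)) assignments$species_id
        else rep("all", nrow(assignments))
  tab <- table(sp, assignments$donor_phylum)
  prop <- sweep(unclass(tab), 1L, rowSums(tab), "/")
  prop
}

#' Flag endosymbiont-derived genes
#'
#' A validated HGT gene is endosymbiont-derived if its donor genus matches a
#' genus known to live endosymbiotically in the host, by case-insensitive
#' exact genus match; a leading "Candidatus " is stripped from both sides
#' before comparison.
#'
#' @param assignments Data.frame with a `donor_genus` column.
#' @param endosymbiont_genera Non-empty character vector of genus names.
#' @return Logical vector, one flag per assignment row.
#' @export
flag_endosymbiont_derived <- function(assignments, endosymbiont_genera) {
  if (length(endosymbiont_genera) == 0L)
    stopf("endosymbiont genus list is empty")
  norm <- function(x) tolower(sub("^candidatus\\s+", "", trimws(x),
                                  ignore.case = TRUE))
  norm(assignments$donor_genus) %in% norm(endosymbiont_genera)
}

#' Read an endosymbiont genus list (one genus per line, '#' comments)
#' @param path Path to the TSV/plain list.
#' @return Character vector of genus names.
#' @export
read_genus_list <- function(path) {
  x <- readLines(path)
  x <- trimws(sub("#.*$", "", x))
  x <- x[nzchar(x)]
  if (!length(x)) stopf("no genera found in %s", path)
  x
}

#' Cluster transferred genes into cross-species families
#'
#' Families are connected components of the bidirectional-best-hit (BBH)
#' graph: for each gene and each other species, its best-scoring hit is
#' found; an edge is kept when the relationship is mutual and the score
#' passes `link_threshold`. When self-scores (rows with identical
#' species/gene on both sides) are available, the threshold applies to the
#' bitscore ratio `score / min(self_a, self_b)`; otherwise to the raw score.
#' Components are closed by single linkage. This is a deliberately
#' self-contained, deterministic stand-in for a full orthology inference
#' tool.
#'
#' @param proteins Data.frame enumerating all genes: columns `species_id`,
#'   `gene_id`. Genes with no qualifying edge become singleton families.
#' @param scores Data.frame of pairwise scores: columns `species_a`,
#'   `gene_a`, `species_b`, `gene_b`, `bitscore`.
#' @param link_threshold Minimum (ratio or raw) score for an edge
#'   (default 0.5).
#' @return Data.frame of class `hgt_families` with columns `family_id`,
#'   `species_id`, `gene_id`; `family_id` is named after the
#'   lexicographically smallest member.
#' @export
cluster_families <- function(proteins, scores, link_threshold = 0.5) {
  node <- function(sp, g) paste(sp, g, sep = ":")
  all_nodes <- sort(node(proteins$species_id, proteins$gene_id))
  if (anyDuplicated(all_nodes)) stopf("duplicate species/gene entry")
  self_rows <- scores$species_a == scores$species_b &
    scores$gene_a == scores$gene_b
  selfs <- structure(scores$bitscore[self_rows],
                     names = node(scores$species_a[self_rows],
                                  scores$gene_a[self_rows]))
  cross <- scores[!self_rows & scores$species_a != scores$species_b, ,
                  drop = FALSE]
  edges <- character(0)
  if (nrow(cross)) {
    a <- node(cross$species_a, cross$gene_a)
    b <- node(cross$species_b, cross$gene_b)
    # directed best hit of each gene into each other species
    key <- paste(a, cross$species_b, sep = "->")
    ord <- order(key, -cross$bitscore, b, method = "radix")
    bestrow <- ord[!duplicated(key[ord])]
    best <- structure(b[bestrow], names = key[bestrow])
    bestscore <- structure(cross$bitscore[bestrow], names = key[bestrow])
    # mutual pairs
    for (i in seq_along(best)) {
      u <- sub("->.*$", "", names(best)[i]); v <- best[[i]]
      if (u >= v) next  # each unordered pair once
      sp_u <- sub(":.*$", "", u)
      bk <- paste(v, sp_u, sep = "->")
      if (!bk %in% names(best) || best[[bk]] != u) next
      sc <- min(bestscore[[i]], bestscore[[bk]])
      denom <- if (!is.na(selfs[u]) && !is.na(selfs[v]))
        min(selfs[u], selfs[v]) else NA_real_
      val <- if (!is.na(denom) && denom > 0) sc / denom else sc
      if (val >= link_threshold) edges <- c(edges, u, v)
    }
  }
  g <- igraph::add_vertices(igraph::make_empty_graph(directed = FALSE),
                            length(all_nodes), name = all_nodes)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  fam <- split(names(comp), comp)
  fam_ids <- vapply(fam, function(members) paste0("fam:", min(members)),
                    character(1))
  out <- do.call(rbind, lapply(seq_along(fam), function(i) {
    m <- sort(fam[[i]])
    data.frame(family_id = fam_ids[[i]],
               species_id = sub(":.*$", "", m),
               gene_id = sub("^[^:]*:", "", m),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$family_id, out$species_id, out$gene_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hgt_families", "data.frame")
  out
}

#' Count families shared across species subsets
#'
#' Each family contributes to exactly one cell keyed by the set of species
#' it occurs in (a Venn-style partition); the core count is the number of
#' families present in every species of `species_list`.
#'
#' @param families An `hgt_families` data.frame.
#' @param species_list Character vector of all species under comparison.
#' @return List with `cells` (data.frame `species_subset`, `n_families`),
#'   `core_count`, and `n_families`.
#' @export
shared_family_counts <- function(families, species_list) {
  if (nrow(families) == 0L) stopf("no families supplied")
  present <- lapply(split(families$species_id, families$family_id),
                    function(s) sort(unique(s)))
  keys <- vapply(present, paste, character(1), collapse = "+")
  tab <- table(keys)
  cells <- data.frame(species_subset = names(tab),
                      n_families = as.integer(tab),
                      stringsAsFactors = FALSE)
  core_key <- paste(sort(unique(species_list)), collapse = "+")
  core <- sum(keys == core_key)
  list(cells = cells[order(cells$species_subset), , drop = FALSE],
       core_count = core, n_families = length(present))
}
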