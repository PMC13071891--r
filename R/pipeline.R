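#' Run the full HGT detection and analysis pipeline
#'
#' Composes the stages end-to-end: hit-profile screening and contamination
#' filtering, phylogenetic validation, feature and expression comparisons of
#' transferred versus native genes, term enrichment, donor attribution with
#' endosymbiont flagging, germline scaffold dispersion, and cross-species
#' family sharing. "Native" in the comparisons means genes that are not
#' validated transfers but pass the contamination filter (putative bacterial
#' contamination is excluded from both groups).
#'
#' @param input An `hgt_sim` object, a dataset directory (see
#'   [read_dataset()]), or a list with the same elements.
#' @param cfg A [screen_config()].
#' @param link_threshold Family-clustering score-ratio threshold.
#' @param out_dir Optional directory: writes `report.tsv` (per-gene calls),
#'   `enrichment.tsv`, `donors.tsv`, `family_cells.tsv` and
#'   `manifest.json`.
#' @return Object of class `hgt_run`: list with `calls`, `feature_tests`,
#'   `enrichment`, `donors`, `phylum_spectrum`, `mic`, `families`,
#'   `shared_families`, `manifest`.
#' @export
run_hgt_pipeline <- function(input, cfg = screen_config(),
                             link_threshold = 0.5, out_dir = NULL) {
  dat <- if (is.character(input)) read_dataset(input) else input
  for (el in c("contigs", "genes", "hit_tables", "homolog_counts"))
    if (is.null(dat[[el]])) stopf("pipeline input lacks element '%s'", el)

  calls <- screen_genome(dat$contigs, dat$genes, dat$hit_tables, cfg)
  calls <- validate_candidates(calls, dat$homolog_counts, dat$trees)
  hgt_ids <- calls$gene_id[calls$final_status == "HGT"]
  native_ids <- calls$gene_id[calls$final_status != "HGT" &
                                calls$contamination_pass]

  feature_tests <- list()
  if (length(hgt_ids) && length(native_ids)) {
    genes <- dat$genes
    idx <- function(ids) match(ids, genes$gene_id)
    cds_seq <- function(i) {
      ctg <- dat$contigs$sequence[match(genes$contig_id[i],
                                        dat$contigs$contig_id)]
      paste(substring(ctg, genes$exons[[i]][, "start"],
                      genes$exons[[i]][, "end"]), collapse = "")
    }
    gc_h <- gc_content(vapply(idx(hgt_ids), cds_seq, character(1)))
    gc_n <- gc_content(vapply(idx(native_ids), cds_seq, character(1)))
    feature_tests$gc <- wilcoxon_rank_sum(gc_h, gc_n, mode = "normal")
    feature_tests$cds_length <- wilcoxon_rank_sum(
      genes$cds_length_bp[idx(hgt_ids)], genes$cds_length_bp[idx(native_ids)],
      mode = "normal")
    intron_tab <- rbind(
      HGT = c(with = sum(genes$n_introns[idx(hgt_ids)] >= 1L),
              without = sum(genes$n_introns[idx(hgt_ids)] == 0L)),
      NATIVE = c(with = sum(genes$n_introns[idx(native_ids)] >= 1L),
                 without = sum(genes$n_introns[idx(native_ids)] == 0L)))
    feature_tests$intron_proportion <- tryCatch(
      chi_square_independence(intron_tab), error = function(e) NULL)
    if (!is.null(dat$expression)) {
      ex <- dat$expression
      tpms <- stats::setNames(tpm(ex$count, ex$effective_length), ex$gene_id)
      feature_tests$expression <- wilcoxon_rank_sum(
        tpms[hgt_ids], tpms[native_ids], mode = "normal")
    }
  }

  enrichment <- NULL
  if (!is.null(dat$annotations) && length(hgt_ids)) {
    universe <- c(hgt_ids, native_ids)
    enrichment <- hypergeometric_enrichment(hgt_ids, dat$annotations,
                                            universe)
  }

  donors <- NULL; spectrum <- NULL
  if (length(hgt_ids)) {
    donors <- assign_donors(hgt_ids, dat$hit_tables, cfg)
    if (!is.null(dat$endosymbiont_genera))
      donors$endosymbiont_derived <-
        flag_endosymbiont_derived(donors, dat$endosymbiont_genera)
    spectrum <- phylum_spectrum(donors)
  }

  mic <- if (!is.null(dat$mic_map) && nrow(dat$mic_map))
    mic_dispersion(dat$mic_map)

  families <- NULL; shared <- NULL
  if (!is.null(dat$family_proteins) && nrow(dat$family_proteins)) {
    families <- cluster_families(dat$family_proteins, dat$family_scores,
                                 link_threshold)
    shared <- shared_family_counts(families,
                                   unique(dat$family_proteins$species_id))
  }

  manifest <- list(
    seed = if (!is.null(dat$cfg)) dat$cfg$seed,
    screen_config = unclass(cfg),
    n_genes = nrow(calls),
    n_screen_pass = sum(calls$screen_pass),
    n_candidates = sum(calls$candidate),
    n_validated_hgt = length(hgt_ids),
    n_putative_contamination = sum(!calls$contamination_pass),
    verdict_counts = as.list(table(calls$phylo_verdict)),
    telomere_bearing_fraction = if (length(hgt_ids))
      mean(calls$has_telomere[match(hgt_ids, calls$gene_id)]),
    n_endosymbiont_derived = if (!is.null(donors) &&
                                 !is.null(donors$endosymbiont_derived))
      sum(donors$endosymbiont_derived),
    core_family_count = if (!is.null(shared)) shared$core_count)

  run <- structure(list(calls = calls, feature_tests = feature_tests,
                        enrichment = enrichment, donors = donors,
                        phylum_spectrum = spectrum, mic = mic,
                        families = families, shared_families = shared,
                        manifest = manifest),
                   class = "hgt_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(calls, file.path(out_dir, "report.tsv"))
    if (!is.null(enrichment))
      write_tsv(enrichment, file.path(out_dir, "enrichment.tsv"))
    if (!is.null(donors))
      write_tsv(donors, file.path(out_dir, "donors.tsv"))
    if (!is.null(shared))
      write_tsv(shared$cells, file.path(out_dir, "family_cells.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  run
}

#' @export
print.hgt_run <- function(x, ...) {
  m <- x$manifest
  cat("Horizontal gene transfer pipeline run\n")
  cat(sprintf("  genes analysed        : %d\n", m$n_genes))
  cat(sprintf("  screened candidates   : %d\n", m$n_candidates))
  cat(sprintf("  validated HGT genes   : %d\n", m$n_validated_hgt))
  if (!is.null(m$telomere_bearing_fraction))
    cat(sprintf("  telomere-bearing HGT  : %.1f%%\n",
                100 * m$telomere_bearing_fraction))
  if (!is.null(m$n_endosymbiont_derived))
    cat(sprintf("  endosymbiont-derived  : %d\n", m$n_endosymbiont_derived))
  if (!is.null(m$core_family_count))
    cat(sprintf("  core shared families  : %d\n", m$core_family_count))
  invisible(x)
}

#' @method summary hgt_run
#' @export
summary.hgt_run <- function(object, ...) {
  print(object)
  if (length(object$feature_tests)) {
    cat("  feature comparisons (transferred vs native):\n")
    for (nm in names(object$feature_tests)) {
      t <- object$feature_tests[[nm]]
      if (!is.null(t))
        cat(sprintf("    %-18s %s p = %.3g\n", nm, t$method, t$p_value))
    }
  }
  if (!is.null(object$enrichment) && nrow(object$enrichment))
    cat(sprintf("  top enriched term: %s (q = %.3g)\n",
                object$enrichment$term[1L], object$enrichment$q[1L]))
  invisible(object)
}
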