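#' Screening configuration
#'
#' Thresholds for the taxonomic hit-profile screen and the
#' nanochromosome-specific contamination filter.
#'
#' @param evalue_cutoff Hits with E-value above this are discarded before any
#'   other rule (default `1e-5`).
#' @param prokaryote_fraction_threshold The retained-hit prokaryote fraction
#'   must strictly exceed this ("more than 50 percent"; default `0.5`).
#' @param telomere_motifs Telomeric repeat units scanned at contig ends
#'   (default the Euplotes C4A4/G4T4 octamers); reverse complements are
#'   scanned automatically.
#' @param telomere_window_bp A tandem repeat run may start anywhere within
#'   this many bases of the contig end (default 50).
#' @param telomere_min_units Minimum number of tandem motif copies for an end
#'   run to count as a telomere (default 2).
#' @param self_taxon_excluded Genera removed from hit profiles before
#'   best-hit/fraction computation (self-hits; default `"Euplotes"`).
#' @return Object of class `screen_config`.
#' @export
screen_config <- function(evalue_cutoff = 1e-5,
                          prokaryote_fraction_threshold = 0.5,
                          telomere_motifs = c("CCCCAAAA", "GGGGTTTT"),
                          telomere_window_bp = 50L,
                          telomere_min_units = 2L,
                          self_taxon_excluded = "Euplotes") {
  stopifnot(is.numeric(evalue_cutoff), evalue_cutoff > 0)
  if (!(prokaryote_fraction_threshold > 0 && prokaryote_fraction_threshold < 1))
    stopf("prokaryote_fraction_threshold must lie strictly in (0, 1)")
  if (length(telomere_motifs) == 0L || any(!nzchar(telomere_motifs)) ||
      any(grepl("[^ACGT]", telomere_motifs)))
    stopf("telomere_motifs must be non-empty DNA strings")
  if (telomere_min_units < 1L) stopf("telomere_min_units must be >= 1")
  structure(list(evalue_cutoff = evalue_cutoff,
                 prokaryote_fraction_threshold = prokaryote_fraction_threshold,
                 telomere_motifs = toupper(telomere_motifs),
                 telomere_window_bp = as.integer(telomere_window_bp),
                 telomere_min_units = as.integer(telomere_min_units),
                 self_taxon_excluded = self_taxon_excluded),
            class = "screen_config")
}

# longest tandem run of any motif (or reverse complement) starting within
# `window` bases of the 5' end; a ragged partial leading unit is tolerated
# because the run may start at any offset inside the window
tandem_units_5p <- function(seq, motifs, window) {
  n <- nchar(seq)
  best <- 0L
  for (m in unique(c(motifs, revcomp(motifs)))) {
    k <- nchar(m)
    for (off in seq_len(min(window, n))) {
      cnt <- 0L
      p <- off
      while (p + k - 1L <= n && substr(seq, p, p + k - 1L) == m) {
        cnt <- cnt + 1L
        p <- p + k
      }
      if (cnt > best) best <- cnt
    }
  }
  best
}

#' Detect telomeric repeats at nanochromosome ends
#'
#' Euplotes macronuclear nanochromosomes are capped by 5'-(C4A4)n telomeric
#' repeats (read G4T4 on the other strand). Each contig end is scanned for
#' tandem copies of the configured motifs and their reverse complements; the
#' run may start anywhere within `telomere_window_bp` of the end, which
#' tolerates ragged telomere boundaries and partial flanking units. The 3'
#' end is scanned as the 5' end of the reverse complement, so
#' reverse-complementing a contig exactly swaps the two unit counts.
#'
#' @param contigs A `nanochromosomes` data.frame.
#' @param cfg A [screen_config()].
#' @return `contigs` with `left_telomere_units`/`right_telomere_units`
#'   filled.
#' @export
detect_telomeres <- function(contigs, cfg = screen_config()) {
  contigs$left_telomere_units <- vapply(
    contigs$sequence, tandem_units_5p, integer(1),
    motifs = cfg$telomere_motifs, window = cfg$telomere_window_bp,
    USE.NAMES = FALSE)
  contigs$right_telomere_units <- vapply(
    revcomp(contigs$sequence), tandem_units_5p, integer(1),
    motifs = cfg$telomere_motifs, window = cfg$telomere_window_bp,
    USE.NAMES = FALSE)
  contigs
}

#' @rdname detect_telomeres
#' @return `has_telomere()`: logical; a contig has a telomere iff either end
#'   carries at least `telomere_min_units` tandem units (one telomere
#'   suffices).
#' @export
has_telomere <- function(contigs, cfg = screen_config()) {
  pmax(contigs$left_telomere_units, contigs$right_telomere_units) >=
    cfg$telomere_min_units
}

#' Evaluate the taxonomic hit profile of one gene
#'
#' Hits above the E-value cutoff and self-hits (genus in
#' `self_taxon_excluded`) are removed; among retained hits the best hit is
#' the minimal E-value (ties broken by maximal bitscore, then subject id).
#' The screen passes iff at least one hit is retained, the best hit is
#' prokaryotic, and the prokaryote fraction strictly exceeds the threshold.
#'
#' @param hits Data.frame of hits for one gene (may be `NULL` or empty).
#' @param cfg A [screen_config()].
#' @return List with `passed_evalue`, `best_hit_prokaryotic`,
#'   `prokaryote_hit_fraction`, `screen_pass`, `n_retained`, and `best_hit`
#'   (one-row data.frame or `NULL`).
#' @export
evaluate_hit_profile <- function(hits, cfg = screen_config()) {
  fail <- list(passed_evalue = FALSE, best_hit_prokaryotic = FALSE,
               prokaryote_hit_fraction = 0, screen_pass = FALSE,
               n_retained = 0L, best_hit = NULL)
  if (is.null(hits) || nrow(hits) == 0L) return(fail)
  keep <- hits$evalue <= cfg$evalue_cutoff &
    !(tolower(hits$genus) %in% tolower(cfg$self_taxon_excluded))
  ret <- hits[keep, , drop = FALSE]
  if (nrow(ret) == 0L) return(fail)
  best <- ret[order_hits(ret)[1L], , drop = FALSE]
  frac <- mean(is_prokaryote(ret$superkingdom))
  best_prok <- is_prokaryote(best$superkingdom)
  list(passed_evalue = TRUE,
       best_hit_prokaryotic = best_prok,
       prokaryote_hit_fraction = frac,
       screen_pass = best_prok && frac > cfg$prokaryote_fraction_threshold,
       n_retained = nrow(ret),
       best_hit = best)
}

#' Nanochromosome contamination filter
#'
#' A screened candidate is kept only if it shows at least one of two
#' eukaryotic nanochromosome features: a telomeric repeat on its contig, or
#' at least one spliceosomal intron. Genes with neither are treated as
#' putative bacterial contamination.
#'
#' @param has_telomere Logical vector.
#' @param intron_count Integer vector of per-gene intron counts.
#' @return Logical vector: `TRUE` iff telomere present or intron present.
#' @export
contamination_filter <- function(has_telomere, intron_count) {
  stopifnot(length(has_telomere) == length(intron_count))
  if (any(intron_count < 0)) stopf("negative intron count")
  as.logical(has_telomere) | intron_count >= 1L
}

#' Screen a genome for horizontal transfer candidates
#'
#' Runs telomere detection, the per-gene hit-profile screen and the
#' contamination filter, producing one evidence row per gene. Phylogenetic
#' fields are left unset; see [validate_candidates()].
#'
#' @param contigs A `nanochromosomes` data.frame.
#' @param genes A `gene_models` data.frame.
#' @param hit_tables Named list mapping gene ids to hit data.frames (genes
#'   absent from the list are treated as having no hits).
#' @param cfg A [screen_config()].
#' @return An `hgt_calls` data.frame with columns `gene_id`, `passed_evalue`,
#'   `best_hit_prokaryotic`, `prokaryote_hit_fraction`, `has_telomere`,
#'   `has_intron`, `screen_pass`, `contamination_pass`, `candidate`,
#'   `phylo_verdict` (`NA` until validation), `final_status` (`NA`).
#' @export
screen_genome <- function(contigs, genes, hit_tables, cfg = screen_config()) {
  missing_ctg <- setdiff(genes$contig_id, contigs$contig_id)
  if (length(missing_ctg))
    stopf("gene '%s' references missing contig '%s'",
          genes$gene_id[match(missing_ctg[1L], genes$contig_id)],
          missing_ctg[1L])
  contigs <- detect_telomeres(contigs, cfg)
  tel <- has_telomere(contigs, cfg)
  names(tel) <- contigs$contig_id
  prof <- lapply(genes$gene_id, function(g)
    evaluate_hit_profile(hit_tables[[g]], cfg))
  calls <- data.frame(
    gene_id = genes$gene_id,
    passed_evalue = vapply(prof, `[[`, logical(1), "passed_evalue"),
    best_hit_prokaryotic = vapply(prof, `[[`, logical(1), "best_hit_prokaryotic"),
    prokaryote_hit_fraction = vapply(prof, `[[`, numeric(1), "prokaryote_hit_fraction"),
    has_telomere = unname(tel[genes$contig_id]),
    has_intron = genes$n_introns >= 1L,
    screen_pass = vapply(prof, `[[`, logical(1), "screen_pass"),
    stringsAsFactors = FALSE)
  calls$contamination_pass <- contamination_filter(calls$has_telomere,
                                                   genes$n_introns)
  calls$candidate <- calls$screen_pass & calls$contamination_pass
  calls$phylo_verdict <- NA_character_
  calls$final_status <- NA_character_
  class(calls) <- c("hgt_calls", "data.frame")
  calls
}

#' @export
print.hgt_calls <- function(x, ...) {
  cat(sprintf("HGT call table: %d genes\n", nrow(x)))
  cat(sprintf("  screened candidates : %d\n", sum(x$candidate)))
  if (!all(is.na(x$final_status))) {
    cat(sprintf("  validated HGT       : %d\n",
                sum(x$final_status == "HGT", na.rm = TRUE)))
  } else {
    cat("  (phylogenetic validation not yet run)\n")
  }
  invisible(x)
}

#' @method summary hgt_calls
#' @export
summary.hgt_calls <- function(object, ...) {
  s <- list(
    n_genes = nrow(object),
    n_passed_evalue = sum(object$passed_evalue),
    n_screen_pass = sum(object$screen_pass),
    n_contamination_pass = sum(object$contamination_pass),
    n_candidates = sum(object$candidate),
    verdicts = table(object$phylo_verdict, useNA = "ifany"),
    n_hgt = sum(object$final_status == "HGT", na.rm = TRUE))
  class(s) <- "summary.hgt_calls"
  s
}

#' @export
print.summary.hgt_calls <- function(x, ...) {
  cat(sprintf("%d genes; %d pass hit-profile screen; %d pass contamination filter; %d candidates; %d validated HGT\n",
              x$n_genes, x$n_screen_pass, x$n_contamination_pass,
              x$n_candidates, x$n_hgt))
  invisible(x)
}
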