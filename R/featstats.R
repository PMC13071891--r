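#' GC content of DNA sequences
#'
#' `N` bases are excluded from both numerator and denominator.
#'
#' @param sequence Character vector of DNA strings.
#' @return Numeric vector in `[0, 1]`.
#' @export
gc_content <- function(sequence) {
  vapply(toupper(sequence), function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    gc <- sum(ch == "G" | ch == "C")
    at <- sum(ch == "A" | ch == "T")
    if (gc + at == 0L)
      stopf("sequence has no unambiguous A/C/G/T base; GC content undefined")
    gc / (gc + at)
  }, numeric(1), USE.NAMES = FALSE)
}

test_result <- function(statistic, p_value, method) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 method = method), class = "hgt_test")
}

#' @export
print.hgt_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.6g\n", x$method, x$statistic,
              x$p_value))
  invisible(x)
}

# exact two-sided rank-sum p by enumeration over group assignments of the
# pooled midranks (handles ties; used only when the closed-form null
# distribution does not apply)
wilcoxon_exact_enum <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  if (choose(n + m, min(n, m)) > 3e6)
    stopf("exact rank-sum enumeration infeasible for these sample sizes")
  small_is_x <- n <= m
  ksmall <- min(n, m)
  sums <- utils::combn(r, ksmall, sum)
  tot <- sum(r)
  obs <- sum(r[seq_len(n)])
  stat <- if (small_is_x) sums else tot - sums
  eps <- 1e-9
  p_lo <- mean(stat <= obs + eps)
  p_hi <- mean(stat >= obs - eps)
  min(1, 2 * min(p_lo, p_hi))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Compares two independent samples. `exact` mode uses the exact null
#' distribution of the rank sum (the closed-form distribution when the data
#' are tie-free, full enumeration over group assignments of the pooled
#' midranks otherwise); the two-sided p is twice the smaller tail,
#' capped at 1. `normal` mode uses the mean/variance approximation with tie
#' and continuity corrections. `auto` picks exact when
#' `min(length(x), length(y)) <= 8` and the pooled data are tie-free.
#'
#' @param x,y Non-empty numeric vectors.
#' @param mode One of `"auto"`, `"exact"`, `"normal"`.
#' @return An `hgt_test` with the Mann-Whitney `U` of `x`, the p-value, and
#'   method `wilcoxon_exact` or `wilcoxon_normal`.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L)
    stopf("both samples must be non-empty")
  n <- length(x); m <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0L
  if (mode == "auto") mode <- if (min(n, m) <= 8L && !ties) "exact" else "normal"
  u <- sum(rank(c(x, y))[seq_len(n)]) - n * (n + 1) / 2
  if (mode == "exact") {
    if (!ties) {
      p_lo <- stats::pwilcox(u, n, m)
      p_hi <- stats::pwilcox(u - 1, n, m, lower.tail = FALSE)
      p <- min(1, 2 * min(p_lo, p_hi))
    } else {
      p <- wilcoxon_exact_enum(x, y)
    }
    return(test_result(u, p, "wilcoxon_exact"))
  }
  res <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = TRUE))
  test_result(u, res$p.value, "wilcoxon_normal")
}

#' Pearson chi-square test of independence for a 2x2 table
#'
#' Uncorrected Pearson statistic (no continuity correction), df = 1,
#' upper-tail p. Used for the intron-containing proportion comparison of
#' transferred versus native genes.
#'
#' @param tab 2x2 matrix of non-negative counts; all row and column margins
#'   must be positive.
#' @return An `hgt_test` with method `chi_square`.
#' @export
chi_square_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stopf("expected a 2x2 count table")
  if (any(tab < 0) || any(tab != round(tab)))
    stopf("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("zero row or column margin; expected counts undefined")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  test_result(res$statistic, res$p.value, "chi_square")
}

#' Transcripts-per-million normalization
#'
#' `tpm_i = 1e6 * (counts_i / lengths_i) / sum_j (counts_j / lengths_j)`;
#' the result always sums to one million.
#'
#' @param counts Non-negative numeric vector of read counts.
#' @param lengths_bp Positive effective lengths, same length as `counts`.
#' @return Numeric TPM vector.
#' @export
tpm <- function(counts, lengths_bp) {
  if (length(counts) != length(lengths_bp))
    stopf("counts and lengths_bp must have equal length")
  if (any(lengths_bp <= 0)) stopf("lengths must be positive")
  if (any(counts < 0)) stopf("counts must be non-negative")
  rate <- counts / lengths_bp
  s <- sum(rate)
  if (s <= 0) stopf("all counts are zero; TPM undefined")
  1e6 * rate / s
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} (m * p_(j) / j)` capped at
#' 1, mapped back to input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Hypergeometric term enrichment of a study set
#'
#' For each annotation term, the upper-tail hypergeometric p-value
#' `P(X >= k)` for drawing `k` term-annotated genes in a study set of size
#' `n` from a universe of `N` genes of which `K` carry the term, with BH
#' adjustment across all tested terms.
#'
#' @param study_set Character vector of gene ids (must be a subset of
#'   `universe`).
#' @param annotation_map Data.frame with columns `gene_id`, `term`.
#' @param universe Character vector of background gene ids.
#' @return Data.frame with columns `term`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   ordered by increasing `p`.
#' @export
hypergeometric_enrichment <- function(study_set, annotation_map, universe) {
  universe <- unique(universe)
  study_set <- unique(study_set)
  outside <- setdiff(study_set, universe)
  if (length(outside))
    stopf("study gene '%s' is not in the universe", outside[1L])
  ann <- annotation_map[annotation_map$gene_id %in% universe, , drop = FALSE]
  ann <- unique(ann[, c("gene_id", "term")])
  if (nrow(ann) == 0L)
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0)))
  N <- length(universe); n <- length(study_set)
  terms <- sort(unique(ann$term))
  K <- vapply(terms, function(t) sum(ann$term == t), integer(1))
  k <- vapply(terms, function(t)
    sum(ann$gene_id[ann$term == t] %in% study_set), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = terms, k = k, K = K, n = n, N = N, p = p,
                    q = bh_adjust(p), row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$p, out$term), , drop = FALSE]
}

#' Translate an open reading frame
#'
#' The default genetic code is the Euplotid nuclear code (NCBI table 10), in
#' which UGA encodes cysteine and only UAA/UAG terminate. The ORF span is
#' stop-exclusive, so any in-frame stop codon is an error; the protein
#' length is exactly `nchar(dna) / 3`.
#'
#' @param dna DNA string, length divisible by 3.
#' @param genetic_code `"euplotid"` (default), `"standard"`, or an NCBI
#'   genetic-code table id accepted by [Biostrings::getGeneticCode()].
#' @return Amino-acid string.
#' @export
translate_orf <- function(dna, genetic_code = "euplotid") {
  dna <- toupper(dna)
  if (nchar(dna) %% 3 != 0)
    stopf("ORF length %d is not divisible by 3", nchar(dna))
  id <- switch(genetic_code, euplotid = "10", standard = "1", genetic_code)
  code <- Biostrings::getGeneticCode(id)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                           genetic.code = code,
                                           no.init.codon = TRUE))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0)
    stopf("internal stop codon at codon position %d under genetic code %s",
          as.integer(stop_at), id)
  aa
}

#' Dispersion of genes over germline (micronuclear) scaffolds
#'
#' @param gene_to_scaffold_map Data.frame with columns `gene_id`,
#'   `scaffold_id`, or a named character vector (names = gene ids).
#' @return List with `n_genes_mapped`, `n_scaffolds`,
#'   `max_genes_per_scaffold`.
#' @export
mic_dispersion <- function(gene_to_scaffold_map) {
  if (is.data.frame(gene_to_scaffold_map)) {
    scaf <- gene_to_scaffold_map$scaffold_id
    genes <- gene_to_scaffold_map$gene_id
  } else {
    scaf <- unname(gene_to_scaffold_map)
    genes <- names(gene_to_scaffold_map)
  }
  if (length(scaf) == 0L) stopf("gene-to-scaffold map is empty")
  tab <- table(scaf)
  list(n_genes_mapped = length(unique(genes)),
       n_scaffolds = length(tab),
       max_genes_per_scaffold = as.integer(max(tab)))
}
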