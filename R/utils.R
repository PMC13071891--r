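# internal helpers shared across modules

# reverse-complement of an ACGTN string (vectorized)
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", toupper(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

is_prokaryote <- function(superkingdom) superkingdom %in% c("Bacteria", "Archaea")

# run `expr` under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# ordering used for best-hit selection everywhere: ascending E-value,
# descending bitscore, then subject id (deterministic, order-independent)
order_hits <- function(hits) {
  order(hits$evalue, -hits$bitscore, hits$sseqid, method = "radix")
}
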