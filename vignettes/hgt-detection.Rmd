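---
title: "Detecting bacterial gene transfer in nanochromosome genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting bacterial gene transfer in nanochromosome genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliateHGT)
```

## The detection model

Ciliate macronuclear genomes are highly fragmented: each nanochromosome is a
gene-sized molecule capped by telomeric repeats. Bacterial horizontal gene
transfer (HGT) detection in this setting must separate three classes that a
naive similarity search confounds — native genes, resident transferred
genes, and bacterial contamination co-assembled with the host. The pipeline
treats a gene as transferred only when three independent lines of evidence
agree.

**Stage 1 — taxonomic hit profile.** Per-gene homology hits carry their
subject taxonomy (superkingdom, phylum, genus, species). Hits above the
E-value cutoff (default $10^{-5}$) and hits to the host's own genus
(default *Euplotes*) are removed first; self-hits are excluded because any
well-assembled host gene would otherwise have a eukaryotic best hit by
construction, making the best-hit rule vacuous. Among retained hits the best
hit is the minimum E-value, with ties broken by maximal bitscore and then
lexicographic subject id — a total order, so the result cannot depend on
input row order. The screen passes when the best hit is prokaryotic
(Bacteria or Archaea) and the prokaryote fraction strictly exceeds 0.5:
exactly half is a fail, because the rule is a strict majority. "Hits" means
retained hit rows, counting each subject row once; the interface does not
distinguish HSPs from subjects, which is a property of the upstream search,
not of this package.

**Stage 2 — contamination filter.** A prokaryote-looking gene is kept only
if its contig shows a telomere or its model shows at least one intron
(either criterion suffices). Telomere detection scans both contig ends for
tandem copies of C₄A₄/G₄T₄ and their reverse complements. Two tunables
matter here:

* `telomere_window_bp` (default 50): a repeat run may start anywhere within
  the first/last 50 bp, because macronuclear telomere boundaries are ragged
  and assemblies often retain a few subtelomeric bases; allowing an offset
  also tolerates a partial leading repeat unit.
* `telomere_min_units` (default 2): one octamer (8 bp) can occur by chance
  (about $50 \times 4 \times 4^{-8}$ per end for the scanned motif set);
  requiring two tandem units (16 bp exact match) drives the false-positive
  rate per contig to roughly $10^{-7}$ while real telomeres carry many
  units.

The 3' end is scanned as the 5' end of the reverse complement, which makes
the detector exactly strand-symmetric.

**Stage 3 — phylogenetic validation.** Candidates with more than five
prokaryotic homologs and no eukaryotic homolog in the reference search are
accepted without a tree ("more than five" is a strict inequality: five is
not enough). Candidates with homologs in both domains need a gene tree. The
placement rule — "the query clusters in a prokaryotic clade that has a
eukaryotic outgroup" — is operationalized on the unrooted topology, since
maximum-likelihood gene trees come unrooted and no rooting procedure is
assumed: the verdict is supported iff some bipartition splits the tips into
(A, B) with A containing every query tip, A minus the queries non-empty and
entirely prokaryotic, and at least one eukaryote in B. Requiring
A∖QUERY ≠ ∅ means a query-only clade sister to eukaryotes is not "in the
prokaryotic clade"; allowing multiple query tips handles in-paralogs that
duplicated after the transfer. Because the rule is a function of the
bipartition set alone, it is invariant under rerooting and tip order; the
test suite verifies it against an independent split-enumeration oracle on
every unrooted topology up to 8 tips under every prokaryote/eukaryote
composition (class assignments beyond one canonical labelling per
composition are tip permutations of enumerated topologies, hence covered).
Branch supports are ignored: no support threshold is assumed, and collapsing
weak edges is left to the caller's tree preparation. Candidates with five or
fewer prokaryote-only homologs are left `UNSUPPORTED` and excluded rather
than guessed.

A gene's final status is `HGT` iff stage 1 and stage 2 both pass and the
verdict is `HGT_NO_TREE` or `HGT_TREE_SUPPORTED`.

## Downstream statistics

Transferred genes are compared with native genes (all genes passing the
contamination filter but not called transferred) on four axes: GC content of
the spliced CDS, CDS length, intron-containing proportion, and TPM
expression. Proportions use the uncorrected Pearson χ² on the 2×2 table —
the continuity-corrected default of `chisq.test` is deliberately switched
off, and the choice is exposed in `chi_square_independence()`. Continuous
comparisons use the two-sided Wilcoxon rank-sum test; `exact` mode uses the
closed-form null distribution when the pooled data are tie-free and full
enumeration over group assignments of the pooled midranks otherwise (the
exact two-sided p is twice the smaller tail, capped at 1), while `auto`
falls back to the normal approximation with tie and continuity corrections
when min(n, m) > 8 or ties are present. The GC comparison has no named test
upstream of this package; it is implemented as a Wilcoxon rank-sum for
consistency with the other continuous comparisons.

Enrichment uses the upper-tail hypergeometric test per term with
Benjamini–Hochberg adjustment across all tested terms. The universe defaults
to all analysed host genes — the background is configurable because the
choice (all genes vs all annotated genes) is a genuine free parameter of any
enrichment analysis.

ORFs are translated under the Euplotid nuclear genetic code (NCBI table 10,
UGA = Cys, stops UAA/UAG only) by default. ORF spans are stop-exclusive, so
a protein is always exactly length/3 residues and any in-frame stop is an
error; 1,209 nt and 1,260 nt reading frames therefore yield 403 and 420
residues.

Family clustering across species is a deliberate methodological
substitution, not a reproduction of a full orthology inference tool:
families are connected components, under single linkage, of the
bidirectional-best-hit graph, with an edge kept when the bitscore reaches
`link_threshold` (default 0.5) of the smaller self-score. This keeps the
stage deterministic, dependency-free and exhaustively testable (components
are checked against a naive transitive-closure oracle). Donor phylum names
are taken verbatim from the hit table — no synonym resolution — and
endosymbiont-derived flags use case-insensitive genus equality after
stripping a "Candidatus " prefix.

## What the simulator emulates — and what it does not

`simulate_dataset()` is first-class, tested code that generates the
statistical structure the analysis assumes: telomere-capped nanochromosomes
(2–4 repeat units per end) for native and transferred genes; 26 bp introns
starting GT and ending AG, present with equal probability (default 0.3) in
both host classes, emulating the ancient-acquisition scenario in which
transferred genes have acquired host-like structure; contaminant contigs
with neither telomeres nor introns; hit profiles whose retained rows realise
the configured prokaryote fractions exactly (default 0.8 for transfers, 0.2
for natives) plus rows that must be discarded (E-value failures, a
self-genus hit); homolog counts that route half of the transfers through the
no-tree shortcut and half through the tree test; random binary gene trees
with the query planted inside (or, for negative controls, outside) the
prokaryotic clade; negative-binomial expression (dispersion 0.3, a typical
over-dispersion for bulk counts) with the transferred-class mean scaled by
a multiplier (default 0.3, i.e. transfers expressed lower; 1 gives the
null); equal GC (0.35, a realistic AT-rich ciliate value) in both host
classes; a planted enriched term; and a family benchmark with core families
present in all species. Every generated dataset is self-validated against
the class definitions before being returned, and output is byte-identical
under a fixed seed.

The simulator deliberately does *not* model sequence-level homology (hit
tables and trees are drawn directly, because the analysis consumes those
layers), codon usage, read-level expression noise, assembly artefacts such
as chimeric contigs, or borderline hit profiles near the 50% boundary.
Passing the planted-truth benchmark therefore shows that the decision rules
compose correctly and separate cleanly separable classes — it does not show
how the pipeline degrades on real data whose evidence is marginal; rule
boundaries are instead pinned by direct tests at the 50% and
five-homolog edges.

## Numerical choices and degenerate inputs

* Best-hit ties: E-value, then bitscore, then subject id (deterministic).
* Empty retained hit set: screen fails with the fraction reported as 0.
* Strict inequalities at both published boundaries (fraction > 0.5;
  prokaryotic homologs > 5).
* Exact Wilcoxon enumeration is capped at $3 \times 10^6$ subsets; beyond
  that, exact mode is an error rather than a silent approximation.
* χ² requires positive margins; a zero margin is an error, not NaN.
* TPM requires a positive rate sum; all-zero counts are an error.
* Viral or unclassified superkingdoms are parse errors: the decision rules
  are a strict prokaryote/eukaryote dichotomy, and silently binning a virus
  on either side would change hit fractions. How hits lacking taxonomy were
  treated upstream is unknowable here, so they are rejected loudly.
* Trees: unlabeled or unclassified tips are errors; the placement test
  refuses trees missing any of the three classes, naming the missing one.

## Test problem sizes

The shipped suite exercises the pipeline end-to-end on a simulated genome of
200 native, 20 transferred and 10 contaminant genes (seed 1), checks the
placement test against the enumeration oracle on all unrooted topologies of
4–8 tips, verifies the exact statistics against brute-force enumeration
(rank-sum up to 8 per group, hypergeometric up to a universe of 12), and
calibrates the four feature tests under the null (multiplier 1, identical
class distributions, 60 genes per class) over 200 seeded replicates,
requiring each rejection rate at α = 0.05 to fall inside the exact binomial
99% interval. These sizes were chosen as the smallest that make every rule
path observable.

## Known limitations

* The screen is taxonomy-driven: transfers from taxa misannotated in the
  hit table, or genes whose best hit is eukaryotic due to database bias,
  are invisible to it. Parametric signals (codon usage, k-mer composition)
  are out of scope.
* The placement test is purely topological; it ignores branch lengths and
  support values, and a poorly inferred gene tree will mislead it.
* BBH single-linkage families can chain distinct families through a shared
  intermediate at permissive thresholds; the threshold is exposed for this
  reason.
* Telomere detection assumes the C₄A₄/G₄T₄ repeat family; other telomere
  chemistries require supplying different motifs via `screen_config()`.
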