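---
title: "GO slim composition of gene sets: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GO slim composition of gene sets: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goslimr)
```

## The problem

Most genomes are functionally annotated by transfer: a query sequence is
assumed to share function with its closest well-annotated homolog. For
characterizing a whole gene set — a transcriptome, the paralogs retained
after a genome duplication, a tissue-specific expression cluster — the
full Gene Ontology is too granular, and the useful summary is the set's
composition over GO *slims*: a small, flat, non-overlapping panel of
high-level categories. `goslimr` implements the transfer-and-summarize
workflow end to end, with the statistics needed to compare compositions
between gene sets.

The pipeline is deliberately decomposed so that the expensive step runs
once: the similarity search produces a 12-column tabular file, and all
filtering, ranking, tabulation, merging, and testing operate on that file
and can be re-run cheaply under different parameters.

## Model and procedure

### Search stage

Queries are nucleotide coding sequences; the reference is a protein
database, so the search is translated (`blastx`-style). Defaults are
lenient on purpose — `num_threads = 1`, `max_target_seqs = 50`,
`evalue_threshold = 0.001` — because stringency belongs to the
re-runnable best-hit stage, not the search. DIAMOND is supported as a
faster, somewhat less sensitive alternative and is run in its default
sensitivity mode (no evidence favored any particular preset, and the
default is the reproducible choice). Nothing downstream depends on which
program produced the file; any `-outfmt 6`-shaped result is accepted, and
the test suite never invokes a real search program (a stub executable
stands in).

### Filtering and best-hit semantics

A hit survives filtering iff

* `evalue <= max_evalue` (default `1e-5`): the filter *removes
  strictly-greater* E-values, so a hit exactly at the cutoff survives;
* `length >= min_alignment_length`, `pident >= min_percent_identity`,
  `bitscore >= min_bitscore` (defaults 0): minima pass at-or-above.

The boundary conventions are stated explicitly because grid-style
stringency sweeps place hits exactly at cutoffs; the suite plants such
hits and asserts the counts. No universal thresholds exist across gene
families and divergence depths, which is why the three minima default to
zero and the sweep helper (`stringency_sweep()`, with `stringency_presets()`
covering E-value 1e-5…1e-20, length 30…150, identity 10…40, bitscore
33…75 and the four combined corner presets) exists at all.

One hit per query is then retained: the minimum E-value (default) or the
maximum of bitscore, alignment length, or percent identity. Ties are
broken by higher bitscore, then by earlier input position. The tie-break
chain is a package convention — the underlying tools do not define one —
chosen so results are deterministic and the final fallback matches the
search tool's own output ordering. Multiple HSP rows for one
query–subject pair are treated as independent candidate hits; merging
HSPs is out of scope.

### Annotation transfer and counting

A slim mapping associates reference identifiers with categories at one of
two granularities. Gene-model identifiers carry an isoform suffix
(`AT1G01010.1`); stripping exactly one trailing `.digits` group (the
pattern is configurable per reference) yields the locus. Locus-level
lookup can only gain matches relative to gene level when the locus
mapping is the gene mapping with keys collapsed, and the suite asserts
that monotonicity. Queries whose winning subject is absent from the
mapping are *kept* with an empty category set: the fraction annotated is
a first-class diagnostic (it is how one notices an inappropriate
reference database), so unmappable queries must stay in the denominator.

Counting unit: each query contributes one count to each *distinct*
category in its set, so a gene with three slims adds three counts.
Frequencies divide by the total number of (query, category) pairs, which
forces every frequency table to sum to 1 — the normalization pie and
bubble plots need. The alternative denominator (number of annotated
queries) would make "frequencies" sum to more than 1 whenever genes carry
multiple slims; we document our choice as a package convention rather
than claim it is the only reading.

Four tables are emitted per gene set — (gene, locus) × (raw, frequency) —
plus a coverage summary (`n_input`, `n_with_hit`, `n_annotated`,
proportion annotated) and a JSON run log with all parameters and stage
counts.

### Merging and visualization

`merge_tables()` outer-merges tables sharing level and kind: categories
are the sorted union, missing cells are zero, column sums are conserved.
The figure families are per-sample pie charts, a grouped bar plot,
heatmaps, and a bubble graph whose marker area is the cell's share of its
column total. Heatmaps come in raw and `log10(x + 1)` variants: a few
categories (plastid-related ones in plant transcriptomes, famously) can
dominate the counts and flatten a linear color scale. The log transform
applies to *counts*, not frequencies — frequencies are already
normalized, and the +1 pseudocount keeps zeros at zero. Tests assert on
the data handed to the plotting layer (wedge fractions, matrix cells,
bubble proportions), never on pixels, so renderer upgrades cannot break
them.

### Enrichment

For focal vs reference gene sets the raw-count vectors form a 2 × C
table. Pearson's χ² without continuity correction is computed from the
textbook quantities (`E = row·col/N`, `df = C − 1` for two rows), and each
category is called from the focal cell's residual with threshold 2:
`over` iff residual > 2, `under` iff residual < −2, `ns` otherwise. Both
inequalities are strict — a residual of exactly 2 is `ns`. The default
residual is the raw Pearson residual `(O − E)/√E`, the convention of the
duplicate-gene-retention literature that the ±2 rule comes from; the
standardized (adjusted) residual `(O − E)/√(E(1 − row/N)(1 − col/N))` is
available via `type = "adjusted"` for users who prefer an approximately
N(0,1) scale. No multiple-testing correction is applied across
categories, matching field practice for this descriptive use; the
documentation flags it, and users testing many comparisons should adjust
externally. Categories with zero column totals make expected counts
degenerate: they are an explicit error unless `drop_empty = TRUE`,
because silently dropping data is worse for reproducibility than asking.

## The synthetic world

`generate_fixture()` creates a FASTA, a hits file, and gene/locus
mappings with *planted* truth computed during construction, not by the
pipeline: the unique minimum-E-value winner per query, the pass/fail
pattern of every hit, the four summary tables, and the coverage. Defaults
(chosen once): 1–5 hits per query with distinct E-values from a grid
1e-5…1e-40 (all at or below the default cutoff, so default filtering is
lossless and every query retains a winner), two isoforms per reference
locus, 1–3 categories per mapped gene model from a 36-term
plant-slim-style vocabulary, 80% of winners mappable (the acceptance run
uses 200 queries at 40%, giving coverage exactly 0.40). `inject_ties`
duplicates winning E-values with strictly lower bitscores to exercise the
tie-break chain; `extra_locus_only` plants loci present only in the
locus mapping so gene and locus tables diverge by construction.
Generation is seed-deterministic (byte-identical files across runs) and
restores the caller's RNG state.

What a green suite establishes: exact agreement with brute-force oracles
for ranking, merging, and χ²; exact boundary semantics; byte-identical
I/O round-trips; end-to-end reproduction of planted truth. What it does
not establish: anything about real sequence evolution — fixture sequences
are random nucleotides, E-values are drawn from a grid rather than an
alignment model, and no claim about annotation *accuracy* on biological
data follows. Coverage percentages on real transcriptomes depend on the
reference database and divergence, and must be assessed per study.

## Numerical and format choices

* Doubles (E-values, bitscores, frequencies) are serialized as `%.17g`,
  which round-trips exactly; write→read→write is byte-identical and the
  suite asserts it for every format.
* Tabular-hit parsing reports the offending line number for wrong column
  counts and non-numeric fields; mapping readers do the same.
* The canonical mapping dialect is a two-column TSV; the TAIR-style
  dialect takes configurable key/term column indices (that file layout is
  versioned) and treats `!` lines as comments.
* Empty tables, zero-annotation gene sets, and single-table merges are
  valid and tested, not errors.

## Known limitations

* No GO aspect (BP/MF/CC) stratification: tabulation is category-flat,
  as in the figures this package emulates.
* No top-k or reciprocal-best-hit transfer; exactly one best hit per
  query.
* The search driver shells out; database construction
  (`makeblastdb`/`diamond makedb`) is a documented manual step.
* Enrichment offers χ² residual calls only — no exact tests, no FDR
  machinery; downstream statistics are intentionally left to other tools.
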