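# goslimr

Functional annotation of a gene set is usually transferred, not measured:
sequences are searched against a well-annotated reference (e.g.
*Arabidopsis thaliana* gene models), and the Gene Ontology terms of the
best-matching reference genes are carried over. For many questions the raw
term lists are too fine-grained, and what is wanted is the *composition* of
a gene set over a small, non-overlapping panel of high-level categories —
GO slims. `goslimr` is an R package for exactly that workflow, aimed at
plant (and other non-model) transcriptomics: from a nucleotide FASTA of
coding sequences plus a 12-column tabular similarity-search result, it
produces per-gene-set GO slim summary tables, merged multi-set tables,
publication-style figures, and over/under-representation calls between
gene sets.

## The method in brief

1. **Search (optional).** A translated search of nucleotide queries
   against a reference protein database (`blastx` or `diamond blastx`)
   with lenient defaults (`-num_threads 1 -max_target_seqs 50 -evalue
   0.001`). Any tool producing BLAST `-outfmt 6` output can be used
   instead; the whole stage is bypassable with a precomputed file.
2. **Best hits.** Hits are filtered — a hit survives iff
   `E ≤ E_max` (default `1e-5`; strictly-greater E-values are removed) and
   `length ≥ L_min`, `pident ≥ P_min`, `bitscore ≥ B_min` (defaults 0) —
   then exactly one hit per query is kept, optimizing a chosen metric
   (lowest E-value by default; alternatively highest bitscore, longest
   alignment, or highest percent identity), with ties broken by higher
   bitscore and then input order.
3. **Slim tables.** Each winning subject id is looked up in a GO slim
   mapping at gene-model level (id verbatim) and locus level (isoform
   suffix stripped: `AT1G01010.1 → AT1G01010`). Four tables result per
   gene set: raw counts and frequencies at each level. One query
   annotated to *k* slims contributes *k* counts, so frequencies (counts
   divided by total annotation pairs) sum to 1. Annotation coverage
   (fraction of input sequences with ≥ 1 slim) is reported alongside.
4. **Merge and visualize.** Tables from several gene sets are
   outer-merged (union of categories, zero-filled) and rendered as pie
   charts, bar plots, raw and `log10(x+1)` heatmaps, and bubble graphs
   whose marker area is each category's share of its gene set's
   annotations.
5. **Enrichment.** For a focal vs a reference gene set, a 2 × C
   contingency table is tested with Pearson's χ²
   (`E = row·col/N`, `X² = Σ(O−E)²/E`, `df = C−1`), and each category is
   called from the focal-cell Pearson residual `(O−E)/√E`: `over` if
   residual > 2, `under` if < −2, `ns` otherwise (strict inequalities, no
   multiplicity correction).

## Worked example

```r
library(goslimr)
we <- worked_example()                 # three small overlapping gene sets

merge_tables(we$freq)$matrix |> round(3)
#>                    fern_a fern_b fern_c
#> binding             0.421  0.243  0.304
#> cell cycle          0.088  0.000  0.065
#> metabolic process   0.070  0.324  0.283
#> nucleotide binding  0.000  0.162  0.000
#> photosynthesis      0.000  0.000  0.217
#> ribosome            0.281  0.122  0.000
#> transport           0.140  0.149  0.130

ct  <- build_contingency(we$focal, we$reference, drop_empty = TRUE)
res <- residual_calls(ct)              # fern_a vs fern_b
res
#> slim_enrichment: chi2 = 164.625, df = 5, p = 1.02e-33 (pearson residuals, |r| > 2)
#>   3 over-represented, 2 under-represented, 1 ns
res$table[, c("category", "residual", "call")]
#>             category   residual  call
#> 1            binding  2.9951439  over
#> 2         cell cycle  4.2815441  over
#> 3  metabolic process -5.2420938 under
#> 4 nucleotide binding -5.1085337 under
#> 5           ribosome  3.4730008  over
#> 6          transport -0.2075297    ns
```

The merged matrix says, e.g., that 42.1% of `fern_a`'s annotations fall in
`binding`; the enrichment table says `ribosome` is over-represented in
`fern_a` relative to `fern_b` (residual 3.47 > 2) while `metabolic
process` is under-represented (−5.24 < −2) and `transport` shows no
evidence of difference.

## Command line

The installed `exec/goslimr` script exposes the stages as subcommands:

```sh
goslimr run --fasta queries.fasta --hits hits.tsv \
        --mapping-gene mapping_gene.tsv --outdir out           # full pipeline
goslimr parse-best-hits --evalue 1e-20 hits.tsv                # refilter, no re-search
goslimr merge -m both set1_gene_freq.tsv set2_gene_freq.tsv    # table + figures
goslimr enrich --focal paralogs_gene_raw.tsv --reference all_gene_raw.tsv
goslimr simulate --seed 7 --out-dir fixture                    # synthetic data
```

Multi-gene-set batching is a shell loop over `run`; every run writes a
JSON run log with parameters and stage counts for exact replication.

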