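# Annotation transfer: map each query's best hit to GO slim categories
# at gene-model and locus granularity and tabulate counts, frequencies,
# and annotation coverage.

#' Collapse a gene-model identifier to its locus identifier
#'
#' TAIR-style gene models carry a trailing isoform suffix
#' (`AT1G01010.1`) that collapses to the locus (`AT1G01010`); Phytozome
#' identifiers follow the same convention (`Ceric.1Z000100.1`). Exactly
#' one trailing suffix group is removed if present, so the operation is
#' idempotent on already-collapsed ids. The suffix pattern is
#' configurable because the convention varies across references.
#'
#' @param subject_id Character vector of subject identifiers.
#' @param suffix_pattern Regular expression for the isoform suffix;
#'   default: one trailing dot-digits group.
#' @return The identifiers with the suffix removed where present.
#' @export
to_locus_id <- function(subject_id, suffix_pattern = "\\.[0-9]+$") {
  sub(suffix_pattern, "", subject_id)
}

#' Transfer GO slim categories to queries via their best hits
#'
#' At `level = "gene"` the lookup key is the winning subject id verbatim;
#' at `level = "locus"` it is [to_locus_id()] of the subject id. Queries
#' whose key is absent from the mapping receive an empty category set --
#' they stay in the result so coverage statistics can count them as
#' unannotated rather than dropping them.
#'
#' @param best A `best_hits` table (see [select_best_hits()]).
#' @param mapping A `slim_mapping` keyed at the chosen level.
#' @param level `"gene"` or `"locus"`.
#' @param suffix_pattern Passed to [to_locus_id()] for locus level.
#' @return Named list, query id -> character vector of categories
#'   (possibly empty), one element per query in `best`.
#' @export
annotate_queries <- function(best, mapping, level = c("gene", "locus"),
                             suffix_pattern = "\\.[0-9]+$") {
  level <- match.arg(level)
  stopifnot(inherits(mapping, "slim_mapping"))
  if (length(mapping$entries) == 0) {
    stop("mapping has no entries", call. = FALSE)
  }
  keys <- if (level == "gene") best$sseqid else {
    to_locus_id(best$sseqid, suffix_pattern)
  }
  ann <- lapply(keys, function(k) {
    hit <- mapping$entries[[k]]
    if (is.null(hit)) character(0) else hit
  })
  stats::setNames(ann, best$qseqid)
}

#' Tabulate GO slim category counts
#'
#' Each query contributes one count to each distinct category in its
#' set: a gene annotated to three slims increments three categories.
#' With this counting unit the raw table total equals the number of
#' (query, category) annotation pairs and the derived frequencies sum
#' to 1 -- the normalization used by pie and bubble plots.
#'
#' @param annotations Named list, query -> character vector of
#'   categories, as returned by [annotate_queries()].
#' @return Named integer vector, category -> count, sorted
#'   lexicographically by category.
#' @export
count_slims <- function(annotations) {
  pairs <- unlist(lapply(annotations, unique), use.names = FALSE)
  if (length(pairs) == 0) {
    return(stats::setNames(integer(0), character(0)))
  }
  tab <- table(pairs)
  counts <- stats::setNames(as.integer(tab), names(tab))
  counts[order(names(counts))]
}

#' Convert raw category counts to frequencies
#'
#' @param raw Named numeric vector of non-negative counts.
#' @return Named numeric vector summing to 1 (empty input stays empty).
#' @export
to_frequencies <- function(raw) {
  if (length(raw) == 0) return(stats::setNames(numeric(0), character(0)))
  total <- sum(raw)
  if (total == 0) return(stats::setNames(numeric(0), character(0)))
  raw / total
}

#' Build the four per-gene-set summary tables
#'
#' Produces (gene, raw), (gene, frequency), (locus, raw),
#' (locus, frequency) tables with coverage metadata. The gene-level and
#' locus-level mappings are independent inputs because reference
#' distributions key their GO slim files at either granularity; if
#' `mapping_locus` is omitted it is derived from `mapping_gene` by
#' collapsing keys with [to_locus_id()].
#'
#' @param best A `best_hits` table.
#' @param mapping_gene `slim_mapping` keyed by gene-model id.
#' @param mapping_locus `slim_mapping` keyed by locus id, or `NULL`.
#' @param n_input Number of sequences in the input gene set (>= number
#'   of queries in `best`).
#' @param label Gene-set name stamped on the tables.
#' @param suffix_pattern Isoform-suffix pattern for [to_locus_id()].
#' @return Named list of four `slim_table`s: `gene_raw`, `gene_freq`,
#'   `locus_raw`, `locus_freq`.
#' @export
make_all_tables <- function(best, mapping_gene, mapping_locus = NULL,
                            n_input, label = "geneset",
                            suffix_pattern = "\\.[0-9]+$") {
  n_with_hit <- nrow(best)
  if (n_input < n_with_hit) {
    stop("n_input must be >= number of queries with a best hit",
         call. = FALSE)
  }
  if (is.null(mapping_locus)) {
    mapping_locus <- collapse_mapping_to_locus(mapping_gene, suffix_pattern)
  }
  one_level <- function(mapping, level) {
    ann <- annotate_queries(best, mapping, level = level,
                            suffix_pattern = suffix_pattern)
    raw <- count_slims(ann)
    n_annotated <- sum(lengths(ann) > 0)
    list(
      raw = slim_table(raw, label = label, level = level, kind = "raw",
                       n_input = n_input, n_with_hit = n_with_hit,
                       n_annotated = n_annotated),
      freq = slim_table(to_frequencies(raw), label = label, level = level,
                        kind = "frequency", n_input = n_input,
                        n_with_hit = n_with_hit, n_annotated = n_annotated)
    )
  }
  gene <- one_level(mapping_gene, "gene")
  locus <- one_level(mapping_locus, "locus")
  list(gene_raw = gene$raw, gene_freq = gene$freq,
       locus_raw = locus$raw, locus_freq = locus$freq)
}

#' Collapse a gene-model-keyed mapping to locus keys
#'
#' Locus entries are the union of the categories of the locus's gene
#' models, so collapsing can only add lookup opportunities, never remove
#' them.
#'
#' @param mapping `slim_mapping` keyed by gene-model id.
#' @param suffix_pattern Isoform-suffix pattern for [to_locus_id()].
#' @return `slim_mapping` keyed by locus id.
#' @export
collapse_mapping_to_locus <- function(mapping,
                                      suffix_pattern = "\\.[0-9]+$") {
  stopifnot(inherits(mapping, "slim_mapping"))
  keys <- to_locus_id(names(mapping$entries), suffix_pattern)
  cats <- mapping$entries
  entries <- lapply(split(cats, keys), function(x) {
    sort(unique(unlist(x, use.names = FALSE)))
  })
  entries <- entries[order(names(entries))]
  structure(list(entries = entries, dialect = mapping$dialect,
                 excluded_categories = mapping$excluded_categories),
            class = "slim_mapping")
}

#' Proportion of input sequences annotated to at least one slim
#'
#' The key coverage diagnostic of the pipeline: how much of the input
#' gene set received any functional label at all.
#'
#' @param table A `slim_table` with populated coverage metadata.
#' @return `n_annotated / n_input`.
#' @export
annotation_coverage <- function(table) {
  stopifnot(inherits(table, "slim_table"))
  if (is.na(table$n_input) || table$n_input <= 0) {
    stop("annotation_coverage requires n_input > 0", call. = FALSE)
  }
  table$n_annotated / table$n_input
}

#' Write the coverage summary for a set of tables
#'
#' One row per (level) with label, input/hit/annotated counts and the
#' annotated proportion.
#'
#' @param tables List of `slim_table`s (typically [make_all_tables()]
#'   output).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_coverage_summary <- function(tables, path) {
  raw <- Filter(function(t) t$kind == "raw", tables)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("label", "level", "n_input", "n_with_hit",
                     "n_annotated", "proportion_annotated"),
                   collapse = "\t"), con, sep = "\n")
  for (t in raw) {
    writeLines(paste(t$label, t$level, t$n_input, t$n_with_hit,
                     t$n_annotated,
                     .fmt_num(t$n_annotated / t$n_input), sep = "\t"),
               con, sep = "\n")
  }
  invisible(path)
}
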