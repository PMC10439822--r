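# End-to-end driver for one gene set: hits (external search or
# precomputed) -> filter -> best hit -> four summary tables -> coverage
# summary + machine-readable run log.

#' Run the full annotation pipeline for one gene set
#'
#' Reads the query FASTA (for the coverage denominator), obtains a
#' 12-column tabular hit set -- either from `hits` (precomputed) or by
#' invoking the external search in `search` -- filters it, selects one
#' best hit per query, transfers GO slim categories at gene and locus
#' level, and writes: the best-hit file, the four summary tables, a
#' coverage summary, and a JSON run log recording parameters and stage
#' counts (hits read, hits passing, queries with a best hit, queries
#' annotated) for exact replication.
#'
#' Because filtering is decoupled from searching, rerunning with
#' stricter criteria on the same `hits` file never re-executes the
#' search.
#'
#' @param fasta Path to the input nucleotide FASTA.
#' @param mapping_gene Path to the gene-level mapping file, or a
#'   `slim_mapping`.
#' @param mapping_locus Optional locus-level mapping (path or
#'   `slim_mapping`); derived from `mapping_gene` by locus collapse when
#'   absent.
#' @param hits Path to a precomputed tabular hits file, or `NULL` to run
#'   the external search.
#' @param search A [search_config()]; required when `hits` is `NULL`.
#' @param criteria A [filter_criteria()].
#' @param metric Ranking metric, one of [ranking_metrics()].
#' @param outdir Output directory.
#' @param label Gene-set label (defaults to the FASTA basename).
#' @param mapping_dialect,excluded_categories,key_col,term_col Passed to
#'   [read_slim_mapping()] when mappings are given as paths.
#' @param suffix_pattern Isoform-suffix pattern for locus collapsing.
#' @return Invisibly, a list with `tables` (the four `slim_table`s),
#'   `best` (the `best_hits` table), `files` (all output paths), and
#'   `counts` (the stage counts).
#' @export
run_pipeline <- function(fasta, mapping_gene, mapping_locus = NULL,
                         hits = NULL, search = NULL,
                         criteria = filter_criteria(),
                         metric = "evalue",
                         outdir = ".",
                         label = NULL,
                         mapping_dialect = "canonical",
                         excluded_categories = character(),
                         key_col = 1L, term_col = 2L,
                         suffix_pattern = "\\.[0-9]+$") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  queries <- read_fasta(fasta)
  if (is.null(label)) {
    label <- sub("\\.(fa|fasta|fna|fas)$", "", basename(fasta),
                 ignore.case = TRUE)
  }

  if (is.null(hits)) {
    if (is.null(search)) {
      stop("supply either a precomputed hits file (hits=) or a ",
           "search_config (search=)", call. = FALSE)
    }
    hits <- file.path(outdir, paste0(label, "_search.tsv"))
    run_search(fasta, search, hits)
  }
  hit_tab <- read_tabular_hits(hits)

  load_mapping <- function(x) {
    if (inherits(x, "slim_mapping")) return(x)
    read_slim_mapping(x, dialect = mapping_dialect,
                      excluded_categories = excluded_categories,
                      key_col = key_col, term_col = term_col)
  }
  mg <- load_mapping(mapping_gene)
  ml <- if (is.null(mapping_locus)) NULL else load_mapping(mapping_locus)

  unknown <- setdiff(unique(hit_tab$qseqid), queries$id)
  if (length(unknown) > 0) {
    warning(sprintf("%d hit query id(s) not present in the FASTA (e.g. %s)",
                    length(unknown), unknown[1]), call. = FALSE)
  }

  surviving <- filter_hits(hit_tab, criteria)
  best <- select_best_hits(surviving, metric = metric)
  tables <- make_all_tables(best, mg, ml, n_input = nrow(queries),
                            label = label, suffix_pattern = suffix_pattern)

  files <- list(best_hits = file.path(outdir, paste0(label, "_best_hits.tsv")))
  write_best_hits(best, files$best_hits)
  for (nm in names(tables)) {
    files[[nm]] <- file.path(outdir, slim_table_filename(tables[[nm]]))
    write_slim_table(tables[[nm]], files[[nm]])
  }
  files$coverage <- file.path(outdir, paste0(label, "_coverage.tsv"))
  write_coverage_summary(tables, files$coverage)

  counts <- list(n_input_sequences = nrow(queries),
                 n_hits_read = nrow(hit_tab),
                 n_hits_passing = nrow(surviving),
                 n_queries_with_best_hit = nrow(best),
                 n_annotated_gene = tables$gene_raw$n_annotated,
                 n_annotated_locus = tables$locus_raw$n_annotated)
  files$run_log <- file.path(outdir, paste0(label, "_run_log.json"))
  log <- list(
    label = label,
    inputs = list(fasta = fasta, hits = hits),
    parameters = list(
      max_evalue = criteria$max_evalue,
      min_alignment_length = criteria$min_alignment_length,
      min_percent_identity = criteria$min_percent_identity,
      min_bitscore = criteria$min_bitscore,
      ranking_metric = metric,
      suffix_pattern = suffix_pattern,
      mapping_dialect = mapping_dialect,
      excluded_categories = excluded_categories),
    stage_counts = counts)
  jsonlite::write_json(log, files$run_log, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)

  message(sprintf(
    "[%s] %d sequences; %d hits read, %d passing; %d best hits; %d/%d annotated (gene level)",
    label, counts$n_input_sequences, counts$n_hits_read,
    counts$n_hits_passing, counts$n_queries_with_best_hit,
    counts$n_annotated_gene, counts$n_input_sequences))

  invisible(list(tables = tables, best = best, files = files,
                 counts = counts))
}
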