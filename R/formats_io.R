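# On-disk formats: FASTA, 12-column tabular hits (BLAST outfmt 6),
# GO slim mapping dialects, and TSV summary tables.

#' Column names of the 12-column tabular hit format
#'
#' The standard BLAST `-outfmt 6` layout: query id, subject id, percent
#' identity, alignment length, mismatches, gap opens, query/subject
#' coordinates, E-value, bitscore.
#'
#' @return Character vector of length 12.
#' @export
hit_columns <- function() {
  c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
    "qstart", "qend", "sstart", "send", "evalue", "bitscore")
}

.hit_numeric_cols <- c("pident", "evalue", "bitscore")
.hit_integer_cols <- c("length", "mismatch", "gapopen",
                       "qstart", "qend", "sstart", "send")

#' Create an empty hit table
#'
#' @return A zero-row data frame with the outfmt-6 column layout.
#' @export
empty_hits <- function() {
  df <- data.frame(
    qseqid = character(), sseqid = character(),
    pident = numeric(), length = integer(), mismatch = integer(),
    gapopen = integer(), qstart = integer(), qend = integer(),
    sstart = integer(), send = integer(),
    evalue = numeric(), bitscore = numeric(),
    stringsAsFactors = FALSE
  )
  df
}

.validate_hits <- function(hits, where = "hits") {
  stopifnot(is.data.frame(hits))
  missing <- setdiff(hit_columns(), names(hits))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing columns: %s", where,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(hits) == 0) return(invisible(hits))
  if (any(hits$evalue < 0)) stop(where, ": negative E-value", call. = FALSE)
  if (any(hits$pident < 0 | hits$pident > 100)) {
    stop(where, ": percent identity outside [0, 100]", call. = FALSE)
  }
  if (any(hits$length < 1)) {
    stop(where, ": alignment length must be >= 1", call. = FALSE)
  }
  invisible(hits)
}

#' Read a nucleotide FASTA file of coding sequences
#'
#' Sequence ids are the first whitespace-delimited token of each header,
#' matching how similarity-search programs report query ids; the rest of
#' the header is kept as the description. Duplicate ids are an error
#' because downstream per-query bookkeeping assumes unique queries.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id`, `description`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("FASTA file is empty: ", path, call. = FALSE)
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("FASTA record with empty id in ", path, call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate sequence id(s) in %s: %s", path,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  seq_chr <- as.character(seqs)
  if (any(nchar(seq_chr) == 0)) {
    stop("empty sequence in ", path, call. = FALSE)
  }
  data.frame(id = ids, description = desc, sequence = unname(seq_chr),
             stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param records Data frame with columns `id`, `description`, `sequence`
#'   (as returned by [read_fasta()]).
#' @param path Output path.
#' @param width Line width for wrapping sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    header <- records$id[i]
    if (nzchar(records$description[i])) {
      header <- paste(header, records$description[i])
    }
    seq <- records$sequence[i]
    starts <- seq(1L, nchar(seq), by = width)
    lines <- substring(seq, starts, pmin(starts + width - 1L, nchar(seq)))
    writeLines(c(paste0(">", header), lines), con, sep = "\n")
  }
  invisible(path)
}

# %.17g round-trips any double through decimal text exactly, so
# write -> read -> write is byte-identical.
.fmt_num <- function(x) sprintf("%.17g", x)

#' Read a 12-column tabular similarity-search result
#'
#' Parses tab-delimited search output in the BLAST `-outfmt 6` layout
#' (also produced by DIAMOND and other tools). Row order is preserved:
#' best-hit tie-breaking falls back to input order, which mirrors the
#' search tool's own ranking.
#'
#' @param path Path to the tabular hits file.
#' @return Data frame with the columns of [hit_columns()], rows in file
#'   order. An empty file yields a zero-row table.
#' @export
read_tabular_hits <- function(path) {
  if (!file.exists(path)) stop("hits file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- nzchar(lines)
  if (!any(keep)) return(empty_hits())
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != 12L)) {
    bad <- which(ncols != 12L)[1]
    stop(sprintf("%s line %d: expected 12 tab-delimited columns, found %d",
                 path, lineno[bad], ncols[bad]), call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  colnames(m) <- hit_columns()
  df <- data.frame(qseqid = m[, "qseqid"], sseqid = m[, "sseqid"],
                   stringsAsFactors = FALSE)
  for (col in c(.hit_numeric_cols, .hit_integer_cols)) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf("%s line %d: non-numeric value '%s' in column %s",
                   path, lineno[bad], m[bad, col], col), call. = FALSE)
    }
    if (col %in% .hit_integer_cols) v <- as.integer(round(v))
    df[[col]] <- v
  }
  df <- df[, hit_columns()]
  .validate_hits(df, where = path)
  df
}

#' Write hits in the 12-column tabular format
#'
#' E-values and bitscores are serialized with enough digits that
#' `read_tabular_hits(write_tabular_hits(x))` reproduces `x` exactly and
#' re-serialization is byte-identical.
#'
#' @param hits Hit table (see [hit_columns()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tabular_hits <- function(hits, path) {
  .validate_hits(hits)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(hits) > 0) {
    lines <- paste(hits$qseqid, hits$sseqid, .fmt_num(hits$pident),
                   hits$length, hits$mismatch, hits$gapopen,
                   hits$qstart, hits$qend, hits$sstart, hits$send,
                   .fmt_num(hits$evalue), .fmt_num(hits$bitscore),
                   sep = "\t")
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Read a GO slim mapping file
#'
#' A mapping associates each reference subject identifier (gene model or
#' locus) with one or more GO slim categories. Two dialects are
#' supported:
#' \describe{
#'   \item{canonical}{two-column TSV, one `(subject_key, slim_category)`
#'     pair per line; repeated keys accumulate into a set.}
#'   \item{tair}{multi-column TSV in the style of the TAIR GO-slim
#'     distribution; lines starting with `!` are comments and the key and
#'     slim-term columns are configurable because that layout is
#'     versioned.}
#' }
#' Pairs whose category is listed in `excluded_categories` are dropped
#' (e.g. excluding flower/fruit terms when annotating seed-free plants);
#' keys left with no category are absent from the result.
#'
#' @param path Path to the mapping file.
#' @param dialect `"canonical"` or `"tair"`.
#' @param excluded_categories Character vector of category labels to drop.
#' @param key_col,term_col Column indices of the subject key and the slim
#'   term (tair dialect only).
#' @return An object of class `slim_mapping`: a list with `entries`
#'   (named list of character vectors), `dialect`, and
#'   `excluded_categories`.
#' @export
read_slim_mapping <- function(path, dialect = c("canonical", "tair"),
                              excluded_categories = character(),
                              key_col = 1L, term_col = 2L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("mapping file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- nzchar(lines)
  if (dialect == "tair") keep <- keep & !startsWith(lines, "!")
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  min_cols <- if (dialect == "canonical") 2L else max(key_col, term_col)
  ncols <- lengths(fields)
  if (dialect == "canonical" && any(ncols != 2L)) {
    bad <- which(ncols != 2L)[1]
    stop(sprintf("%s line %d: expected 2 tab-delimited columns, found %d",
                 path, lineno[bad], ncols[bad]), call. = FALSE)
  }
  if (any(ncols < min_cols)) {
    bad <- which(ncols < min_cols)[1]
    stop(sprintf("%s line %d: expected at least %d columns, found %d",
                 path, lineno[bad], min_cols, ncols[bad]), call. = FALSE)
  }
  if (dialect == "canonical") {
    keys <- vapply(fields, `[[`, "", 1L)
    terms <- vapply(fields, `[[`, "", 2L)
  } else {
    keys <- vapply(fields, `[[`, "", key_col)
    terms <- vapply(fields, `[[`, "", term_col)
  }
  bad <- which(keys == "" | terms == "")
  if (length(bad) > 0) {
    stop(sprintf("%s line %d: empty key or category", path, lineno[bad[1]]),
         call. = FALSE)
  }
  drop <- terms %in% excluded_categories
  keys <- keys[!drop]
  terms <- terms[!drop]
  entries <- lapply(split(terms, keys), function(x) sort(unique(x)))
  entries <- entries[order(names(entries))]
  structure(list(entries = entries, dialect = dialect,
                 excluded_categories = excluded_categories),
            class = "slim_mapping")
}

#' Build a slim mapping from key/category vectors
#'
#' In-memory constructor used by the fixture generator and tests; the
#' result is identical to reading the equivalent canonical file.
#'
#' @param keys Character vector of subject keys.
#' @param categories Character vector of category labels, parallel to
#'   `keys`.
#' @return A `slim_mapping`.
#' @export
slim_mapping <- function(keys, categories) {
  stopifnot(length(keys) == length(categories),
            all(nzchar(keys)), all(nzchar(categories)))
  entries <- lapply(split(categories, keys), function(x) sort(unique(x)))
  entries <- entries[order(names(entries))]
  structure(list(entries = entries, dialect = "canonical",
                 excluded_categories = character()),
            class = "slim_mapping")
}

#' Write a slim mapping in the canonical two-column dialect
#'
#' @param mapping A `slim_mapping`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_slim_mapping <- function(mapping, path) {
  stopifnot(inherits(mapping, "slim_mapping"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  keys <- names(mapping$entries)
  if (length(keys) > 0) {
    lines <- unlist(lapply(keys, function(k) {
      paste(k, mapping$entries[[k]], sep = "\t")
    }))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' @export
print.slim_mapping <- function(x, ...) {
  cat(sprintf("slim_mapping: %d subject keys, %d categories (%s dialect)\n",
              length(x$entries),
              length(unique(unlist(x$entries))), x$dialect))
  invisible(x)
}

#' Construct a GO slim count table
#'
#' One gene set's per-category summary, tagged with the identifier
#' granularity (`gene` or `locus`) and the value kind (`raw` counts or
#' `frequency`), plus annotation-coverage metadata.
#'
#' @param values Named numeric vector, category label -> value. Stored
#'   sorted lexicographically by category.
#' @param label Gene-set name.
#' @param level `"gene"` or `"locus"`.
#' @param kind `"raw"` or `"frequency"`.
#' @param n_input Number of input sequences in the gene set.
#' @param n_with_hit Number of queries with a surviving best hit.
#' @param n_annotated Number of queries with at least one slim category.
#' @return An object of class `slim_table`.
#' @export
slim_table <- function(values, label, level = c("gene", "locus"),
                       kind = c("raw", "frequency"),
                       n_input = NA_integer_, n_with_hit = NA_integer_,
                       n_annotated = NA_integer_) {
  level <- match.arg(level)
  kind <- match.arg(kind)
  values <- unlist(values)
  if (length(values) > 0) {
    stopifnot(!is.null(names(values)), all(nzchar(names(values))))
    values <- values[order(names(values))]
    if (anyDuplicated(names(values))) {
      stop("duplicate category labels in slim table", call. = FALSE)
    }
    if (any(values < 0)) stop("negative values in slim table", call. = FALSE)
    if (kind == "raw" && any(values != round(values))) {
      stop("raw slim table values must be integers", call. = FALSE)
    }
  } else {
    values <- stats::setNames(numeric(0), character(0))
  }
  structure(list(values = values, label = label, level = level, kind = kind,
                 n_input = as.integer(n_input),
                 n_with_hit = as.integer(n_with_hit),
                 n_annotated = as.integer(n_annotated)),
            class = "slim_table")
}

#' @export
print.slim_table <- function(x, ...) {
  cat(sprintf("slim_table '%s' (%s level, %s): %d categories\n",
              x$label, x$level, x$kind, length(x$values)))
  if (!is.na(x$n_input)) {
    cat(sprintf("  coverage: %d input, %d with best hit, %d annotated\n",
                x$n_input, x$n_with_hit, x$n_annotated))
  }
  invisible(x)
}

# Infer (level, kind) from the conventional filename suffix
# <label>_{gene|locus}_{raw|freq}.tsv; returns NULL if it does not match.
.table_meta_from_filename <- function(path) {
  base <- sub("\\.tsv$", "", basename(path))
  m <- regmatches(base, regexec("_(gene|locus)_(raw|freq)$", base))[[1]]
  if (length(m) == 0) return(NULL)
  list(label = sub("_(gene|locus)_(raw|freq)$", "", base),
       level = m[2], kind = if (m[3] == "raw") "raw" else "frequency")
}

#' Read a GO slim summary table from TSV
#'
#' The format is a header row `GO_slim_category<TAB><label>` followed by
#' one row per category. Level and kind are inferred from the
#' conventional filename suffix `_{gene|locus}_{raw|freq}.tsv` unless
#' given explicitly.
#'
#' @param path Path to a TSV summary table.
#' @param level,kind Override the values inferred from the filename.
#' @param label Override the gene-set label (defaults to the header).
#' @return A `slim_table`. Coverage metadata is `NA` (it lives in the
#'   separate coverage summary file).
#' @export
read_slim_table <- function(path, level = NULL, kind = NULL, label = NULL) {
  if (!file.exists(path)) stop("table file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0 || !nzchar(lines[1])) {
    stop("missing header row in ", path, call. = FALSE)
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) != 2 || header[1] != "GO_slim_category") {
    stop(path, ": header must be 'GO_slim_category<TAB><label>'",
         call. = FALSE)
  }
  meta <- .table_meta_from_filename(path)
  if (is.null(level)) level <- meta$level
  if (is.null(kind)) kind <- meta$kind
  if (is.null(label)) label <- header[2]
  if (is.null(level) || is.null(kind)) {
    stop(path, ": cannot infer level/kind from filename; pass them explicitly",
         call. = FALSE)
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    return(slim_table(stats::setNames(numeric(0), character(0)),
                      label = label, level = level, kind = kind))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != 2L)) {
    bad <- which(ncols != 2L)[1]
    stop(sprintf("%s line %d: expected 2 columns", path, bad + 1L),
         call. = FALSE)
  }
  cats <- vapply(fields, `[[`, "", 1L)
  vals <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop(sprintf("%s line %d: non-numeric cell", path, bad + 1L),
         call. = FALSE)
  }
  slim_table(stats::setNames(vals, cats), label = label,
             level = level, kind = kind)
}

#' Write a GO slim summary table to TSV
#'
#' @param table A `slim_table`.
#' @param path Output path; by convention
#'   `<label>_{gene|locus}_{raw|freq}.tsv`.
#' @return `path`, invisibly.
#' @export
write_slim_table <- function(table, path) {
  stopifnot(inherits(table, "slim_table"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  vals <- if (table$kind == "raw") {
    sprintf("%d", as.integer(round(table$values)))
  } else {
    .fmt_num(table$values)
  }
  writeLines(c(paste("GO_slim_category", table$label, sep = "\t"),
               if (length(table$values) > 0)
                 paste(names(table$values), vals, sep = "\t")),
             con, sep = "\n")
  invisible(path)
}

#' Conventional filename for a slim summary table
#'
#' @param table A `slim_table`.
#' @return e.g. `"mysample_gene_raw.tsv"`.
#' @export
slim_table_filename <- function(table) {
  sprintf("%s_%s_%s.tsv", table$label, table$level,
          if (table$kind == "raw") "raw" else "freq")
}
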