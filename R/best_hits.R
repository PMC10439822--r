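# Threshold filtering of tabular hits and selection of one best hit per
# query under a configurable ranking metric.

#' Filtering thresholds for tabular hits
#'
#' The E-value filter removes hits whose E-value is strictly greater than
#' `max_evalue` (a hit at exactly the cutoff survives); the other three
#' metrics are minima and pass at-or-above. Defaults keep every hit with
#' E-value <= 1e-5 and leave the other thresholds at 0: no universal
#' cutoffs exist across gene families and divergence levels, so the
#' lenient defaults are meant to be tightened per study.
#'
#' @param max_evalue Maximum E-value retained (default `1e-5`).
#' @param min_alignment_length Minimum alignment length (residues).
#' @param min_percent_identity Minimum percent identity.
#' @param min_bitscore Minimum bitscore.
#' @return An object of class `filter_criteria`.
#' @export
filter_criteria <- function(max_evalue = 1e-5, min_alignment_length = 0,
                            min_percent_identity = 0, min_bitscore = 0) {
  stopifnot(max_evalue > 0, min_alignment_length >= 0,
            min_percent_identity >= 0, min_bitscore >= 0)
  structure(list(max_evalue = max_evalue,
                 min_alignment_length = min_alignment_length,
                 min_percent_identity = min_percent_identity,
                 min_bitscore = min_bitscore),
            class = "filter_criteria")
}

#' @export
print.filter_criteria <- function(x, ...) {
  cat(sprintf(
    "filter_criteria: evalue <= %g, length >= %g, pident >= %g, bitscore >= %g\n",
    x$max_evalue, x$min_alignment_length, x$min_percent_identity,
    x$min_bitscore))
  invisible(x)
}

#' The four supported ranking metrics
#'
#' @return `c("evalue", "bitscore", "length", "pident")`. Lower is better
#'   for `evalue`; higher is better for the rest.
#' @export
ranking_metrics <- function() c("evalue", "bitscore", "length", "pident")

#' Filter hits by threshold criteria
#'
#' A hit is retained iff `evalue <= max_evalue` and `length >=
#' min_alignment_length` and `pident >= min_percent_identity` and
#' `bitscore >= min_bitscore`. Output rows are an order-preserving
#' subsequence of the input.
#'
#' @param hits Hit table (see [hit_columns()]).
#' @param criteria A [filter_criteria()].
#' @return The surviving rows, in input order.
#' @export
filter_hits <- function(hits, criteria = filter_criteria()) {
  .validate_hits(hits)
  stopifnot(inherits(criteria, "filter_criteria"))
  keep <- hits$evalue <= criteria$max_evalue &
    hits$length >= criteria$min_alignment_length &
    hits$pident >= criteria$min_percent_identity &
    hits$bitscore >= criteria$min_bitscore
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select one best hit per query
#'
#' Per query the winner optimizes the ranking metric (minimum for
#' `evalue`, maximum otherwise). Ties are broken by higher bitscore, then
#' by earlier position in the input, so the result is deterministic; the
#' input-order fallback matches the search tool's own output ranking.
#' The input is assumed to be already filtered -- criteria are not
#' re-applied here.
#'
#' @param hits Filtered hit table.
#' @param metric One of [ranking_metrics()].
#' @return An object of class `best_hits`: a data frame with one winning
#'   row per query (in order of first appearance of each query), with the
#'   ranking metric and any filter provenance stored as attributes.
#' @export
select_best_hits <- function(hits, metric = c("evalue", "bitscore",
                                              "length", "pident")) {
  .validate_hits(hits)
  metric <- match.arg(metric)
  if (nrow(hits) == 0) {
    out <- empty_hits()
  } else {
    key <- switch(metric,
                  evalue = hits$evalue,
                  bitscore = -hits$bitscore,
                  length = -as.numeric(hits$length),
                  pident = -hits$pident)
    ord <- order(key, -hits$bitscore, seq_len(nrow(hits)))
    ranked <- hits[ord, , drop = FALSE]
    ranked <- ranked[!duplicated(ranked$qseqid), , drop = FALSE]
    # report winners in order of each query's first appearance in input
    first_seen <- match(ranked$qseqid, unique(hits$qseqid))
    out <- ranked[order(first_seen), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("best_hits", class(out)), metric = metric)
}

#' Write a best-hit table
#'
#' Tab-delimited with a header: query and subject first, then the four
#' ranking metrics for reference.
#'
#' @param best A `best_hits` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_best_hits <- function(best, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("query_id", "subject_id", "pident", "length",
                     "evalue", "bitscore"), collapse = "\t"), con, sep = "\n")
  if (nrow(best) > 0) {
    writeLines(paste(best$qseqid, best$sseqid, .fmt_num(best$pident),
                     best$length, .fmt_num(best$evalue),
                     .fmt_num(best$bitscore), sep = "\t"), con, sep = "\n")
  }
  invisible(path)
}

#' Count hits and queries surviving a grid of filter criteria
#'
#' Applies [filter_hits()] once per criteria set and tabulates how many
#' hits pass and how many queries retain at least one hit. Useful for
#' stringency sweeps: when the grid is nested by stringency the counts
#' are monotone non-increasing.
#'
#' @param hits Hit table.
#' @param grid Named list of [filter_criteria()]; names label the rows.
#' @return Data frame with columns `label`, `n_hits_passing`,
#'   `n_queries_with_hit`.
#' @export
stringency_sweep <- function(hits, grid) {
  if (!is.list(grid) || length(grid) == 0 ||
      !all(vapply(grid, inherits, TRUE, "filter_criteria"))) {
    stop("grid must be a non-empty list of filter_criteria", call. = FALSE)
  }
  labels <- names(grid)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- paste0("criteria_", seq_along(grid))
  }
  rows <- lapply(seq_along(grid), function(i) {
    surv <- filter_hits(hits, grid[[i]])
    data.frame(label = labels[i],
               n_hits_passing = nrow(surv),
               n_queries_with_hit = length(unique(surv$qseqid)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Named stringency-sweep presets
#'
#' The grids used for sensitivity analysis of the filtering stage:
#' single-metric sweeps over E-value (1e-5, 1e-10, 1e-15, 1e-20),
#' alignment length (30, 50, 100, 150), percent identity (10, 25, 33,
#' 40), and bitscore (33, 50, 60, 75), plus the four combined presets
#' from least stringent (1e-5, 30, 10, 33) to most stringent (1e-5, 150,
#' 40, 75).
#'
#' @param type Which grid to return.
#' @return Named list of [filter_criteria()], ordered least to most
#'   stringent.
#' @export
stringency_presets <- function(type = c("combined", "evalue", "length",
                                        "pident", "bitscore")) {
  type <- match.arg(type)
  ev <- c(1e-5, 1e-10, 1e-15, 1e-20)
  len <- c(30, 50, 100, 150)
  pid <- c(10, 25, 33, 40)
  bit <- c(33, 50, 60, 75)
  switch(type,
    evalue = stats::setNames(
      lapply(ev, function(e) filter_criteria(max_evalue = e)),
      sprintf("evalue_%g", ev)),
    length = stats::setNames(
      lapply(len, function(l) filter_criteria(min_alignment_length = l)),
      sprintf("length_%d", len)),
    pident = stats::setNames(
      lapply(pid, function(p) filter_criteria(min_percent_identity = p)),
      sprintf("pident_%d", pid)),
    bitscore = stats::setNames(
      lapply(bit, function(b) filter_criteria(min_bitscore = b)),
      sprintf("bitscore_%d", bit)),
    combined = stats::setNames(
      lapply(seq_len(4), function(i) {
        filter_criteria(max_evalue = 1e-5, min_alignment_length = len[i],
                        min_percent_identity = pid[i], min_bitscore = bit[i])
      }),
      c("least_stringent", "less_stringent", "more_stringent",
        "most_stringent"))
  )
}
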