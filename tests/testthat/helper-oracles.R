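# Independent oracles and small in-memory generators used across the
# suite. These deliberately re-derive expectations by brute force /
# direct construction, never by calling the code paths they check.

# Brute-force best-hit oracle: per query, scan every row, pick the
# optimum of the metric, break ties by max bitscore then earliest row.
oracle_best_hits <- function(hits, metric) {
  qs <- unique(hits$qseqid)
  idx <- vapply(qs, function(q) {
    rows <- which(hits$qseqid == q)
    val <- switch(metric,
                  evalue = hits$evalue[rows],
                  bitscore = hits$bitscore[rows],
                  length = as.numeric(hits$length[rows]),
                  pident = hits$pident[rows])
    best <- if (metric == "evalue") min(val) else max(val)
    cand <- rows[val == best]
    if (length(cand) > 1) {
      bb <- hits$bitscore[cand]
      cand <- cand[bb == max(bb)]
    }
    cand[1]
  }, 1L)
  out <- hits[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random in-memory hit table; ties injected on the ranking values with
# probability tie_prob by duplicating rows with a perturbed bitscore.
random_hits <- function(n_queries = 20, max_hits = 5, tie_prob = 0.3) {
  rows <- lapply(seq_len(n_queries), function(i) {
    k <- sample.int(max_hits, 1)
    df <- data.frame(
      qseqid = sprintf("q%03d", i),
      sseqid = sprintf("s%03d", sample.int(500, k)),
      pident = sample(seq(10, 100, by = 0.5), k, replace = TRUE),
      length = sample(30:400, k, replace = TRUE),
      mismatch = sample(0:50, k, replace = TRUE),
      gapopen = sample(0:5, k, replace = TRUE),
      qstart = 1L, qend = 300L, sstart = 1L, send = 100L,
      evalue = sample(10^-(2:40), k, replace = TRUE),
      bitscore = sample(seq(30, 500, by = 0.5), k, replace = TRUE),
      stringsAsFactors = FALSE)
    if (stats::runif(1) < tie_prob && k >= 1) {
      dup <- df[sample.int(k, 1), , drop = FALSE]
      dup$sseqid <- sprintf("s%03d", sample.int(500, 1))
      dup$bitscore <- dup$bitscore + sample(c(-5, 0, 5), 1)
      df <- rbind(df, dup)
    }
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Hit table planted on the stringency-sweep value grids: the full cross
# of values sitting exactly at and around every cutoff used by the
# single-metric and combined presets.
grid_planted_hits <- function() {
  ev <- c(1e-4, 2e-5, 1e-5, 5e-6, 2e-10, 1e-10, 5e-11, 2e-15, 1e-15,
          5e-16, 2e-20, 1e-20, 5e-21)
  len <- c(29L, 30L, 31L, 49L, 50L, 99L, 100L, 150L, 151L)
  pid <- c(9.9, 10, 10.1, 24.9, 25, 33, 39.9, 40, 41)
  bit <- c(32.9, 33, 33.1, 49, 50, 60, 74.9, 75, 76)
  g <- expand.grid(evalue = ev, length = len, pident = pid, bitscore = bit,
                   KEEP.OUT.ATTRS = FALSE)
  n <- nrow(g)
  data.frame(
    qseqid = sprintf("q%05d", seq_len(n)),
    sseqid = sprintf("s%05d", seq_len(n)),
    pident = g$pident, length = g$length,
    mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = 3L * g$length, sstart = 1L, send = g$length,
    evalue = g$evalue, bitscore = g$bitscore,
    stringsAsFactors = FALSE)
}

# Literal pass/fail of one hit table under one criteria set -- the
# planted truth for sweep counts (each query has exactly one hit here).
planted_pass <- function(hits, crit) {
  hits$evalue <= crit$max_evalue &
    hits$length >= crit$min_alignment_length &
    hits$pident >= crit$min_percent_identity &
    hits$bitscore >= crit$min_bitscore
}

# Brute-force dictionary merge of slim tables: named-vector accumulation
# into a union dictionary, independent of the matrix machinery.
oracle_merge <- function(tables) {
  cats <- sort(unique(unlist(lapply(tables, function(t) names(t$values)))))
  out <- matrix(0, nrow = length(cats), ncol = length(tables),
                dimnames = list(cats,
                                make.unique(vapply(tables, `[[`, "",
                                                   "label"))))
  for (j in seq_along(tables)) {
    for (cat in names(tables[[j]]$values)) {
      out[cat, j] <- tables[[j]]$values[[cat]]
    }
  }
  out
}

# Random slim table for merge tests.
random_slim_table <- function(label, kind = "raw", n_cats = 6,
                              vocabulary = letters) {
  cats <- sort(sample(vocabulary, n_cats))
  vals <- if (kind == "raw") {
    stats::setNames(sample(1:50, n_cats, replace = TRUE), cats)
  } else {
    v <- stats::runif(n_cats)
    stats::setNames(v / sum(v), cats)
  }
  slim_table(vals, label = label, level = "gene", kind = kind,
             n_input = 100, n_with_hit = 90, n_annotated = 80)
}

expect_hits_equal <- function(a, b) {
  expect_equal(as.data.frame(a)[hit_columns()],
               as.data.frame(b)[hit_columns()],
               ignore_attr = TRUE)
}
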