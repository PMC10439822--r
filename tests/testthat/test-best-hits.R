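mk_hit <- function(q = "q1", s = "s1", evalue = 1e-10, bitscore = 100,
                   length = 100L, pident = 50) {
  data.frame(qseqid = q, sseqid = s, pident = pident, length = length,
             mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 300L,
             sstart = 1L, send = 100L, evalue = evalue,
             bitscore = bitscore, stringsAsFactors = FALSE)
}

test_that("E-value filter removes strictly-greater values only", {
  hits <- rbind(mk_hit(evalue = 2e-5), mk_hit(evalue = 1e-6),
                mk_hit(evalue = 1e-5))
  kept <- filter_hits(hits, filter_criteria())
  expect_equal(kept$evalue, c(1e-6, 1e-5))  # exactly-at-cutoff survives
})

test_that("minima pass at-or-above", {
  hits <- rbind(mk_hit(length = 99L), mk_hit(length = 100L),
                mk_hit(pident = 39.9), mk_hit(pident = 40),
                mk_hit(bitscore = 74), mk_hit(bitscore = 75))
  crit <- filter_criteria(min_alignment_length = 100,
                          min_percent_identity = 40, min_bitscore = 75)
  kept <- filter_hits(hits, crit)
  # rows failing any minimum (length 99, pident 39.9, bitscore 74) drop;
  # rows exactly at each cutoff survive
  expect_equal(nrow(kept), 3L)
  expect_true(all(kept$length >= 100 & kept$pident >= 40 &
                    kept$bitscore >= 75))

  expect_equal(nrow(filter_hits(hits,
                                filter_criteria(min_alignment_length = 100,
                                                min_percent_identity = 0,
                                                min_bitscore = 0))), 5L)
})

test_that("filter output is an order-preserving subsequence", {
  set.seed(21)
  for (i in 1:10) {
    hits <- random_hits(30, 5)
    crit <- filter_criteria(max_evalue = 1e-10,
                            min_alignment_length = sample(0:200, 1),
                            min_bitscore = sample(0:300, 1))
    kept <- filter_hits(hits, crit)
    key <- function(h) paste(h$qseqid, h$sseqid, h$evalue, h$bitscore,
                             h$length, h$pident)
    expect_true(all(key(kept) %in% key(hits)))
    expect_false(is.unsorted(match(key(kept), key(hits))))
  }
})

test_that("select_best_hits picks the metric optimum", {
  hits <- rbind(mk_hit(s = "s1", evalue = 1e-10, bitscore = 100),
                mk_hit(s = "s2", evalue = 1e-20, bitscore = 90),
                mk_hit(s = "s3", evalue = 1e-8, bitscore = 300))
  expect_equal(select_best_hits(hits, "evalue")$sseqid, "s2")
  expect_equal(select_best_hits(hits, "bitscore")$sseqid, "s3")
})

test_that("ties break by bitscore, then input order; result is deterministic", {
  hits <- rbind(mk_hit(s = "s1", evalue = 1e-10, bitscore = 180),
                mk_hit(s = "s2", evalue = 1e-10, bitscore = 200),
                mk_hit(s = "s3", evalue = 1e-10, bitscore = 200))
  best <- select_best_hits(hits, "evalue")
  expect_equal(best$sseqid, "s2")  # bitscore tie resolved by input order
  expect_identical(select_best_hits(hits, "evalue")$sseqid,
                   best$sseqid)
})

test_that("select_best_hits equals the brute-force oracle on random fixtures", {
  set.seed(99)
  for (i in 1:40) {
    hits <- random_hits(n_queries = sample(5:40, 1), max_hits = 5)
    for (metric in ranking_metrics()) {
      got <- select_best_hits(hits, metric)
      want <- oracle_best_hits(hits, metric)
      expect_hits_equal(got, want)
    }
  }
})

test_that("stringency_sweep matches filter_hits and planted grid truth", {
  hits <- grid_planted_hits()
  grid <- c(stringency_presets("evalue"), stringency_presets("length"),
            stringency_presets("pident"), stringency_presets("bitscore"),
            stringency_presets("combined"))
  sweep <- stringency_sweep(hits, grid)
  expect_equal(nrow(sweep), length(grid))
  for (i in seq_along(grid)) {
    pass <- planted_pass(hits, grid[[i]])
    expect_equal(sweep$n_hits_passing[i], sum(pass))
    expect_equal(sweep$n_queries_with_hit[i],
                 length(unique(hits$qseqid[pass])))
  }
  # single-element grid equals a direct filter_hits call
  one <- stringency_sweep(hits, list(default = filter_criteria()))
  expect_equal(one$n_hits_passing, nrow(filter_hits(hits)))
  expect_error(stringency_sweep(hits, list()), "non-empty")
})

test_that("nested criteria give non-increasing counts (monotonicity)", {
  set.seed(7)
  hits <- rbind(grid_planted_hits()[sample.int(6561, 800), ],
                random_hits(100, 4))
  for (type in c("evalue", "length", "pident", "bitscore", "combined")) {
    sweep <- stringency_sweep(hits, stringency_presets(type))
    expect_false(is.unsorted(rev(sweep$n_hits_passing)),
                 info = paste("hits non-increasing for", type))
    expect_false(is.unsorted(rev(sweep$n_queries_with_hit)),
                 info = paste("queries non-increasing for", type))
  }
})

test_that("combined presets are exactly the published grid corners", {
  p <- stringency_presets("combined")
  expect_equal(names(p)[c(1, 4)], c("least_stringent", "most_stringent"))
  expect_equal(unlist(p$least_stringent), c(max_evalue = 1e-5,
                                            min_alignment_length = 30,
                                            min_percent_identity = 10,
                                            min_bitscore = 33))
  expect_equal(unlist(p$most_stringent), c(max_evalue = 1e-5,
                                           min_alignment_length = 150,
                                           min_percent_identity = 40,
                                           min_bitscore = 75))
})

test_that("best-hit files round-trip enough for annotation transfer", {
  hits <- rbind(mk_hit(q = "q1", s = "AT1G01010.1"),
                mk_hit(q = "q2", s = "AT1G02020.2"))
  best <- select_best_hits(hits, "evalue")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_best_hits(best, f)
  back <- read_best_hits(f)
  expect_equal(back$qseqid, best$qseqid)
  expect_equal(back$sseqid, best$sseqid)
})
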