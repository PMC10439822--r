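test_that("read_fasta parses ids, descriptions, and errors on duplicates", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">q1 some description here", "ATGCATGC",
               ">q2", "GGGTTTAAA"), f)
  rec <- read_fasta(f)
  expect_equal(rec$id, c("q1", "q2"))
  expect_equal(rec$description, c("some description here", ""))
  expect_equal(rec$sequence, c("ATGCATGC", "GGGTTTAAA"))

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">q1", "ATG", ">q1", "GGG"), dup)
  expect_error(read_fasta(dup), "q1")

  expect_error(read_fasta(tempfile()), "not found")
  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_fasta(empty), "empty")
})

test_that("fasta round-trips through write_fasta, including long sequences", {
  rec <- data.frame(id = c("a", "b"),
                    description = c("desc one", ""),
                    sequence = c(paste(rep("ATGC", 60), collapse = ""), "TTT"),
                    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(rec, f)
  expect_equal(read_fasta(f), rec)
})

test_that("read_tabular_hits parses outfmt-6 lines including scientific notation", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("q1\ts1\t97.5\t120\t3\t0\t1\t360\t1\t120\t1e-50\t230", f)
  h <- read_tabular_hits(f)
  expect_equal(nrow(h), 1L)
  expect_equal(h$qseqid, "q1")
  expect_equal(h$sseqid, "s1")
  expect_equal(h$pident, 97.5)
  expect_equal(h$length, 120L)
  expect_equal(h$evalue, 1e-50)
  expect_equal(h$bitscore, 230)
})

test_that("read_tabular_hits handles empty files and reports bad lines", {
  f <- withr::local_tempfile(fileext = ".tsv")
  file.create(f)
  expect_equal(nrow(read_tabular_hits(f)), 0L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("q1\ts1\t97.5\t120\t3\t0\t1\t360\t1\t120\t1e-50", bad)
  expect_error(read_tabular_hits(bad), "line 1.*12")

  nonnum <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("q1\ts1\t97.5\t120\t3\t0\t1\t360\t1\t120\t1e-50\t230",
               "q2\ts2\tabc\t120\t3\t0\t1\t360\t1\t120\t1e-50\t230"),
             nonnum)
  expect_error(read_tabular_hits(nonnum), "line 2")
})

test_that("tabular hits round-trip losslessly and preserve order", {
  set.seed(11)
  hits <- random_hits(n_queries = 60, max_hits = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tabular_hits(hits, f)
  back <- read_tabular_hits(f)
  expect_hits_equal(back, hits)
  # order preservation: parsed query/subject order matches file order
  raw <- strsplit(readLines(f), "\t", fixed = TRUE)
  expect_equal(vapply(raw, `[[`, "", 1), back$qseqid)
  expect_equal(vapply(raw, `[[`, "", 2), back$sseqid)
  # re-serialization is byte-identical
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_tabular_hits(back, f2)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("canonical slim mapping reader aggregates and excludes", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tbinding", "g1\ttransport", "g2\tbinding",
               "g1\tbinding"), f)
  m <- read_slim_mapping(f)
  expect_equal(m$entries, list(g1 = c("binding", "transport"),
                               g2 = "binding"))

  m2 <- read_slim_mapping(f, excluded_categories = "transport")
  expect_equal(m2$entries, list(g1 = "binding", g2 = "binding"))

  # a key whose only category is excluded disappears entirely
  m3 <- read_slim_mapping(f, excluded_categories = c("binding"))
  expect_equal(names(m3$entries), "g1")
  expect_false(any(vapply(m3$entries, function(x) "binding" %in% x, TRUE)))
})

test_that("tair dialect with comments and configurable columns matches canonical", {
  canon <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("AT1G01010.1\tbinding", "AT1G01010.1\ttransport",
               "AT1G02020.1\tnucleus"), canon)
  tair <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("! TAIR-style distribution file",
               "! key<TAB>aspect<TAB>slim term<TAB>evidence",
               "AT1G01010.1\tF\tbinding\tIEA",
               "AT1G01010.1\tP\ttransport\tIDA",
               "AT1G02020.1\tC\tnucleus\tIEA"), tair)
  expect_equal(read_slim_mapping(tair, dialect = "tair", key_col = 1,
                                 term_col = 3)$entries,
               read_slim_mapping(canon)$entries)
})

test_that("mapping reader rejects malformed lines with line numbers", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tbinding", "only_one_column"), f)
  expect_error(read_slim_mapping(f), "line 2")
  expect_error(read_slim_mapping(f, dialect = "bogus"))
})

test_that("mapping exclusion property: entries shrink and excluded labels vanish", {
  set.seed(5)
  for (i in 1:20) {
    keys <- sprintf("g%02d", sample.int(30, 40, replace = TRUE))
    cats <- sample(letters[1:6], 40, replace = TRUE)
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(paste(keys, cats, sep = "\t"), f)
    full <- read_slim_mapping(f)
    excl <- sample(letters[1:6], 2)
    cut <- read_slim_mapping(f, excluded_categories = excl)
    expect_lte(length(cut$entries), length(full$entries))
    expect_false(any(unlist(cut$entries) %in% excl))
  }
})

test_that("slim tables round-trip through TSV with filename-inferred tags", {
  t1 <- slim_table(c(binding = 3, transport = 1), label = "setA",
                   level = "gene", kind = "raw",
                   n_input = 10, n_with_hit = 8, n_annotated = 4)
  d <- withr::local_tempdir()
  p <- file.path(d, slim_table_filename(t1))
  expect_equal(basename(p), "setA_gene_raw.tsv")
  write_slim_table(t1, p)
  back <- read_slim_table(p)
  expect_equal(back$values, t1$values)
  expect_equal(back$level, "gene")
  expect_equal(back$kind, "raw")
  expect_equal(back$label, "setA")

  # frequencies survive within 1e-12 (in fact exactly, via %.17g)
  tf <- slim_table(c(a = 1/3, b = 2/3), label = "setA", level = "locus",
                   kind = "frequency")
  pf <- file.path(d, slim_table_filename(tf))
  write_slim_table(tf, pf)
  expect_equal(read_slim_table(pf)$values, tf$values, tolerance = 1e-12)

  # empty table is valid
  t0 <- slim_table(stats::setNames(numeric(0), character(0)),
                   label = "empty", level = "gene", kind = "raw")
  p0 <- file.path(d, slim_table_filename(t0))
  write_slim_table(t0, p0)
  expect_length(read_slim_table(p0)$values, 0)
})

test_that("slim table reader rejects missing headers and non-numeric cells", {
  d <- withr::local_tempdir()
  bad <- file.path(d, "x_gene_raw.tsv")
  writeLines(c("wrong\theader", "a\t1"), bad)
  expect_error(read_slim_table(bad), "header")
  bad2 <- file.path(d, "y_gene_raw.tsv")
  writeLines(c("GO_slim_category\ty", "a\tnot_a_number"), bad2)
  expect_error(read_slim_table(bad2), "non-numeric")
  # no filename convention and no explicit tags
  bad3 <- file.path(d, "plain.tsv")
  writeLines(c("GO_slim_category\tz", "a\t1"), bad3)
  expect_error(read_slim_table(bad3), "infer")
  expect_equal(read_slim_table(bad3, level = "gene", kind = "raw")$values,
               c(a = 1))
})
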