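# Deterministic synthetic fixtures with planted ground truth: FASTA
# queries, tabular hits, gene/locus slim mappings, and the analytically
# known outcomes (best hits, tables, coverage) the pipeline must
# reproduce.

# A small vocabulary of plant GO slim category labels, in the spirit of
# the QuickGO plant slim; fixtures draw the first n_categories.
.slim_vocab <- c(
  "binding", "transport", "metabolic process", "nucleotide binding",
  "protein modification process", "ribosome", "endoplasmic reticulum",
  "cell cycle", "signal transduction", "response to stress", "nucleus",
  "plasma membrane", "DNA binding", "kinase activity", "plastid",
  "mitochondrion", "translation", "transcription", "cell wall",
  "lipid metabolic process", "carbohydrate metabolic process",
  "photosynthesis", "hydrolase activity", "transferase activity",
  "cytoskeleton", "vacuole", "cell differentiation", "embryo development",
  "secondary metabolic process", "transporter activity",
  "oxidoreductase activity", "RNA binding", "catalytic activity",
  "protein binding", "extracellular region", "golgi apparatus"
)

#' Specification of a synthetic fixture
#'
#' The stated world of the generator: how many queries, reference
#' subjects and categories exist, how many hits each query receives,
#' what fraction of winning subjects can be annotated, and the E-value
#' grid hits are drawn from. Identical seeds give identical fixtures.
#'
#' @param n_queries Number of query sequences.
#' @param n_subjects Number of reference gene models (must allow
#'   distinct subjects per query's hit list).
#' @param n_categories Number of GO slim categories in the mapping.
#' @param hits_per_query Integer range `c(min, max)` of hits per query.
#' @param fraction_mappable Fraction of queries whose winning subject is
#'   present in the gene-level mapping (the planted annotation
#'   coverage).
#' @param evalue_grid Distinct E-values hits are drawn from; all at or
#'   below the default 1e-5 cutoff so every query keeps a best hit under
#'   default filtering.
#' @param seq_length Length of the random ATGC query sequences (they
#'   exercise FASTA I/O and coverage denominators, not alignment).
#' @param inject_ties Fraction of queries that additionally receive a
#'   decoy hit tied on E-value with the planted winner but with a lower
#'   bitscore, to exercise the tie-break chain.
#' @param extra_locus_only Number of unmappable queries whose winning
#'   subject's locus is added to the locus-level mapping only, planting
#'   a gene/locus coverage divergence.
#' @param seed Integer seed; the generator is deterministic given the
#'   spec.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_queries = 50L, n_subjects = 4L * n_queries,
                         n_categories = 8L, hits_per_query = c(1L, 5L),
                         fraction_mappable = 0.8,
                         evalue_grid = 10^-(5:40),
                         seq_length = 120L,
                         inject_ties = 0,
                         extra_locus_only = 0L,
                         seed = 1L) {
  stopifnot(n_queries >= 1, n_subjects >= 1, n_categories >= 1,
            length(hits_per_query) == 2, hits_per_query[1] >= 1,
            hits_per_query[2] >= hits_per_query[1],
            fraction_mappable >= 0, fraction_mappable <= 1,
            inject_ties >= 0, inject_ties <= 1,
            extra_locus_only >= 0, seq_length >= 1)
  if (length(unique(evalue_grid)) < hits_per_query[2] + 1) {
    stop("evalue_grid must offer more distinct values than hits_per_query",
         call. = FALSE)
  }
  if (n_subjects < hits_per_query[2]) {
    stop("n_subjects too small for hits_per_query", call. = FALSE)
  }
  structure(list(n_queries = as.integer(n_queries),
                 n_subjects = as.integer(n_subjects),
                 n_categories = as.integer(n_categories),
                 hits_per_query = as.integer(hits_per_query),
                 fraction_mappable = fraction_mappable,
                 evalue_grid = sort(unique(evalue_grid)),
                 seq_length = as.integer(seq_length),
                 inject_ties = inject_ties,
                 extra_locus_only = as.integer(extra_locus_only),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

.fixture_categories <- function(n) {
  if (n <= length(.slim_vocab)) return(.slim_vocab[seq_len(n)])
  c(.slim_vocab, sprintf("slim category %02d", seq_len(n - length(.slim_vocab))))
}

#' Generate a synthetic fixture with planted ground truth
#'
#' Writes a query FASTA, a 12-column tabular hits file, and gene- and
#' locus-level canonical mapping files into `dir`, and returns the
#' planted truth: the expected best hit per query under the default
#' E-value ranking, the expected four summary tables, and the expected
#' annotation coverage at each level. The truth is computed by
#' construction while planting -- not by the pipeline code under test --
#' so it serves as an independent oracle.
#'
#' Construction guarantees: each query's hits carry distinct E-values,
#' so the winner (minimum E-value) is unique; with `inject_ties > 0` a
#' decoy duplicates the winning E-value but has a strictly lower
#' bitscore, so the bitscore tie-break must pick the planted winner. All
#' E-values are at or below 1e-5, so default filtering removes nothing.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return An object of class `fixture`: list with `files` (paths:
#'   `fasta`, `hits`, `mapping_gene`, `mapping_locus`), `spec`, `label`,
#'   and `truth` -- list with `best_subject` (named character, query ->
#'   winning subject), `tables` (four `slim_table`s), `coverage_gene`,
#'   `coverage_locus`, `n_annotated_gene`, `n_annotated_locus`.
#' @export
generate_fixture <- function(spec = fixture_spec(), dir = tempfile("fix_")) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  nq <- spec$n_queries
  query_ids <- sprintf("q%04d", seq_len(nq))
  cats <- .fixture_categories(spec$n_categories)

  # reference gene models: loci FIXL####, 1-2 isoforms each
  n_loci <- ceiling(spec$n_subjects / 2)
  loci <- sprintf("FIXL%04d", seq_len(n_loci))
  isoforms <- rep(1:2, length.out = spec$n_subjects)
  subj_locus <- rep(loci, each = 2)[seq_len(spec$n_subjects)]
  subjects <- paste0(subj_locus, ".", isoforms)

  # partition queries: mappable winners vs not
  n_map <- round(spec$fraction_mappable * nq)
  mappable_q <- sort(sample.int(nq, n_map))
  is_mappable <- seq_len(nq) %in% mappable_q

  # partition subjects into mapped / unmapped pools; winners are drawn
  # from the pool matching the query's planted mappability
  n_subj_mapped <- max(n_map > 0, min(spec$n_subjects - (n_map < nq),
                                      ceiling(spec$n_subjects * 0.6)))
  if (n_map == 0) n_subj_mapped <- 0
  if (n_map == nq) n_subj_mapped <- spec$n_subjects
  mapped_subj <- if (n_subj_mapped > 0) {
    sort(sample(subjects, n_subj_mapped))
  } else character(0)
  unmapped_subj <- setdiff(subjects, mapped_subj)

  # gene-level mapping: 1-3 categories per mapped gene model
  map_keys <- character(0)
  map_cats <- character(0)
  gene_cats <- stats::setNames(vector("list", length(subjects)), subjects)
  for (s in mapped_subj) {
    k <- sample.int(min(3L, length(cats)), 1L)
    cs <- sort(sample(cats, k))
    gene_cats[[s]] <- cs
    map_keys <- c(map_keys, rep(s, k))
    map_cats <- c(map_cats, cs)
  }
  mapping_gene <- slim_mapping(map_keys, map_cats)
  mapping_locus <- collapse_mapping_to_locus(mapping_gene)

  # hits: per query, k distinct subjects with distinct E-values; the
  # planted winner takes the minimum
  rows <- vector("list", nq)
  winner <- character(nq)
  tie_queries <- if (spec$inject_ties > 0) {
    sort(sample.int(nq, round(spec$inject_ties * nq)))
  } else integer(0)
  kk <- seq(spec$hits_per_query[1], spec$hits_per_query[2])
  for (i in seq_len(nq)) {
    k <- if (length(kk) == 1L) kk else sample(kk, 1L)
    pool <- if (is_mappable[i]) mapped_subj else unmapped_subj
    win <- sample(pool, 1L)
    others <- sample(setdiff(subjects, win), k - 1L)
    subj <- c(win, others)
    ev <- sort(sample(spec$evalue_grid, k))  # winner gets the minimum
    bits <- sort(sample(seq(60, 500), k), decreasing = TRUE)
    pid <- round(stats::runif(k, 25, 99), 1)
    len <- sample(40:400, k, replace = TRUE)
    df <- data.frame(
      qseqid = query_ids[i], sseqid = subj, pident = pid, length = len,
      mismatch = as.integer(round(len * (100 - pid) / 100)),
      gapopen = sample(0:3, k, replace = TRUE),
      qstart = 1L, qend = 3L * len, sstart = 1L, send = len,
      evalue = ev, bitscore = as.numeric(bits),
      stringsAsFactors = FALSE)
    decoy_pool <- setdiff(subjects, subj)
    if (i %in% tie_queries && length(decoy_pool) > 0) {
      decoy <- df[1, ]
      decoy$sseqid <- if (length(decoy_pool) == 1L) decoy_pool else
        sample(decoy_pool, 1L)
      decoy$bitscore <- df$bitscore[1] - 10  # loses the bitscore tie-break
      df <- rbind(df, decoy)
    }
    # shuffle row order so winners are not trivially first
    df <- df[sample.int(nrow(df)), , drop = FALSE]
    rows[[i]] <- df
    winner[i] <- win
  }
  hits <- do.call(rbind, rows)
  rownames(hits) <- NULL
  names(winner) <- query_ids

  # plant extra locus-only mapping entries for some unmappable queries
  if (spec$extra_locus_only > 0) {
    unmapped_q <- setdiff(seq_len(nq), mappable_q)
    pick <- utils::head(unmapped_q, spec$extra_locus_only)
    extra_loci <- unique(to_locus_id(winner[pick]))
    extra_loci <- setdiff(extra_loci, names(mapping_locus$entries))
    if (length(extra_loci) > 0) {
      ek <- character(0); ec <- character(0)
      for (l in extra_loci) {
        k <- sample.int(min(2L, length(cats)), 1L)
        cs <- sort(sample(cats, k))
        ek <- c(ek, rep(l, k)); ec <- c(ec, cs)
      }
      all_k <- c(unlist(mapply(function(key, v) rep(key, length(v)),
                               names(mapping_locus$entries),
                               mapping_locus$entries,
                               SIMPLIFY = FALSE), use.names = FALSE), ek)
      all_c <- c(unlist(mapping_locus$entries, use.names = FALSE), ec)
      mapping_locus <- slim_mapping(all_k, all_c)
    }
  }

  # random ATGC sequences (FASTA I/O + coverage denominators only)
  seqs <- vapply(seq_len(nq), function(i) {
    paste(sample(c("A", "T", "G", "C"), spec$seq_length, replace = TRUE),
          collapse = "")
  }, "")
  fasta_df <- data.frame(id = query_ids,
                         description = sprintf("synthetic query %d",
                                               seq_len(nq)),
                         sequence = seqs, stringsAsFactors = FALSE)

  files <- list(fasta = file.path(dir, "queries.fasta"),
                hits = file.path(dir, "hits.tsv"),
                mapping_gene = file.path(dir, "mapping_gene.tsv"),
                mapping_locus = file.path(dir, "mapping_locus.tsv"))
  write_fasta(fasta_df, files$fasta)
  write_tabular_hits(hits, files$hits)
  write_slim_mapping(mapping_gene, files$mapping_gene)
  write_slim_mapping(mapping_locus, files$mapping_locus)

  # ---- planted truth, computed by construction ----
  label <- sprintf("fixture_seed%d", spec$seed)
  truth_counts <- function(mapping, locus_level) {
    keys <- if (locus_level) to_locus_id(winner) else winner
    per_query <- lapply(keys, function(k) {
      v <- mapping$entries[[k]]
      if (is.null(v)) character(0) else v
    })
    pairs <- unlist(per_query, use.names = FALSE)
    counts <- if (length(pairs) == 0) {
      stats::setNames(integer(0), character(0))
    } else {
      tab <- table(pairs)
      out <- stats::setNames(as.integer(tab), names(tab))
      out[order(names(out))]
    }
    list(counts = counts, n_annotated = sum(lengths(per_query) > 0))
  }
  tg <- truth_counts(mapping_gene, FALSE)
  tl <- truth_counts(mapping_locus, TRUE)
  truth_tables <- list(
    gene_raw = slim_table(tg$counts, label, "gene", "raw",
                          nq, nq, tg$n_annotated),
    gene_freq = slim_table(to_frequencies(tg$counts), label, "gene",
                           "frequency", nq, nq, tg$n_annotated),
    locus_raw = slim_table(tl$counts, label, "locus", "raw",
                           nq, nq, tl$n_annotated),
    locus_freq = slim_table(to_frequencies(tl$counts), label, "locus",
                            "frequency", nq, nq, tl$n_annotated))

  structure(list(
    files = files, spec = spec, label = label, dir = dir,
    truth = list(best_subject = winner,
                 tables = truth_tables,
                 n_annotated_gene = tg$n_annotated,
                 n_annotated_locus = tl$n_annotated,
                 coverage_gene = tg$n_annotated / nq,
                 coverage_locus = tl$n_annotated / nq)),
    class = "fixture")
}

# save/restore the global RNG state so fixture generation does not
# perturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' A small three-gene-set worked example
#'
#' Builds three overlapping GO slim summary tables (raw and frequency)
#' with planted values, sized like the toy example gene sets that ship
#' with annotation pipelines. Set `"fern_a"` is deliberately skewed
#' toward `binding`/`ribosome` and away from `metabolic process`
#' relative to `"fern_b"`, so an enrichment comparison of the two has a
#' known over/under structure; `"fern_c"` adds a category absent from
#' the others to exercise outer merging.
#'
#' @return List with `raw` and `freq` (named lists of three
#'   `slim_table`s each) and `focal`/`reference` (the planted count
#'   vectors for the enrichment demo).
#' @export
worked_example <- function() {
  counts <- list(
    fern_a = c("binding" = 120, "ribosome" = 80, "transport" = 40,
               "metabolic process" = 20, "cell cycle" = 25),
    fern_b = c("binding" = 90, "ribosome" = 45, "transport" = 55,
               "metabolic process" = 120, "nucleotide binding" = 60),
    fern_c = c("binding" = 70, "transport" = 30, "photosynthesis" = 50,
               "metabolic process" = 65, "cell cycle" = 15)
  )
  raw <- lapply(names(counts), function(lbl) {
    v <- counts[[lbl]]
    slim_table(v, label = lbl, level = "gene", kind = "raw",
               n_input = sum(v), n_with_hit = sum(v), n_annotated = sum(v))
  })
  names(raw) <- names(counts)
  freq <- lapply(raw, function(t) {
    slim_table(to_frequencies(t$values), label = t$label, level = t$level,
               kind = "frequency", n_input = t$n_input,
               n_with_hit = t$n_with_hit, n_annotated = t$n_annotated)
  })
  list(raw = raw, freq = freq,
       focal = counts$fern_a, reference = counts$fern_b)
}
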