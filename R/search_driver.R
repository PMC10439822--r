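# Optional driver for an external translated similarity search
# (nucleotide queries vs protein database). The whole stage is
# bypassable: any 12-column tabular file is accepted downstream.

#' Configure an external similarity search
#'
#' Defaults follow the lenient search stage of the pipeline
#' (`-num_threads 1 -max_target_seqs 50 -evalue 0.001`): filtering is
#' deliberately deferred to the best-hit stage so one expensive search
#' can feed many filterings.
#'
#' @param program `"blast"` (blastx) or `"diamond"` (diamond blastx).
#' @param database_path Path to the formatted protein database. Building
#'   the database (`makeblastdb -dbtype prot` / `diamond makedb`) is a
#'   documented manual step, not part of this driver.
#' @param num_threads Threads for the search program.
#' @param max_target_seqs Maximum subjects reported per query.
#' @param evalue_threshold Search-stage E-value cutoff.
#' @param extra_args Extra command tokens appended verbatim.
#' @param executable Override the executable name/path (used by tests to
#'   substitute a stub).
#' @return An object of class `search_config`.
#' @export
search_config <- function(program = c("blast", "diamond"),
                          database_path = NULL,
                          num_threads = 1L,
                          max_target_seqs = 50L,
                          evalue_threshold = 0.001,
                          extra_args = character(),
                          executable = NULL) {
  program <- match.arg(program)
  stopifnot(evalue_threshold > 0, max_target_seqs >= 1, num_threads >= 1)
  if (is.null(executable)) {
    executable <- switch(program, blast = "blastx", diamond = "diamond")
  }
  structure(list(program = program, database_path = database_path,
                 num_threads = as.integer(num_threads),
                 max_target_seqs = as.integer(max_target_seqs),
                 evalue_threshold = evalue_threshold,
                 extra_args = as.character(extra_args),
                 executable = executable),
            class = "search_config")
}

#' Assemble the command line for a translated search
#'
#' Pure string assembly -- nothing is executed. The token list requests a
#' translated nucleotide-vs-protein search with 12-column tabular output
#' and carries the configured thread count, subject cap, and E-value
#' threshold.
#'
#' @param config A [search_config()].
#' @param query Path to the query FASTA.
#' @param out Path for the tabular output.
#' @return Character vector of command tokens (executable first).
#' @export
build_search_command <- function(config, query, out) {
  stopifnot(inherits(config, "search_config"))
  ev <- format(config$evalue_threshold, scientific = FALSE, trim = TRUE)
  if (config$evalue_threshold < 1e-4) {
    ev <- format(config$evalue_threshold, trim = TRUE)
  }
  if (config$program == "blast") {
    tokens <- c(config$executable,
                "-query", query,
                "-db", config$database_path,
                "-out", out,
                "-outfmt", "6",
                "-num_threads", as.character(config$num_threads),
                "-max_target_seqs", as.character(config$max_target_seqs),
                "-evalue", ev)
  } else {
    tokens <- c(config$executable, "blastx",
                "--query", query,
                "--db", config$database_path,
                "--out", out,
                "--outfmt", "6",
                "--threads", as.character(config$num_threads),
                "--max-target-seqs", as.character(config$max_target_seqs),
                "--evalue", ev)
  }
  c(tokens, config$extra_args)
}

#' Run the external similarity search
#'
#' Validates the query FASTA, invokes the configured executable, checks
#' the exit status, and verifies the output parses as 12-column tabular
#' hits. If the executable is missing the error points at the
#' precomputed-hits entry point, which needs no external program.
#'
#' @param fasta Path to the query FASTA (must be non-empty).
#' @param config A [search_config()].
#' @param out Path for the tabular hits file.
#' @return `out`, invisibly.
#' @export
run_search <- function(fasta, config, out) {
  stopifnot(inherits(config, "search_config"))
  read_fasta(fasta)  # errors on missing/empty query before invocation
  exe <- config$executable
  resolved <- if (file.exists(exe)) exe else Sys.which(exe)
  if (!nzchar(resolved)) {
    stop(sprintf(paste0(
      "search executable '%s' not found on PATH. If you already have a ",
      "12-column tabular result, skip the search and supply it directly ",
      "(e.g. run_pipeline(..., hits = <file>))."), exe), call. = FALSE)
  }
  if (!is.null(config$database_path) && !file.exists(config$database_path) &&
      !any(file.exists(paste0(config$database_path,
                              c(".pin", ".phr", ".psq", ".dmnd"))))) {
    stop("search database not found: ", config$database_path, call. = FALSE)
  }
  tokens <- build_search_command(config, fasta, out)
  errfile <- tempfile("search_stderr_")
  status <- suppressWarnings(
    system2(tokens[1], args = tokens[-1], stdout = FALSE, stderr = errfile)
  )
  if (!identical(status, 0L)) {
    msg <- if (file.exists(errfile)) {
      paste(readLines(errfile, warn = FALSE), collapse = "\n")
    } else ""
    if (file.exists(out)) unlink(out)  # never leave partial output
    stop(sprintf("search program exited with status %s\n%s", status, msg),
         call. = FALSE)
  }
  if (!file.exists(out)) {
    stop("search program exited 0 but wrote no output: ", out, call. = FALSE)
  }
  read_tabular_hits(out)  # contract: output must parse
  invisible(out)
}
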