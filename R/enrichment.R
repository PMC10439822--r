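# Chi-squared comparison of GO slim composition between a focal gene
# set (e.g. retained paralogs) and a reference gene set (e.g. the full
# transcriptome), with residual-based over/under-representation calls.

#' Build a 2 x C contingency table of slim counts
#'
#' Row 0 is the focal gene set, row 1 the reference; columns are the
#' union of the two category sets, with missing cells 0. Categories
#' whose column total is 0 carry no information and make the expected
#' counts degenerate; they are removed when `drop_empty = TRUE`,
#' otherwise left in place (and [chi_square()] will refuse them).
#'
#' @param focal,reference Named numeric vectors of raw category counts.
#' @param drop_empty Drop categories with zero column total.
#' @return An object of class `slim_contingency`: list with
#'   `categories`, `observed` (2 x C integer matrix), `row_totals`,
#'   `col_totals`, `n`.
#' @export
build_contingency <- function(focal, reference, drop_empty = FALSE) {
  cats <- sort(unique(c(names(focal), names(reference))))
  if (length(cats) == 0) stop("no categories supplied", call. = FALSE)
  obs <- matrix(0, nrow = 2, ncol = length(cats),
                dimnames = list(c("focal", "reference"), cats))
  if (length(focal) > 0) obs["focal", names(focal)] <- unname(focal)
  if (length(reference) > 0) {
    obs["reference", names(reference)] <- unname(reference)
  }
  if (any(obs < 0) || any(obs != round(obs))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (drop_empty) {
    keep <- colSums(obs) > 0
    obs <- obs[, keep, drop = FALSE]
  }
  if (ncol(obs) < 2) {
    stop("need at least two usable categories", call. = FALSE)
  }
  n <- sum(obs)
  if (n <= 0) stop("grand total must be positive", call. = FALSE)
  structure(list(categories = colnames(obs), observed = obs,
                 row_totals = rowSums(obs), col_totals = colSums(obs),
                 n = n),
            class = "slim_contingency")
}

.expected_matrix <- function(table) {
  outer(table$row_totals, table$col_totals) / table$n
}

#' Chi-squared test of homogeneity on a slim contingency table
#'
#' Classical Pearson chi-squared without continuity correction:
#' `E[i,j] = row_i * col_j / N`, `X2 = sum (O - E)^2 / E`,
#' `df = (rows - 1)(cols - 1)`, p-value from the upper tail of the
#' chi-squared distribution.
#'
#' @param table A `slim_contingency`.
#' @return List with `chi2`, `df`, `p_value`.
#' @export
chi_square <- function(table) {
  stopifnot(inherits(table, "slim_contingency"))
  expected <- .expected_matrix(table)
  if (any(expected == 0)) {
    stop(paste0("expected count of 0 (a category or row has zero total); ",
                "rebuild the table with build_contingency(..., ",
                "drop_empty = TRUE)"), call. = FALSE)
  }
  chi2 <- sum((table$observed - expected)^2 / expected)
  df <- (nrow(table$observed) - 1L) * (ncol(table$observed) - 1L)
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Residual-based over/under-representation calls
#'
#' For each category the residual of the focal-row cell is computed and
#' compared against a symmetric threshold (default 2, the convention of
#' the duplicate-gene-retention literature): residual > threshold is
#' called `over`, residual < -threshold `under`, otherwise `ns`. Both
#' inequalities are strict, so a residual of exactly 2 is `ns`.
#'
#' `type = "pearson"` (default) uses the raw Pearson residual
#' `(O - E) / sqrt(E)`; `type = "adjusted"` uses the standardized
#' residual `(O - E) / sqrt(E (1 - row/N)(1 - col/N))`, which is
#' approximately standard normal. No multiple-testing correction is
#' applied across categories.
#'
#' @param table A `slim_contingency`.
#' @param threshold Call threshold (> 0).
#' @param type `"pearson"` or `"adjusted"`.
#' @return An object of class `slim_enrichment`: list with `chi2`, `df`,
#'   `p_value`, `threshold`, `residual_type`, and `table` -- a data
#'   frame with columns `category`, `observed_focal`,
#'   `observed_reference`, `expected_focal`, `residual`, `call`.
#' @export
residual_calls <- function(table, threshold = 2,
                           type = c("pearson", "adjusted")) {
  stopifnot(inherits(table, "slim_contingency"), threshold > 0)
  type <- match.arg(type)
  test <- chi_square(table)
  expected <- .expected_matrix(table)
  o <- table$observed["focal", ]
  e <- expected["focal", ]
  resid <- (o - e) / sqrt(e)
  if (type == "adjusted") {
    adj <- sqrt((1 - table$row_totals["focal"] / table$n) *
                  (1 - table$col_totals / table$n))
    resid <- resid / adj
  }
  call <- ifelse(resid > threshold, "over",
                 ifelse(resid < -threshold, "under", "ns"))
  out <- data.frame(category = table$categories,
                    observed_focal = unname(o),
                    observed_reference = unname(
                      table$observed["reference", ]),
                    expected_focal = unname(e),
                    residual = unname(resid),
                    call = unname(call),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(list(chi2 = test$chi2, df = test$df, p_value = test$p_value,
                 threshold = threshold, residual_type = type, table = out),
            class = "slim_enrichment")
}

#' @export
print.slim_enrichment <- function(x, ...) {
  cat(sprintf(
    "slim_enrichment: chi2 = %.3f, df = %d, p = %.3g (%s residuals, |r| > %g)\n",
    x$chi2, x$df, x$p_value, x$residual_type, x$threshold))
  n_over <- sum(x$table$call == "over")
  n_under <- sum(x$table$call == "under")
  cat(sprintf("  %d over-represented, %d under-represented, %d ns\n",
              n_over, n_under, nrow(x$table) - n_over - n_under))
  invisible(x)
}

#' Write an enrichment result to TSV
#'
#' @param result A `slim_enrichment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(result, path) {
  stopifnot(inherits(result, "slim_enrichment"))
  tab <- result$table
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(tab), collapse = "\t"), con, sep = "\n")
  for (i in seq_len(nrow(tab))) {
    writeLines(paste(tab$category[i], tab$observed_focal[i],
                     tab$observed_reference[i],
                     .fmt_num(tab$expected_focal[i]),
                     .fmt_num(tab$residual[i]), tab$call[i], sep = "\t"),
               con, sep = "\n")
  }
  invisible(path)
}

#' Heatmap of enrichment calls across several comparisons
#'
#' One column per comparison (typically per species), one row per
#' category in the union: over-represented cells red, under-represented
#' blue, non-significant (or absent from that comparison) gray. The
#' residual magnitudes behind the figure are written alongside as a TSV
#' so the picture is fully reproducible.
#'
#' @param results Named list of `slim_enrichment` objects.
#' @param outpath Image path (extension `.png` or `.svg`); the residual
#'   TSV is written next to it with the suffix `_residuals.tsv`.
#' @return Invisibly, a list with `residuals` (category x comparison
#'   matrix), `calls` (same shape, character), `files`.
#' @export
enrichment_heatmap <- function(results, outpath) {
  if (length(results) == 0) stop("no enrichment results", call. = FALSE)
  stopifnot(all(vapply(results, inherits, TRUE, "slim_enrichment")))
  if (is.null(names(results))) {
    names(results) <- paste0("comparison_", seq_along(results))
  }
  cats <- sort(unique(unlist(lapply(results,
                                    function(r) r$table$category))))
  resid <- matrix(NA_real_, nrow = length(cats), ncol = length(results),
                  dimnames = list(cats, names(results)))
  calls <- matrix("ns", nrow = length(cats), ncol = length(results),
                  dimnames = list(cats, names(results)))
  for (s in names(results)) {
    tab <- results[[s]]$table
    resid[tab$category, s] <- tab$residual
    calls[tab$category, s] <- tab$call
  }
  df <- data.frame(
    category = rep(cats, times = length(results)),
    comparison = rep(names(results), each = length(cats)),
    call = factor(as.vector(calls), levels = c("over", "under", "ns")),
    stringsAsFactors = FALSE)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = comparison, y = category,
                                        fill = call)) +
    ggplot2::geom_tile(color = "grey40") +
    ggplot2::scale_fill_manual(values = c(over = "firebrick",
                                          under = "steelblue",
                                          ns = "grey80"),
                               drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, fill = "representation") +
    ggplot2::theme_minimal()
  ext <- tolower(tools::file_ext(outpath))
  if (!ext %in% c("png", "svg")) {
    stop("outpath must end in .png or .svg", call. = FALSE)
  }
  h <- 0.25 * length(cats) + 2.5
  if (ext == "png") {
    grDevices::png(outpath, width = 7, height = h, units = "in", res = 150,
                   type = "cairo")
  } else {
    grDevices::svg(outpath, width = 7, height = h)
  }
  print(p)
  grDevices::dev.off()
  tsv <- paste0(tools::file_path_sans_ext(outpath), "_residuals.tsv")
  con <- file(tsv, open = "wb")
  writeLines(paste(c("category", colnames(resid)), collapse = "\t"), con,
             sep = "\n")
  for (i in seq_len(nrow(resid))) {
    vals <- ifelse(is.na(resid[i, ]), "NA", .fmt_num(resid[i, ]))
    writeLines(paste(c(rownames(resid)[i], vals), collapse = "\t"), con,
               sep = "\n")
  }
  close(con)
  invisible(list(residuals = resid, calls = calls,
                 files = c(outpath, tsv)))
}
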