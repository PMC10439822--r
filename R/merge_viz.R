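# Outer merge of per-gene-set summary tables into one category x sample
# matrix, and the four visualization families (pie, bar, heatmap,
# bubble).

#' Outer-merge summary tables from multiple gene sets
#'
#' Categories are the lexicographically sorted union over the inputs;
#' cells absent from a source table are 0, so each merged column sum
#' equals the source table's total. Column order follows input order.
#' All inputs must share level and kind -- merging gene-level raw counts
#' with locus-level frequencies would be meaningless.
#'
#' @param tables List of `slim_table`s (length >= 1).
#' @return An object of class `merged_table`: list with `matrix`
#'   (category x sample), `kind`, `level`.
#' @export
merge_tables <- function(tables) {
  if (inherits(tables, "slim_table")) tables <- list(tables)
  if (length(tables) == 0 ||
      !all(vapply(tables, inherits, TRUE, "slim_table"))) {
    stop("merge_tables needs a non-empty list of slim_table objects",
         call. = FALSE)
  }
  kinds <- unique(vapply(tables, `[[`, "", "kind"))
  levels <- unique(vapply(tables, `[[`, "", "level"))
  if (length(kinds) != 1 || length(levels) != 1) {
    stop(sprintf("cannot merge tables of mixed level (%s) or kind (%s)",
                 paste(levels, collapse = ","),
                 paste(kinds, collapse = ",")), call. = FALSE)
  }
  labels <- vapply(tables, `[[`, "", "label")
  labels <- make.unique(labels)
  cats <- sort(unique(unlist(lapply(tables, function(t) names(t$values)))))
  m <- matrix(0, nrow = length(cats), ncol = length(tables),
              dimnames = list(cats, labels))
  for (j in seq_along(tables)) {
    v <- tables[[j]]$values
    if (length(v) > 0) m[names(v), j] <- unname(v)
  }
  structure(list(matrix = m, kind = kinds, level = levels),
            class = "merged_table")
}

#' @export
print.merged_table <- function(x, ...) {
  cat(sprintf("merged_table (%s level, %s): %d categories x %d gene sets\n",
              x$level, x$kind, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Log-transform a merged raw-count matrix
#'
#' Cellwise `log10(x + 1)`, so zeros stay 0 and the transform is
#' monotone. Raw counts only: a handful of very abundant categories
#' (e.g. plastid transcripts in plant transcriptomes) would otherwise
#' swamp the heatmap color scale.
#'
#' @param m A `merged_table` with `kind == "raw"`.
#' @return A `merged_table` with `kind == "log10_raw"`.
#' @export
log_transform <- function(m) {
  stopifnot(inherits(m, "merged_table"))
  if (m$kind != "raw") {
    stop("log_transform applies to raw-count tables only", call. = FALSE)
  }
  if (any(m$matrix < 0)) stop("negative cell in raw matrix", call. = FALSE)
  structure(list(matrix = log10(m$matrix + 1), kind = "log10_raw",
                 level = m$level),
            class = "merged_table")
}

#' Write a merged table to TSV
#'
#' First column `GO_slim_category`, then one column per gene set.
#'
#' @param m A `merged_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_merged_table <- function(m, path) {
  stopifnot(inherits(m, "merged_table"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("GO_slim_category", colnames(m$matrix)),
                   collapse = "\t"), con, sep = "\n")
  for (i in seq_len(nrow(m$matrix))) {
    writeLines(paste(c(rownames(m$matrix)[i], .fmt_num(m$matrix[i, ])),
                     collapse = "\t"), con, sep = "\n")
  }
  invisible(path)
}

#' Read a merged table from TSV
#'
#' @param path Path written by [write_merged_table()].
#' @param kind,level Tags to stamp on the result (the TSV itself is
#'   untagged).
#' @return A `merged_table`.
#' @export
read_merged_table <- function(path, kind = "raw", level = "gene") {
  lines <- readLines(path)
  if (length(lines) == 0) stop("missing header in ", path, call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "GO_slim_category") {
    stop(path, ": first column must be GO_slim_category", call. = FALSE)
  }
  body <- lines[-1][nzchar(lines[-1])]
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(fields) != length(header))) {
    stop(path, ": ragged rows", call. = FALSE)
  }
  cats <- vapply(fields, `[[`, "", 1L)
  m <- matrix(0, nrow = length(cats), ncol = length(header) - 1L,
              dimnames = list(cats, header[-1]))
  for (i in seq_along(fields)) {
    v <- suppressWarnings(as.numeric(fields[[i]][-1]))
    if (anyNA(v)) stop(sprintf("%s line %d: non-numeric cell", path, i + 1L),
                       call. = FALSE)
    m[i, ] <- v
  }
  structure(list(matrix = m, kind = kind, level = level),
            class = "merged_table")
}

.plot_long <- function(m) {
  data.frame(
    category = rep(rownames(m$matrix), times = ncol(m$matrix)),
    sample = rep(colnames(m$matrix), each = nrow(m$matrix)),
    value = as.vector(m$matrix),
    stringsAsFactors = FALSE
  )
}

.save_plot <- function(p, stem, outdir, formats, width = 7, height = 5.5) {
  paths <- character(0)
  for (fmt in formats) {
    path <- file.path(outdir, paste0(stem, ".", fmt))
    dev <- switch(fmt,
                  png = function(f) grDevices::png(f, width = width,
                                                   height = height,
                                                   units = "in", res = 150,
                                                   type = "cairo"),
                  svg = function(f) grDevices::svg(f, width = width,
                                                   height = height))
    dev(path)
    print(p)
    grDevices::dev.off()
    paths <- c(paths, path)
  }
  paths
}

#' Render visualizations of a merged table
#'
#' The four figure families: per-sample pie charts of category
#' proportions; a grouped bar plot; heatmaps of the matrix as-is and of
#' `log10(x + 1)` counts; and a bubble graph whose marker area is
#' proportional to each cell's share of its sample's column total (the
#' proportion of that gene set's annotations falling in the category).
#'
#' Tests against this function should assert on the returned
#' `plot_data`, not on pixels: the data fed to the plotting layer is the
#' contract, the renderer is not.
#'
#' @param m A `merged_table`.
#' @param kinds Subset of `c("pie", "bar", "heatmap", "heatmap_log",
#'   "bubble")`.
#' @param outdir Output directory (created if needed).
#' @param formats Image formats, subset of `c("png", "svg")`.
#' @return Invisibly, a list with `files` (paths written) and
#'   `plot_data` (named list of the data behind each figure; pie entries
#'   carry per-sample wedge fractions, bubble entries the per-cell
#'   proportions).
#' @export
render <- function(m, kinds = c("pie", "bar", "heatmap", "heatmap_log",
                                "bubble"),
                   outdir = ".", formats = c("png", "svg")) {
  stopifnot(inherits(m, "merged_table"))
  allowed <- c("pie", "bar", "heatmap", "heatmap_log", "bubble")
  bad <- setdiff(kinds, allowed)
  if (length(bad) > 0) {
    stop("unknown plot kind(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (nrow(m$matrix) == 0 || ncol(m$matrix) == 0) {
    stop("cannot render an empty merged table", call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  plot_data <- list()
  long <- .plot_long(m)

  if ("pie" %in% kinds) {
    pies <- list()
    for (s in colnames(m$matrix)) {
      col <- m$matrix[, s]
      col <- col[col > 0]
      if (length(col) == 0) next
      frac <- col / sum(col)
      df <- data.frame(category = names(frac), fraction = unname(frac),
                       stringsAsFactors = FALSE)
      p <- ggplot2::ggplot(df, ggplot2::aes(x = "", y = fraction,
                                            fill = category)) +
        ggplot2::geom_col(width = 1, color = "white") +
        ggplot2::coord_polar(theta = "y") +
        ggplot2::labs(title = s, x = NULL, y = NULL) +
        ggplot2::theme_void()
      files <- c(files, .save_plot(p, paste0("pie_", s), outdir, formats,
                                   width = 6, height = 6))
      pies[[s]] <- df
    }
    plot_data$pie <- pies
  }

  if ("bar" %in% kinds) {
    p <- ggplot2::ggplot(long, ggplot2::aes(x = category, y = value,
                                            fill = sample)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = "GO slim category",
                    y = if (m$kind == "frequency") "frequency" else "count") +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                         hjust = 1))
    files <- c(files, .save_plot(p, "barplot", outdir, formats, width = 9))
    plot_data$bar <- long
  }

  heat <- function(mat, stem, legend) {
    df <- data.frame(
      category = rep(rownames(mat), times = ncol(mat)),
      sample = rep(colnames(mat), each = nrow(mat)),
      value = as.vector(mat), stringsAsFactors = FALSE)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = sample, y = category,
                                          fill = value)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                   name = legend) +
      ggplot2::labs(x = NULL, y = NULL) +
      ggplot2::theme_minimal()
    files <<- c(files, .save_plot(p, stem, outdir, formats,
                                  height = 0.25 * nrow(mat) + 2.5))
    df
  }
  if ("heatmap" %in% kinds) {
    plot_data$heatmap <- heat(m$matrix, "heatmap", m$kind)
  }
  if ("heatmap_log" %in% kinds) {
    lm <- log_transform(m)
    plot_data$heatmap_log <- heat(lm$matrix, "heatmap_log", "log10(x+1)")
  }

  if ("bubble" %in% kinds) {
    totals <- colSums(m$matrix)
    prop <- sweep(m$matrix, 2, ifelse(totals > 0, totals, 1), "/")
    df <- data.frame(
      category = rep(rownames(prop), times = ncol(prop)),
      sample = rep(colnames(prop), each = nrow(prop)),
      proportion = as.vector(prop), stringsAsFactors = FALSE)
    df <- df[df$proportion > 0, , drop = FALSE]
    p <- ggplot2::ggplot(df, ggplot2::aes(x = sample, y = category,
                                          size = proportion)) +
      ggplot2::geom_point(alpha = 0.75, color = "steelblue") +
      ggplot2::scale_size_area(max_size = 10,
                               name = "proportion of annotations") +
      ggplot2::labs(x = NULL, y = NULL) +
      ggplot2::theme_bw()
    files <- c(files, .save_plot(p, "bubble", outdir, formats,
                                 height = 0.25 * nrow(m$matrix) + 2.5))
    plot_data$bubble <- df
  }

  invisible(list(files = files, plot_data = plot_data))
}
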