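#' Read a BED-like file
#'
#' Tab-separated, 0-based half-open coordinates, no track lines. With 2+
#' numeric columns the second and third are validated as `start < end`
#' intervals (BED3+); point files (`chrom`, `pos`) use `n_fields = 2`.
#' Malformed lines are reported with their line numbers.
#'
#' @param path file path.
#' @param n_fields minimum number of fields required (default 3).
#' @param col_names names for the leading columns; defaults to BED6-style
#'   names truncated to the observed width.
#' @return data.frame sorted by (chrom, start).
#' @export
read_bed <- function(path, n_fields = 3L, col_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, quote = "",
                         comment.char = "#")
  if (ncol(x) < n_fields) {
    stop("expected >= ", n_fields, " tab-separated fields", call. = FALSE)
  }
  default_names <- c("chrom", "start", "end", "name", "score", "strand")
  names(x)[seq_len(min(ncol(x), 6L))] <-
    (col_names %||% default_names)[seq_len(min(ncol(x), 6L))]
  if (!is.numeric(x$start)) stop("non-numeric start coordinates", call. = FALSE)
  bad <- which(x$start < 0)
  if (length(bad)) {
    stop("negative coordinate on line ", bad[1], call. = FALSE)
  }
  if ("end" %in% names(x) && is.numeric(x$end) && n_fields >= 3L) {
    bad <- which(x$start >= x$end)
    if (length(bad)) {
      stop("start >= end on line ", bad[1], call. = FALSE)
    }
  }
  x[order(x$chrom, x$start), , drop = FALSE]
}

#' Write a BED-like data.frame
#'
#' @param df data.frame whose first columns are `chrom`, `start`, ...
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a per-CG count matrix as TSV
#'
#' Sites are rows (`site_id` = `chrom:pos`), samples are columns. A header
#' comment records the chromosome lengths so the matrix round-trips
#' exactly.
#'
#' @param cm a [coverage_matrix()].
#' @param path output path.
#' @export
write_counts <- function(cm, path) {
  stopifnot(inherits(cm, "coverage_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# chrom_lengths=",
                    paste(names(cm$chrom_lengths), unlist(cm$chrom_lengths),
                          sep = ":", collapse = ",")), con)
  df <- data.frame(site_id = paste0(cm$site_chrom, ":", cm$site_pos),
                   cm$counts, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  first <- readLines(path, n = 1L)
  chrom_lengths <- NULL
  if (startsWith(first, "# chrom_lengths=")) {
    spec <- strsplit(sub("# chrom_lengths=", "", first), ",")[[1]]
    parts <- strsplit(spec, ":")
    chrom_lengths <- stats::setNames(
      as.numeric(vapply(parts, `[`, "", 2L)),
      vapply(parts, `[`, "", 1L)
    )
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  id <- strsplit(df$site_id, ":")
  coverage_matrix(
    as.matrix(df[, -1, drop = FALSE]),
    vapply(id, `[`, "", 1L),
    as.integer(vapply(id, `[`, "", 2L)),
    chrom_lengths = chrom_lengths
  )
}

#' Write sample metadata / generic result tables
#'
#' TSV with header; floats at full precision (tables are the machine
#' interface; rounding is left to reports).
#'
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
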