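#' Read binned duplicate-pair counts from a delimited file
#'
#' Canonical layout: three columns `(bin, s, count)` or two columns
#' `(s, count)`, tab-separated by default, with optional `#` comment lines
#' and an optional header. Malformed rows are rejected with their line
#' numbers.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param bin_width optional override; otherwise inferred from the spacing
#'   of `s`.
#' @return A [binned_counts()] object.
#' @export
read_counts <- function(path, dialect = c("tsv", "csv"), bin_width = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  line_no <- which(keep)
  if (!length(lines)) stop("no data rows in ", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  first <- suppressWarnings(as.numeric(fields[[1]]))
  has_header <- any(is.na(first))
  if (has_header) {
    header <- tolower(trimws(fields[[1]]))
    fields <- fields[-1]; line_no <- line_no[-1]
  } else {
    header <- if (length(fields[[1]]) >= 3) c("bin", "s", "count")
              else c("s", "count")
  }
  if (!length(fields)) stop("file contains a header but no data rows: ", path)
  s_col <- match("s", header)
  c_col <- match("count", header)
  if (is.na(s_col) || is.na(c_col))
    stop("could not resolve columns `s` and `count` in ", path,
         " (found: ", paste(header, collapse = ", "), ")")
  n_col <- length(header)
  s <- numeric(length(fields)); cnt <- numeric(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != n_col)
      stop(sprintf("line %d: expected %d fields, found %d", line_no[i],
                   n_col, length(f)))
    vals <- suppressWarnings(as.numeric(f))
    if (is.na(vals[s_col]) || is.na(vals[c_col]))
      stop(sprintf("line %d: non-numeric value in `s` or `count`", line_no[i]))
    s[i] <- vals[s_col]; cnt[i] <- vals[c_col]
  }
  bad <- which(cnt < 0 | cnt != round(cnt))
  if (length(bad))
    stop(sprintf("line %d: count must be a non-negative integer (got %g)",
                 line_no[bad[1]], cnt[bad[1]]))
  if (length(s) > 1 && any(diff(s) <= 0))
    stop(sprintf("line %d: `s` values must be strictly increasing",
                 line_no[which(diff(s) <= 0)[1] + 1]))
  if (is.null(bin_width))
    bin_width <- if (length(s) > 1) stats::median(diff(s)) else s[1]
  binned_counts(cnt, s = s, bin_width = bin_width)
}

#' Write binned counts to a delimited file
#'
#' Inverse of [read_counts()]: writes `(bin, s, count)` with a header and a
#' `#` comment recording the producing package version.
#'
#' @param data a [binned_counts()].
#' @param path output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @param comment optional extra `#` comment lines (e.g. simulation seed).
#' @export
write_counts <- function(data, path, dialect = c("tsv", "csv"),
                         comment = character(0)) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(data, "binned_counts"))
  sep <- if (dialect == "tsv") "\t" else ","
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# subfunr %s binned duplicate-pair counts",
                       as.character(utils::packageVersion("subfunr"))),
               if (length(comment)) paste0("# ", comment) else character(0),
               paste(c("bin", "s", "count"), collapse = sep),
               sprintf(paste0("%d", sep, "%.12g", sep, "%d"),
                       seq_along(data$s), data$s, data$counts)), con)
  invisible(path)
}
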