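#' Read a subject table
#'
#' Tab-separated table with required columns `id`, `site`, `diagnosis`,
#' `age`, `sex` (optionally `mmse`, `moca`). Malformed rows are reported
#' with their line number.
#'
#' @param path File path.
#' @return Tibble of subject records.
#' @export
read_subject_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) < 2) stopf("%s: no subject rows", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  required <- c("id", "site", "diagnosis", "age", "sex")
  missing <- setdiff(required, header)
  if (length(missing)) {
    stopf("%s: missing required column(s): %s", path,
          paste(missing, collapse = ", "))
  }
  n_col <- length(header)
  bad <- which(lengths(fields[-1]) != n_col)
  if (length(bad)) {
    stopf("%s: malformed row at line %d (%d fields, expected %d)",
          path, bad[1] + 1L, lengths(fields[-1])[bad[1]], n_col)
  }
  body <- do.call(rbind, fields[-1])
  colnames(body) <- header
  out <- as_tibble(as.data.frame(body, stringsAsFactors = FALSE))
  for (col in intersect(c("age", "mmse", "moca", "severity"), header)) {
    val <- suppressWarnings(as.numeric(out[[col]]))
    if (anyNA(val) && !anyNA(out[[col]])) {
      stopf("%s: non-numeric value in column '%s'", path, col)
    }
    out[[col]] <- val
  }
  out
}

#' Read a delimited numeric matrix
#'
#' Whitespace/tab-delimited text, one matrix row per line. Ragged rows are
#' reported with their line number; an expected region count can be
#' enforced.
#'
#' @param path File path.
#' @param n_regions Optional expected number of rows.
#' @return Numeric matrix.
#' @export
read_matrix <- function(path, n_regions = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("%s: empty matrix", path)
  fields <- strsplit(trimws(lines), "[\t ]+")
  widths <- lengths(fields)
  if (length(unique(widths)) != 1) {
    bad <- which(widths != widths[1])[1]
    stopf("%s: truncated or ragged row at line %d (%d fields, expected %d)",
          path, bad, widths[bad], widths[1])
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              nrow = length(fields), byrow = TRUE)
  if (anyNA(m)) stopf("%s: non-numeric entries in matrix", path)
  if (!is.null(n_regions) && nrow(m) != n_regions) {
    stopf("%s: %d rows but %d regions expected", path, nrow(m), n_regions)
  }
  m
}

#' Write a numeric matrix as delimited text
#'
#' @param m Numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    stopf("%s: GMT line %d has fewer than 3 fields", path, short[1])
  }
  stats::setNames(
    lapply(fields, function(f) unique(f[-(1:2)])),
    vapply(fields, `[[`, character(1), 1)
  )
}

#' Pearson similarity between two regional maps
#'
#' Used for sensitivity analyses (e.g. comparing difference maps across
#' network densities). Constant maps have no defined correlation and are
#' reported as missing.
#'
#' @param map_a,map_b Equal-length numeric vectors.
#' @return Pearson r, or `NA` with a warning for constant input.
#' @export
similarity_map <- function(map_a, map_b) {
  if (length(map_a) != length(map_b)) {
    stopf("maps differ in length (%d vs %d)", length(map_a), length(map_b))
  }
  if (sd(map_a) == 0 || sd(map_b) == 0) {
    warnf("constant map: similarity undefined, reported as missing")
    return(NA_real_)
  }
  cor(map_a, map_b)
}
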