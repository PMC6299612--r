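#' Read 12-column tabular similarity-search results
#'
#' Consumes the standard 12-column tab-separated output of protein similarity
#' searches (query id, subject id, percent identity, alignment length,
#' mismatches, gap opens, query start, query end, subject start, subject end,
#' E-value, bit score). Rows are kept in input order.
#'
#' @param input path to the tabular file, or a character vector of lines.
#' @param query_lengths named numeric vector or two-column data.frame mapping
#'   query id to query length (residues); queries absent from the map get
#'   `NA` query length and are flagged in the `coverage_defined` column.
#' @return data.frame with one row per hit: `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `mismatches`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `evalue`, `bitscore`,
#'   `query_length`, `coverage_defined`.
#' @export
read_hits_tabular <- function(input, query_lengths = NULL) {
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input)) {
    lines <- readLines(input)
  } else {
    lines <- unlist(strsplit(input, "\n"))
  }
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    i <- which(nf != 12L)[1L]
    stop("malformed hit row at line ", i, ": expected 12 tab-separated ",
         "columns, found ", nf[i])
  }
  m <- do.call(rbind, fields)
  num <- function(j, what) {
    x <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(x)) {
      stop("malformed hit row at line ", which(is.na(x))[1L],
           ": non-numeric ", what)
    }
    x
  }
  hits <- data.frame(
    query_id = m[, 1L], subject_id = m[, 2L],
    percent_identity = num(3L, "percent identity"),
    alignment_length = num(4L, "alignment length"),
    mismatches = num(5L, "mismatch count"),
    gap_opens = num(6L, "gap open count"),
    q_start = num(7L, "query start"), q_end = num(8L, "query end"),
    s_start = num(9L, "subject start"), s_end = num(10L, "subject end"),
    evalue = num(11L, "E-value"), bitscore = num(12L, "bit score"),
    stringsAsFactors = FALSE
  )
  bad <- which(hits$evalue < 0)
  if (length(bad)) stop("malformed hit row at line ", bad[1L],
                        ": negative E-value")
  bad <- which(hits$percent_identity < 0 | hits$percent_identity > 100)
  if (length(bad)) stop("malformed hit row at line ", bad[1L],
                        ": percent identity outside [0, 100]")
  bad <- which(hits$q_start > hits$q_end | hits$s_start > hits$s_end)
  if (length(bad)) stop("malformed hit row at line ", bad[1L],
                        ": span start greater than end")
  bad <- which(hits$alignment_length < 1)
  if (length(bad)) stop("malformed hit row at line ", bad[1L],
                        ": alignment length < 1")
  ql <- normalize_query_lengths(query_lengths)
  hits$query_length <- unname(ql[hits$query_id])
  hits$coverage_defined <- !is.na(hits$query_length)
  hits
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             percent_identity = numeric(), alignment_length = numeric(),
             mismatches = numeric(), gap_opens = numeric(),
             q_start = numeric(), q_end = numeric(),
             s_start = numeric(), s_end = numeric(),
             evalue = numeric(), bitscore = numeric(),
             query_length = numeric(), coverage_defined = logical(),
             stringsAsFactors = FALSE)
}

normalize_query_lengths <- function(query_lengths) {
  if (is.null(query_lengths)) return(stats::setNames(numeric(), character()))
  if (is.data.frame(query_lengths)) {
    return(stats::setNames(as.numeric(query_lengths[[2L]]),
                           as.character(query_lengths[[1L]])))
  }
  stats::setNames(as.numeric(query_lengths), names(query_lengths))
}

#' Write hits in 12-column tabular form
#'
#' @param hits data.frame as returned by [read_hits_tabular()].
#' @param path output path, or `NULL` to return lines.
#' @return invisibly, the lines written.
#' @export
write_hits_tabular <- function(hits, path = NULL) {
  cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start",
            "s_end", "evalue", "bitscore")
  lines <- apply(hits[, cols, drop = FALSE], 1L, paste, collapse = "\t")
  lines <- as.character(lines)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
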