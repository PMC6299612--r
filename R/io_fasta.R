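#' Sequence records
#'
#' A `pld_records` object is a plain `data.frame` with one row per protein
#' sequence and columns:
#' \describe{
#'   \item{id}{accession-like identifier, unique within the set}
#'   \item{residues}{amino-acid string (20 standard letters plus `X`)}
#'   \item{taxon}{list column; ordered lineage path, most inclusive rank
#'     first (e.g. kingdom, phylum, class, ...)}
#'   \item{evidence}{list column; subset of `genome`, `transcriptome`,
#'     `EST`, `proteome` (may be empty = unknown)}
#'   \item{source_note}{free-text provenance note}
#' }
#'
#' @param id,residues character vectors of equal length.
#' @param taxon list of character vectors (or a single vector recycled).
#' @param evidence list of character vectors.
#' @param source_note character vector.
#' @return a `pld_records` data.frame.
#' @export
pld_records <- function(id, residues, taxon = NULL, evidence = NULL,
                        source_note = NULL) {
  n <- length(id)
  stopifnot(length(residues) == n)
  if (is.null(taxon)) taxon <- rep(list(character()), n)
  if (is.character(taxon)) taxon <- rep(list(taxon), n)
  if (is.null(evidence)) evidence <- rep(list(character()), n)
  if (is.character(evidence)) evidence <- rep(list(evidence), n)
  if (is.null(source_note)) source_note <- rep("", n)
  rec <- data.frame(id = as.character(id), residues = as.character(residues),
                    stringsAsFactors = FALSE)
  rec$taxon <- taxon
  rec$evidence <- evidence
  rec$source_note <- as.character(source_note)
  validate_records(rec)
  class(rec) <- c("pld_records", "data.frame")
  rec
}

AA_ALPHABET_20X <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                     "R","S","T","V","W","Y","X")

validate_records <- function(rec) {
  if (anyDuplicated(rec$id)) {
    dup <- rec$id[duplicated(rec$id)][1L]
    stop("duplicate sequence id: ", dup)
  }
  if (any(!nzchar(rec$residues))) {
    stop("empty sequence for id: ", rec$id[!nzchar(rec$residues)][1L])
  }
  bad <- vapply(strsplit(rec$residues, ""), function(x)
    any(!x %in% AA_ALPHABET_20X), logical(1))
  if (any(bad)) {
    stop("invalid residue characters in sequence: ", rec$id[bad][1L])
  }
  invisible(rec)
}

EVIDENCE_TYPES <- c("genome", "transcriptome", "EST", "proteome")

#' Read protein FASTA into sequence records
#'
#' Headers are parsed as `>id free text [lineage;separated;by;semicolons]`,
#' with an optional `evidence=type1+type2` token in the free text. The
#' bracketed suffix, when present, becomes the ordered lineage path. Input
#' order is preserved and a [write_fasta()] round trip reproduces the input
#' up to line wrapping.
#'
#' @param input path to a FASTA file, or a character vector of FASTA lines
#'   (useful for tests).
#' @return a [pld_records()] data.frame.
#' @export
read_fasta <- function(input) {
  path <- as_input_path(input)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) {
    return(pld_records(character(), character()))
  }
  headers <- names(set)
  parsed <- lapply(headers, parse_fasta_header)
  pld_records(
    id = vapply(parsed, `[[`, "", "id"),
    residues = toupper(as.character(set)),
    taxon = lapply(parsed, `[[`, "taxon"),
    evidence = lapply(parsed, `[[`, "evidence"),
    source_note = vapply(parsed, `[[`, "", "note")
  )
}

as_input_path <- function(input) {
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input)) {
    return(input)
  }
  path <- tempfile(fileext = ".fa")
  lines <- if (length(input)) unlist(strsplit(input, "\n")) else character()
  writeLines(lines, path)
  path
}

parse_fasta_header <- function(h) {
  h <- trimws(h)
  id <- sub("\\s.*$", "", h)
  rest <- trimws(sub("^\\S+", "", h))
  taxon <- character()
  m <- regmatches(rest, regexpr("\\[[^][]*\\]\\s*$", rest))
  if (length(m) == 1L && nzchar(m)) {
    taxon <- trimws(strsplit(substr(m, 2L, nchar(m) - 1L), ";")[[1]])
    taxon <- taxon[nzchar(taxon)]
    rest <- trimws(sub("\\[[^][]*\\]\\s*$", "", rest))
  }
  evidence <- character()
  em <- regmatches(rest, regexpr("evidence=\\S+", rest))
  if (length(em) == 1L && nzchar(em)) {
    evidence <- strsplit(sub("^evidence=", "", em), "\\+")[[1]]
    evidence <- intersect(evidence, EVIDENCE_TYPES)
    rest <- trimws(gsub("evidence=\\S+", "", rest))
  }
  list(id = id, taxon = taxon, evidence = evidence, note = rest)
}

#' Write sequence records as FASTA
#'
#' @param records a [pld_records()] data.frame.
#' @param path output file path, or `NULL` to return the lines.
#' @param width line-wrap width for residues.
#' @return invisibly, the FASTA lines.
#' @export
write_fasta <- function(records, path = NULL, width = 60L) {
  lines <- unlist(lapply(seq_len(nrow(records)), function(i) {
    hdr <- paste0(">", records$id[i])
    note <- records$source_note[i]
    if (nzchar(note)) hdr <- paste(hdr, note)
    ev <- records$evidence[[i]]
    if (length(ev)) hdr <- paste0(hdr, " evidence=", paste(ev, collapse = "+"))
    tax <- records$taxon[[i]]
    if (length(tax)) hdr <- paste0(hdr, " [", paste(tax, collapse = ";"), "]")
    body <- records$residues[i]
    starts <- seq(1L, nchar(body), by = width)
    c(hdr, substring(body, starts, pmin(starts + width - 1L, nchar(body))))
  }))
  if (length(lines) == 0L) lines <- character()
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Lineage comparison at a fixed rank
#'
#' Lineages are ordered paths; two records belong to the same group at rank
#' index `rank` when their paths agree on the first `rank` elements.
#'
#' @param a,b character vectors (lineage paths).
#' @param rank 1-based rank index (e.g. 2 = phylum when paths start at
#'   kingdom).
#' @return `TRUE`, `FALSE`, or `NA` when either lineage is too short.
#' @export
same_lineage_at <- function(a, b, rank = 2L) {
  if (length(a) < rank || length(b) < rank) return(NA)
  all(a[seq_len(rank)] == b[seq_len(rank)])
}
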