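#' Find open reading frames in a nucleotide sequence
#'
#' Scans all six frames of both strands for open reading frames under the
#' standard genetic code. By default an ORF runs from a Met to the next stop
#' codon; with `allow_partial = TRUE`, ORFs truncated at either sequence
#' edge (no Met, or no stop) are also reported, which suits incomplete
#' transcriptome fragments.
#'
#' @param sequence DNA string over `A`, `C`, `G`, `T`, `N` (case
#'   insensitive). Ambiguous codons translate to `X`.
#' @param min_aa_length minimum peptide length to report.
#' @param allow_partial allow edge-truncated ORFs.
#' @return data.frame sorted by peptide length (descending) with columns
#'   `peptide`, `frame` (+1..+3 forward, -1..-3 reverse), `start`, `end`
#'   (1-based inclusive coordinates of the coding region, excluding the stop
#'   codon, always on the input strand with `start <= end`), and `partial`.
#' @export
find_orfs <- function(sequence, min_aa_length = 1L, allow_partial = FALSE) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    stop("non-DNA characters (other than N) in input sequence")
  }
  L <- nchar(sequence)
  fwd <- sequence
  rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
  out <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) fwd else rev
    for (f in 1:3) {
      n_codons <- (nchar(s) - f + 1L) %/% 3L
      if (n_codons < 1L) next
      sub <- substr(s, f, f + 3L * n_codons - 1L)
      aa <- suppressWarnings(as.character(Biostrings::translate(
        Biostrings::DNAString(sub), if.fuzzy.codon = "solve")))
      orfs <- scan_frame(aa, allow_partial)
      if (nrow(orfs) == 0L) next
      # codon k (1-based) occupies strand positions f+3(k-1) .. f+3k-1
      st_strand <- f + 3L * (orfs$aa_start - 1L)
      en_strand <- f + 3L * orfs$aa_end - 1L
      if (strand == 1L) {
        st <- st_strand; en <- en_strand
      } else {
        st <- L + 1L - en_strand; en <- L + 1L - st_strand
      }
      out[[length(out) + 1L]] <- data.frame(
        peptide = orfs$peptide, frame = strand * f,
        start = st, end = en, partial = orfs$partial,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(peptide = character(), frame = integer(), start = integer(),
               end = integer(), partial = logical(), stringsAsFactors = FALSE)
  res <- res[nchar(res$peptide) >= min_aa_length, , drop = FALSE]
  res <- res[order(-nchar(res$peptide), res$frame, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Scan one translated frame for ORFs. Returns aa coordinates within the
# frame (1-based codon indices, stop codon excluded).
scan_frame <- function(aa, allow_partial) {
  chars <- strsplit(aa, "")[[1]]
  stops <- which(chars == "*")
  seg_starts <- c(1L, stops + 1L)
  seg_ends <- c(stops - 1L, length(chars))
  has_stop <- c(rep(TRUE, length(stops)), FALSE)
  res <- list()
  for (k in seq_along(seg_starts)) {
    a <- seg_starts[k]; b <- seg_ends[k]
    if (a > b) next
    mets <- which(chars[a:b] == "M")
    partial_n <- FALSE
    if (length(mets)) {
      start <- a + mets[1L] - 1L
    } else if (allow_partial && a == 1L) {
      start <- a
      partial_n <- TRUE
    } else {
      next
    }
    if (!has_stop[k] && !allow_partial) next
    res[[length(res) + 1L]] <- data.frame(
      peptide = paste(chars[start:b], collapse = ""),
      aa_start = start, aa_end = b,
      partial = partial_n || !has_stop[k],
      stringsAsFactors = FALSE)
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(peptide = character(), aa_start = integer(),
               aa_end = integer(), partial = logical(),
               stringsAsFactors = FALSE)
}
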