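#' Read a rooted Newick tree
#'
#' Thin wrapper around [ape::read.tree()] adding the validation the
#' reconciliation functions rely on: exactly one root, unique tip labels,
#' and a position-annotated error for unbalanced parentheses. Polytomies
#' are permitted.
#'
#' @param text Newick string (or a path to a file containing one).
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(text) {
  if (length(text) == 1L && !grepl("[();]", text) && file.exists(text)) {
    text <- paste(readLines(text), collapse = "")
  }
  check_parens(text)
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("Newick parse error")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip label: ", tree$tip.label[duplicated(tree$tip.label)][1L])
  }
  tree
}

check_parens <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("Newick parse error: unbalanced ')' at position ", i)
      }
    }
  }
  if (depth != 0L) {
    stop("Newick parse error: ", depth, " unclosed '(' at end of input")
  }
  invisible(TRUE)
}

#' Write a tree as Newick
#'
#' @param tree a `phylo` object.
#' @param path output path, or `NULL` to return the string.
#' @return invisibly, the Newick string.
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree)
  if (!is.null(path)) writeLines(s, path)
  invisible(s)
}

#' Read / write a presence/absence matrix
#'
#' TSV with a `taxon` column naming tree tips and one column per gene
#' family holding `present`, `absent`, or `unknown` (alternatively `1`,
#' `0`, `NA`).
#'
#' @param path TSV path (or character vector of lines for `read_presence`).
#' @return data.frame with `taxon` plus one character column per family.
#' @export
read_presence <- function(path) {
  if (length(path) > 1L || grepl("\n", path)) {
    tc <- textConnection(paste(path, collapse = "\n"))
    on.exit(close(tc))
    df <- utils::read.delim(tc, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  stopifnot("taxon" %in% names(df))
  for (j in setdiff(names(df), "taxon")) {
    df[[j]] <- normalize_states(df[[j]])
  }
  df
}

normalize_states <- function(x) {
  if (is.numeric(x)) {
    out <- ifelse(is.na(x), "unknown", ifelse(x > 0, "present", "absent"))
    return(out)
  }
  x <- tolower(trimws(as.character(x)))
  x[x %in% c("1", "present", "p", "yes")] <- "present"
  x[x %in% c("0", "absent", "a", "no")] <- "absent"
  x[x %in% c("", "na", "unknown", "?")] <- "unknown"
  bad <- setdiff(unique(x), c("present", "absent", "unknown"))
  if (length(bad)) stop("unrecognized presence state: ", bad[1L])
  x
}

#' @rdname read_presence
#' @param presence data.frame as returned by `read_presence`.
#' @export
write_presence <- function(presence, path) {
  utils::write.table(presence, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
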