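# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately re-derive results by enumeration, not by calling the
# package's own algorithms.

# --- alignment oracle -------------------------------------------------------

blosum62_oracle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# Enumerates every ends-free global alignment of a and b under BLOSUM62
# with affine gaps (open 10, extend 1; a gap of length L costs 10 + L).
# Returns the identities (terminal-overhang columns excluded) of all
# co-optimal alignments.
brute_identity_set <- function(a, b, gap_open = 10, gap_ext = 1) {
  B <- blosum62_oracle()
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  best <- -Inf
  alns <- list()
  rec <- function(i, j, score, state, pa, pb) {
    if (i == n || j == m) {
      # trailing overhang free
      if (score > best + 1e-9) {
        best <<- score
        alns <<- list(list(pa = pa, pb = pb))
      } else if (abs(score - best) <= 1e-9) {
        alns[[length(alns) + 1L]] <<- list(pa = pa, pb = pb)
      }
      return()
    }
    rec(i + 1, j + 1, score + B[ca[i + 1], cb[j + 1]], 1L,
        c(pa, ca[i + 1]), c(pb, cb[j + 1]))
    rec(i, j + 1, score - (if (state == 2L) gap_ext else gap_open + gap_ext),
        2L, c(pa, "-"), c(pb, cb[j + 1]))
    rec(i + 1, j, score - (if (state == 3L) gap_ext else gap_open + gap_ext),
        3L, c(pa, ca[i + 1]), c(pb, "-"))
  }
  # leading overhang free: start with i0 residues of a (or j0 of b) dangling
  for (i0 in 0:n) rec(i0, 0L, 0, 0L, character(), character())
  for (j0 in 1:m) rec(0L, j0, 0, 0L, character(), character())
  idents <- vapply(alns, function(al) {
    oracle_alignment_identity(al$pa, al$pb)
  }, numeric(1))
  unique(round(idents, 9))
}

# identity over aligned columns minus terminal-overhang gap columns
# (independent reimplementation of the definition)
oracle_alignment_identity <- function(p, s) {
  n <- length(p)
  if (n == 0L) return(0)
  gap <- p == "-" | s == "-"
  lead <- 0L
  while (lead < n && gap[lead + 1L]) lead <- lead + 1L
  trail <- 0L
  while (trail < n - lead && gap[n - trail]) trail <- trail + 1L
  keep <- seq.int(lead + 1L, length.out = n - lead - trail)
  if (length(keep) == 0L) return(0)
  100 * sum(p[keep] == s[keep] & p[keep] != "-") / length(keep)
}

# --- reconciliation oracles -------------------------------------------------

oracle_tree_info <- function(tree) {
  ntip <- ape::Ntip(tree)
  list(ntip = ntip, n_nodes = ntip + tree$Nnode, edges = tree$edge,
       root = ntip + 1L)
}

# Minimum losses over all ancestral assignments with a single origin at the
# root (root present, no absent->present edge anywhere).
oracle_dollo_root <- function(tree, present_tips) {
  info <- oracle_tree_info(tree)
  states <- ifelse(tree$tip.label %in% present_tips, 1L, 0L)
  n_int <- tree$Nnode
  best <- Inf
  for (mask in 0:(2^n_int - 1L)) {
    assign <- c(states, as.integer(intToBits(mask))[seq_len(n_int)])
    if (assign[info$root] != 1L) next
    gains <- losses <- 0L
    ok <- TRUE
    for (e in seq_len(nrow(info$edges))) {
      p <- assign[info$edges[e, 1L]]; ch <- assign[info$edges[e, 2L]]
      if (p == 0L && ch == 1L) { ok <- FALSE; break }
      if (p == 1L && ch == 0L) losses <- losses + 1L
    }
    if (ok && losses < best) best <- losses
  }
  best
}

# Minimum total cost over all ancestral assignments with asymmetric costs;
# a present root is charged one origin gain. Also returns the number of
# co-optimal assignments.
oracle_min_cost <- function(tree, present_tips, gain, loss) {
  info <- oracle_tree_info(tree)
  states <- ifelse(tree$tip.label %in% present_tips, 1L, 0L)
  n_int <- tree$Nnode
  best <- Inf; n_best <- 0L
  for (mask in 0:(2^n_int - 1L)) {
    assign <- c(states, as.integer(intToBits(mask))[seq_len(n_int)])
    cost <- if (assign[info$root] == 1L) gain else 0
    for (e in seq_len(nrow(info$edges))) {
      p <- assign[info$edges[e, 1L]]; ch <- assign[info$edges[e, 2L]]
      if (p == 0L && ch == 1L) cost <- cost + gain
      if (p == 1L && ch == 0L) cost <- cost + loss
      if (cost > best) break
    }
    if (cost < best - 1e-9) { best <- cost; n_best <- 1L }
    else if (abs(cost - best) <= 1e-9) n_best <- n_best + 1L
  }
  list(cost = best, n_co_optimal = n_best)
}

# random rooted tree with unique single-letter-ish tip labels
random_tree <- function(n, seed) {
  set.seed(seed)
  tree <- ape::rtree(n, br = NULL)
  tree$tip.label <- paste0("t", seq_len(n))
  tree
}
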