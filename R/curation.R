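## Curation of candidate family sequences: redundancy, completeness,
## active-site divergence, cross-taxon contamination, and evidence-based
## confidence.

blosum62 <- local({
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

#' Curation policy
#'
#' @param redundancy_identity percent identity above which two sequences are
#'   redundant (90 general; 95 for densely sampled groups).
#' @param min_length minimum sequence length in residues.
#' @param min_domain_fraction minimum covered fraction of the reference
#'   domain.
#' @param contaminant_identity percent identity above which a cross-taxon
#'   match is flagged as probable contamination.
#' @param required_evidence_types distinct evidence types needed for a taxon
#'   group to count as confidently represented.
#' @param compat_rank lineage rank index at which taxa must agree to be
#'   exempt from contaminant flagging (2 = phylum).
#' @param exceptions character vector of ids exempt from removal.
#' @return a `pld_curation_policy` list.
#' @export
curation_policy <- function(redundancy_identity = 90, min_length = 225L,
                            min_domain_fraction = 0.75,
                            contaminant_identity = 50,
                            required_evidence_types = 2L,
                            compat_rank = 2L, exceptions = character()) {
  stopifnot(redundancy_identity > 0, redundancy_identity <= 100,
            min_length > 0, min_domain_fraction > 0,
            min_domain_fraction <= 1, contaminant_identity > 0,
            contaminant_identity <= 100)
  structure(list(redundancy_identity = redundancy_identity,
                 min_length = as.integer(min_length),
                 min_domain_fraction = min_domain_fraction,
                 contaminant_identity = contaminant_identity,
                 required_evidence_types = as.integer(required_evidence_types),
                 compat_rank = as.integer(compat_rank),
                 exceptions = exceptions),
            class = "pld_curation_policy")
}

#' Percent identity from an ends-free global alignment
#'
#' Aligns the two sequences globally with free terminal gaps (BLOSUM62, gap
#' opening 10, extension 1) and returns 100 x matches / aligned columns,
#' where columns inside a terminal overhang of either sequence are excluded
#' from the denominator (so fragments are scored over their overlap) and
#' internal gap columns count as non-matching. Symmetric; 100 iff the
#' sequences are identical.
#'
#' @param a,b amino-acid strings.
#' @return percent identity in [0, 100].
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  if (a == b) return(100)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 1,
    type = "overlap")
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  alignment_identity(p, s)
}

# identity over aligned columns, excluding terminal-overhang gap columns
alignment_identity <- function(p, s) {
  n <- length(p)
  if (n == 0L) return(0)
  gap_p <- p == "-"; gap_s <- s == "-"
  lead <- 0L
  while (lead < n && (gap_p[lead + 1L] || gap_s[lead + 1L])) lead <- lead + 1L
  trail <- 0L
  while (trail < n - lead && (gap_p[n - trail] || gap_s[n - trail]))
    trail <- trail + 1L
  keep <- seq.int(lead + 1L, length.out = n - lead - trail)
  if (length(keep) == 0L) return(0)
  100 * sum(p[keep] == s[keep] & !gap_p[keep]) / length(keep)
}

#' Greedy redundancy filtering
#'
#' Records are visited by decreasing length (ties broken by id); a record
#' is kept unless its identity to an already-kept representative reaches
#' the threshold, in which case it maps to that representative. Policy
#' exceptions are always kept.
#'
#' @param records a [pld_records()] data.frame.
#' @param threshold percent identity threshold.
#' @param exceptions ids always kept.
#' @return list with `kept` (record ids), `removed` (data.frame: `id`,
#'   `representative`, `identity`).
#' @export
filter_redundancy <- function(records, threshold = 90,
                              exceptions = character()) {
  if (nrow(records) == 0L) {
    return(list(kept = character(),
                removed = data.frame(id = character(),
                                     representative = character(),
                                     identity = numeric(),
                                     stringsAsFactors = FALSE)))
  }
  ord <- order(-nchar(records$residues), records$id)
  kept <- character(); removed <- list()
  for (i in ord) {
    id <- records$id[i]
    if (id %in% exceptions) { kept <- c(kept, id); next }
    rep_hit <- NA_character_; rep_ident <- NA_real_
    for (k in kept) {
      ident <- pairwise_identity(records$residues[i],
                                 records$residues[records$id == k])
      if (ident >= threshold) { rep_hit <- k; rep_ident <- ident; break }
    }
    if (is.na(rep_hit)) {
      kept <- c(kept, id)
    } else {
      removed[[length(removed) + 1L]] <- data.frame(
        id = id, representative = rep_hit, identity = rep_ident,
        stringsAsFactors = FALSE)
    }
  }
  list(kept = kept,
       removed = if (length(removed)) do.call(rbind, removed) else
         data.frame(id = character(), representative = character(),
                    identity = numeric(), stringsAsFactors = FALSE))
}

#' Remove fragmentary sequences
#'
#' A record is removed when it is shorter than `min_length` residues or
#' covers less than `min_domain_fraction` of the reference domain, unless
#' listed in the policy exceptions (kept and flagged). Records whose domain
#' mapping shows an internal deletion spanning an active-site position are
#' removed with reason "active-site deletion".
#'
#' @param records a [pld_records()] data.frame.
#' @param domain_info data.frame with columns `id`, `covered_fraction`, and
#'   optionally `active_site_deleted` (logical), typically derived from
#'   [map_to_reference()].
#' @param policy a [curation_policy()].
#' @return list with `kept` (ids), `flagged` (kept exceptions), `removed`
#'   (data.frame: `id`, `reason`).
#' @export
filter_fragments <- function(records, domain_info,
                             policy = curation_policy()) {
  missing <- setdiff(records$id, domain_info$id)
  if (length(missing)) {
    stop("records missing from domain_info: ",
         paste(missing, collapse = ", "))
  }
  info <- domain_info[match(records$id, domain_info$id), , drop = FALSE]
  asd <- if ("active_site_deleted" %in% names(info))
    isTRUE_vec(info$active_site_deleted) else rep(FALSE, nrow(records))
  too_short <- nchar(records$residues) < policy$min_length
  too_partial <- info$covered_fraction < policy$min_domain_fraction
  reason <- ifelse(asd, "active-site deletion",
            ifelse(too_short, "short sequence",
            ifelse(too_partial, "partial domain", NA_character_)))
  exempt <- records$id %in% policy$exceptions & !is.na(reason)
  removed_idx <- which(!is.na(reason) & !exempt)
  list(kept = records$id[is.na(reason) | exempt],
       flagged = records$id[exempt],
       removed = data.frame(id = records$id[removed_idx],
                            reason = reason[removed_idx],
                            stringsAsFactors = FALSE))
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Canonical active-site specification
#'
#' @param core_positions positions whose joint nonconservative divergence
#'   marks a record as divergent.
#' @return a `pld_active_site_spec` list: named canonical residues and the
#'   core subset.
#' @export
active_site_spec <- function(core_positions = c("His12", "Glu32", "His47")) {
  canonical <- c(His12 = "H", Glu32 = "E", Asp34 = "D", His47 = "H",
                 Asp91 = "D", Lys93 = "K")
  stopifnot(all(core_positions %in% names(canonical)))
  structure(list(canonical = canonical, core_positions = core_positions),
            class = "pld_active_site_spec")
}

#' Classify active-site residues of a mapped record
#'
#' Each canonical position is scored against the record residue it maps to:
#' `canonical` if equal, `conservative` if the BLOSUM62 substitution score
#' is positive, `nonconservative` if it is zero or negative, `missing` if
#' the position is gapped. The verdict is `divergent` when every core
#' position (His12, Glu32, His47 by default) is nonconservative or missing.
#'
#' @param record one-row [pld_records()] (or an amino-acid string).
#' @param site_positions named integer vector mapping position labels to
#'   record coordinates (`NA` = gapped), e.g. from [map_to_reference()].
#' @param spec an [active_site_spec()].
#' @return list with `states` (named character vector) and `verdict`
#'   (`"normal"` or `"divergent"`).
#' @export
screen_active_site <- function(record, site_positions,
                               spec = active_site_spec()) {
  residues <- if (is.data.frame(record)) record$residues[1L] else record
  chars <- strsplit(residues, "")[[1]]
  B <- blosum62()
  states <- vapply(names(spec$canonical), function(lbl) {
    pos <- site_positions[[lbl]]
    if (is.null(pos) || is.na(pos) || pos < 1 || pos > length(chars)) {
      return("missing")
    }
    aa <- chars[pos]
    can <- spec$canonical[[lbl]]
    if (aa == can) return("canonical")
    if (!aa %in% rownames(B)) return("nonconservative")
    if (B[aa, can] > 0) "conservative" else "nonconservative"
  }, "")
  core <- states[spec$core_positions]
  verdict <- if (all(core %in% c("nonconservative", "missing")))
    "divergent" else "normal"
  list(states = states, verdict = verdict)
}

#' Flag probable cross-taxon contaminants
#'
#' A record is flagged when its identity to a reference record exceeds the
#' contaminant threshold while the two lineages differ at the compatibility
#' rank (phylum by default). Identical cross-lineage pairs are always
#' flagged regardless of threshold. Records lacking lineage annotation are
#' skipped with a warning.
#'
#' @param records candidate [pld_records()].
#' @param references reference [pld_records()] (e.g. known mite sequences).
#' @param policy a [curation_policy()].
#' @return data.frame with `id`, `reference`, `identity`, `record_lineage`,
#'   `reference_lineage`.
#' @export
flag_contaminants <- function(records, references,
                              policy = curation_policy()) {
  out <- list()
  for (i in seq_len(nrow(records))) {
    lin <- records$taxon[[i]]
    if (length(lin) < policy$compat_rank) {
      warning("record ", records$id[i], " lacks lineage at rank ",
              policy$compat_rank, "; skipped")
      next
    }
    for (j in seq_len(nrow(references))) {
      rlin <- references$taxon[[j]]
      if (length(rlin) < policy$compat_rank) next
      same <- same_lineage_at(lin, rlin, policy$compat_rank)
      if (isTRUE(same)) next
      ident <- pairwise_identity(records$residues[i],
                                 references$residues[j])
      if (ident > policy$contaminant_identity || ident == 100) {
        out[[length(out) + 1L]] <- data.frame(
          id = records$id[i], reference = references$id[j],
          identity = ident,
          record_lineage = paste(lin, collapse = ";"),
          reference_lineage = paste(rlin, collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(id = character(), reference = character(),
               identity = numeric(), record_lineage = character(),
               reference_lineage = character(), stringsAsFactors = FALSE)
}

#' Label records by evidence-based confidence
#'
#' Evidence types are aggregated per taxon group (lineage prefix up to
#' `group_rank`); a record is low-confidence when its group is supported by
#' fewer than `required_evidence_types` distinct types (e.g. a transcriptome-
#' only phylum).
#'
#' @param records a [pld_records()] data.frame.
#' @param policy a [curation_policy()].
#' @param group_rank lineage rank defining the taxon group (default 2 =
#'   phylum).
#' @return data.frame with `id`, `group`, `evidence_types`, `confidence`
#'   (`"confident"` / `"low"`).
#' @export
flag_low_confidence <- function(records, policy = curation_policy(),
                                group_rank = 2L) {
  group <- vapply(records$taxon, function(lin) {
    paste(lin[seq_len(min(group_rank, length(lin)))], collapse = ";")
  }, "")
  ev_by_group <- tapply(records$evidence, group, function(evs) {
    unique(unlist(evs))
  })
  n_types <- vapply(group, function(g) length(ev_by_group[[g]]), 0L)
  data.frame(id = records$id, group = group,
             evidence_types = vapply(group, function(g)
               paste(sort(ev_by_group[[g]]), collapse = ","), ""),
             confidence = ifelse(n_types >= policy$required_evidence_types,
                                 "confident", "low"),
             stringsAsFactors = FALSE, row.names = NULL)
}
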