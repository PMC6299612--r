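#' Screening policy for tabular similarity-search hits
#'
#' A subject is accepted when it hits a single query below `e_single`, or at
#' least `min_queries_multi` distinct queries below `e_multi`; only hits
#' covering more than `min_coverage` of the query participate. All
#' thresholds are strict inequalities (`E < cutoff`, `coverage > cutoff`).
#'
#' @param e_single single-query E-value threshold.
#' @param e_multi multi-query E-value threshold (must be >= `e_single`).
#' @param min_coverage minimum aligned fraction of the query length.
#' @param min_queries_multi distinct queries required on the multi branch.
#' @return a `pld_screen_policy` list.
#' @export
screen_policy <- function(e_single = 1e-05, e_multi = 1e-03,
                          min_coverage = 0.75, min_queries_multi = 2L) {
  stopifnot(e_multi >= e_single, min_coverage > 0, min_coverage <= 1,
            min_queries_multi >= 1)
  structure(list(e_single = e_single, e_multi = e_multi,
                 min_coverage = min_coverage,
                 min_queries_multi = as.integer(min_queries_multi)),
            class = "pld_screen_policy")
}

#' Query coverage of a hit
#'
#' Fraction of the query length spanned by the aligned region
#' (`q_end - q_start + 1`) / `query_length`. Values above 1 (possible when
#' the alignment is gapped) are clamped to 1 with a warning.
#'
#' @param hits one or more hit rows (data.frame from
#'   [read_hits_tabular()]).
#' @return numeric vector of coverages in (0, 1].
#' @export
coverage <- function(hits) {
  if (any(is.na(hits$query_length))) {
    stop("unknown query length for query: ",
         hits$query_id[is.na(hits$query_length)][1L])
  }
  cov <- (hits$q_end - hits$q_start + 1) / hits$query_length
  if (any(cov > 1)) {
    warning("coverage > 1 clamped for ", sum(cov > 1), " hit(s)")
    cov <- pmin(cov, 1)
  }
  cov
}

#' Accept subjects from a hit table under the screening policy
#'
#' Per (query, subject) pair only the best (lowest) E-value among
#' sufficient-coverage hits is kept; a subject is accepted iff its best
#' E-value to any query is below `e_single`, or it is below `e_multi` for at
#' least `min_queries_multi` distinct queries. Subjects whose only support
#' fails the coverage rule are reported as fragmentary.
#'
#' @param hits data.frame from [read_hits_tabular()].
#' @param policy a [screen_policy()].
#' @return list with `accepted` (character vector of subject ids),
#'   `rationale` (data.frame: `subject_id`, `decision`, `branch`,
#'   `best_evalue`, `n_supporting_queries`, `supporting_queries`), and
#'   `fragmentary` (subjects excluded solely by the coverage rule).
#' @export
accept_hits <- function(hits, policy = screen_policy()) {
  if (nrow(hits) == 0L) {
    return(list(accepted = character(),
                rationale = data.frame(subject_id = character(),
                                       decision = character(),
                                       branch = character(),
                                       best_evalue = numeric(),
                                       n_supporting_queries = integer(),
                                       supporting_queries = character(),
                                       stringsAsFactors = FALSE),
                fragmentary = character()))
  }
  cov <- coverage(hits)
  usable <- cov > policy$min_coverage
  subjects <- unique(hits$subject_id)
  rat <- lapply(subjects, function(s) {
    rows <- hits$subject_id == s
    ok <- rows & usable
    if (!any(ok)) {
      return(data.frame(subject_id = s, decision = "rejected",
                        branch = "fragmentary hit",
                        best_evalue = min(hits$evalue[rows]),
                        n_supporting_queries = 0L, supporting_queries = "",
                        stringsAsFactors = FALSE))
    }
    best <- tapply(hits$evalue[ok], hits$query_id[ok], min)
    best_e <- min(best)
    single <- best_e < policy$e_single
    multi_q <- names(best)[best < policy$e_multi]
    multi <- length(multi_q) >= policy$min_queries_multi
    branch <- if (single) "single-query" else if (multi) "multi-query"
      else "none"
    support <- if (single) names(best)[which.min(best)] else if (multi)
      multi_q else character()
    data.frame(subject_id = s,
               decision = if (single || multi) "accepted" else "rejected",
               branch = branch, best_evalue = best_e,
               n_supporting_queries = length(support),
               supporting_queries = paste(sort(support), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rationale <- do.call(rbind, rat)
  list(accepted = rationale$subject_id[rationale$decision == "accepted"],
       rationale = rationale,
       fragmentary = rationale$subject_id[rationale$branch ==
                                            "fragmentary hit"])
}

#' Expand accepted subjects across secondary search rounds
#'
#' `round_results` is a list of hit tables, one per round; queries of round
#' r must be drawn from the seed queries plus subjects accepted in rounds
#' < r. The accepted set grows monotonically; each subject is tagged with
#' its earliest round of discovery and the query that reached it.
#'
#' @param seed_queries character vector of round-1 query ids.
#' @param round_results list of hit data.frames (round 1, 2, ...).
#' @param policy a [screen_policy()].
#' @param max_rounds cap on rounds processed.
#' @return data.frame with `subject_id`, `round`, `via_query`.
#' @export
expand_rounds <- function(seed_queries, round_results,
                          policy = screen_policy(),
                          max_rounds = length(round_results)) {
  known_queries <- seed_queries
  found <- data.frame(subject_id = character(), round = integer(),
                      via_query = character(), stringsAsFactors = FALSE)
  for (r in seq_len(min(max_rounds, length(round_results)))) {
    hits <- round_results[[r]]
    stray <- setdiff(unique(hits$query_id), known_queries)
    if (length(stray)) {
      stop("round ", r, " queries not among seeds or previously accepted ",
           "subjects: ", paste(stray, collapse = ", "))
    }
    res <- accept_hits(hits, policy)
    new <- setdiff(res$accepted, found$subject_id)
    if (length(new)) {
      via <- vapply(new, function(s) {
        q <- res$rationale$supporting_queries[res$rationale$subject_id == s]
        strsplit(q, ",")[[1]][1]
      }, "")
      found <- rbind(found, data.frame(subject_id = new, round = r,
                                       via_query = via,
                                       stringsAsFactors = FALSE))
    }
    known_queries <- union(known_queries, found$subject_id)
  }
  found
}
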