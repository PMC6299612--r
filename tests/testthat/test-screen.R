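mk_hit <- function(q, s, e, q_start, q_end, qlen = 300) {
  data.frame(query_id = q, subject_id = s, percent_identity = 40,
             alignment_length = q_end - q_start + 1, mismatches = 0,
             gap_opens = 0, q_start = q_start, q_end = q_end,
             s_start = 1, s_end = q_end - q_start + 1, evalue = e,
             bitscore = 100, query_length = qlen, coverage_defined = TRUE,
             stringsAsFactors = FALSE)
}

test_that("coverage is the aligned fraction of the query", {
  expect_equal(coverage(mk_hit("q", "s", 1e-9, 1, 300)), 1.0)
  expect_equal(coverage(mk_hit("q", "s", 1e-9, 1, 150)), 0.5)
  expect_equal(coverage(mk_hit("q", "s", 1e-9, 26, 250)), 0.75)
  h <- mk_hit("q", "s", 1e-9, 1, 330)
  expect_warning(cv <- coverage(h), "clamped")
  expect_equal(cv, 1.0)
  h$query_length <- NA
  expect_error(coverage(h), "unknown query length")
})

test_that("acceptance implements the single/multi-query E-value rule", {
  pol <- screen_policy()
  # single strong hit above coverage
  r1 <- accept_hits(mk_hit("q1", "s1", 1e-06, 1, 240), pol)
  expect_equal(r1$accepted, "s1")
  expect_equal(r1$rationale$branch, "single-query")
  # two weak hits from distinct queries
  r2 <- accept_hits(rbind(mk_hit("q1", "s2", 1e-04, 1, 240),
                          mk_hit("q2", "s2", 1e-04, 1, 240)), pol)
  expect_equal(r2$accepted, "s2")
  expect_equal(r2$rationale$branch, "multi-query")
  # one weak hit only: rejected
  r3 <- accept_hits(mk_hit("q1", "s3", 1e-04, 1, 240), pol)
  expect_equal(r3$accepted, character())
  # strong but fragmentary: excluded and flagged
  r4 <- accept_hits(mk_hit("q1", "s4", 1e-30, 1, 150), pol)
  expect_equal(r4$accepted, character())
  expect_equal(r4$fragmentary, "s4")
  # thresholds are strict: E exactly at the cutoff is rejected
  r5 <- accept_hits(mk_hit("q1", "s5", 1e-05, 1, 240), pol)
  expect_equal(r5$accepted, character())
  # two weak hits from the same query do not satisfy the multi branch
  r6 <- accept_hits(rbind(mk_hit("q1", "s6", 1e-04, 1, 240),
                          mk_hit("q1", "s6", 2e-04, 10, 250)), pol)
  expect_equal(r6$accepted, character())
  expect_equal(nrow(accept_hits(mk_hit("q", "s", 1, 1, 2)[0, ], pol)$rationale),
               0L)
})

random_hit_table <- function(seed, n_subjects = 6, n_queries = 3) {
  set.seed(seed)
  n <- sample(5:25, 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    mk_hit(paste0("q", sample(n_queries, 1)),
           paste0("s", sample(n_subjects, 1)),
           10^stats::runif(1, -8, -1), 1, sample(c(150, 240, 290), 1))
  }))
}

test_that("acceptance is monotone in E-values", {
  pol <- screen_policy()
  for (seed in 1:15) {
    hits <- random_hit_table(seed)
    before <- accept_hits(hits, pol)$accepted
    improved <- hits
    k <- sample(nrow(hits), 1)
    improved$evalue[k] <- improved$evalue[k] / 1000
    after <- accept_hits(improved, pol)$accepted
    expect_true(all(before %in% after), info = paste("seed", seed))
  }
})

test_that("equal thresholds degenerate to a single-threshold filter", {
  pol <- screen_policy(e_single = 1e-04, e_multi = 1e-04)
  for (seed in 21:35) {
    hits <- random_hit_table(seed)
    got <- sort(accept_hits(hits, pol)$accepted)
    cov <- coverage(hits)
    simple <- sort(unique(hits$subject_id[hits$evalue < 1e-04 & cov > 0.75]))
    expect_equal(got, simple, info = paste("seed", seed))
  }
})

test_that("round expansion tracks earliest discovery and validates queries", {
  pol <- screen_policy()
  r1 <- mk_hit("seed1", "hitA", 1e-08, 1, 260)
  r2 <- mk_hit("hitA", "hitB", 1e-08, 1, 260)
  out <- expand_rounds("seed1", list(r1, r2), pol)
  expect_equal(out$round[out$subject_id == "hitA"], 1L)
  expect_equal(out$round[out$subject_id == "hitB"], 2L)
  expect_equal(out$via_query[out$subject_id == "hitB"], "hitA")
  # one round, nothing new in round 2
  out1 <- expand_rounds("seed1", list(r1, r1), pol)
  expect_equal(nrow(out1), 1L)
  expect_error(expand_rounds("seed1", list(r2)), "not among seeds")
})

test_that("multi-round expansion equals the transitive closure", {
  pol <- screen_policy()
  set.seed(99)
  for (rep in 1:5) {
    # random acceptance edges q -> s among 8 labels, seeds = {n1}
    labels <- paste0("n", 1:8)
    edges <- expand.grid(q = labels, s = labels, stringsAsFactors = FALSE)
    edges <- edges[edges$q != edges$s & stats::runif(nrow(edges)) < 0.18, ]
    mk_round <- function(queries) {
      rows <- edges[edges$q %in% queries, ]
      if (nrow(rows) == 0) return(mk_hit("x", "y", 1, 1, 2)[0, ])
      do.call(rbind, lapply(seq_len(nrow(rows)), function(i)
        mk_hit(rows$q[i], rows$s[i], 1e-08, 1, 260)))
    }
    # brute-force closure limited to 3 rounds
    reach <- character(); frontier <- "n1"
    for (r in 1:3) {
      new <- setdiff(edges$s[edges$q %in% frontier], reach)
      reach <- union(reach, new)
      frontier <- union("n1", reach)
    }
    rounds <- list(); frontier <- "n1"; acc <- character()
    for (r in 1:3) {
      rounds[[r]] <- mk_round(frontier)
      acc <- union(acc, accept_hits(rounds[[r]], pol)$accepted)
      frontier <- union("n1", acc)
    }
    out <- expand_rounds("n1", rounds, pol)
    expect_setequal(out$subject_id, reach)
  }
})
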