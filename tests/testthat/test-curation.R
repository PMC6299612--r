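test_that("pairwise identity handles the base cases", {
  expect_equal(pairwise_identity("ACDEFGHIKL", "ACDEFGHIKL"), 100)
  expect_equal(pairwise_identity("ACDEFGHIKL", "ACDEFGHIKW"), 90)
  expect_error(pairwise_identity("", "ACD"), "empty sequence")
})

test_that("pairwise identity is symmetric and reflexive", {
  set.seed(5)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:10) {
    a <- paste(sample(aa, sample(8:30, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aa, sample(8:30, 1), replace = TRUE), collapse = "")
    expect_equal(pairwise_identity(a, a), 100)
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("fragments score by their overlap, not their missing ends", {
  full <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 5), collapse = "")
  frag <- substr(full, 21, 60)
  expect_equal(pairwise_identity(full, frag), 100)
})

test_that("greedy redundancy clustering keeps long representatives", {
  base <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 5), collapse = "")  # 100 aa
  # 5 substitutions per 100 residues ~ 95% identity
  chars <- strsplit(base, "")[[1]]
  chars[c(10, 30, 50, 70, 90)] <- c("W", "A", "Y", "A", "A")
  near <- paste(chars, collapse = "")
  other <- paste(rep("MNQRSTVWYACDEFGHIKLP", 5), collapse = "")
  recs <- pld_records(c("s1", "s2", "s3"), c(base, near, other))
  out <- filter_redundancy(recs, 90)
  expect_setequal(out$kept, c("s1", "s3"))
  expect_equal(out$removed$id, "s2")
  expect_equal(out$removed$representative, "s1")
  # threshold 100: only exact duplicates collapse
  out100 <- filter_redundancy(recs, 100)
  expect_setequal(out100$kept, c("s1", "s2", "s3"))
  dup <- pld_records(c("a", "b"), c(base, base))
  expect_equal(filter_redundancy(dup, 100)$removed$id, "b")
  expect_equal(nrow(filter_redundancy(recs[0, ], 90)$removed), 0L)
})

test_that("redundancy output is a maximal representative set", {
  d <- make_dataset(generator_config(seed = 21, n_st = 6, n_at = 4,
                                     n_aquatic = 4, n_basal = 2, n_decoy = 0,
                                     redundancy_pairs = 4,
                                     fragment_count = 0,
                                     contaminant_pairs = 0,
                                     divergent_count = 0))
  out <- filter_redundancy(d$records, 90)
  # no two kept records reach the threshold
  kept <- d$records[d$records$id %in% out$kept, ]
  for (i in seq_len(nrow(kept) - 1)) {
    for (j in seq((i + 1), nrow(kept))) {
      expect_lt(pairwise_identity(kept$residues[i], kept$residues[j]), 90)
    }
  }
  # every removed record violates the threshold against its representative
  if (nrow(out$removed)) {
    for (k in seq_len(nrow(out$removed))) {
      a <- d$records$residues[d$records$id == out$removed$id[k]]
      b <- d$records$residues[d$records$id == out$removed$representative[k]]
      expect_gte(pairwise_identity(a, b), 90)
    }
  }
})

test_that("fragment filtering applies length, domain fraction and exceptions", {
  recs <- pld_records(c("short", "partial", "full"),
                      c(strrep("A", 200), strrep("A", 300), strrep("A", 300)))
  info <- data.frame(id = c("short", "partial", "full"),
                     covered_fraction = c(0.9, 0.5, 1.0))
  out <- filter_fragments(recs, info)
  expect_setequal(out$removed$id, c("short", "partial"))
  expect_equal(out$removed$reason[out$removed$id == "short"],
               "short sequence")
  expect_equal(out$removed$reason[out$removed$id == "partial"],
               "partial domain")
  expect_equal(out$kept, "full")
  # exception: kept despite covering only 75% of the domain
  pol <- curation_policy(exceptions = "partial")
  out2 <- filter_fragments(recs, info, pol)
  expect_true("partial" %in% out2$kept)
  expect_equal(out2$flagged, "partial")
  # active-site deletion dominates
  info$active_site_deleted <- c(FALSE, FALSE, TRUE)
  out3 <- filter_fragments(recs, info)
  expect_equal(out3$removed$reason[out3$removed$id == "full"],
               "active-site deletion")
  expect_error(filter_fragments(recs, info[1:2, ]), "missing from")
})

test_that("active-site screening grades substitutions by BLOSUM62", {
  st <- make_family_sequence("ST", seed = 2)
  site <- st$truth$active_site
  ok <- screen_active_site(st$record, site)
  expect_true(all(ok$states == "canonical"))
  expect_equal(ok$verdict, "normal")

  chars <- strsplit(st$record$residues, "")[[1]]
  chars[site["His12"]] <- "L"; chars[site["Glu32"]] <- "G"
  chars[site["His47"]] <- "L"
  div <- screen_active_site(paste(chars, collapse = ""), site)
  expect_equal(div$verdict, "divergent")
  expect_equal(unname(div$states["His12"]), "nonconservative")

  chars <- strsplit(st$record$residues, "")[[1]]
  chars[site["His47"]] <- "Y"  # His->Tyr scores +2: conservative
  cons <- screen_active_site(paste(chars, collapse = ""), site)
  expect_equal(unname(cons$states["His47"]), "conservative")
  expect_equal(cons$verdict, "normal")

  gapped <- site; gapped["His12"] <- NA
  mis <- screen_active_site(st$record, gapped)
  expect_equal(unname(mis$states["His12"]), "missing")
})

test_that("contaminant flagging respects identity and lineage rank", {
  mite_seq <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 5), collapse = "")
  refs <- pld_records("mite1", mite_seq,
                      taxon = c("Eukaryota", "Arthropoda", "Acari"))
  # identical sequence assigned to a plant: always flagged
  plant <- pld_records("plant1", mite_seq,
                       taxon = c("Eukaryota", "Streptophyta"))
  f1 <- flag_contaminants(plant, refs)
  expect_equal(f1$id, "plant1")
  expect_equal(f1$identity, 100)
  # ~55% identical insect sequence: flagged (> 50%)
  chars <- strsplit(mite_seq, "")[[1]]
  idx <- seq(1, 89, by = 2)  # 45 substitutions -> 55% identity
  chars[idx] <- ifelse(chars[idx] == "W", "A", "W")
  insect <- pld_records("fly1", paste(chars, collapse = ""),
                        taxon = c("Eukaryota", "Hexapodia", "Insecta"))
  f2 <- flag_contaminants(insect, refs)
  expect_equal(f2$id, "fly1")
  expect_true(f2$identity > 50)
  # same-phylum record at similar identity: exempt
  chel <- pld_records("tick1", paste(chars, collapse = ""),
                      taxon = c("Eukaryota", "Arthropoda", "Ixodida"))
  expect_equal(nrow(flag_contaminants(chel, refs)), 0L)
  # missing lineage: skipped with a warning
  anon <- pld_records("anon1", mite_seq)
  expect_warning(f4 <- flag_contaminants(anon, refs), "lacks lineage")
  expect_equal(nrow(f4), 0L)
})

test_that("evidence confidence aggregates per taxon group", {
  recs <- pld_records(
    c("a", "b", "c", "d"),
    c("ACDEF", "GHIKL", "MNPQR", "STVWY"),
    taxon = list(c("Eukaryota", "Ctenophora"), c("Eukaryota", "Ctenophora"),
                 c("Eukaryota", "Mollusca"), c("Eukaryota", "Rotifera")),
    evidence = list("genome", "transcriptome", "transcriptome", character()))
  out <- flag_low_confidence(recs)
  expect_equal(out$confidence[out$id == "a"], "confident")  # group has both
  expect_equal(out$confidence[out$id == "b"], "confident")
  expect_equal(out$confidence[out$id == "c"], "low")
  expect_equal(out$confidence[out$id == "d"], "low")       # empty evidence
})
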