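## Synthetic GDPD-like SMase D/PLD sequence and scenario generator.
##
## Sequences follow a fixed single-domain architecture: conserved
## secondary-structure anchor blocks (strands/helices) and diagnostic
## residues are planted at known coordinates; connecting framework is drawn
## from a background composition that deliberately excludes cysteine, so
## that cysteine topology never arises by chance. The generator's truth
## annotations record every planted feature.

# background alphabet: 19 amino acids, cysteine excluded (planted only)
BG_ALPHABET <- setdiff(AA_ALPHABET_20X, c("C", "X"))

# fixed anchor blocks (conserved across the family)
ANCHOR_NTERM   <- c("V", "E", "T", NA, "N")  # NA = background position
ANCHOR_BETA1   <- "VKIAL"
ANCHOR_ALPHA1  <- "GDLA"
ANCHOR_BETA2   <- "GSIVLFTK"
ANCHOR_BETA3   <- "TLKSVG"
ANCHOR_BETA4   <- "FIVK"
ANCHOR_LINKER  <- "GPL"

# C-terminal plug motif: 17 columns; key columns hold the Arg-Asp salt
# bridge (2, 3), hydrophobic Ala (7) and Pro (10), and the buried Trp (14)
PLUG_CONSENSUS <- "NRDLIGAVSPGKLWIKE"
PLUG_KEY_COLS  <- c(2L, 3L, 7L, 10L, 14L)

# DUF-B cysteine-rich repeat: 10 cysteines with fixed inter-cysteine
# spacings, a glycine-rich stretch, and a terminal tyrosine (~72 residues)
DUFB_GAPS <- c(6L, 6L, 6L, 7L, 6L, 7L, 6L, 6L, 6L)
DUFB_TAIL_GLY <- "GGSGG"

# segment lengths of the core domain (catalytic-loop and ba1 lengths vary)
SEG_NTERM2 <- 6L; SEG_ALPHA1B <- 8L; SEG_MID1 <- 27L
SEG_MID2 <- 18L; SEG_MID3 <- 138L; SEG_TAIL <- 6L
BA1_FAMILY_LEN <- 2L
CAT_HIS_OFFSET <- 5L   # His47 sits at loop position 5 in every clade

# Run expr with a local, restored RNG seeded by `seed` (NULL = use current).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv())
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

bg_residues <- function(n) {
  if (n <= 0L) return(character())
  sample(BG_ALPHABET, n, replace = TRUE)
}

anchor_chars <- function(x) strsplit(x, "")[[1]]

# Catalytic-loop content per clade: His at CAT_HIS_OFFSET, clade cysteines.
make_cat_loop <- function(clade) {
  len <- switch(clade,
    ST = 15L,
    AT = sample(9:13, 1L),
    Aquatic = sample(c(17L, 19L, 21L, 23L), 1L),
    basal = 7L,
    `GDPD-decoy` = 40L)  # stands in for the GDPD-I insert
  loop <- bg_residues(len)
  loop[CAT_HIS_OFFSET] <- "H"
  cys <- integer()
  if (clade == "ST") {
    cys <- c(3L, len - 3L)
  } else if (clade == "Aquatic") {
    cys <- c(3L, 8L, 11L, len - 3L)  # ST-homologous pair plus an extra pair
  }
  loop[cys] <- "C"
  list(residues = loop, length = len, cys_offsets = cys)
}

#' Generate one synthetic family (or decoy) sequence with truth annotation
#'
#' Builds a single-domain protein with the family's diagnostic features
#' planted at known, recorded coordinates: the canonical active site (His12,
#' Glu32, Asp34, His47, Asp91, Lys93 in mature numbering), a short
#' beta-alpha-1 loop (or a loop at least six residues longer plus a GDPD-I
#' style insert for the GDPD decoy), a clade-specific catalytic loop length
#' and cysteine pattern (ST: 15 residues with a cysteine pair plus a linker
#' cysteine; AT: 9-13 residues, no cysteines; Aquatic: >= 17 residues with
#' the ST pair plus an extra pair; basal: short, no cysteines), and the
#' C-terminal plug motif (absent in the decoy).
#'
#' @param clade one of `"ST"`, `"AT"`, `"Aquatic"`, `"basal"`,
#'   `"GDPD-decoy"`.
#' @param seed integer seed for this record (NULL = current RNG stream).
#' @param mutation_rate per-site substitution probability applied to
#'   non-diagnostic positions (framework, anchors, non-key motif columns).
#' @param n_dufb number of DUF-B cysteine-rich repeats appended after the
#'   domain (Aquatic-style architecture).
#' @param id sequence identifier.
#' @return list with `record` (one-row [pld_records()]) and `truth` (list of
#'   planted coordinates and feature values).
#' @export
make_family_sequence <- function(clade, seed = NULL, mutation_rate = 0,
                                 n_dufb = 0L, id = paste0(clade, "_1")) {
  clades <- c("ST", "AT", "Aquatic", "basal", "GDPD-decoy")
  if (!clade %in% clades) {
    stop("unknown clade label: ", clade, " (expected one of ",
         paste(clades, collapse = ", "), ")")
  }
  with_seed(seed, {
    ba1_len <- if (clade == "GDPD-decoy") BA1_FAMILY_LEN + 6L + sample(0:2, 1L)
               else BA1_FAMILY_LEN
    cat <- make_cat_loop(clade)
    has_plug <- clade != "GDPD-decoy"
    has_linker_cys <- clade %in% c("ST", "Aquatic")

    seq <- character(0)
    fixed <- logical(0)     # positions never touched by noise
    add <- function(res, fix) {
      seq <<- c(seq, res)
      fixed <<- c(fixed, rep(fix, length(res)))
    }
    # N-terminal block with plug-partner residues at 1-3 and 5
    nterm <- ifelse(is.na(ANCHOR_NTERM), bg_residues(5L), ANCHOR_NTERM)
    add(nterm, FALSE); add(bg_residues(SEG_NTERM2), FALSE)
    pos_h12 <- length(seq) + 1L; add("H", TRUE)
    add(anchor_chars(ANCHOR_BETA1), FALSE)
    ba1_start <- length(seq) + 1L
    add(bg_residues(ba1_len), FALSE)
    ba1_end <- length(seq)
    add(anchor_chars(ANCHOR_ALPHA1), FALSE)
    add(bg_residues(SEG_ALPHA1B), FALSE)
    pos_e32 <- length(seq) + 1L; add("E", TRUE)
    add(bg_residues(1L), FALSE)
    pos_d34 <- length(seq) + 1L; add("D", TRUE)
    add(anchor_chars(ANCHOR_BETA2), FALSE)
    cat_start <- length(seq) + 1L
    fix_loop <- rep(FALSE, cat$length)
    fix_loop[c(CAT_HIS_OFFSET, cat$cys_offsets)] <- TRUE
    add(cat$residues, NA)  # placeholder, set fixed flags next
    fixed[cat_start:(cat_start + cat$length - 1L)] <- fix_loop
    cat_end <- length(seq)
    pos_h47 <- cat_start + CAT_HIS_OFFSET - 1L
    add(anchor_chars(ANCHOR_BETA3), FALSE)
    add(bg_residues(SEG_MID1), FALSE)
    pos_d91 <- length(seq) + 1L; add("D", TRUE)
    add(bg_residues(1L), FALSE)
    pos_k93 <- length(seq) + 1L; add("K", TRUE)
    add(anchor_chars(ANCHOR_BETA4), FALSE)
    add(bg_residues(SEG_MID2), FALSE)
    add(anchor_chars(ANCHOR_LINKER), FALSE)
    pos_linker_cys <- length(seq) + 1L
    add(if (has_linker_cys) "C" else bg_residues(1L), has_linker_cys)
    add(bg_residues(SEG_MID3), FALSE)
    plug_start <- length(seq) + 1L
    if (has_plug) {
      plug <- anchor_chars(PLUG_CONSENSUS)
      fix_plug <- seq_along(plug) %in% PLUG_KEY_COLS
      add(plug, NA)
      fixed[plug_start:(plug_start + length(plug) - 1L)] <- fix_plug
    } else {
      add(bg_residues(nchar(PLUG_CONSENSUS)), FALSE)
    }
    plug_end <- length(seq)
    add(bg_residues(SEG_TAIL), FALSE)

    dufb_spans <- list()
    for (k in seq_len(n_dufb)) {
      st <- length(seq) + 1L
      add(make_dufb_repeat(), NA)
      en <- length(seq)
      fixed[st:en] <- grepl("[CGY]", seq[st:en])  # keep the repeat signature
      dufb_spans[[k]] <- c(start = st, end = en)
    }

    # substitution noise on mutable positions (never to/from the planted set)
    if (mutation_rate > 0) {
      mutable <- which(!fixed)
      hit <- mutable[stats::runif(length(mutable)) < mutation_rate]
      for (i in hit) {
        seq[i] <- sample(setdiff(BG_ALPHABET, seq[i]), 1L)
      }
    }

    residues <- paste(seq, collapse = "")
    truth <- list(
      id = id, clade = clade,
      length = nchar(residues),
      ba1_start = ba1_start, ba1_end = ba1_end, ba1_length = ba1_len,
      cat_start = cat_start, cat_end = cat_end, cat_length = cat$length,
      cat_cys_positions = cat_start + cat$cys_offsets - 1L,
      cat_cys_count = length(cat$cys_offsets),
      linker_cys = has_linker_cys, linker_cys_pos = pos_linker_cys,
      active_site = c(His12 = pos_h12, Glu32 = pos_e32, Asp34 = pos_d34,
                      His47 = pos_h47, Asp91 = pos_d91, Lys93 = pos_k93),
      plug_present = has_plug, plug_start = plug_start, plug_end = plug_end,
      dufb_count = n_dufb, dufb_spans = dufb_spans)
    list(record = pld_records(id, residues), truth = truth)
  })
}

#' Build one DUF-B cysteine-rich repeat
#'
#' Ten cysteines at the canonical spacings, background filler between them,
#' a glycine-rich stretch and a terminal tyrosine. `stretch_gap` /
#' `stretch_by` widen one inter-cysteine spacing, for probing the detector's
#' spacing tolerance.
#'
#' @param stretch_gap index (1-9) of the spacing to perturb, or `NULL`.
#' @param stretch_by residues added to that spacing.
#' @return character vector of residues.
#' @export
make_dufb_repeat <- function(stretch_gap = NULL, stretch_by = 0L) {
  gaps <- DUFB_GAPS
  if (!is.null(stretch_gap)) gaps[stretch_gap] <- gaps[stretch_gap] + stretch_by
  out <- "C"
  for (g in gaps) out <- c(out, bg_residues(g), "C")
  c(out, anchor_chars(DUFB_TAIL_GLY), "Y")
}

#' Generator configuration
#'
#' @param seed integer master seed; identical configuration and seed give
#'   byte-identical datasets.
#' @param n_st,n_at,n_aquatic,n_basal,n_decoy records per clade class.
#' @param mutation_rate within-clade divergence (substitutions per mutable
#'   site).
#' @param fragment_count number of planted fragmentary records (truncated to
#'   180 residues, below both the 225-residue and 75%-domain thresholds).
#' @param contaminant_pairs number of planted cross-taxon contaminant pairs
#'   (identical sequences assigned to incompatible phyla).
#' @param redundancy_pairs number of planted near-duplicate pairs
#'   (about 98% identity to an existing record).
#' @param divergent_count number of planted active-site-divergent variants
#'   (His12/Glu32/His47 replaced nonconservatively).
#' @return a `pld_generator_config` list.
#' @export
generator_config <- function(seed = 1L, n_st = 10L, n_at = 10L,
                             n_aquatic = 10L, n_basal = 5L, n_decoy = 5L,
                             mutation_rate = 0.02, fragment_count = 2L,
                             contaminant_pairs = 1L, redundancy_pairs = 2L,
                             divergent_count = 1L) {
  cfg <- list(seed = as.integer(seed), n_st = n_st, n_at = n_at,
              n_aquatic = n_aquatic, n_basal = n_basal, n_decoy = n_decoy,
              mutation_rate = mutation_rate, fragment_count = fragment_count,
              contaminant_pairs = contaminant_pairs,
              redundancy_pairs = redundancy_pairs,
              divergent_count = divergent_count)
  counts <- unlist(cfg[c("n_st", "n_at", "n_aquatic", "n_basal", "n_decoy",
                         "fragment_count", "contaminant_pairs",
                         "redundancy_pairs", "divergent_count")])
  stopifnot(all(counts >= 0), mutation_rate >= 0, mutation_rate <= 1)
  class(cfg) <- "pld_generator_config"
  cfg
}

CLADE_LINEAGES <- list(
  ST = list(c("Eukaryota", "Arthropoda", "Chelicerata"),
            c("Eukaryota", "Arthropoda", "Myriapoda"),
            c("Eukaryota", "Cnidaria", "Anthozoa")),
  AT = list(c("Bacteria", "Actinobacteria", "Actinomycetia"),
            c("Eukaryota", "Ascomycota", "Eurotiomycetes")),
  Aquatic = list(c("Eukaryota", "Ctenophora", "Tentaculata"),
                 c("Eukaryota", "Rotifera", "Bdelloidea"),
                 c("Eukaryota", "Arthropoda", "Branchiopoda")),
  basal = list(c("Bacteria", "Proteobacteria", "Betaproteobacteria")),
  `GDPD-decoy` = list(c("Bacteria", "Proteobacteria", "Gammaproteobacteria")))

record_seed <- function(master, i) (master %% 100000L) * 10000L + i

#' Generate a complete synthetic dataset with truth annotations
#'
#' Produces family and decoy sequences, planted near-duplicates, fragments,
#' cross-taxon contaminant pairs and active-site-divergent variants, plus a
#' 12-column tabular hit file whose per-subject E-values and coverages span
#' the screening rule's accept/reject boundaries. Every planted property is
#' recorded in the truth table.
#'
#' @param config a [generator_config()].
#' @return list with `records` ([pld_records()]), `references`
#'   (contamination reference records, kept separate as in real use),
#'   `truth` (data.frame, one row per record), `truths` (full per-record
#'   truth lists), `hits` (data.frame as from [read_hits_tabular()]),
#'   `query_lengths` (named vector), and `hit_truth` (expected screening
#'   decision per subject).
#' @export
make_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "pld_generator_config"))
  clade_counts <- c(ST = config$n_st, AT = config$n_at,
                    Aquatic = config$n_aquatic, basal = config$n_basal,
                    `GDPD-decoy` = config$n_decoy)
  recs <- list(); truths <- list(); rows <- list()
  idx <- 0L
  add_record <- function(rec, truth, extra) {
    idx <<- idx + 1L
    recs[[idx]] <<- rec
    truths[[idx]] <<- truth
    rows[[idx]] <<- cbind(
      data.frame(id = rec$id, clade = truth$clade, length = truth$length,
                 ba1_length = truth$ba1_length, cat_length = truth$cat_length,
                 cat_cys_count = truth$cat_cys_count,
                 linker_cys = truth$linker_cys,
                 plug_present = truth$plug_present,
                 dufb_count = truth$dufb_count, stringsAsFactors = FALSE),
      extra)
  }
  no_flags <- data.frame(redundant_with = NA_character_, fragment = FALSE,
                         contaminant_of = NA_character_, divergent = FALSE,
                         stringsAsFactors = FALSE)

  i_global <- 0L
  for (clade in names(clade_counts)) {
    lineages <- CLADE_LINEAGES[[clade]]
    for (k in seq_len(clade_counts[[clade]])) {
      i_global <- i_global + 1L
      id <- sprintf("%s_%03d", sub("GDPD-decoy", "GDPD", clade), k)
      n_dufb <- if (clade == "Aquatic") ((k - 1L) %% 4L) + 1L else 0L
      fam <- make_family_sequence(clade, seed = record_seed(config$seed, i_global),
                                  mutation_rate = config$mutation_rate,
                                  n_dufb = n_dufb, id = id)
      lin <- lineages[[((k - 1L) %% length(lineages)) + 1L]]
      ev <- list(c("genome", "transcriptome"), c("transcriptome"),
                 c("genome"), c("transcriptome", "proteome"))[[((k - 1L) %% 4L) + 1L]]
      fam$record$taxon <- list(lin)
      fam$record$evidence <- list(ev)
      add_record(fam$record, fam$truth, no_flags)
    }
  }
  base_n <- idx

  # near-duplicate pairs: copy an existing record with ~2% substitutions
  for (k in seq_len(config$redundancy_pairs)) {
    i_global <- i_global + 1L
    src <- recs[[((k - 1L) %% base_n) + 1L]]
    src_truth <- truths[[((k - 1L) %% base_n) + 1L]]
    dup <- with_seed(record_seed(config$seed, i_global), {
      chars <- strsplit(src$residues, "")[[1]]
      n_sub <- max(1L, round(0.02 * length(chars)))
      # substitute only background positions (diagnostic residues kept)
      cand <- which(chars %in% BG_ALPHABET)
      at <- sample(cand, min(n_sub, length(cand)))
      for (i in at) chars[i] <- sample(setdiff(BG_ALPHABET, chars[i]), 1L)
      paste(chars, collapse = "")
    })
    id <- sprintf("DUP_%03d", k)
    rec <- pld_records(id, dup, taxon = src$taxon[[1]],
                       evidence = src$evidence[[1]])
    tr <- src_truth; tr$id <- id
    extra <- no_flags; extra$redundant_with <- src$id
    add_record(rec, tr, extra)
  }

  # fragments: fresh ST-architecture sequences truncated to 180 residues
  for (k in seq_len(config$fragment_count)) {
    i_global <- i_global + 1L
    id <- sprintf("FRAG_%03d", k)
    fam <- make_family_sequence("ST", seed = record_seed(config$seed, i_global),
                                mutation_rate = config$mutation_rate, id = id)
    fam$record$residues <- substr(fam$record$residues, 1L, 180L)
    fam$record$taxon <- list(CLADE_LINEAGES$ST[[1]])
    tr <- fam$truth; tr$length <- 180L
    tr$plug_present <- FALSE; tr$plug_start <- NA; tr$plug_end <- NA
    extra <- no_flags; extra$fragment <- TRUE
    add_record(fam$record, tr, extra)
  }

  # contaminant pairs: dataset records identical to a known reference
  # sequence (kept separate, as contamination references are in real use)
  # but assigned to an incompatible phylum
  references <- list()
  for (k in seq_len(config$contaminant_pairs)) {
    i_global <- i_global + 1L
    ref_id <- sprintf("MITE_%03d", k)
    fam <- make_family_sequence("ST", seed = record_seed(config$seed, i_global),
                                mutation_rate = config$mutation_rate,
                                id = ref_id)
    ref <- fam$record
    ref$taxon <- list(c("Eukaryota", "Arthropoda", "Acari"))
    ref$evidence <- list(c("genome", "transcriptome"))
    references[[k]] <- ref
    con_id <- sprintf("PLANT_%03d", k)
    con <- pld_records(con_id, fam$record$residues,
                       taxon = c("Eukaryota", "Streptophyta", "Magnoliopsida"),
                       evidence = "transcriptome")
    tr <- fam$truth; tr$id <- con_id
    extra <- no_flags; extra$contaminant_of <- ref_id
    add_record(con, tr, extra)
  }
  references <- if (length(references)) {
    refs <- do.call(rbind, references)
    class(refs) <- c("pld_records", "data.frame")
    refs
  } else pld_records(character(), character())

  # active-site-divergent variants (nonconservative at His12/Glu32/His47)
  for (k in seq_len(config$divergent_count)) {
    i_global <- i_global + 1L
    id <- sprintf("DIV_%03d", k)
    fam <- make_family_sequence("ST", seed = record_seed(config$seed, i_global),
                                mutation_rate = config$mutation_rate, id = id)
    chars <- strsplit(fam$record$residues, "")[[1]]
    chars[fam$truth$active_site["His12"]] <- "L"
    chars[fam$truth$active_site["Glu32"]] <- "G"
    chars[fam$truth$active_site["His47"]] <- "L"
    fam$record$residues <- paste(chars, collapse = "")
    fam$record$taxon <- list(CLADE_LINEAGES$ST[[2]])
    extra <- no_flags; extra$divergent <- TRUE
    add_record(fam$record, fam$truth, extra)
  }

  records <- do.call(rbind, recs)
  class(records) <- c("pld_records", "data.frame")
  truth <- do.call(rbind, rows)

  hit_tab <- with_seed(record_seed(config$seed, i_global + 1L),
                       make_hit_table(records$id))
  list(records = records, references = references, truth = truth,
       truths = truths, hits = hit_tab$hits,
       query_lengths = hit_tab$query_lengths, hit_truth = hit_tab$truth)
}

# Builds a synthetic 12-column hit table over the dataset's subjects, with
# one of five scenarios per subject spanning the screening rule boundaries.
make_hit_table <- function(subject_ids) {
  queries <- c("Q1", "Q2", "Q3")
  qlen <- stats::setNames(c(280, 280, 280), queries)
  scen <- rep(c("single_strong", "multi_weak", "single_weak",
                "low_coverage", "boundary"),
              length.out = length(subject_ids))
  rows <- list(); truth <- list()
  mk <- function(q, s, e, cov) {
    alen <- round(cov * qlen[[q]])
    data.frame(query_id = q, subject_id = s, percent_identity = 40,
               alignment_length = alen, mismatches = round(0.6 * alen),
               gap_opens = 2, q_start = 1, q_end = alen,
               s_start = 1, s_end = alen, evalue = e,
               bitscore = round(-10 * log10(e + 1e-300)),
               stringsAsFactors = FALSE)
  }
  for (i in seq_along(subject_ids)) {
    s <- subject_ids[i]
    rows[[i]] <- switch(scen[i],
      single_strong = mk("Q1", s, 1e-08, 0.9),
      multi_weak = rbind(mk("Q1", s, 1e-04, 0.8), mk("Q2", s, 2e-04, 0.8)),
      single_weak = mk("Q1", s, 1e-04, 0.85),
      low_coverage = mk("Q2", s, 1e-30, 0.5),
      boundary = mk("Q3", s, 1e-05, 0.9))
    truth[[i]] <- data.frame(
      subject_id = s, scenario = scen[i],
      expected_accept = scen[i] %in% c("single_strong", "multi_weak"),
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, rows)
  hits$query_length <- unname(qlen[hits$query_id])
  hits$coverage_defined <- TRUE
  list(hits = hits, query_lengths = qlen, truth = do.call(rbind, truth))
}

#' Write a generated dataset to files
#'
#' @param dataset result of [make_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "sequences.fa")
  write_fasta(dataset$records, fa)
  rf <- file.path(dir, "references.fa")
  write_fasta(dataset$references, rf)
  tr <- file.path(dir, "truth.tsv")
  utils::write.table(dataset$truth, tr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ht <- file.path(dir, "hits.tsv")
  write_hits_tabular(dataset$hits, ht)
  ql <- file.path(dir, "query_lengths.tsv")
  utils::write.table(
    data.frame(query_id = names(dataset$query_lengths),
               length = unname(dataset$query_lengths)),
    ql, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fa, references = rf, truth = tr, hits = ht,
              query_lengths = ql))
}

#' Simulate a single-gain-plus-losses (Dollo) scenario on a tree
#'
#' Chooses `n_losses` branches below the gain node such that the lost
#' subtrees are mutually non-nested and remain maximal (no set of sibling
#' losses silently merges into a single larger loss), and at least one tip
#' stays present. The planted scenario is therefore exactly recoverable by
#' [dollo_losses()].
#'
#' @param tree rooted `phylo`.
#' @param n_losses number of loss branches to plant.
#' @param seed integer seed.
#' @param gain_node node number of the single gain (default: root).
#' @return list with `tree`, `gain_node` (label), `gain_node_num`,
#'   `loss_branches` (list of tip sets named by branch child label),
#'   `presence` (named state vector over tips).
#' @export
simulate_dollo <- function(tree, n_losses, seed = NULL, gain_node = NULL) {
  if (is.null(gain_node)) gain_node <- root_node(tree)
  ntip <- ape::Ntip(tree)
  kids <- node_children(tree)
  tu <- tips_under(tree)
  gain_tips <- tu[[gain_node]]
  if (length(gain_tips) < 2L && n_losses > 0L) {
    stop("infeasible n_losses: maximum feasible below this gain node is 0")
  }
  max_feas <- max_feasible_losses(tree, gain_node)
  if (n_losses > max_feas) {
    stop("infeasible n_losses: maximum feasible below this gain node is ",
         max_feas)
  }
  descend <- function(v) {
    if (v <= ntip) return(integer())
    out <- integer()
    for (k in kids[[v]]) out <- c(out, k, descend(k))
    out
  }
  candidates <- descend(gain_node)
  # randomized backtracking: a valid set exists whenever n_losses is
  # feasible, but a purely greedy draw can paint itself into a corner
  extend <- function(chosen, needed) {
    if (needed == 0L) return(chosen)
    for (v in sample(candidates, length(candidates))) {
      if (v %in% chosen) next
      trial <- c(chosen, v)
      lost_tips <- unique(unlist(tu[trial]))
      if (length(lost_tips) >= length(gain_tips)) next
      # the trial set must itself be the maximal absent subtrees
      if (!setequal(maximal_absent(tree, gain_node, lost_tips), trial)) next
      res <- extend(trial, needed - 1L)
      if (!is.null(res)) return(res)
    }
    NULL
  }
  chosen <- with_seed(seed, extend(integer(), n_losses))
  if (is.null(chosen)) {
    stop("infeasible n_losses: maximum feasible below this gain node is ",
         max_feas)
  }
  lost_tips <- unique(unlist(tu[chosen]))
  presence <- stats::setNames(rep("absent", ntip), tree$tip.label)
  presence[setdiff(gain_tips, lost_tips)] <- "present"
  branches <- lapply(chosen, function(v) tu[[v]])
  names(branches) <- vapply(chosen, function(v) node_label(tree, v), "")
  list(tree = tree, gain_node = node_label(tree, gain_node),
       gain_node_num = gain_node, loss_branches = branches,
       presence = presence)
}

# node numbers of maximal all-absent subtrees below `gain`, given lost tips
maximal_absent <- function(tree, gain, lost_tips) {
  ntip <- ape::Ntip(tree)
  kids <- node_children(tree)
  all_absent <- logical(ntip + tree$Nnode)
  for (v in postorder_nodes(tree)) {
    all_absent[v] <- if (v <= ntip) tree$tip.label[v] %in% lost_tips
      else length(kids[[v]]) > 0L && all(all_absent[kids[[v]]])
  }
  out <- integer()
  stack <- kids[[gain]]
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    if (all_absent[v]) out <- c(out, v)
    else if (v > ntip) stack <- c(stack, kids[[v]])
  }
  out
}

# Maximum number of maximal, non-nested loss branches below `gain` keeping
# at least one tip present: dynamic programme over subtree options
# (lose a child wholly = 1 event, or keep it partially present = f(child)).
max_feasible_losses <- function(tree, gain) {
  ntip <- ape::Ntip(tree)
  kids <- node_children(tree)
  f <- numeric(ntip + tree$Nnode)
  for (v in postorder_nodes(tree)) {
    if (v <= ntip) { f[v] <- 0; next }
    vals <- vapply(kids[[v]], function(k) max(1, f[k]), numeric(1))
    part <- vapply(kids[[v]], function(k) f[k], numeric(1))
    # at least one child must stay partially present
    f[v] <- sum(vals) - min(vals - part)
  }
  f[gain]
}
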