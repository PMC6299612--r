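## Signature extraction and clade classification: reference profile,
## sequence-to-profile mapping, loop measurement, plug-motif scoring,
## DUF-B repeat detection.

# profile column layout (widths of consecutive blocks)
profile_layout <- function() {
  widths <- c(nterm = 11L, his12 = 1L, beta1 = 5L, ba1 = 2L, alpha1a = 4L,
              alpha1b = 8L, glu32 = 1L, x33 = 1L, asp34 = 1L, beta2 = 8L,
              cat = 23L, beta3 = 6L, mid1 = 27L, asp91 = 1L, x92 = 1L,
              lys93 = 1L, beta4 = 4L, mid2 = 18L, linker = 3L,
              linker_cys = 1L, mid3 = 138L, plug = 17L, tail = 6L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  block <- function(nm) seq.int(starts[[nm]], ends[[nm]])
  list(
    width = unname(ends[length(ends)]),
    ba1_cols = block("ba1"),
    cat_cols = block("cat"),
    plug_cols = block("plug"),
    linker_cys_col = starts[["linker_cys"]],
    nterm_partner_cols = c(1L, 2L, 3L, 5L),
    active_cols = c(His12 = starts[["his12"]], Glu32 = starts[["glu32"]],
                    Asp34 = starts[["asp34"]],
                    His47 = starts[["cat"]] + CAT_HIS_OFFSET - 1L,
                    Asp91 = starts[["asp91"]], Lys93 = starts[["lys93"]]),
    anchors = c(ba1_left = ends[["beta1"]], ba1_right = starts[["alpha1a"]],
                cat_left = ends[["beta2"]], cat_right = starts[["beta3"]]),
    # completeness core: conserved catalytic-domain columns only (the plug
    # is a membership feature, not a completeness criterion)
    core_cols = unique(c(starts[["his12"]], block("beta1"), block("alpha1a"),
                         starts[["glu32"]], starts[["asp34"]],
                         block("beta2"),
                         starts[["cat"]] + CAT_HIS_OFFSET - 1L,
                         block("beta3"), starts[["asp91"]],
                         starts[["lys93"]], block("beta4"),
                         block("linker"), starts[["linker_cys"]]))
  )
}

# Place one generated exemplar onto the profile columns (row of the
# packaged alignment). Loops shorter than their block are padded with gaps:
# the catalytic loop keeps its first 8 residues left-anchored (covering the
# His and the first cysteines) and its last residues right-anchored.
exemplar_row <- function(residues, truth, layout) {
  chars <- strsplit(residues, "")[[1]]
  row <- rep("-", layout$width)
  put <- function(cols, pos) row[cols] <<- chars[pos]
  a <- layout$anchors
  put(1:17, 1:17)                                   # nterm..beta1 (fixed len)
  put(layout$ba1_cols, truth$ba1_start:truth$ba1_end)
  n_pre <- truth$cat_start - truth$ba1_end - 1L     # alpha1..beta2 block
  put((a[["ba1_right"]]):(a[["cat_left"]]),
      (truth$ba1_end + 1L):(truth$cat_start - 1L))
  lc <- truth$cat_length
  left_n <- min(lc, 8L)
  put(layout$cat_cols[seq_len(left_n)],
      truth$cat_start:(truth$cat_start + left_n - 1L))
  rem <- lc - left_n
  if (rem > 0L) {
    put(layout$cat_cols[(length(layout$cat_cols) - rem + 1L):
                          length(layout$cat_cols)],
        (truth$cat_start + left_n):(truth$cat_end))
  }
  n_post <- truth$length - truth$cat_end            # beta3..tail block
  put((a[["cat_right"]]):(a[["cat_right"]] + n_post - 1L),
      (truth$cat_end + 1L):truth$length)
  stopifnot(n_pre == a[["cat_left"]] - a[["ba1_right"]] + 1L)
  row
}

#' Build the packaged reference profile
#'
#' Constructs the family reference alignment from synthetic exemplars of
#' the four family clades (generated noise-free at fixed seeds), derives
#' per-column residue frequencies (Laplace pseudocount 1) and a log-odds
#' PSSM against a uniform background, annotates the diagnostic columns
#' (beta-alpha-1 loop, catalytic loop, active site, plug motif, linker
#' cysteine), and calibrates the plug-motif presence threshold on 1,000
#' seeded random-shuffle negatives so that at least 99% of them score below
#' it. Deterministic: the same seed always yields the same profile. A
#' user-supplied alignment of real exemplars can be substituted via
#' `alignment`/`truths`.
#'
#' @param seed integer seed for exemplar generation and calibration.
#' @param n_per_clade exemplars generated per family clade.
#' @param alignment optional character matrix (rows = exemplars, columns =
#'   profile columns) replacing the generated exemplars.
#' @return object of class `pld_profile`.
#' @export
build_reference_profile <- function(seed = 20180427L, n_per_clade = 4L,
                                    alignment = NULL) {
  layout <- profile_layout()
  if (is.null(alignment)) {
    rows <- list()
    i <- 0L
    for (clade in c("ST", "AT", "Aquatic", "basal")) {
      for (k in seq_len(n_per_clade)) {
        i <- i + 1L
        ex <- make_family_sequence(clade, seed = seed + i,
                                   id = paste0("ex_", clade, "_", k))
        rows[[i]] <- exemplar_row(ex$record$residues, ex$truth, layout)
      }
    }
    alignment <- do.call(rbind, rows)
  }
  stopifnot(ncol(alignment) == layout$width)
  aa <- setdiff(AA_ALPHABET_20X, "X")
  counts <- apply(alignment, 2L, function(col) {
    tab <- table(factor(col, levels = aa))
    as.numeric(tab)
  })
  rownames(counts) <- aa
  n_ex <- nrow(alignment)
  freq <- (counts + 1) / (n_ex + length(aa))
  # log-odds in half-bit units (the BLOSUM convention), so the affine gap
  # penalties (open 10, extend 1) act on their usual scale
  pssm <- 2 * log2(freq * length(aa))

  profile <- structure(list(
    layout = layout, pssm = pssm, freq = freq, residues = aa,
    n_exemplars = n_ex, gap_open = 10, gap_ext = 1,
    map_score_floor = 100, seed = seed), class = "pld_profile")
  profile$plug_threshold <- calibrate_plug_threshold(profile, seed + 5000L)
  profile
}

# 99th-percentile plug-score threshold on seeded random negatives
calibrate_plug_threshold <- function(profile, seed, n_null = 1000L) {
  scores <- with_seed(seed, {
    vapply(seq_len(n_null), function(i) {
      s <- paste(bg_residues(60L), collapse = "")
      plug_window_score(s, profile)$score
    }, numeric(1))
  })
  sort(scores)[ceiling(0.99 * n_null)] + 1e-09
}

#' @export
print.pld_profile <- function(x, ...) {
  cat("GDPD-like SMase D/PLD reference profile:", x$layout$width,
      "columns,", x$n_exemplars, "exemplars\n",
      " plug threshold:", round(x$plug_threshold, 2), "\n")
  invisible(x)
}

# Shared cached default profile (deterministic, so safe to cache).
profile_cache <- new.env(parent = emptyenv())

#' Default packaged reference profile (cached)
#' @return a `pld_profile`.
#' @export
default_profile <- function() {
  if (is.null(profile_cache$profile)) {
    profile_cache$profile <- build_reference_profile()
  }
  profile_cache$profile
}

residue_index <- function(residues, profile) {
  chars <- strsplit(residues, "")[[1]]
  idx <- match(chars, profile$residues) - 1L
  idx[is.na(idx)] <- -1L
  idx
}

#' Map a record onto the reference profile
#'
#' Ends-free global alignment of the record against the profile PSSM
#' (affine gaps). Returns the record position aligned to every profile
#' column, the covered fraction of the annotated core columns, the mapped
#' active-site positions, and whether the record is mappable at all (score
#' above the profile's floor); unmappable records are treated as
#' non-family downstream.
#'
#' @param record one-row [pld_records()] or an amino-acid string.
#' @param profile a `pld_profile` from [build_reference_profile()].
#' @return list with `score`, `colmap` (integer vector, `NA` = gapped
#'   column), `covered_fraction`, `site_positions` (named), `mappable`.
#' @export
map_to_reference <- function(record, profile = default_profile()) {
  residues <- if (is.data.frame(record)) record$residues[1L] else record
  stopifnot(nzchar(residues))
  idx <- residue_index(residues, profile)
  al <- profile_align_cpp(idx, profile$pssm, profile$gap_open,
                          profile$gap_ext)
  colmap <- al$colmap
  core <- profile$layout$core_cols
  list(score = al$score,
       colmap = colmap,
       covered_fraction = mean(!is.na(colmap[core])),
       site_positions = stats::setNames(
         colmap[profile$layout$active_cols],
         names(profile$layout$active_cols)),
       mappable = al$score >= profile$map_score_floor)
}

#' Measure the beta-alpha-1 and catalytic loops of a mapped record
#'
#' Loop length is the number of record residues between the fixed flanking
#' anchor columns (insertions inside the loop count toward the length, which
#' is what makes the long, variable Aquatic loops measurable). Cysteine
#' positions are reported in record coordinates. When an anchor column is
#' gapped the feature is marked missing (`NA`).
#'
#' @param mapping result of [map_to_reference()].
#' @param record the same record (for residue lookup).
#' @param profile the profile used for the mapping.
#' @return list with `ba1_length`, `cat_loop_length`, `cat_cys_positions`,
#'   `cat_cys_count`, `linker_cys_present`.
#' @export
measure_loops <- function(mapping, record, profile = default_profile()) {
  residues <- if (is.data.frame(record)) record$residues[1L] else record
  chars <- strsplit(residues, "")[[1]]
  a <- profile$layout$anchors
  cm <- mapping$colmap
  span_len <- function(left, right) {
    pl <- cm[left]; pr <- cm[right]
    if (is.na(pl) || is.na(pr) || pr <= pl) return(NA_integer_)
    pr - pl - 1L
  }
  ba1 <- span_len(a[["ba1_left"]], a[["ba1_right"]])
  cat_len <- span_len(a[["cat_left"]], a[["cat_right"]])
  cys_pos <- integer()
  if (!is.na(cat_len) && cat_len > 0L) {
    inside <- (cm[a[["cat_left"]]] + 1L):(cm[a[["cat_right"]]] - 1L)
    cys_pos <- inside[chars[inside] == "C"]
  }
  lk <- cm[profile$layout$linker_cys_col]
  list(ba1_length = ba1, cat_loop_length = cat_len,
       cat_cys_positions = cys_pos, cat_cys_count = length(cys_pos),
       linker_cys_present = !is.na(lk) && chars[lk] == "C")
}

# best 17-column plug-motif window within the final 40 residues
plug_window_score <- function(residues, profile, start_at = NULL) {
  chars <- strsplit(residues, "")[[1]]
  L <- length(chars)
  cols <- profile$layout$plug_cols
  w <- length(cols)
  if (L < w) return(list(score = -Inf, start = NA_integer_))
  score_at <- function(st) {
    idx <- match(chars[st:(st + w - 1L)], profile$residues)
    sum(vapply(seq_len(w), function(k) {
      if (is.na(idx[k])) 0 else profile$pssm[idx[k], cols[k]]
    }, numeric(1)))
  }
  starts <- if (!is.null(start_at)) start_at else
    seq.int(max(1L, L - 39L), L - w + 1L)
  starts <- starts[starts >= 1L & starts <= L - w + 1L]
  if (length(starts) == 0L) return(list(score = -Inf, start = NA_integer_))
  scores <- vapply(starts, score_at, numeric(1))
  best <- which.max(scores)
  list(score = scores[best], start = starts[best])
}

#' Score the C-terminal plug motif
#'
#' Log-odds PSSM score over the 17 plug-motif columns, evaluated at the
#' mapped motif location when a profile mapping is supplied (falling back
#' to the best-scoring window within the final 40 residues otherwise).
#' Presence calls use the profile's calibrated threshold, set so that at
#' least 99% of seeded random negatives score below it.
#'
#' @param record one-row [pld_records()] or an amino-acid string.
#' @param profile a `pld_profile`.
#' @param mapping optional result of [map_to_reference()].
#' @return list with `plug_score`, `plug_present`, `motif_span`.
#' @export
score_plug_motif <- function(record, profile = default_profile(),
                             mapping = NULL) {
  residues <- if (is.data.frame(record)) record$residues[1L] else record
  best <- plug_window_score(residues, profile)
  if (!is.null(mapping)) {
    st <- mapping$colmap[profile$layout$plug_cols[1L]]
    if (!is.na(st)) {
      mapped <- plug_window_score(residues, profile, start_at = st)
      if (mapped$score > best$score) best <- mapped
    }
  }
  w <- length(profile$layout$plug_cols)
  list(plug_score = best$score,
       plug_present = is.finite(best$score) &&
         best$score >= profile$plug_threshold,
       motif_span = if (is.na(best$start)) c(NA_integer_, NA_integer_)
         else c(best$start, best$start + w - 1L))
}

#' Detect DUF-B cysteine-rich repeats
#'
#' Scans the sequence for the packaged DUF-B signature: ten cysteines at
#' the canonical inter-cysteine spacings (each spacing tolerating +/- `tol`
#' residues), followed by a glycine-rich stretch (>= 3 Gly in the next six
#' residues) and a tyrosine. Non-overlapping matches are counted left to
#' right.
#'
#' @param record one-row [pld_records()] or an amino-acid string.
#' @param tol per-spacing tolerance in residues.
#' @return list with `count` and `spans` (data.frame `start`, `end`).
#' @export
detect_dufb_repeats <- function(record, tol = 2L) {
  residues <- if (is.data.frame(record)) record$residues[1L] else record
  chars <- strsplit(residues, "")[[1]]
  cys <- which(chars == "C")
  spans <- list()
  scan_from <- 1L
  for (c0 in cys) {
    if (c0 < scan_from) next
    cur <- c0
    ok <- TRUE
    for (g in DUFB_GAPS) {
      lo <- cur + g + 1L - tol; hi <- cur + g + 1L + tol
      nxt <- cys[cys >= lo & cys <= hi]
      if (length(nxt) == 0L) { ok <- FALSE; break }
      target <- cur + g + 1L
      cur <- nxt[which.min(abs(nxt - target))]
    }
    if (!ok) next
    tail_start <- cur + 1L
    tail6 <- chars[seq.int(tail_start, min(tail_start + 5L, length(chars)))]
    if (sum(tail6 == "G") < 3L) next
    ys <- which(chars == "Y")
    y <- ys[ys > cur & ys <= cur + 10L]
    if (length(y) == 0L) next
    spans[[length(spans) + 1L]] <- c(start = c0, end = y[1L])
    scan_from <- y[1L] + 1L
  }
  df <- if (length(spans)) as.data.frame(do.call(rbind, spans)) else
    data.frame(start = integer(), end = integer())
  list(count = nrow(df), spans = df)
}

#' Clade signature specification
#'
#' Default rule parameters for the three family clades plus the family and
#' decoy gates.
#'
#' @param st_length,st_tol ST catalytic-loop length and tolerance.
#' @param st_min_cys minimum ST loop cysteines (the conserved pair).
#' @param at_range AT catalytic-loop length range.
#' @param aquatic_min_length,aquatic_min_cys Aquatic loop minimums.
#' @param ba1_max maximum family beta-alpha-1 loop length; decoys exceed it
#'   by at least `decoy_ba1_excess`.
#' @param decoy_ba1_excess extra loop length marking a GDPD-style loop.
#' @return a `pld_clade_spec` list.
#' @export
clade_signature_spec <- function(st_length = 15L, st_tol = 1L,
                                 st_min_cys = 2L, at_range = c(9L, 13L),
                                 aquatic_min_length = 17L,
                                 aquatic_min_cys = 4L, ba1_max = 3L,
                                 decoy_ba1_excess = 6L) {
  stopifnot(at_range[2L] < st_length, st_length < aquatic_min_length)
  structure(list(st_length = st_length, st_tol = st_tol,
                 st_min_cys = st_min_cys, at_range = at_range,
                 aquatic_min_length = aquatic_min_length,
                 aquatic_min_cys = aquatic_min_cys, ba1_max = ba1_max,
                 decoy_ba1_excess = decoy_ba1_excess),
            class = "pld_clade_spec")
}

#' Extract the full feature profile of a record
#'
#' @param record one-row [pld_records()] or an amino-acid string.
#' @param profile a `pld_profile`.
#' @return list of features consumed by [classify_clade()].
#' @export
extract_features <- function(record, profile = default_profile()) {
  mapping <- map_to_reference(record, profile)
  loops <- measure_loops(mapping, record, profile)
  plug <- score_plug_motif(record, profile, mapping)
  dufb <- detect_dufb_repeats(record)
  site <- screen_active_site(record, mapping$site_positions)
  c(loops, plug,
    list(dufb_count = dufb$count, dufb_spans = dufb$spans,
         active_site_states = site$states,
         active_site_verdict = site$verdict,
         mappable = mapping$mappable, map_score = mapping$score,
         covered_fraction = mapping$covered_fraction))
}

#' Classify a feature profile into a family clade
#'
#' Decision order: (1) non-family when the plug motif is absent or the
#' beta-alpha-1 loop exceeds the family gate (or the record is unmappable);
#' (2) ST-like (loop length 15 +/- tolerance with the conserved cysteine
#' pair); (3) Aquatic (long loop, >= 4 cysteines); (4) AT-like (short
#' variable loop without cysteines); (5) otherwise basal/unclassified. The
#' catalytic-loop signature cannot distinguish AT-like from basal
#' sequences, so AT-like calls carry that caveat in the rule trace.
#'
#' @param features result of [extract_features()].
#' @param spec a [clade_signature_spec()].
#' @return list with `label` (one of `ST-like`, `Aquatic`, `AT-like`,
#'   `basal/unclassified`, `non-family`) and `trace` (character vector of
#'   the comparisons made).
#' @export
classify_clade <- function(features, spec = clade_signature_spec()) {
  trace <- character()
  note <- function(x) trace <<- c(trace, x)
  lab <- NULL

  if (!isTRUE(features$mappable)) {
    note("unmappable to reference profile -> non-family")
    lab <- "non-family"
  } else if (!isTRUE(features$plug_present)) {
    note(sprintf("plug motif absent (score %.1f < threshold) -> non-family",
                 features$plug_score))
    lab <- "non-family"
  } else if (!is.na(features$ba1_length) &&
             features$ba1_length > spec$ba1_max) {
    note(sprintf("ba1 loop %d > family gate %d -> non-family (GDPD-like)",
                 features$ba1_length, spec$ba1_max))
    lab <- "non-family"
  } else {
    note(sprintf("plug present, ba1 loop %s <= %d: family member",
                 features$ba1_length, spec$ba1_max))
    len <- features$cat_loop_length
    ncys <- features$cat_cys_count
    if (is.na(len)) {
      note("catalytic loop unmeasurable -> basal/unclassified")
      lab <- "basal/unclassified"
    } else if (abs(len - spec$st_length) <= spec$st_tol &&
               ncys >= spec$st_min_cys) {
      note(sprintf("loop %d ~ %d with %d cysteines (pair conserved%s) -> ST-like",
                   len, spec$st_length, ncys,
                   if (features$linker_cys_present) ", linker Cys present"
                   else ""))
      lab <- "ST-like"
    } else if (len >= spec$aquatic_min_length &&
               ncys >= spec$aquatic_min_cys) {
      note(sprintf("loop %d >= %d with %d cysteines -> Aquatic", len,
                   spec$aquatic_min_length, ncys))
      lab <- "Aquatic"
    } else if (len >= spec$at_range[1L] && len <= spec$at_range[2L] &&
               ncys == 0L) {
      note(sprintf(
        "loop %d in [%d,%d], no cysteines -> AT-like (basal not excluded by this signature)",
        len, spec$at_range[1L], spec$at_range[2L]))
      lab <- "AT-like"
    } else {
      note(sprintf("loop %d / %d cysteines matches no clade rule -> basal/unclassified",
                   len, ncys))
      lab <- "basal/unclassified"
    }
  }
  list(label = lab, trace = trace)
}

#' Classify a set of records
#'
#' @param records a [pld_records()] data.frame.
#' @param profile a `pld_profile`.
#' @param spec a [clade_signature_spec()].
#' @return data.frame with `id`, `label`, `plug_score`, `ba1_length`,
#'   `cat_loop_length`, `cys_pattern`, `dufb_repeats`, `rule_trace`.
#' @export
classify_records <- function(records, profile = default_profile(),
                             spec = clade_signature_spec()) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    f <- extract_features(records[i, , drop = FALSE], profile)
    cl <- classify_clade(f, spec)
    data.frame(
      id = records$id[i], label = cl$label,
      plug_score = round(f$plug_score, 2),
      ba1_length = f$ba1_length, cat_loop_length = f$cat_loop_length,
      cys_pattern = paste0(f$cat_cys_count, "loop",
                           if (f$linker_cys_present) "+linker" else ""),
      dufb_repeats = f$dufb_count,
      rule_trace = paste(cl$trace, collapse = " | "),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-column residue frequencies of an alignment
#'
#' @param alignment character vector of equal-length aligned sequences, or
#'   a character matrix (rows = sequences).
#' @param columns column indices to tabulate (default: all).
#' @return matrix of frequencies (rows: residues plus `-`), columns summing
#'   to 1.
#' @export
column_frequencies <- function(alignment, columns = NULL) {
  if (is.character(alignment) && !is.matrix(alignment)) {
    if (length(alignment) == 0L) stop("empty alignment")
    nc <- unique(nchar(alignment))
    if (length(nc) != 1L) stop("aligned sequences differ in length")
    alignment <- do.call(rbind, strsplit(alignment, ""))
  }
  if (nrow(alignment) == 0L) stop("empty alignment")
  if (is.null(columns)) columns <- seq_len(ncol(alignment))
  lv <- c(setdiff(AA_ALPHABET_20X, "X"), "X", "-")
  out <- vapply(columns, function(j) {
    tab <- table(factor(alignment[, j], levels = lv))
    as.numeric(tab) / nrow(alignment)
  }, numeric(length(lv)))
  rownames(out) <- lv
  colnames(out) <- columns
  out
}
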