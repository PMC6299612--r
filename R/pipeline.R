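## End-to-end orchestration: screen -> curate -> classify -> gain/loss,
## with an audit trail and a reproducible run manifest.

#' Pipeline configuration
#'
#' @param fasta path to the candidate protein FASTA.
#' @param hits optional path to the 12-column tabular hit file (screening
#'   skipped when `NULL`).
#' @param query_lengths optional path to a two-column TSV (query id,
#'   length), required with `hits`.
#' @param tree optional Newick path for the gain/loss stage.
#' @param presence optional presence/absence TSV path (with `tree`).
#' @param references optional FASTA of contamination reference sequences
#'   (e.g. known mite proteins).
#' @param out_dir output directory.
#' @param seed integer seed recorded in the manifest (the pipeline itself
#'   is deterministic).
#' @param screen a [screen_policy()].
#' @param curation a [curation_policy()].
#' @param clade_spec a [clade_signature_spec()].
#' @param origin_mode origin placement for [dollo_losses()].
#' @param gain_costs gain-cost sweep for [scenario_table()].
#' @return a `pld_pipeline_config` list.
#' @export
pipeline_config <- function(fasta, hits = NULL, query_lengths = NULL,
                            tree = NULL, presence = NULL, references = NULL,
                            out_dir = "pldfam_out", seed = 1L,
                            screen = screen_policy(),
                            curation = curation_policy(),
                            clade_spec = clade_signature_spec(),
                            origin_mode = "root",
                            gain_costs = c(1, 2, 5, 10)) {
  for (p in c(fasta, hits, query_lengths, tree, presence, references)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  if (!is.null(hits) && is.null(query_lengths)) {
    stop("query_lengths is required when hits are supplied")
  }
  structure(list(fasta = fasta, hits = hits, query_lengths = query_lengths,
                 tree = tree, presence = presence, references = references,
                 out_dir = out_dir, seed = as.integer(seed), screen = screen,
                 curation = curation, clade_spec = clade_spec,
                 origin_mode = origin_mode, gain_costs = gain_costs),
            class = "pld_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: (1) screening of tabular hits under the E-value/coverage policy;
#' (2) curation of the screened sequences (fragments, redundancy,
#' active-site divergence, contaminants, evidence confidence); (3) signature
#' classification; (4) gain/loss reconciliation when a tree and presence
#' matrix are configured. Writes `accepted.tsv`, `kept.fa`, `audit.tsv`,
#' `calls.tsv`, `features.tsv`, `gainloss.tsv`, and `manifest.json` into
#' the output directory. Identical configuration and inputs produce
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pld_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  audit <- list()
  note <- function(ids, action, rule, detail = "") {
    if (length(ids)) {
      audit[[length(audit) + 1L]] <<- data.frame(
        id = ids, action = action, rule = rule, detail = detail,
        stringsAsFactors = FALSE)
    }
  }
  counts <- list()

  records <- stage("read", read_fasta(config$fasta))
  counts$input <- nrow(records)

  # stage 1: homology screening
  if (!is.null(config$hits)) {
    ql <- utils::read.delim(config$query_lengths, stringsAsFactors = FALSE)
    hits <- stage("screen", read_hits_tabular(config$hits, ql))
    scr <- stage("screen", accept_hits(hits, config$screen))
    utils::write.table(scr$rationale, file.path(config$out_dir,
                                                "accepted.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dropped <- setdiff(records$id, scr$accepted)
    note(dropped, "removed", "screen", "not accepted by E-value/coverage rule")
    records <- records[records$id %in% scr$accepted, , drop = FALSE]
  } else {
    scr <- NULL
  }
  counts$screened <- nrow(records)

  profile <- default_profile()

  # stage 2: curation
  cur <- stage("curate", {
    mappings <- lapply(seq_len(nrow(records)), function(i)
      map_to_reference(records[i, , drop = FALSE], profile))
    domain_info <- data.frame(
      id = records$id,
      covered_fraction = vapply(mappings, `[[`, 0, "covered_fraction"),
      stringsAsFactors = FALSE)
    fr <- filter_fragments(records, domain_info, config$curation)
    note(fr$removed$id, "removed", "fragment", fr$removed$reason)
    note(fr$flagged, "flagged", "fragment", "retained exception")
    keep <- records$id %in% fr$kept
    records <- records[keep, , drop = FALSE]
    mappings <- mappings[keep]

    red <- filter_redundancy(records, config$curation$redundancy_identity,
                             config$curation$exceptions)
    if (nrow(red$removed)) {
      note(red$removed$id, "removed", "redundancy",
           paste0("representative=", red$removed$representative))
    }
    keep <- records$id %in% red$kept
    records <- records[keep, , drop = FALSE]
    mappings <- mappings[keep]

    verdicts <- vapply(seq_len(nrow(records)), function(i) {
      screen_active_site(records[i, , drop = FALSE],
                         mappings[[i]]$site_positions)$verdict
    }, "")
    div <- records$id[verdicts == "divergent"]
    note(div, "removed", "active-site", "nonconservative core active site")
    records <- records[verdicts != "divergent", , drop = FALSE]

    if (!is.null(config$references)) {
      refs <- read_fasta(config$references)
      fl <- flag_contaminants(records, refs, config$curation)
      if (nrow(fl)) {
        note(fl$id, "removed", "contaminant",
             paste0("reference=", fl$reference, " identity=",
                    round(fl$identity, 1)))
        records <- records[!records$id %in% fl$id, , drop = FALSE]
      }
    }

    conf <- flag_low_confidence(records, config$curation)
    low <- conf$id[conf$confidence == "low"]
    note(low, "flagged", "low-confidence",
         "taxon group lacks two independent evidence types")
    list(records = records, confidence = conf)
  })
  records <- cur$records
  counts$curated <- nrow(records)
  write_fasta(records, file.path(config$out_dir, "kept.fa"))

  # stage 3: classification
  calls <- stage("classify", classify_records(records, profile,
                                              config$clade_spec))
  calls$confidence <- cur$confidence$confidence[match(calls$id,
                                                      cur$confidence$id)]
  utils::write.table(calls, file.path(config$out_dir, "calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  feats <- lapply(seq_len(nrow(records)), function(i) {
    f <- extract_features(records[i, , drop = FALSE], profile)
    data.frame(id = records$id[i], plug_score = round(f$plug_score, 2),
               plug_present = f$plug_present, ba1_length = f$ba1_length,
               cat_loop_length = f$cat_loop_length,
               cat_cys_count = f$cat_cys_count,
               linker_cys = f$linker_cys_present,
               dufb_count = f$dufb_count,
               covered_fraction = round(f$covered_fraction, 3),
               stringsAsFactors = FALSE)
  })
  features <- do.call(rbind, feats)
  utils::write.table(features, file.path(config$out_dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts$classified <- nrow(calls)

  # stage 4: gain/loss reconciliation
  gainloss <- NULL
  if (!is.null(config$tree) && !is.null(config$presence)) {
    gainloss <- stage("gainloss", {
      tree <- read_newick(config$tree)
      pres <- read_presence(config$presence)
      fams <- setdiff(names(pres), "taxon")
      rows <- lapply(fams, function(fam) {
        col <- presence_column(pres, fam)
        rep <- dollo_losses(tree, col, origin_mode = config$origin_mode,
                            family = fam)
        data.frame(family = fam, origin = rep$origin_node,
                   loss_count = rep$loss_count,
                   loss_branches = paste(names(rep$loss_branches),
                                         collapse = ","),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
    utils::write.table(gainloss, file.path(config$out_dir, "gainloss.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  audit_df <- if (length(audit)) do.call(rbind, audit) else
    data.frame(id = character(), action = character(), rule = character(),
               detail = character(), stringsAsFactors = FALSE)
  utils::write.table(audit_df, file.path(config$out_dir, "audit.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "pldfam",
    version = as.character(utils::packageVersion("pldfam")),
    seed = config$seed,
    policies = list(screen = unclass(config$screen),
                    curation = unclass(config$curation),
                    clade_spec = unclass(config$clade_spec)),
    stage_counts = counts)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(records = records, calls = calls, features = features,
                 screen = scr, gainloss = gainloss, audit = audit_df,
                 manifest = manifest))
}

#' Tabulate clade calls by taxon group
#'
#' @param calls data.frame with at least `id` and `label` (as written by
#'   [run_pipeline()] or [classify_records()]); a `confidence` column, when
#'   present, marks low-confidence records in the output.
#' @param records the [pld_records()] the calls refer to (for lineages).
#' @param rank lineage rank defining the group (default 2 = phylum).
#' @return data.frame of counts per (group x label) with a totals row.
#' @export
summarize_by_taxon <- function(calls, records, rank = 2L) {
  if (nrow(calls) == 0L) {
    return(data.frame(group = character(), label = character(),
                      n = integer(), n_low_confidence = integer(),
                      stringsAsFactors = FALSE))
  }
  lin <- records$taxon[match(calls$id, records$id)]
  group <- vapply(lin, function(x) {
    if (length(x) == 0L) return("(unknown)")
    paste(x[seq_len(min(rank, length(x)))], collapse = ";")
  }, "")
  low <- if ("confidence" %in% names(calls)) calls$confidence == "low"
    else rep(FALSE, nrow(calls))
  agg <- stats::aggregate(list(n = seq_len(nrow(calls))),
                          by = list(group = group, label = calls$label),
                          FUN = length)
  agg_low <- stats::aggregate(list(n_low_confidence = low),
                              by = list(group = group, label = calls$label),
                              FUN = sum)
  out <- merge(agg, agg_low, by = c("group", "label"))
  out <- out[order(out$group, out$label), , drop = FALSE]
  total <- data.frame(group = "TOTAL", label = "", n = sum(out$n),
                      n_low_confidence = sum(out$n_low_confidence),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  rbind(out, total)
}
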