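## Reconciliation of gene-family presence/absence with a rooted species tree:
## Dollo loss counting under a single-origin vertical-descent model, and
## minimum-cost gain/loss histories with asymmetric event costs.

# ---- tree helpers (phylo, rooted, polytomies allowed) ----

root_node <- function(tree) ape::Ntip(tree) + 1L

node_children <- function(tree) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", n_nodes)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2L])
  }
  kids
}

node_parent <- function(tree) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  par <- rep(NA_integer_, n_nodes)
  par[tree$edge[, 2L]] <- tree$edge[, 1L]
  par
}

# postorder list of node numbers (children before parents)
postorder_nodes <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  c(tree$edge[, 2L][!duplicated(tree$edge[, 2L])], root_node(tree))
}

# tip labels under each node, as a list indexed by node number
tips_under <- function(tree) {
  ntip <- ape::Ntip(tree)
  kids <- node_children(tree)
  out <- vector("list", ntip + tree$Nnode)
  for (v in postorder_nodes(tree)) {
    if (v <= ntip) {
      out[[v]] <- tree$tip.label[v]
    } else {
      out[[v]] <- unlist(lapply(kids[[v]], function(k) out[[k]]))
    }
  }
  out
}

node_label <- function(tree, v) {
  ntip <- ape::Ntip(tree)
  if (v <= ntip) return(tree$tip.label[v])
  lab <- tree$node.label[v - ntip]
  if (is.null(lab) || is.na(lab) || !nzchar(lab)) paste0("node", v) else lab
}

# ---- presence-state handling ----

# Accepts a character vector of present tip names, or a named vector of
# states over tips ("present"/"absent"/"unknown"); returns a named state
# vector covering every tip of `tree`.
normalize_presence <- function(tree, presence) {
  tips <- tree$tip.label
  if (is.null(names(presence))) {
    unknownable <- setdiff(presence, tips)
    if (length(unknownable)) {
      stop("present taxa not in tree: ", paste(unknownable, collapse = ", "))
    }
    states <- stats::setNames(rep("absent", length(tips)), tips)
    states[presence] <- "present"
    return(states)
  }
  bad <- setdiff(names(presence), tips)
  if (length(bad)) stop("taxa not in tree: ", paste(bad, collapse = ", "))
  states <- stats::setNames(rep("absent", length(tips)), tips)
  states[names(presence)] <- normalize_states(presence)
  states
}

# Applies the unknown-state policy; returns list(tree, states, unknown_tips).
apply_unknown_policy <- function(tree, states,
                                 unknown = c("excluded", "absent", "present")) {
  unknown_policy <- match.arg(unknown)
  unk <- names(states)[states == "unknown"]
  if (length(unk) == 0L) {
    return(list(tree = tree, states = states, unknown_tips = character()))
  }
  if (unknown_policy == "absent") {
    states[unk] <- "absent"
  } else if (unknown_policy == "present") {
    states[unk] <- "present"
  } else {
    if (length(unk) >= ape::Ntip(tree) - 1L) {
      stop("cannot exclude unknown tips: fewer than 2 resolved tips remain")
    }
    tree <- ape::drop.tip(tree, unk, collapse.singles = TRUE)
    states <- states[tree$tip.label]
  }
  list(tree = tree, states = states, unknown_tips = unk)
}

# ---- Dollo loss counting ----

#' Count gene losses under a single-origin (Dollo) model
#'
#' Places exactly one gain of the family at an origin node and explains every
#' absence below it by losses on the maximal all-absent subtrees. Because the
#' loss branches are maximal, the returned loss count is the minimum over all
#' single-gain explanations.
#'
#' @param tree rooted `phylo` tree (polytomies allowed).
#' @param presence character vector of present tip names, or a named state
#'   vector over tips with values `present`/`absent`/`unknown`.
#' @param origin_mode `"mrca"` (default) puts the gain on the most recent
#'   common ancestor of the present tips; `"root"` puts it at the tree root.
#' @param unknown policy for `unknown` tips: `"excluded"` (drop from the tree
#'   and report separately; default), `"absent"`, or `"present"`.
#' @param family optional family name carried into the report.
#' @return object of class `pld_loss_report`: a list with `family`,
#'   `origin_node` (label), `origin_mode`, `loss_branches` (list of per-branch
#'   tip sets, named by the branch's child node label), `loss_count`,
#'   `present_tips`, and `unknown_tips`.
#' @export
dollo_losses <- function(tree, presence, origin_mode = c("mrca", "root"),
                         unknown = "excluded", family = NA_character_) {
  origin_mode <- match.arg(origin_mode)
  states <- normalize_presence(tree, presence)
  adj <- apply_unknown_policy(tree, states, unknown)
  tree <- adj$tree; states <- adj$states
  present <- names(states)[states == "present"]
  if (length(present) == 0L) stop("no present tips: cannot place a gain")

  ntip <- ape::Ntip(tree)
  kids <- node_children(tree)
  tu <- tips_under(tree)
  all_absent <- logical(ntip + tree$Nnode)
  for (v in postorder_nodes(tree)) {
    all_absent[v] <- if (v <= ntip) states[tree$tip.label[v]] == "absent"
      else all(all_absent[kids[[v]]])
  }

  origin <- if (origin_mode == "root") root_node(tree) else {
    if (length(present) == 1L) match(present, tree$tip.label)
    else ape::getMRCA(tree, present)
  }

  # maximal all-absent subtrees strictly below the origin
  loss_nodes <- integer()
  if (!(origin <= ntip)) {
    stack <- kids[[origin]]
    while (length(stack)) {
      v <- stack[[1L]]; stack <- stack[-1L]
      if (all_absent[v]) {
        loss_nodes <- c(loss_nodes, v)
      } else if (v > ntip) {
        stack <- c(stack, kids[[v]])
      }
    }
  }
  branches <- lapply(loss_nodes, function(v) tu[[v]])
  names(branches) <- vapply(loss_nodes, function(v) node_label(tree, v), "")
  structure(list(
    family = family,
    origin_node = node_label(tree, origin),
    origin_mode = origin_mode,
    loss_branches = branches,
    loss_count = length(branches),
    present_tips = present,
    unknown_tips = adj$unknown_tips
  ), class = "pld_loss_report")
}

#' @export
print.pld_loss_report <- function(x, ...) {
  cat("Dollo loss report", if (!is.na(x$family)) paste0("(", x$family, ")"),
      "\n  origin:", x$origin_node, paste0("[", x$origin_mode, "]"),
      "\n  losses:", x$loss_count, "\n")
  if (length(x$unknown_tips)) {
    cat("  unknown tips (excluded):", paste(x$unknown_tips, collapse = ", "),
        "\n")
  }
  invisible(x)
}

# ---- minimum-cost gain/loss histories ----

#' Minimum-cost gain/loss history on a rooted tree
#'
#' Two-state (absent/present) ancestral reconstruction with asymmetric
#' transition costs: a gain (absent to present) costs `gain_cost` and a loss
#' (present to absent) costs `loss_cost`, summed over branches by dynamic
#' programming from the tips to the root. The state prior at the root is
#' absent, so a family present at the root is charged one origin gain (free
#' when `gain_cost` is infinite, which reproduces the single-origin Dollo
#' model exactly). Ties at the root favour the absent state (gains placed as
#' late as possible); ties along branches favour keeping the parental state.
#'
#' @inheritParams dollo_losses
#' @param gain_cost positive cost per gain (may be `Inf`).
#' @param loss_cost positive cost per loss.
#' @return list with `total_cost`, `n_gains` (origin included), `n_losses`,
#'   `events` (data.frame: `node`, `type`), `states` (named by node label),
#'   `root_state`, and `n_co_optimal` (number of co-optimal ancestral state
#'   assignments).
#' @export
min_cost_history <- function(tree, presence, gain_cost = 1, loss_cost = 1,
                             unknown = "excluded") {
  stopifnot(gain_cost > 0, loss_cost > 0, is.finite(loss_cost))
  states <- normalize_presence(tree, presence)
  if (all(states == "unknown")) stop("all tip states unknown")
  adj <- apply_unknown_policy(tree, states, unknown)
  tree <- adj$tree; states <- adj$states

  ntip <- ape::Ntip(tree)
  n_nodes <- ntip + tree$Nnode
  kids <- node_children(tree)
  # state 1 = absent, 2 = present; trans[s, t] = cost of parent s -> child t
  trans <- matrix(c(0, loss_cost, gain_cost, 0), 2L, 2L,
                  dimnames = list(c("absent", "present"),
                                  c("absent", "present")))
  cost <- matrix(Inf, n_nodes, 2L)
  nopt <- matrix(0, n_nodes, 2L)
  for (v in postorder_nodes(tree)) {
    if (v <= ntip) {
      s <- states[tree$tip.label[v]]
      cost[v, ] <- if (s == "present") c(Inf, 0) else c(0, Inf)
      nopt[v, ] <- ifelse(is.finite(cost[v, ]), 1, 0)
    } else {
      for (s in 1:2) {
        tot <- 0; cnt <- 1
        for (k in kids[[v]]) {
          opts <- cost[k, ] + trans[s, ]
          m <- min(opts)
          tot <- tot + m
          cnt <- cnt * sum(nopt[k, which(opts == m)])
        }
        cost[v, s] <- tot
        nopt[v, s] <- cnt
      }
    }
  }
  r <- root_node(tree)
  origin_charge <- c(0, if (is.finite(gain_cost)) gain_cost else 0)
  root_cost <- cost[r, ] + origin_charge
  total <- min(root_cost)
  if (!is.finite(total)) stop("no finite-cost history exists")
  root_state <- which(root_cost == total)[1L]  # absent favoured on tie
  n_co <- sum(nopt[r, which(root_cost == total)])

  # backtrack one optimal assignment (prefer parental state on ties)
  assign <- integer(n_nodes)
  assign[r] <- root_state
  preorder <- rev(postorder_nodes(tree))
  for (v in preorder) {
    if (v <= ntip) next
    s <- assign[v]
    for (k in kids[[v]]) {
      opts <- cost[k, ] + trans[s, ]
      best <- which(opts == min(opts))
      assign[k] <- if (s %in% best) s else best[1L]
    }
  }
  par <- node_parent(tree)
  ev_nodes <- which(!is.na(par) & assign != assign[par])
  ev_type <- ifelse(assign[ev_nodes] == 2L, "gain", "loss")
  events <- data.frame(
    node = vapply(ev_nodes, function(v) node_label(tree, v), ""),
    type = ev_type, stringsAsFactors = FALSE)
  n_gains <- sum(ev_type == "gain") + (root_state == 2L)
  labels <- vapply(seq_len(n_nodes), function(v) node_label(tree, v), "")
  list(total_cost = total,
       n_gains = n_gains,
       n_losses = sum(ev_type == "loss"),
       events = events,
       states = stats::setNames(c("absent", "present")[assign], labels),
       root_state = c("absent", "present")[root_state],
       n_co_optimal = n_co)
}

#' Gain/loss scenario table over a sweep of gain costs
#'
#' Summarises, for each gain cost in `gain_costs` (loss cost fixed at
#' `loss_cost`), the minimum-cost history of a presence column, plus a pure
#' single-origin (Dollo) row with `gain_cost = Inf`. As the gain/loss cost
#' ratio rises, the number of gains in the optimum is non-increasing.
#'
#' @inheritParams min_cost_history
#' @param gain_costs numeric vector of finite gain costs to sweep.
#' @return data.frame with columns `gain_cost`, `cost_ratio`, `n_gains`,
#'   `n_losses`, `total_cost`, `dollo` (logical row marker).
#' @export
scenario_table <- function(tree, presence, gain_costs = c(1, 2, 5, 10),
                           loss_cost = 1, unknown = "excluded") {
  rows <- lapply(c(sort(gain_costs), Inf), function(g) {
    h <- min_cost_history(tree, presence, gain_cost = g,
                          loss_cost = loss_cost, unknown = unknown)
    data.frame(gain_cost = g, cost_ratio = g / loss_cost,
               n_gains = h$n_gains, n_losses = h$n_losses,
               total_cost = h$total_cost, dollo = !is.finite(g))
  })
  do.call(rbind, rows)
}

# ---- monophyly ----

#' Test whether a tip set is monophyletic on a rooted gene tree
#'
#' @param gene_tree rooted `phylo`.
#' @param tip_set character vector of tip labels (must all exist).
#' @return list with `monophyletic` (logical), `mrca` (node label), and
#'   `clade_size` (tip count of the smallest clade containing `tip_set`;
#'   equals `length(tip_set)` iff monophyletic). Singletons are monophyletic
#'   by convention.
#' @export
is_monophyletic <- function(gene_tree, tip_set) {
  missing <- setdiff(tip_set, gene_tree$tip.label)
  if (length(missing)) {
    stop("unknown tip name(s): ", paste(missing, collapse = ", "))
  }
  tip_set <- unique(tip_set)
  if (length(tip_set) == 1L) {
    return(list(monophyletic = TRUE, mrca = tip_set, clade_size = 1L))
  }
  mrca <- ape::getMRCA(gene_tree, tip_set)
  clade_tips <- tips_under(gene_tree)[[mrca]]
  list(monophyletic = setequal(clade_tips, tip_set),
       mrca = node_label(gene_tree, mrca),
       clade_size = length(clade_tips))
}

# ---- packaged example data ----

#' Taxon-level eukaryote tree and PLD family presence annotations
#'
#' Loads the packaged phylum/class-level eukaryotic consensus tree (30 tips,
#' labelled internal clades: M Metazoa, C Cnidaria, D Deuterostomia,
#' P Protostomia, S Spiralia, E Ecdysozoa, A Arthropoda, H Hexapoda) together
#' with the per-taxon presence/absence annotations of the ST-like and
#' Aquatic GDPD-like SMase D/PLD families compiled from published genome and
#' transcriptome surveys. Running [dollo_losses()] with the origin at the
#' root on this dataset gives the loss counts implied by a single ancient
#' duplication followed by strictly vertical descent.
#'
#' @return list with `tree` (`phylo`) and `presence` (data.frame with
#'   columns `taxon`, `ST`, `Aquatic`).
#' @export
example_gainloss_data <- function() {
  tree <- read_newick(system.file("extdata", "eukaryote_tree.nwk",
                                  package = "pldfam", mustWork = TRUE))
  presence <- read_presence(system.file("extdata", "pld_presence.tsv",
                                        package = "pldfam", mustWork = TRUE))
  list(tree = tree, presence = presence)
}

#' Presence column as a named state vector
#'
#' @param presence data.frame from [read_presence()].
#' @param family column name.
#' @return named character vector of states keyed by taxon.
#' @export
presence_column <- function(presence, family) {
  stopifnot(family %in% names(presence))
  stats::setNames(presence[[family]], presence$taxon)
}
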