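#' Minimum state changes of a binary character on a rooted tree
#'
#' Small-parsimony (Sankoff) count of the minimum number of state changes
#' needed to explain presence/absence at the tips under unit symmetric costs.
#' Multifurcations are handled directly; on binary trees the result equals
#' Fitch parsimony.
#'
#' @param tree Rooted [ape::phylo] tree.
#' @param tip_states Named character/logical vector over all tip labels:
#'   `"present"`/`"absent"` (or TRUE/FALSE).
#' @return Integer minimum number of changes.
#' @export
min_changes <- function(tree, tip_states) {
  cost <- matrix(c(0, 1, 1, 0), 2, 2,
                 dimnames = list(c("absent", "present"),
                                 c("absent", "present")))
  sankoff_root_costs(tree, tip_states, cost) |> min() |> as.integer()
}

#' Gains when the character can never be lost
#'
#' Minimum number of absent-to-present transitions when present-to-absent
#' transitions are forbidden. Equals the number of maximal all-present clades
#' (a Dollo-style scenario in reverse: the trait is cheap to gain, never
#' lost once gained).
#'
#' @inheritParams min_changes
#' @return Integer number of gains.
#' @export
scenario_gains_no_losses <- function(tree, tip_states) {
  cost <- matrix(c(0, Inf, 1, 0), 2, 2,
                 dimnames = list(c("absent", "present"),
                                 c("absent", "present")))
  ## cost[from, to]: absent->present = 1 (gain), present->absent = Inf
  sankoff_root_costs(tree, tip_states, cost) |> min() |> as.integer()
}

#' Losses when the character was gained once at an ancestral node
#'
#' Minimum number of present-to-absent transitions given the character is
#' present at `gain_node` and cannot be regained below it. Equals the number
#' of maximal all-absent clades below the gain node. Every present tip must
#' descend from `gain_node`.
#'
#' @inheritParams min_changes
#' @param gain_node Node where the single gain happened: `"root"` (default)
#'   or an internal node number.
#' @return Integer number of losses.
#' @export
scenario_losses_given_root_gain <- function(tree, tip_states,
                                            gain_node = "root") {
  states <- normalize_states(tree, tip_states)
  root <- ape::Ntip(tree) + 1L
  node <- if (identical(gain_node, "root")) root else as.integer(gain_node)
  if (node != root) {
    clade_tips <- tree$tip.label[unlist(clade_tip_indices(tree, node))]
    outside_present <- setdiff(names(states)[states == "present"], clade_tips)
    if (length(outside_present)) {
      abort(paste("present tip outside the gain node's clade:",
                  outside_present[1]))
    }
    tree <- ape::extract.clade(tree, node)
    states <- states[tree$tip.label]
  }
  cost <- matrix(c(0, 1, Inf, 0), 2, 2,
                 dimnames = list(c("absent", "present"),
                                 c("absent", "present")))
  ## cost[from, to]: present->absent = 1 (loss), absent->present = Inf
  rc <- sankoff_root_costs(tree, states, cost)
  as.integer(rc[["present"]])
}

normalize_states <- function(tree, tip_states) {
  if (is.logical(tip_states)) {
    tip_states <- ifelse(tip_states, "present", "absent")
  }
  if (is.data.frame(tip_states)) {
    tip_states <- setNames(tip_states[[2]], tip_states[[1]])
  }
  missing <- setdiff(tree$tip.label, names(tip_states))
  if (length(missing)) {
    abort(paste("missing tip state for:", paste(missing, collapse = ", ")))
  }
  st <- tip_states[tree$tip.label]
  if (!all(st %in% c("present", "absent"))) {
    abort("tip states must be 'present' or 'absent'")
  }
  st
}

## Sankoff dynamic program on a rooted (possibly multifurcating) tree.
## Returns the root's cost vector c(absent=, present=).
sankoff_root_costs <- function(tree, tip_states, cost) {
  states <- normalize_states(tree, tip_states)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  costs <- matrix(Inf, ntip + nnode, 2)
  costs[cbind(seq_len(ntip),
              ifelse(states == "absent", 1L, 2L))] <- 0
  edge <- tree$edge
  ord <- postorder_nodes(tree)
  for (nd in ord) {
    kids <- edge[edge[, 1] == nd, 2]
    acc <- c(0, 0)
    for (k in kids) {
      acc <- acc + c(min(cost[1, 1] + costs[k, 1], cost[1, 2] + costs[k, 2]),
                     min(cost[2, 1] + costs[k, 1], cost[2, 2] + costs[k, 2]))
    }
    costs[nd, ] <- acc
  }
  setNames(costs[ntip + 1L, ], c("absent", "present"))
}

## internal nodes in postorder (children before parents)
postorder_nodes <- function(tree) {
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  unique(edge[, 1])
}

clade_tip_indices <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  out <- integer()
  for (k in kids) {
    if (k <= ntip) out <- c(out, k)
    else out <- c(out, unlist(clade_tip_indices(tree, k)))
  }
  list(out)
}

## cost[state_parent, state_child]: careful — the matrices above are written
## with dimnames (from, to) and indexed as cost[parent_state, child_state].

#' Parsimony scenario comparison for a binary character
#'
#' Runs the three counts used to compare evolutionary scenarios for an
#' exon-skipping character: the unconstrained minimum number of changes, the
#' number of gains if the trait was never lost, and the number of losses if
#' the trait arose once at the root. For the shipped amniote/amphibian
#' fixture ([d2s_presence_fixture()]) these are 4, 4 and 6: four
#' independent gains beat one ancestral gain followed by six losses.
#'
#' @inheritParams min_changes
#' @return Object of class `parsimony_scenarios`; `glance()` gives a one-row
#'   tibble with the three counts.
#' @export
skipping_parsimony <- function(tree, tip_states) {
  states <- normalize_states(tree, tip_states)
  structure(list(tree = tree, tip_states = states,
                 min_changes = min_changes(tree, states),
                 gains_only = scenario_gains_no_losses(tree, states),
                 losses_given_root_gain =
                   scenario_losses_given_root_gain(tree, states)),
            class = "parsimony_scenarios")
}

#' @export
print.parsimony_scenarios <- function(x, ...) {
  cat("<parsimony_scenarios>\n")
  cat(sprintf("  tips: %d (%d present)\n", length(x$tip_states),
              sum(x$tip_states == "present")))
  cat(sprintf("  unconstrained minimum changes: %d\n", x$min_changes))
  cat(sprintf("  gains if never lost:           %d\n", x$gains_only))
  cat(sprintf("  losses if gained once at root: %d (total events %d)\n",
              x$losses_given_root_gain, 1L + x$losses_given_root_gain))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.parsimony_scenarios <- function(x, ...) {
  tibble(n_tips = length(x$tip_states),
         n_present = sum(x$tip_states == "present"),
         min_changes = x$min_changes,
         gains_only = x$gains_only,
         losses_given_root_gain = x$losses_given_root_gain)
}

#' @exportS3Method generics::tidy
tidy.parsimony_scenarios <- function(x, ...) {
  tibble(scenario = c("unconstrained", "gains_no_losses", "root_gain_losses"),
         events = c(x$min_changes, x$gains_only,
                    1L + x$losses_given_root_gain))
}

#' Read tip states from a two-column TSV
#'
#' @param path TSV with columns tip label and state (`present`/`absent`); a
#'   header line is detected and skipped.
#' @return Named character vector.
#' @export
read_tip_states <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (!df[1, 2] %in% c("present", "absent")) df <- df[-1, ]
  setNames(df[[2]], df[[1]])
}

#' Write a parsimony scenario report as JSON
#' @param x A `parsimony_scenarios` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parsimony_json <- function(x, path) {
  jsonlite::write_json(list(min_changes = x$min_changes,
                            gains_only = x$gains_only,
                            losses_given_root_gain = x$losses_given_root_gain),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
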