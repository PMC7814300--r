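## Counting and classifying state-change events along the tree, from ML
## posteriors (>= 0.90 evidence rule) or MP state sets (single-state rule).

#' Classify a state change
#'
#' Gap-to-nucleotide changes are gains of the insertion, nucleotide-to-gap
#' changes are losses; among nucleotides, purine-purine or
#' pyrimidine-pyrimidine changes are transitions and purine-pyrimidine
#' changes are transversions. In the 2-state encoding only gain and loss
#' can occur.
#'
#' @param from,to Unequal states from \{GAP, A, C, G, T\} (or
#'   \{absent, present\}).
#' @return One of `"gain"`, `"loss"`, `"transition"`, `"transversion"`.
#' @export
classify_event <- function(from, to) {
  if (identical(from, to)) stop("logic error: from and to states are equal")
  fa <- from %in% c("GAP", "absent")
  ta <- to %in% c("GAP", "absent")
  if (fa && !ta) return("gain")
  if (!fa && ta) return("loss")
  if (!(from %in% NUCLEOTIDES) || !(to %in% NUCLEOTIDES))
    stop("cannot classify change ", from, " -> ", to)
  if ((from %in% PURINES) == (to %in% PURINES)) "transition" else "transversion"
}

## internal: argmax-with-threshold state call from one posterior row
call_node_state <- function(p, threshold) {
  i <- which.max(p)
  if (p[i] >= threshold) names(p)[i] else NA_character_
}

empty_events <- function() {
  data.frame(parent = character(), child = character(),
             from = character(), to = character(),
             category = character(), framework = character(),
             stringsAsFactors = FALSE)
}

#' Count state transitions from ML marginal posteriors
#'
#' For every parent-child edge, each node is assigned its maximum-posterior
#' state provided that posterior is at least `threshold`, and is otherwise
#' ambiguous. An event is emitted iff neither node is ambiguous and the two
#' states differ; this conservative rule only reports transitions backed by
#' strong likelihood changes on both ends of the edge.
#'
#' @param tree Rooted `phylo`.
#' @param posteriors Node-posterior matrix from [marginal_posteriors()]
#'   (rows cover all tips and internal nodes).
#' @param threshold Minimal posterior for an unambiguous call; must lie in
#'   (0.5, 1] so the thresholded argmax is unique (default 0.90).
#' @return Data frame of events: `parent`, `child`, `from`, `to`,
#'   `category`, `framework`.
#' @export
count_transitions_ml <- function(tree, posteriors, threshold = 0.90) {
  if (!(threshold > 0.5 && threshold <= 1))
    stop("parameter error: threshold must lie in (0.5, 1]")
  nn <- node_names(tree)
  if (!all(nn %in% rownames(posteriors)))
    stop("posteriors do not cover all tree nodes")
  calls <- vapply(nn, function(v) call_node_state(posteriors[v, ], threshold),
                  character(1))
  edge <- tree$edge
  out <- empty_events()
  for (i in seq_len(nrow(edge))) {
    sp <- calls[[edge[i, 1L]]]
    sc <- calls[[edge[i, 2L]]]
    if (is.na(sp) || is.na(sc) || sp == sc) next
    out[nrow(out) + 1L, ] <- list(nn[edge[i, 1L]], nn[edge[i, 2L]], sp, sc,
                                  classify_event(sp, sc), "ML")
  }
  out
}

#' Count state transitions from MP state sets
#'
#' An event is emitted iff both the parental and the descendant node have a
#' single most-parsimonious state and the two states differ.
#'
#' @param tree Rooted binary `phylo` (the tree the MP run used; taken from
#'   `mp_sets` when omitted).
#' @param mp_sets An [mp_state_sets()] result.
#' @return Data frame of events as in [count_transitions_ml()].
#' @export
count_transitions_mp <- function(tree = NULL, mp_sets) {
  if (is.null(tree)) tree <- mp_sets$tree
  nn <- node_names(tree)
  if (!all(nn %in% names(mp_sets$sets)))
    stop("MP state sets do not cover all tree nodes")
  edge <- tree$edge
  out <- empty_events()
  for (i in seq_len(nrow(edge))) {
    setp <- mp_sets$sets[[nn[edge[i, 1L]]]]
    setc <- mp_sets$sets[[nn[edge[i, 2L]]]]
    if (length(setp) != 1L || length(setc) != 1L || setp == setc) next
    out[nrow(out) + 1L, ] <- list(nn[edge[i, 1L]], nn[edge[i, 2L]],
                                  setp, setc, classify_event(setp, setc), "MP")
  }
  out
}

#' Summarise an event list
#'
#' @param events Event data frame from a counting function.
#' @param clade_map Optional data frame `node`, `clade`; events are tallied
#'   by the clade of their child node.
#' @return List with `by_category` (named counts over gain / loss /
#'   transition / transversion, summing to `nrow(events)`), `by_pair`
#'   (from, to, count) and optionally `by_clade`.
#' @export
summarize_events <- function(events, clade_map = NULL) {
  cats <- c("gain", "loss", "transition", "transversion")
  by_category <- stats::setNames(
    vapply(cats, function(cc) sum(events$category == cc), integer(1)), cats)
  by_pair <- if (nrow(events)) {
    agg <- stats::aggregate(list(count = seq_len(nrow(events))),
                            by = list(from = events$from, to = events$to),
                            FUN = length)
    agg[order(agg$from, agg$to), , drop = FALSE]
  } else {
    data.frame(from = character(), to = character(), count = integer())
  }
  out <- list(by_category = by_category, by_pair = by_pair,
              n_events = nrow(events))
  if (!is.null(clade_map)) {
    cl <- clade_map$clade[match(events$child, clade_map$node)]
    out$by_clade <- table(clade = cl[!is.na(cl)],
                          category = events$category[!is.na(cl)])
  }
  out
}
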