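## Sankoff maximum parsimony with unit change cost, returning for every
## node the set of states attained in at least one reconstruction of
## minimal total cost (the MPR-style state sets), plus the minimal score.

#' Maximum-parsimony ancestral state sets (Sankoff)
#'
#' Polytomies are resolved to an arbitrary binary tree first (seeded random
#' resolution, as `multi2di` does), then Sankoff dynamic programming with
#' unit cost per state change runs an up-pass (minimal subtree costs) and a
#' down-pass (minimal cost of the rest of the tree), so that a state belongs
#' to a node's set iff some reconstruction of minimal total cost assigns it.
#' All tips must have observed states.
#'
#' @param tree Rooted `phylo`; polytomies allowed.
#' @param states State table covering every tip.
#' @param k Number of states (2 or 5); 5-state tables are collapsed when
#'   `k = 2`.
#' @param seed Seed for the arbitrary polytomy resolution (default 1;
#'   irrelevant on binary trees).
#' @return List of class `mp_state_sets` with `sets` (named list: node ->
#'   character vector of states), `score` (minimal number of changes) and
#'   `tree` (the binary tree actually used).
#' @export
mp_state_sets <- function(tree, states, k = 2L, seed = 1L) {
  k <- as.integer(k)
  lv <- state_levels(k)
  st <- stats::setNames(states$state, states$taxon)
  if (k == 2L && any(st %in% STATES5)) st <- collapse_states(st)
  miss <- setdiff(tree$tip.label, names(st))
  if (length(miss))
    stop("data error: missing tip state(s): ",
         paste(utils::head(miss, 5L), collapse = ", "))
  if (!ape::is.binary.phylo(tree)) {
    set.seed(seed)
    tree <- ape::multi2di(tree, random = TRUE)
  }
  so <- st[tree$tip.label]
  if (!all(so %in% lv))
    stop("tip state(s) outside the ", k, "-state alphabet: ",
         paste(unique(so[!(so %in% lv)]), collapse = ", "))
  n_tip <- ape::Ntip(tree)
  n_tot <- n_tip + tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge
  n_edge <- nrow(edge)
  ## D[v, s]: minimal changes within the subtree of v given state s at v
  D <- matrix(0, n_tot, k, dimnames = list(NULL, lv))
  D[seq_len(n_tip), ] <- Inf
  D[cbind(seq_len(n_tip), match(so, lv))] <- 0
  ## E[e, s]: min over child states of (cost + D_child), per edge, indexed
  ## by the state of the parent
  E <- matrix(NA_real_, n_edge, k)
  for (i in seq_len(n_edge)) {
    p <- edge[i, 1L]; ch <- edge[i, 2L]
    dmin <- min(D[ch, ])
    E[i, ] <- pmin(D[ch, ], dmin + 1)
    D[p, ] <- D[p, ] + E[i, ]
  }
  root <- edge[n_edge, 1L]
  score <- min(D[root, ])
  ## U[v, s]: minimal changes outside the subtree of v given state s at v
  U <- matrix(NA_real_, n_tot, k)
  U[root, ] <- 0
  by_parent <- split(seq_len(n_edge), edge[, 1L])
  for (i in rev(seq_len(n_edge))) {
    p <- edge[i, 1L]; ch <- edge[i, 2L]
    sibs <- by_parent[[as.character(p)]]
    rest <- U[p, ] + D[p, ] - E[i, ]    # cost above p + p's other subtrees
    ## min over parent state s_p of rest(s_p) + cost(s_p, s_child)
    rmin <- min(rest)
    U[ch, ] <- pmin(rest, rmin + 1)
  }
  total <- D + U
  sets <- lapply(seq_len(n_tot), function(v) lv[total[v, ] <= score + 1e-9])
  names(sets) <- node_names(tree)
  structure(list(sets = sets, score = as.integer(round(score)), tree = tree),
            class = "mp_state_sets")
}

#' @export
print.mp_state_sets <- function(x, ...) {
  cat("Sankoff MP reconstruction: score =", x$score, "changes;",
      length(x$sets), "node state sets\n")
  invisible(x)
}
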