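## Felsenstein pruning over a rooted, possibly polytomous phylogeny, the
## 1-D maximum-likelihood rate fit, and rerooting-method marginal ancestral
## posteriors computed by a single down-pass + up-pass (contractually
## identical to literally rerooting at every node, since the ER model is
## time-reversible with a uniform stationary distribution).

## internal: tip partial-likelihood matrix (n_tip x k). Observed tips are
## indicator rows; tips absent from the state table are all-ones
## ("fully ambiguous") when missing = "ambiguous", otherwise an error.
tip_partials <- function(tree, states, model, missing = c("ambiguous", "error")) {
  missing <- match.arg(missing)
  lv <- model$levels
  st <- stats::setNames(states$state, states$taxon)
  if (model$k == 2L && any(st %in% STATES5)) st <- collapse_states(st)
  n <- ape::Ntip(tree)
  L <- matrix(1, n, model$k, dimnames = list(tree$tip.label, lv))
  miss <- !(tree$tip.label %in% names(st))
  if (any(miss)) {
    if (missing == "error")
      stop("missing tip state(s): ",
           paste(utils::head(tree$tip.label[miss], 5L), collapse = ", "))
    warning(sum(miss), " tip(s) without a state treated as fully ambiguous")
  }
  obs <- tree$tip.label[!miss]
  so <- st[obs]
  if (!all(so %in% lv))
    stop("tip state(s) outside the ", model$k, "-state alphabet: ",
         paste(unique(so[!(so %in% lv)]), collapse = ", "))
  L[obs, ] <- 0
  L[cbind(obs, so)] <- 1
  L
}

## internal: full pruning pass. Returns per-node scaled conditional
## likelihoods (down-pass), log scaling factors, per-edge messages
## M_e(s_parent) = sum_s P(t_e)[s_parent, s] L_child(s), and the total
## log-likelihood at the root.
pruning_pass <- function(tree, states, model, missing = "ambiguous") {
  n_tip <- ape::Ntip(tree)
  n_tot <- n_tip + tree$Nnode
  k <- model$k
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge
  elen <- tr$edge.length
  if (is.null(elen)) elen <- rep(1, nrow(edge))
  L <- matrix(1, n_tot, k)
  L[seq_len(n_tip), ] <- tip_partials(tree, states, model, missing)
  logscale <- numeric(n_tot)
  Plist <- vector("list", nrow(edge))
  M <- matrix(NA_real_, nrow(edge), k)
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1L]; ch <- edge[i, 2L]
    P <- er_transition_matrix(model, elen[i])
    Plist[[i]] <- P
    m <- as.vector(P %*% L[ch, ])
    M[i, ] <- m
    L[p, ] <- L[p, ] * m
    logscale[p] <- logscale[p] + logscale[ch]
    mx <- max(L[p, ])
    if (mx <= 0 || !is.finite(mx))
      stop("numerical error: zero or non-finite partial likelihood at node ", p)
    L[p, ] <- L[p, ] / mx
    logscale[p] <- logscale[p] + log(mx)
  }
  root <- edge[nrow(edge), 1L]
  loglik <- log(sum(model$root_prior * L[root, ])) + logscale[root]
  list(L = L, logscale = logscale, M = M, Plist = Plist,
       edge = edge, root = root, loglik = loglik)
}

#' Pruning log-likelihood of tip states under an ER Mk model
#'
#' Felsenstein's pruning algorithm over the rooted (possibly polytomous)
#' tree, with per-node rescaling; the root conditional likelihoods are
#' combined with the model's root prior.
#'
#' @param tree A rooted `phylo` object with edge lengths.
#' @param states State table covering the tree tips (tips without a state
#'   are treated per `missing`).
#' @param model An [er_model()].
#' @param missing `"ambiguous"` (default; all-ones partial with a warning)
#'   or `"error"`.
#' @return The log-likelihood (finite scalar).
#' @export
prune_loglik <- function(tree, states, model, missing = "ambiguous") {
  ll <- pruning_pass(tree, states, model, missing)$loglik
  if (!is.finite(ll)) stop("numerical error: non-finite log-likelihood")
  ll
}

#' Maximum-likelihood fit of the ER substitution rate
#'
#' 1-D bounded maximisation of [prune_loglik] over
#' `q in [1e-8, q_max]` by [stats::optimize] (tolerance 1e-8). Monomorphic
#' tip data carry no change signal: the rate is pinned at the lower bound
#' with a warning.
#'
#' @param tree Rooted `phylo` with edge lengths.
#' @param states State table for the tips.
#' @param k Number of states (2 or 5).
#' @param q_max Upper bound for the rate; default `100 / mean root-to-tip
#'   path length`, an effectively saturated rate.
#' @param root_prior Optional root prior (default uniform).
#' @param tol Optimisation tolerance (default 1e-8).
#' @return An `er_model` with the fitted `q` and elements `loglik`, `q_max`.
#' @export
fit_rate <- function(tree, states, k, q_max = NULL, root_prior = NULL,
                     tol = 1e-8) {
  k <- as.integer(k)
  lv <- state_levels(k)
  st <- states$state
  if (k == 2L && any(st %in% STATES5)) st <- collapse_states(st)
  obs <- st[states$taxon %in% tree$tip.label]
  if (is.null(q_max)) {
    depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
    md <- mean(depths)
    if (!is.finite(md) || md <= 0) md <- 1
    q_max <- 100 / md
  }
  if (length(unique(obs)) < 2L) {
    warning("monomorphic tip states: rate pinned at the lower bound 1e-8")
    m <- er_model(k, 1e-8, root_prior)
    m$loglik <- prune_loglik(tree, states, m)
    m$q_max <- q_max
    return(m)
  }
  f <- function(q) prune_loglik(tree, states, er_model(k, q, root_prior))
  opt <- stats::optimize(f, interval = c(1e-8, q_max), maximum = TRUE,
                         tol = tol)
  if (!is.finite(opt$objective))
    stop("numerical error: rate optimisation failed (logL = ",
         opt$objective, " at q = ", opt$maximum, ")")
  m <- er_model(k, opt$maximum, root_prior)
  m$loglik <- opt$objective
  m$q_max <- q_max
  m
}

#' Marginal ancestral state posteriors (rerooting method)
#'
#' For every node, the marginal posterior probability of each state given
#' all tip data, equal to the root posterior of the tree rerooted at that
#' node. Computed without literal rerooting via one post-order pass
#' (conditional likelihoods below each node) and one pre-order pass
#' (likelihood of the rest of the tree), with per-node rescaling.
#'
#' @inheritParams prune_loglik
#' @return Matrix of `n_tip + n_node` rows (tips first, named by label;
#'   internal nodes named `N<index>`) by k state columns; rows sum to 1 and
#'   tip rows with observed states are indicator vectors.
#' @export
marginal_posteriors <- function(tree, states, model, missing = "ambiguous") {
  pp <- pruning_pass(tree, states, model, missing)
  k <- model$k
  edge <- pp$edge
  n_edge <- nrow(edge)
  n_tot <- ape::Ntip(tree) + tree$Nnode
  O <- matrix(NA_real_, n_tot, k)
  O[pp$root, ] <- model$root_prior
  ## pre-order: visit edges parent-before-child by reversing the postorder
  by_parent <- split(seq_len(n_edge), edge[, 1L])
  for (i in rev(seq_len(n_edge))) {
    p <- edge[i, 1L]
    ch <- edge[i, 2L]
    if (!is.na(O[ch, 1L])) next
    sibs <- by_parent[[as.character(p)]]
    ## product of sibling messages, excluding this child's own edge
    rows <- sibs[sibs != i]
    W <- O[p, ]
    for (r in rows) W <- W * pp$M[r, ]
    v <- as.vector(crossprod(pp$Plist[[i]], W))  # t(P) %*% W
    s <- sum(v)
    if (!is.finite(s) || s <= 0)
      stop("numerical error: degenerate outside likelihood at node ", ch)
    O[ch, ] <- v / s
  }
  post <- pp$L * O
  rs <- rowSums(post)
  if (any(!is.finite(rs)) || any(rs <= 0))
    stop("numerical error: NaN or zero posterior mass at some node")
  post <- post / rs
  dimnames(post) <- list(node_names(tree), model$levels)
  post
}
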