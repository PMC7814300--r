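## Independent brute-force oracles and small fixture builders used across
## the suite. These deliberately share no code with the package internals:
## likelihoods and parsimony scores are computed by full enumeration over
## ancestral state assignments, frequencies by per-column census loops.

## alignment matrix from named strings
aln_fix <- function(...) {
  x <- c(...)
  m <- do.call(rbind, strsplit(toupper(x), ""))
  rownames(m) <- names(x)
  m
}

rand_states <- function(tree, levels) {
  data.frame(taxon = tree$tip.label,
             state = sample(levels, ape::Ntip(tree), replace = TRUE),
             stringsAsFactors = FALSE)
}

## exhaustive joint likelihood: sum over every assignment of states to the
## internal nodes of prior(root) * prod over edges of P(parent -> child)
enum_likelihood <- function(tree, states, model) {
  lv <- model$levels
  k <- model$k
  n <- ape::Ntip(tree)
  tot <- n + tree$Nnode
  tipP <- matrix(0, n, k)
  rownames(tipP) <- tree$tip.label
  s <- stats::setNames(states$state, states$taxon)
  if (k == 2L && any(s %in% c("GAP", "A", "C", "G", "T")))
    s <- nd3shift::collapse_states(s)
  for (tx in tree$tip.label) tipP[tx, match(s[[tx]], lv)] <- 1
  elen <- tree$edge.length
  if (is.null(elen)) elen <- rep(1, nrow(tree$edge))
  Pe <- lapply(elen, function(t) er_transition_matrix(model, t))
  internals <- (n + 1L):tot
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internals))))
  total <- 0
  marg <- matrix(0, tot, k)
  for (g in seq_len(nrow(grid))) {
    asg <- integer(tot)
    asg[internals] <- grid[g, ]
    pr <- model$root_prior[asg[n + 1L]]   # ape root is node n+1
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
      pr <- pr * if (ch <= n) sum(Pe[[e]][asg[p], ] * tipP[ch, ]) else
        Pe[[e]][asg[p], asg[ch]]
    }
    total <- total + pr
    for (v in internals) marg[v, asg[v]] <- marg[v, asg[v]] + pr
  }
  list(loglik = log(total),
       marginals = marg[internals, , drop = FALSE] / total)
}

## exhaustive parsimony: minimal number of parent != child differences over
## all internal assignments, plus the per-node union of minimal assignments
enum_parsimony <- function(tree, states, levels) {
  n <- ape::Ntip(tree)
  tot <- n + tree$Nnode
  s <- stats::setNames(states$state, states$taxon)
  tip_idx <- match(s[tree$tip.label], levels)
  internals <- (n + 1L):tot
  grid <- as.matrix(expand.grid(rep(list(seq_along(levels)),
                                    length(internals))))
  costs <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    asg <- integer(tot)
    asg[seq_len(n)] <- tip_idx
    asg[internals] <- grid[g, ]
    costs[g] <- sum(asg[tree$edge[, 1L]] != asg[tree$edge[, 2L]])
  }
  best <- min(costs)
  sets <- vector("list", tot)
  for (v in internals) {
    col <- grid[costs == best, match(v, internals), drop = TRUE]
    sets[[v]] <- levels[sort(unique(col))]
  }
  for (v in seq_len(n)) sets[[v]] <- levels[tip_idx[v]]
  list(score = best, sets = sets)
}

## per-column nucleotide census, the slow way
census_frequencies <- function(aln, taxa = NULL) {
  if (!is.null(taxa)) aln <- aln[taxa, , drop = FALSE]
  nucs <- c("A", "C", "G", "T")
  out <- matrix(NA_real_, ncol(aln), 4, dimnames = list(NULL, nucs))
  cov <- integer(ncol(aln))
  for (j in seq_len(ncol(aln))) {
    cnt <- sapply(nucs, function(nt) sum(aln[, j] == nt))
    cov[j] <- sum(cnt)
    if (cov[j] > 0) out[j, ] <- cnt / cov[j]
  }
  list(freq = out, coverage = cov)
}
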