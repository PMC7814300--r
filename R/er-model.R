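## Equal-rates (ER) Mk model: k discrete states, one shared substitution
## rate q between every ordered state pair. Rate matrix Q has off-diagonal
## entries q and diagonal -(k-1)q, so exp(Qt) has the closed form used in
## er_transition_matrix().

#' Construct an equal-rates Mk model
#'
#' @param k Number of states (2 or 5).
#' @param q Per-pair substitution rate, >= 0.
#' @param root_prior Probability vector over the k states at the root;
#'   default uniform (the ER stationary distribution).
#' @return An object of class `er_model`.
#' @export
er_model <- function(k, q, root_prior = NULL) {
  k <- as.integer(k)
  lv <- state_levels(k)
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0)
    stop("q must be a single non-negative rate")
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  if (length(root_prior) != k || any(root_prior < 0))
    stop("root_prior must be a length-", k, " non-negative vector")
  if (abs(sum(root_prior) - 1) > 1e-12)
    stop("root_prior must sum to 1 (within 1e-12)")
  structure(list(k = k, q = q, root_prior = stats::setNames(root_prior, lv),
                 levels = lv),
            class = "er_model")
}

#' @export
print.er_model <- function(x, ...) {
  cat("Equal-rates Mk model: k =", x$k, ", q =", format(x$q), "\n")
  if (!is.null(x$loglik)) cat("log-likelihood:", format(x$loglik), "\n")
  invisible(x)
}

#' ER transition probability matrix
#'
#' Closed form for `exp(Qt)` under the equal-rates model:
#' `P_ii(t) = 1/k + (k-1)/k * exp(-kqt)`,
#' `P_ij(t) = 1/k - 1/k * exp(-kqt)` for `i != j`. Rows sum to 1; `t = 0`
#' gives the identity and `q*t -> Inf` gives the uniform stationary matrix.
#'
#' @param model An `er_model`.
#' @param t Branch length, >= 0.
#' @return k x k row-stochastic matrix with state dimnames.
#' @export
er_transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "er_model"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("domain error: branch length t must be a single value >= 0")
  k <- model$k
  e <- exp(-k * model$q * t)
  P <- matrix((1 - e) / k, k, k)
  diag(P) <- 1 / k + (k - 1) * e / k
  dimnames(P) <- list(model$levels, model$levels)
  P
}
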