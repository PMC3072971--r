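# Symmetric Mk model: pruning likelihood, rate fitting, marginal ASR.
#
# A character column is a named vector over the tree's tips with values in
# 0..(k-1), NA for missing ('?'). State 1 codes "present" for the binary
# spicule characters; the engine itself is generic in k.

#' Construct an Mk model
#'
#' The symmetric k-state continuous-time Markov model (Lewis's Mk with a
#' single rate): every ordered state pair flips at instantaneous rate `rate`
#' per unit branch length; the stationary and default root distribution is
#' uniform.
#'
#' @param k number of states (>= 2).
#' @param rate per-state-pair flip rate (events per unit branch length).
#' @param prior root state prior; defaults to uniform `1/k`.
#' @return an object of class `mk_model`.
#' @export
mk_model <- function(k = 2L, rate = 1, prior = rep(1 / k, k)) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (rate < 0) stop("rate must be >= 0")
  if (length(prior) != k || any(prior < 0) || abs(sum(prior) - 1) > 1e-8)
    stop("prior must be a length-k probability vector")
  structure(list(k = k, rate = rate, prior = prior / sum(prior)),
            class = "mk_model")
}

#' Mk transition probability matrix
#'
#' Closed form for the symmetric model: with flip rate `rate` between each
#' ordered state pair and branch length `t`,
#' `P[i,i] = 1/k + (k-1)/k * exp(-k*rate*t)` and
#' `P[i,j] = 1/k - 1/k * exp(-k*rate*t)` for `i != j`. Rows sum to 1; at
#' `t = 0` the matrix is the identity and as `t` grows all entries approach
#' the stationary value `1/k`.
#'
#' @param rate per-state-pair flip rate.
#' @param t branch length (>= 0), expected substitutions per site.
#' @param k number of states.
#' @return a `k x k` probability matrix.
#' @export
mk_transition_matrix <- function(rate, t, k = 2L) {
  if (t < 0) stop("branch length must be >= 0")
  if (rate < 0) stop("rate must be >= 0")
  e <- exp(-k * rate * t)
  off <- (1 - e) / k
  P <- matrix(off, k, k)
  diag(P) <- 1 / k + (k - 1) / k * e
  P
}

# Shared machinery: validate column against tree, tip partial matrix.
.tip_partials <- function(tree, column, k) {
  tips <- tree$tip.label
  missing_tips <- setdiff(tips, names(column))
  if (length(missing_tips))
    stop("no character state for tip(s): ",
         paste(missing_tips, collapse = ", "))
  st <- column[tips]
  bad <- st[!is.na(st) & (st < 0 | st >= k)]
  if (length(bad)) stop("states out of range 0..", k - 1L)
  part <- matrix(1, k, length(tips))
  obs <- which(!is.na(st))
  for (i in obs) {
    part[, i] <- 0
    part[st[i] + 1L, i] <- 1
  }
  part
}

# Felsenstein pruning pass. Returns postorder-reordered tree, per-node
# (rescaled) conditional likelihoods, accumulated log scalers, and the
# per-edge messages P(t_e) %*% partial(child) needed by the outside pass.
.mk_pruning <- function(tree, column, model) {
  k <- model$k
  ptree <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(ptree)
  ntot <- ntip + ptree$Nnode
  edge <- ptree$edge
  elen <- ptree$edge.length
  part <- matrix(1, k, ntot)
  part[, seq_len(ntip)] <- .tip_partials(ptree, column, k)
  logsc <- numeric(ntot)
  msg <- matrix(NA_real_, k, nrow(edge))
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1L]; ch <- edge[e, 2L]
    P <- mk_transition_matrix(model$rate, elen[e], k)
    msg[, e] <- P %*% part[, ch]
    part[, par] <- part[, par] * msg[, e]
    logsc[par] <- logsc[par] + logsc[ch]
    m <- max(part[, par])
    if (m > 0 && m < 1e-100) {
      part[, par] <- part[, par] / m
      logsc[par] <- logsc[par] + log(m)
    }
  }
  root <- edge[nrow(edge), 1L]
  lik <- sum(model$prior * part[, root])
  list(tree = ptree, part = part, logsc = logsc, msg = msg, root = root,
       loglik = if (lik > 0) log(lik) + logsc[root] else -Inf)
}

#' Log-likelihood of a character column under the Mk model
#'
#' Felsenstein's pruning algorithm on the fixed tree: tip conditional
#' likelihoods are state indicators (all-ones for missing data), internal
#' ones combine the children through the Mk transition matrices, and the
#' likelihood is the root prior dotted with the root conditionals. Partial
#' likelihoods are rescaled per node with accumulated log scalers, so trees
#' with hundreds of tips do not underflow.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param column named state vector over the tips (values `0..k-1` or `NA`).
#' @param model an [mk_model()].
#' @return the log-likelihood (may be `-Inf` for impossible data at rate 0).
#' @export
column_log_likelihood <- function(tree, column, model) {
  .mk_pruning(validate_phylo(tree), column, model)$loglik
}

#' Fit the Mk rate for one character by maximum likelihood
#'
#' One rate per character, maximised by bounded one-dimensional search on
#' `log(rate)` over `[log(1e-8), log(100)]` with convergence tolerance 1e-8.
#' A constant (or effectively constant) column has its likelihood maximised
#' at rate 0; such characters are returned at the lower bound with
#' `constant = TRUE`.
#'
#' @param tree a `phylo` object.
#' @param column named state vector over the tips.
#' @param k number of states.
#' @param lower,upper rate search bounds.
#' @return a list: `model` (the fitted [mk_model()]), `loglik`, `constant`.
#' @export
fit_rate <- function(tree, column, k = 2L, lower = 1e-8, upper = 100) {
  tree <- validate_phylo(tree)
  obs <- column[!is.na(column)]
  if (length(obs) < 2L) stop("need >= 2 non-missing tip states")
  if (length(unique(obs)) == 1L) {
    model <- mk_model(k, lower)
    return(list(model = model,
                loglik = column_log_likelihood(tree, column, model),
                constant = TRUE))
  }
  f <- function(lr)
    column_log_likelihood(tree, column, mk_model(k, exp(lr)))
  opt <- stats::optimize(f, interval = c(log(lower), log(upper)),
                         maximum = TRUE, tol = 1e-8)
  model <- mk_model(k, exp(opt$maximum))
  list(model = model, loglik = opt$objective, constant = FALSE)
}

#' Marginal ancestral-state reconstruction
#'
#' For every node `v` and state `s`, computes the marginal posterior
#' `P(v = s | data) = L(data, v = s) / L(data)` under the Mk model with the
#' given (typically fitted) rate, by combining the pruning (inside) pass with
#' an outside pass — equivalent to re-rooting the tree at every node, but in
#' two traversals. Tip rows are indicator vectors of the observed states
#' (uniform for missing data).
#'
#' @param tree a `phylo` object.
#' @param column named state vector over the tips.
#' @param model an [mk_model()]; see [fit_rate()].
#' @return an object of class `mk_asr`: list with `prob` (node x state
#'   posterior matrix, rows ordered by ape node id: tips `1..n` then
#'   internals), `tree` (the input tree), `model`, `loglik`.
#' @export
marginal_asr <- function(tree, column, model) {
  tree <- validate_phylo(tree)
  pr <- .mk_pruning(tree, column, model)
  ptree <- pr$tree
  k <- model$k
  ntip <- ape::Ntip(ptree)
  ntot <- ntip + ptree$Nnode
  edge <- ptree$edge
  elen <- ptree$edge.length
  # outside pass, preorder = reverse postorder edge order
  up <- matrix(NA_real_, k, ntot)
  up[, pr$root] <- model$prior
  children <- split(seq_len(nrow(edge)), edge[, 1L])
  for (e in rev(seq_len(nrow(edge)))) {
    par <- edge[e, 1L]; ch <- edge[e, 2L]
    sib_prod <- rep(1, k)
    for (e2 in children[[as.character(par)]])
      if (e2 != e) sib_prod <- sib_prod * pr$msg[, e2]
    P <- mk_transition_matrix(model$rate, elen[e], k)
    u <- crossprod(P, up[, par] * sib_prod)[, 1L]
    m <- max(u)
    up[, ch] <- if (m > 0) u / m else u
  }
  prob <- matrix(NA_real_, ntot, k)
  for (v in seq_len(ntot)) {
    w <- up[, v] * pr$part[, v]
    s <- sum(w)
    prob[v, ] <- if (s > 0) w / s else rep(1 / k, k)
  }
  # contract: tips are indicators of what was observed, uniform if missing
  st <- column[ptree$tip.label]
  for (i in seq_len(ntip)) {
    if (is.na(st[i])) prob[i, ] <- rep(1 / k, k)
    else { prob[i, ] <- 0; prob[i, st[i] + 1L] <- 1 }
  }
  colnames(prob) <- paste0("state", seq_len(k) - 1L)
  rownames(prob) <- c(ptree$tip.label, paste0("node", (ntip + 1L):ntot))
  structure(list(prob = prob, tree = tree, model = model,
                 loglik = pr$loglik, column = column),
            class = "mk_asr")
}

#' @export
print.mk_asr <- function(x, ...) {
  cat("Mk marginal ancestral-state reconstruction\n")
  cat("  states:", x$model$k, " rate:", signif(x$model$rate, 6),
      " logL:", signif(x$loglik, 8), "\n")
  cat("  nodes:", nrow(x$prob), "(", ape::Ntip(x$tree), "tips )\n")
  invisible(x)
}

#' Fit and reconstruct one character in one step
#'
#' Convenience wrapper: [fit_rate()] then [marginal_asr()] at the fitted
#' rate.
#'
#' @inheritParams fit_rate
#' @return an `mk_asr` object with an extra `constant` flag.
#' @export
reconstruct_character <- function(tree, column, k = 2L) {
  fit <- fit_rate(tree, column, k)
  rec <- marginal_asr(tree, column, fit$model)
  rec$constant <- fit$constant
  rec
}
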