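# Independent oracles used across the suite. These deliberately avoid the
# package's pruning/counting code paths: likelihoods by exhaustive
# enumeration over internal-node (and missing-tip) state assignments,
# event counts by brute-force edge scans over explicit call vectors.

# Exhaustive-enumeration likelihood of a character column; optionally with
# one node constrained to a state. O(k^(internal nodes)) — tiny trees only.
brute_force_likelihood <- function(tree, column, model, constrain = NULL) {
  k <- model$k
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  edge <- tree$edge
  elen <- tree$edge.length
  states <- column[tree$tip.label]
  miss <- which(is.na(states))
  igrid <- as.matrix(expand.grid(rep(list(0:(k - 1)), nint)))
  tgrid <- if (length(miss))
    as.matrix(expand.grid(rep(list(0:(k - 1)), length(miss))))
  else matrix(0L, 1, 0)
  Ps <- lapply(elen, function(t) mk_transition_matrix(model$rate, t, k))
  tot <- 0
  asn <- integer(ntip + nint)
  for (r in seq_len(nrow(igrid))) {
    asn[(ntip + 1):(ntip + nint)] <- igrid[r, ]
    if (!is.null(constrain) && asn[constrain[1]] != constrain[2]) next
    for (tr in seq_len(nrow(tgrid))) {
      st <- states
      if (length(miss)) st[miss] <- tgrid[tr, ]
      asn[1:ntip] <- st
      p <- model$prior[asn[ntip + 1] + 1]
      for (e in seq_len(nrow(edge)))
        p <- p * Ps[[e]][asn[edge[e, 1]] + 1, asn[edge[e, 2]] + 1]
      tot <- tot + p
    }
  }
  tot
}

# Marginal posterior at one node by constrained-likelihood ratios.
brute_force_marginal <- function(tree, column, model, node) {
  k <- model$k
  L <- brute_force_likelihood(tree, column, model)
  vapply(0:(k - 1), function(s)
    brute_force_likelihood(tree, column, model, constrain = c(node, s)) / L,
    numeric(1))
}

# Edge-scan event counter over explicit per-node (state, tier) vectors;
# independent of count_events' internals.
edge_scan_events <- function(tree, state, tier_ok, type = "loss") {
  from <- if (type == "loss") 1L else 0L
  hits <- 0L
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    if (tier_ok[p] && tier_ok[ch] && !is.na(state[p]) && !is.na(state[ch]) &&
        state[p] == from && state[ch] == (1L - from))
      hits <- hits + 1L
  }
  hits
}

# Build a node_calls data.frame directly from per-node states and tiers
# (bypasses call_states so count_events can be tested in isolation).
make_calls <- function(tree, state, tier) {
  n <- ape::Ntip(tree) + tree$Nnode
  out <- data.frame(node = seq_len(n), label = as.character(seq_len(n)),
                    state = as.integer(state),
                    tier = factor(tier, c("HIGH", "MODERATE", "AMBIGUOUS")),
                    p = NA_real_)
  attr(out, "k") <- 2L
  class(out) <- c("node_calls", "data.frame")
  out
}

# Random rooted binary tree with exponential branch lengths, seeded.
random_tree <- function(n, seed, mean_len = 0.2) {
  set.seed(seed)
  tree <- ape::rtree(n)
  tree$edge.length <- stats::rexp(length(tree$edge.length), 1 / mean_len)
  tree
}

# Random character column, optionally with missing entries.
random_column <- function(tree, k, seed, p_missing = 0) {
  set.seed(seed)
  st <- sample(0:(k - 1), ape::Ntip(tree), replace = TRUE)
  if (p_missing > 0)
    st[stats::runif(length(st)) < p_missing] <- NA
  stats::setNames(st, tree$tip.label)
}
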