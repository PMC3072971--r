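# Seeded generators for trees, characters, depth metadata and alignments
# with the statistical structure the analysis assumes. All generators are
# deterministic given (seed, config); randomness uses R's default
# Mersenne-Twister stream, restored on exit so callers' RNG state is
# untouched.

.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Simulate a birth-death tree with a fixed number of tips
#'
#' A birth-death tree conditioned on the number of extant tips (via
#' \pkg{ape}'s `rphylo`), hence ultrametric, with tips relabelled
#' `T0001, T0002, ...`. Optionally rescaled so the root-to-tip height equals
#' `height` — convenient when branch lengths should look like a molecular
#' tree in expected substitutions per site.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth,death speciation and extinction rates; `death < birth`.
#' @param seed integer seed (generator is deterministic given it).
#' @param height optional root-to-tip height to rescale to.
#' @return a `phylo` object.
#' @export
simulate_tree <- function(n_tips, birth = 1, death = 0, seed = NULL,
                          height = NULL) {
  if (n_tips < 2L) stop("n_tips must be >= 2")
  if (death >= birth) stop("death rate must be < birth rate")
  tree <- .with_seed(seed, ape::rphylo(n_tips, birth = birth, death = death))
  tree$tip.label <- sprintf("T%04d", seq_len(n_tips))
  if (!is.null(height)) {
    h <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length * (height / h)
  }
  tree
}

#' Simulate one Mk character on a tree
#'
#' Root state drawn from the uniform prior; states then evolve along each
#' edge through the Mk transition matrix ([mk_transition_matrix()]) — the
#' exact forward model the reconstruction machinery assumes.
#'
#' @param tree a `phylo` object.
#' @param k number of states.
#' @param rate per-state-pair flip rate.
#' @param seed integer seed.
#' @return a named state vector (values `0..k-1`) over the tips, with the
#'   full node-state vector in `attr(, "node_states")`.
#' @export
simulate_mk_character <- function(tree, k = 2L, rate, seed = NULL) {
  tree <- validate_phylo(tree)
  if (rate < 0) stop("rate must be >= 0")
  .with_seed(seed, {
    ntip <- ape::Ntip(tree)
    ptree <- ape::reorder.phylo(tree, "postorder")
    edge <- ptree$edge
    states <- integer(ntip + tree$Nnode)
    root <- edge[nrow(edge), 1L]
    states[root] <- sample.int(k, 1L) - 1L
    for (e in rev(seq_len(nrow(edge)))) {   # preorder: parents before kids
      P <- mk_transition_matrix(rate, ptree$edge.length[e], k)
      states[edge[e, 2L]] <-
        sample.int(k, 1L, prob = P[states[edge[e, 1L]] + 1L, ]) - 1L
    }
    out <- stats::setNames(states[seq_len(ntip)], ptree$tip.label)
    attr(out, "node_states") <- states
    out
  })
}

#' Plant irreversible losses in disjoint clades
#'
#' Builds a binary character that is present (state 1) everywhere except in
#' `n_losses` disjoint clades, each with at least `min_clade` (and at most
#' `max_clade`) tips, which are set to absent (state 0). The stem edges of
#' the chosen clades are the planted ground-truth loss events, against which
#' event counting can be scored.
#'
#' @param tree a `phylo` object.
#' @param n_losses number of planted losses (>= 0).
#' @param min_clade minimum tips per lost clade.
#' @param max_clade maximum tips per lost clade; default `n_tips/4` (losses
#'   stay rare relative to the background of presence).
#' @param seed integer seed.
#' @details The chosen clades are pairwise disjoint and the resulting
#'   column is required to be identifiable: its unique most-parsimonious
#'   reconstruction is the planted one (minimum change count equals
#'   `n_losses` and exactly one optimal labeling exists, checked by a
#'   Sankoff-style counting pass). This excludes, e.g., sister lost clades
#'   (their union is one clade, one event under any counting protocol) and
#'   configurations where one deeper loss plus a regain of an intervening
#'   present clade ties with the planted losses — ground truth that could
#'   not be recovered even in principle.
#' @return a list: `column` (named 0/1 vector over tips), `clade_nodes`,
#'   `stem_edges` (data.frame parent, child).
#' @export
simulate_loss_scenario <- function(tree, n_losses, min_clade = 2L,
                                   max_clade = NULL, seed = NULL) {
  tree <- validate_phylo(tree)
  ntip <- ape::Ntip(tree)
  if (is.null(max_clade)) max_clade <- max(min_clade, ntip %/% 4L)
  below <- .tips_below(tree)
  column <- stats::setNames(rep(1L, ntip), tree$tip.label)
  if (n_losses == 0L)
    return(list(column = column, clade_nodes = integer(0),
                stem_edges = data.frame(parent = integer(0),
                                        child = integer(0))))
  sizes <- lengths(below)
  cand <- setdiff(which(sizes >= min_clade & sizes <= max_clade &
                          seq_along(sizes) > ntip), ntip + 1L)
  identifiable <- function(set) {
    col <- column
    for (v in set) col[below[[v]]] <- 0L
    .fitch_unique(tree, col, expected_cost = length(set))
  }
  picked <- .with_seed(seed, {
    acc <- integer(0)
    for (v in sample(cand)) {
      if (length(acc) == n_losses) break
      disjoint <- !any(vapply(acc, function(a)
        length(intersect(below[[a]], below[[v]])) > 0L, logical(1)))
      if (disjoint && identifiable(c(acc, v))) acc <- c(acc, v)
    }
    acc
  })
  if (length(picked) < n_losses)
    stop("tree does not admit ", n_losses, " disjoint clades of ",
         min_clade, "-", max_clade, " tips")
  for (v in picked) column[below[[v]]] <- 0L
  edge <- tree$edge
  stems <- data.frame(parent = edge[match(picked, edge[, 2L]), 1L],
                      child = picked)
  list(column = column, clade_nodes = picked, stem_edges = stems)
}

#' Assign bathymetric habits to taxa
#'
#' Either i.i.d. draws from the given shallow/deep proportions (with an
#' optional probability of the `"both"` habit for species spanning the depth
#' threshold), or phylogenetically clustered habits obtained by evolving a
#' slow binary Mk flip character down the tree.
#'
#' @param tree a `phylo` object (taxa are its tips).
#' @param proportions length-2 probabilities for `shallow` and `deep`
#'   (normalised internally).
#' @param p_both probability a taxon is recorded from both zones (applied on
#'   top of the habit draw; i.i.d. mode only).
#' @param clustered evolve habit on the tree instead of i.i.d. draws.
#' @param flip_rate habit flip rate for clustered mode (0 = constant habit).
#' @param depth_threshold_m depth separating the zones, metres.
#' @param seed integer seed.
#' @return a data.frame `taxon`, `habit` with a `depth_threshold_m`
#'   attribute.
#' @export
assign_depth <- function(tree, proportions = c(shallow = 0.5, deep = 0.5),
                         p_both = 0, clustered = FALSE, flip_rate = 0.2,
                         depth_threshold_m = 100, seed = NULL) {
  stopifnot(length(proportions) == 2L, all(proportions >= 0),
            sum(proportions) > 0, p_both >= 0, p_both <= 1)
  pr <- proportions / sum(proportions)
  taxa <- tree$tip.label
  habit <- .with_seed(seed, {
    if (clustered) {
      root_habit <- sample(c("shallow", "deep"), 1L, prob = pr)
      other <- setdiff(c("shallow", "deep"), root_habit)
      sim <- simulate_mk_character(tree, k = 2L, rate = flip_rate)
      root_sim <- attr(sim, "node_states")[ape::Ntip(tree) + 1L]
      ifelse(sim[tree$tip.label] == root_sim, root_habit, other)
    } else {
      h <- sample(c("shallow", "deep"), length(taxa), replace = TRUE,
                  prob = pr)
      if (p_both > 0) {
        b <- stats::runif(length(taxa)) < p_both
        h[b] <- "both"
      }
      h
    }
  })
  out <- data.frame(taxon = taxa, habit = habit, stringsAsFactors = FALSE)
  attr(out, "depth_threshold_m") <- depth_threshold_m
  out
}

#' Simulate a nucleotide alignment under HKY with invariant sites and
#' discrete-gamma rates
#'
#' Sites evolve independently on the tree under an HKY substitution process
#' (transition/transversion ratio `kappa`, arbitrary base frequencies),
#' through \pkg{phangorn}'s sequence simulator. A proportion `prop_invariant`
#' of sites is held invariant (a single base drawn from the frequencies);
#' the remaining sites are spread over `n_categories` equal-probability
#' discrete-gamma rate categories (shape `gamma_shape`; `Inf` = no
#' heterogeneity), rescaled so the expected rate over all sites is 1 and
#' branch lengths keep their substitutions-per-site meaning.
#'
#' @param tree a `phylo` object.
#' @param length alignment width in sites.
#' @param kappa transition/transversion rate ratio.
#' @param base_freq length-4 frequencies (A, C, G, T).
#' @param prop_invariant proportion of invariant sites in `[0, 1]`.
#' @param gamma_shape discrete-gamma shape; `Inf` disables heterogeneity.
#' @param n_categories number of gamma categories.
#' @param seed integer seed.
#' @param name partition name.
#' @return an alignment matrix as from [read_alignment()].
#' @export
simulate_alignment <- function(tree, length, kappa = 2,
                               base_freq = rep(0.25, 4),
                               prop_invariant = 0, gamma_shape = Inf,
                               n_categories = 4L, seed = NULL,
                               name = "simulated") {
  tree <- validate_phylo(tree)
  if (length < 1L) stop("alignment length must be >= 1")
  if (any(base_freq < 0) || abs(sum(base_freq) - 1) > 1e-6)
    stop("base frequencies must be non-negative and sum to 1")
  if (prop_invariant < 0 || prop_invariant > 1)
    stop("prop_invariant must be in [0, 1]")
  .with_seed(seed, {
    n_inv <- stats::rbinom(1L, length, prop_invariant)
    n_var <- length - n_inv
    ntip <- ape::Ntip(tree)
    cols <- matrix(NA_character_, ntip, 0L,
                   dimnames = list(tree$tip.label, NULL))
    if (n_inv > 0L) {
      base <- sample(c("A", "C", "G", "T"), n_inv, replace = TRUE,
                     prob = base_freq)
      cols <- cbind(cols, matrix(base, ntip, n_inv, byrow = TRUE))
    }
    if (n_var > 0L) {
      rates <- if (is.finite(gamma_shape))
        phangorn::discrete.gamma(gamma_shape, n_categories) else 1
      rates <- rates / (1 - prop_invariant)   # overall mean rate 1
      cat_of <- sample(seq_along(rates), n_var, replace = TRUE)
      Q <- c(1, kappa, 1, 1, kappa, 1)        # AC AG AT CG CT GT
      for (c_i in seq_along(rates)) {
        nc <- sum(cat_of == c_i)
        if (nc == 0L) next
        sim <- phangorn::simSeq(tree, l = nc, Q = Q, bf = base_freq,
                                rate = rates[c_i])
        m <- toupper(as.character(sim))
        cols <- cbind(cols, m[tree$tip.label, , drop = FALSE])
      }
    }
    cols <- cols[, sample.int(ncol(cols)), drop = FALSE]  # interleave sites
    attr(cols, "partition") <- name
    cols
  })
}

#' Generate a desk-scale synthetic study bundle
#'
#' A seeded fixture shaped like the study's data: an ultrametric tree over
#' `n_tips` species, a binary spicule-character matrix mixing planted-loss
#' characters (known ground-truth loss edges) with free Mk characters, depth
#' habits at the given shallow/deep proportions, and two nucleotide
#' partitions (a COI-sized and a 28S-sized marker) evolved under HKY+I+G.
#' When `dir` is given, everything is written as plain text (newick, TSV,
#' FASTA) and read back by the package's own readers.
#'
#' @param seed integer seed driving every generator.
#' @param n_tips number of species.
#' @param n_characters number of binary characters; the first
#'   `n_planted` are planted-loss characters, the rest free Mk.
#' @param n_planted number of planted-loss characters.
#' @param mk_rate rate for the free Mk characters.
#' @param losses_per_character planted losses per planted character
#'   (recycled).
#' @param min_clade minimum tips per planted lost clade.
#' @param depth_proportions shallow/deep proportions.
#' @param p_both probability of the `"both"` habit.
#' @param tree_height root-to-tip height in substitutions per site.
#' @param seq_lengths widths of the two simulated partitions.
#' @param prop_invariant,gamma_shape rate-heterogeneity parameters shared by
#'   both partitions.
#' @param kappa transition/transversion ratio.
#' @param base_freq base frequencies (A, C, G, T).
#' @param dir optional output directory.
#' @return a list: `tree`, `characters` (matrix with `classes` attribute),
#'   `classes`, `depth`, `alignments` (list of 2), `planted` (per planted
#'   character: stem edges and clade nodes), `paths` (when written).
#' @export
make_fixture <- function(seed = 1L, n_tips = 89L, n_characters = 13L,
                         n_planted = 6L, mk_rate = 0.5,
                         losses_per_character = c(1L, 2L, 3L),
                         min_clade = 3L,
                         depth_proportions = c(shallow = 43, deep = 46),
                         p_both = 2 / 89, tree_height = 0.5,
                         seq_lengths = c(coi = 660L, rdna = 864L),
                         prop_invariant = 0.367474, gamma_shape = 0.557592,
                         kappa = 3,
                         base_freq = c(0.191611, 0.247736, 0.290797,
                                       0.269856),
                         dir = NULL) {
  stopifnot(n_planted <= n_characters)
  tree <- simulate_tree(n_tips, birth = 1, death = 0.5, seed = seed,
                        height = tree_height)
  mega <- c("triaene", "calthrop", "anatriaene", "desma", "oxea")
  micro <- c("euaster", "sterraster", "aspidaster", "amphiaster",
             "spiraster", "sanidaster", "microrhabd", "toxa")
  nm <- c(mega, micro)
  nm <- if (n_characters <= length(nm)) nm[seq_len(n_characters)]
        else c(nm, sprintf("char%02d", seq_len(n_characters - length(nm))))
  cls <- stats::setNames(ifelse(nm %in% mega, "megasclere", "microsclere"),
                         nm)
  nl <- rep_len(losses_per_character, n_planted)
  chars <- matrix(NA_integer_, n_tips, n_characters,
                  dimnames = list(tree$tip.label, nm))
  planted <- list()
  for (i in seq_len(n_characters)) {
    s <- seed + 1000L + i
    if (i <= n_planted) {
      sc <- simulate_loss_scenario(tree, n_losses = nl[i],
                                   min_clade = min_clade, seed = s)
      chars[, i] <- sc$column[tree$tip.label]
      planted[[nm[i]]] <- sc[c("stem_edges", "clade_nodes")]
    } else {
      chars[, i] <- simulate_mk_character(tree, k = 2L, rate = mk_rate,
                                          seed = s)[tree$tip.label]
    }
  }
  attr(chars, "classes") <- cls
  depth <- assign_depth(tree, proportions = depth_proportions,
                        p_both = p_both, seed = seed + 5000L)
  alignments <- list()
  for (j in seq_along(seq_lengths))
    alignments[[names(seq_lengths)[j]]] <-
      simulate_alignment(tree, length = seq_lengths[j], kappa = kappa,
                         base_freq = base_freq,
                         prop_invariant = prop_invariant,
                         gamma_shape = gamma_shape,
                         seed = seed + 6000L + j,
                         name = names(seq_lengths)[j])
  out <- list(tree = tree, characters = chars, classes = cls, depth = depth,
              alignments = alignments, planted = planted)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(tree = file.path(dir, "tree.nwk"),
                  characters = file.path(dir, "characters.tsv"),
                  depth = file.path(dir, "depth.tsv"),
                  planted = file.path(dir, "planted_events.tsv"))
    write_newick(tree, paths$tree)
    write_character_matrix(chars, paths$characters)
    utils::write.table(depth, paths$depth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    pl <- do.call(rbind, lapply(names(planted), function(n)
      cbind(character = n, planted[[n]]$stem_edges)))
    utils::write.table(pl, paths$planted, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    for (n in names(alignments)) {
      paths[[paste0("alignment_", n)]] <- file.path(dir,
                                                    paste0(n, ".fasta"))
      write_alignment(alignments[[n]], paths[[paste0("alignment_", n)]],
                      "fasta")
    }
    out$paths <- paths
  }
  out
}

# Unit-cost Sankoff pass over binary states: TRUE iff the minimum number of
# state changes equals expected_cost and exactly one optimal labeling of the
# internal nodes achieves it (the planted scenario is the unique MPR).
.fitch_unique <- function(tree, column, expected_cost) {
  ptree <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(ptree)
  ntot <- ntip + ptree$Nnode
  edge <- ptree$edge
  INF <- .Machine$integer.max %/% 4L
  cost <- matrix(0L, 2L, ntot)
  cnt <- matrix(1, 2L, ntot)
  st <- column[ptree$tip.label]
  for (i in seq_len(ntip)) if (!is.na(st[i])) cost[2L - st[i], i] <- INF
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1L]; ch <- edge[e, 2L]
    for (s in 1:2) {
      same <- cost[s, ch]; flip <- cost[3L - s, ch] + 1L
      best <- min(same, flip)
      nb <- (same == best) * cnt[s, ch] + (flip == best) * cnt[3L - s, ch]
      cost[s, par] <- cost[s, par] + best
      cnt[s, par] <- cnt[s, par] * nb
    }
  }
  root <- edge[nrow(edge), 1L]
  mc <- min(cost[, root])
  total <- sum(cnt[cost[, root] == mc, root])
  mc == expected_cost && total == 1
}
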