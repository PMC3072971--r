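# From per-node posteriors to confident calls, loss/gain events, and
# depth-stratified homoplasy summaries. State 1 = spicule present, 0 = absent.

TIER_LEVELS <- c("HIGH", "MODERATE", "AMBIGUOUS")

.tier_rank <- function(tier) match(tier, TIER_LEVELS)

# descendant tip labels below each node, as a list indexed by node id
.tips_below <- function(tree) {
  ntip <- ape::Ntip(tree)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(po)))
    below[[po[e, 1L]]] <- c(below[[po[e, 1L]]], below[[po[e, 2L]]])
  below
}

#' Two-tier confidence calls from a reconstruction
#'
#' Converts per-node posterior probabilities into tiered state calls: a node
#' is called at tier HIGH when its best state has posterior `> high`
#' (default 0.95), at tier MODERATE when the posterior lies in
#' `(moderate, high]` (default 0.65 < p <= 0.95), and is AMBIGUOUS
#' otherwise. Tips with observed states are HIGH by construction (posterior
#' 1); tips with missing data are AMBIGUOUS.
#'
#' @param recon an `mk_asr` object from [marginal_asr()].
#' @param moderate,high posterior thresholds, `0.5 < moderate < high <= 1`.
#' @return a data.frame of class `node_calls`: `node` (ape node id),
#'   `label`, `state` (best state, `NA` when ambiguous), `tier`, `p` (best
#'   posterior).
#' @export
call_states <- function(recon, moderate = 0.65, high = 0.95) {
  stopifnot(inherits(recon, "mk_asr"))
  if (!(moderate > 0.5 && high > moderate && high <= 1))
    stop("need 0.5 < moderate < high <= 1")
  prob <- recon$prob
  best <- max.col(prob, ties.method = "first")
  p <- prob[cbind(seq_len(nrow(prob)), best)]
  tier <- ifelse(p > high, "HIGH", ifelse(p > moderate, "MODERATE",
                                          "AMBIGUOUS"))
  state <- ifelse(tier == "AMBIGUOUS", NA_integer_, best - 1L)
  out <- data.frame(node = seq_len(nrow(prob)), label = rownames(prob),
                    state = state, tier = factor(tier, TIER_LEVELS), p = p)
  attr(out, "k") <- recon$model$k
  class(out) <- c("node_calls", "data.frame")
  out
}

# eligible state at the requested tier, NA when not called that confidently
.eligible_state <- function(calls, tier) {
  want <- .tier_rank(tier)
  ifelse(.tier_rank(as.character(calls$tier)) <= want, calls$state,
         NA_integer_)
}

#' Count independent loss and gain events on tree edges
#'
#' A loss at tier `tier` is an edge whose parent is called present (state 1)
#' and whose child is called absent (state 0), both at tier `tier` or
#' better; a gain is the reverse. Events are maximal by construction: edges
#' deeper inside an already-absent (or already-present) clade have a parent
#' in the new state and cannot qualify again, and ambiguous (or
#' insufficiently confident) nodes break event chains — no event is counted
#' through them. The root itself is never an event.
#'
#' @param calls a `node_calls` data.frame from [call_states()] (binary
#'   character).
#' @param tree the `phylo` object the calls were made on.
#' @param character character name recorded in the output.
#' @param tier minimum confidence tier, `"HIGH"` or `"MODERATE"`.
#' @return a data.frame (class `event_table`): `character`, `parent`,
#'   `child`, `type` (`"loss"`/`"gain"`), `tier` (the weaker of the two node
#'   tiers).
#' @export
count_events <- function(calls, tree, character = "character",
                         tier = c("HIGH", "MODERATE")) {
  tier <- match.arg(tier)
  if (!is.null(attr(calls, "k")) && attr(calls, "k") != 2L)
    stop("event counting is defined for binary characters (k = 2)")
  st <- .eligible_state(calls, tier)
  edge <- tree$edge
  ps <- st[edge[, 1L]]
  cs <- st[edge[, 2L]]
  is_loss <- !is.na(ps) & !is.na(cs) & ps == 1L & cs == 0L
  is_gain <- !is.na(ps) & !is.na(cs) & ps == 0L & cs == 1L
  hit <- which(is_loss | is_gain)
  tr <- .tier_rank(as.character(calls$tier))
  out <- data.frame(
    character = rep(character, length(hit)),
    parent = edge[hit, 1L], child = edge[hit, 2L],
    type = ifelse(is_loss[hit], "loss", "gain"),
    tier = TIER_LEVELS[pmax(tr[edge[hit, 1L]], tr[edge[hit, 2L]])],
    stringsAsFactors = FALSE)
  class(out) <- c("event_table", "data.frame")
  out
}

#' Count independent origins of a state
#'
#' The number of maximal edges on which `state` is gained at the requested
#' tier or better, plus one "root origin" when the root itself is called in
#' `state` that confidently (the state was then present ancestrally, which
#' counts as a single origin but never as an edge event).
#'
#' @inheritParams count_events
#' @param state the state whose origins are counted (default 1, presence).
#' @return a list: `count`, `root_origin` (logical), `events` (the gain
#'   edges as an `event_table`).
#' @export
independent_origins <- function(calls, tree, character = "character",
                                state = 1L, tier = c("HIGH", "MODERATE")) {
  tier <- match.arg(tier)
  st <- .eligible_state(calls, tier)
  edge <- tree$edge
  ps <- st[edge[, 1L]]; cs <- st[edge[, 2L]]
  hit <- which(!is.na(ps) & !is.na(cs) & ps != state & cs == state)
  tr <- .tier_rank(as.character(calls$tier))
  events <- data.frame(
    character = rep(character, length(hit)),
    parent = edge[hit, 1L], child = edge[hit, 2L],
    type = rep("gain", length(hit)),
    tier = TIER_LEVELS[pmax(tr[edge[hit, 1L]], tr[edge[hit, 2L]])],
    stringsAsFactors = FALSE)
  class(events) <- c("event_table", "data.frame")
  root <- ape::Ntip(tree) + 1L
  root_origin <- !is.na(st[root]) && st[root] == state
  list(count = nrow(events) + as.integer(root_origin),
       root_origin = root_origin, events = events)
}

#' Attribute events to bathymetric habitats
#'
#' Each event edge is attributed to the habit shared by all descendant tips
#' of the edge: `shallow` or `deep` when they agree, `mixed` when they
#' disagree, `unknown` when no informative tip remains. Species recorded
#' from both depth zones (`habit == "both"`) are excluded from the consensus
#' and from the strata; they are reported separately by
#' [homoplasy_report()].
#'
#' @param events an `event_table` from [count_events()].
#' @param meta depth metadata: data.frame with columns `taxon` and `habit`
#'   (`"shallow"`, `"deep"`, `"both"`), or a named habit vector.
#' @param tree the `phylo` object.
#' @return the `event_table` with a `habitat` column added.
#' @export
stratify_by_depth <- function(events, meta, tree) {
  habit <- .habit_vector(meta, tree)
  below <- .tips_below(tree)
  habitat <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    h <- habit[below[[events$child[i]]]]
    h <- unique(h[h != "both"])
    habitat[i] <- if (length(h) == 0L) "unknown"
                  else if (length(h) == 1L) h else "mixed"
  }
  events$habitat <- habitat
  events
}

.habit_vector <- function(meta, tree) {
  if (is.data.frame(meta)) {
    if (!all(c("taxon", "habit") %in% names(meta)))
      stop("metadata needs columns 'taxon' and 'habit'")
    habit <- stats::setNames(as.character(meta$habit),
                             as.character(meta$taxon))
  } else habit <- meta
  missing_tips <- setdiff(tree$tip.label, names(habit))
  if (length(missing_tips))
    stop("no depth metadata for tip(s): ",
         paste(missing_tips, collapse = ", "))
  bad <- setdiff(unique(habit), c("shallow", "deep", "both"))
  if (length(bad)) stop("unknown habit value(s): ", paste(bad, collapse = ", "))
  habit[tree$tip.label]
}

#' Per-character homoplasy report
#'
#' Reconstructs (or takes pre-computed reconstructions of) every character,
#' calls states at the two confidence tiers, counts loss and gain events,
#' and stratifies losses and gains by depth habit. Character classes
#' (megasclere/microsclere) are aggregated into class totals.
#'
#' @param recons a named list of `mk_asr` objects, one per character (e.g.
#'   from [reconstruct_character()]).
#' @param tree the `phylo` object used for the reconstructions.
#' @param meta optional depth metadata (see [stratify_by_depth()]); when
#'   `NULL` habitat columns are omitted.
#' @param classes optional named character class vector
#'   (`"megasclere"`/`"microsclere"`), names matching `names(recons)`.
#' @param moderate,high calling thresholds, see [call_states()].
#' @return an object of class `homoplasy_report`: list with `table` (one row
#'   per character: rate, logL, event counts per tier, depth strata at
#'   HIGH), `events` (all event edges with habitat), `class_totals`, and
#'   `both_habit_taxa`.
#' @export
homoplasy_report <- function(recons, tree, meta = NULL, classes = NULL,
                             moderate = 0.65, high = 0.95) {
  chars <- names(recons)
  if (is.null(chars)) chars <- paste0("char", seq_along(recons))
  if (is.null(classes))
    classes <- stats::setNames(rep("unknown", length(chars)), chars)
  all_events <- list()
  rows <- vector("list", length(chars))
  for (i in seq_along(chars)) {
    rec <- recons[[i]]
    calls <- call_states(rec, moderate = moderate, high = high)
    ev_h <- count_events(calls, tree, chars[i], tier = "HIGH")
    ev_m <- count_events(calls, tree, chars[i], tier = "MODERATE")
    if (!is.null(meta)) {
      ev_h <- stratify_by_depth(ev_h, meta, tree)
      ev_m <- stratify_by_depth(ev_m, meta, tree)
    }
    loss_h <- ev_h[ev_h$type == "loss", , drop = FALSE]
    row <- data.frame(
      character = chars[i], class = unname(classes[chars[i]]),
      rate = rec$model$rate, loglik = rec$loglik,
      losses_high = sum(ev_h$type == "loss"),
      gains_high = sum(ev_h$type == "gain"),
      losses_moderate = sum(ev_m$type == "loss"),
      gains_moderate = sum(ev_m$type == "gain"),
      stringsAsFactors = FALSE)
    if (!is.null(meta)) {
      row$losses_high_shallow <- sum(loss_h$habitat == "shallow")
      row$losses_high_deep <- sum(loss_h$habitat == "deep")
      row$losses_high_mixed <- sum(loss_h$habitat == "mixed")
    }
    rows[[i]] <- row
    all_events[[i]] <- ev_m   # MODERATE-or-better includes the HIGH events
  }
  table <- do.call(rbind, rows)
  events <- do.call(rbind, all_events)
  # flag losses that coincide with another character's gain on the same
  # edge ("semantic" replacement rather than outright loss); no conclusion
  # is drawn, the count is informational
  gain_edges <- split(events$child[events$type == "gain"],
                      events$character[events$type == "gain"])
  table$losses_with_coincident_gain <- vapply(table$character, function(ch) {
    mine <- events$child[events$character == ch & events$type == "loss"]
    others <- unlist(gain_edges[setdiff(names(gain_edges), ch)],
                     use.names = FALSE)
    sum(mine %in% others)
  }, integer(1))
  num <- vapply(table, is.numeric, logical(1))
  totals <- stats::aggregate(table[num & names(num) != "rate" &
                                     names(num) != "loglik"],
                             by = list(class = table$class), FUN = sum)
  both <- character(0)
  if (!is.null(meta)) {
    habit <- .habit_vector(meta, tree)
    both <- names(habit)[habit == "both"]
  }
  structure(list(table = table, events = events, class_totals = totals,
                 both_habit_taxa = both,
                 thresholds = c(moderate = moderate, high = high)),
            class = "homoplasy_report")
}

#' @export
print.homoplasy_report <- function(x, ...) {
  cat("Homoplasy report:", nrow(x$table), "characters, thresholds",
      paste(x$thresholds, collapse = "/"), "\n")
  print(x$table, row.names = FALSE)
  if (length(x$both_habit_taxa))
    cat("Taxa recorded from both depth zones (excluded from strata):",
        paste(x$both_habit_taxa, collapse = ", "), "\n")
  invisible(x)
}

#' Write a homoplasy report to TSV files
#'
#' Writes the per-character table, the event-edge table (with the tip set
#' below each event edge), and the class totals.
#'
#' @param x a `homoplasy_report`.
#' @param dir output directory (created if needed).
#' @param tree the `phylo` object, used to list the tips below event edges.
#' @return the directory, invisibly.
#' @export
write_homoplasy_report <- function(x, dir, tree) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(x$table, file.path(dir, "homoplasy_by_character.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ev <- x$events
  if (nrow(ev)) {
    below <- .tips_below(tree)
    ev$tips_below <- vapply(ev$child,
                            function(v) paste(below[[v]], collapse = ","),
                            character(1))
  }
  utils::write.table(ev, file.path(dir, "event_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(x$class_totals, file.path(dir, "class_totals.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Planted-loss recovery experiment
#'
#' End-to-end scoring of the event-counting machinery: on each replicate a
#' birth-death tree is simulated, `n_losses` disjoint identifiable losses
#' are planted ([simulate_loss_scenario()]), the character is reconstructed
#' under the Mk model, states are called at the default thresholds, and the
#' HIGH-tier loss count is compared with the planted number. Planted losses
#' emulate rare irreversible transitions (nominal rate `recon_rate` per unit
#' tree height, far below 1/height), and by default the reconstruction uses
#' that generating rarity scale; with `fit = TRUE` the rate is instead
#' fitted per character ([fit_rate()]), which concentrates stem-node
#' posteriors near the calling threshold and lowers recovery — both numbers
#' are honest summaries, of different questions.
#'
#' @param n_reps number of replicates.
#' @param n_tips tips per simulated tree.
#' @param n_losses planted losses per replicate.
#' @param min_clade minimum tips per lost clade.
#' @param recon_rate reconstruction rate per unit tree height (trees are
#'   scaled to height 1).
#' @param fit fit the rate per character instead of using `recon_rate`.
#' @param seed base seed; replicate seeds are derived from it.
#' @return a list: `recovery` (fraction of replicates whose HIGH-tier loss
#'   count equals `n_losses`), `counts` (per-replicate counts).
#' @export
planted_loss_experiment <- function(n_reps = 200L, n_tips = 64L,
                                    n_losses = 3L, min_clade = 3L,
                                    recon_rate = 0.001, fit = FALSE,
                                    seed = 1L) {
  counts <- integer(n_reps)
  for (i in seq_len(n_reps)) {
    tree <- simulate_tree(n_tips, seed = seed + 2L * i, height = 1)
    sc <- simulate_loss_scenario(tree, n_losses = n_losses,
                                 min_clade = min_clade,
                                 seed = seed + 2L * i + 1L)
    rec <- if (fit) reconstruct_character(tree, sc$column)
           else marginal_asr(tree, sc$column, mk_model(2L, recon_rate))
    ev <- count_events(call_states(rec), tree, tier = "HIGH")
    counts[i] <- sum(ev$type == "loss")
  }
  list(recovery = mean(counts == n_losses), counts = counts)
}
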