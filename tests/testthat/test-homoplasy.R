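test_that("state calling applies the two posterior tiers", {
  tr <- read_newick(text = "((A:0.2,B:0.2):0.2,C:0.4);")
  rec <- marginal_asr(tr, c(A = 0L, B = 0L, C = 1L), mk_model(2, 0.5))
  # craft posteriors to hit each tier exactly
  rec$prob[4, ] <- c(0.97, 0.03)
  rec$prob[5, ] <- c(0.70, 0.30)
  calls <- call_states(rec)
  expect_equal(calls$state[4], 0L)
  expect_equal(as.character(calls$tier[4]), "HIGH")
  expect_equal(calls$state[5], 0L)
  expect_equal(as.character(calls$tier[5]), "MODERATE")
  rec$prob[5, ] <- c(0.60, 0.40)
  calls <- call_states(rec)
  expect_true(is.na(calls$state[5]))
  expect_equal(as.character(calls$tier[5]), "AMBIGUOUS")
  # observed tips are HIGH; thresholds validated
  expect_equal(as.character(calls$tier[1:3]), rep("HIGH", 3))
  expect_error(call_states(rec, moderate = 0.95, high = 0.65), "moderate")
})

test_that("event counting finds maximal confident transitions", {
  # 6-tip caterpillar; lose one 3-tip clade (nodes chosen by hand)
  tr <- read_newick(
    text = "(((A:1,B:1):1,C:1):1,((D:1,E:1):1,F:1):1);")
  ntip <- 6L
  # node ids: tips 1..6 (A..F), root 7, then 8=(ABC), 9=(AB), 10=(DEF), 11=(DE)
  state <- c(0L, 0L, 0L, 1L, 1L, 1L, 1L, 0L, 0L, 1L, 1L)
  tier <- rep("HIGH", 11)
  calls <- make_calls(tr, state, tier)
  ev <- count_events(calls, tr, tier = "HIGH")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "loss")
  expect_equal(ev$parent, 7L)   # stem edge root -> (ABC)
  expect_equal(ev$child, 8L)
  expect_equal(nrow(ev), edge_scan_events(tr, state, rep(TRUE, 11), "loss"))

  # all-present character: no events
  expect_equal(nrow(count_events(make_calls(tr, rep(1L, 11),
                                            rep("HIGH", 11)), tr)), 0L)

  # two disjoint absent clades -> two independent losses
  st2 <- c(0L, 0L, 0L, 0L, 0L, 1L, 1L, 0L, 0L, 1L, 0L)
  ev2 <- count_events(make_calls(tr, st2, tier), tr, tier = "HIGH")
  expect_equal(sum(ev2$type == "loss"), 2L)
  expect_equal(sum(ev2$type == "loss"),
               edge_scan_events(tr, st2, rep(TRUE, 11), "loss"))

  # ambiguous node breaks the chain: no event through it
  tier3 <- tier; tier3[8] <- "AMBIGUOUS"
  st3 <- state; st3[8] <- NA
  expect_equal(nrow(count_events(make_calls(tr, st3, tier3), tr,
                                 tier = "HIGH")), 0L)

  # a MODERATE endpoint is invisible at HIGH tier but counted at MODERATE
  tier4 <- tier; tier4[8] <- "MODERATE"
  ev_h <- count_events(make_calls(tr, state, tier4), tr, tier = "HIGH")
  ev_m <- count_events(make_calls(tr, state, tier4), tr, tier = "MODERATE")
  expect_equal(nrow(ev_h), 0L)
  expect_equal(nrow(ev_m), 1L)
})

test_that("event properties: duality, maximality, tier monotonicity", {
  for (i in 1:10) {
    tr <- simulate_tree(24, seed = 900 + i, height = 1)
    col <- simulate_mk_character(tr, 2, rate = 0.6, seed = 950 + i)
    rec <- reconstruct_character(tr, col)
    calls <- call_states(rec)
    for (tier in c("HIGH", "MODERATE")) {
      ev <- count_events(calls, tr, tier = tier)
      # duality: losses of presence are gains of absence
      flipped <- calls
      flipped$state <- 1L - flipped$state
      evf <- count_events(flipped, tr, tier = tier)
      expect_equal(sum(ev$type == "loss"), sum(evf$type == "gain"))
      expect_equal(sum(ev$type == "gain"), sum(evf$type == "loss"))
      # independent oracle: brute-force edge scan
      st <- ifelse(unclass(calls$tier) <= match(tier, levels(calls$tier)),
                   calls$state, NA)
      ok <- !is.na(st)
      expect_equal(sum(ev$type == "loss"),
                   edge_scan_events(tr, st, ok, "loss"))
      expect_equal(sum(ev$type == "gain"),
                   edge_scan_events(tr, st, ok, "gain"))
    }
    # monotonicity: HIGH-tier count <= MODERATE-or-better count
    expect_lte(nrow(count_events(calls, tr, tier = "HIGH")),
               nrow(count_events(calls, tr, tier = "MODERATE")))
  }
  # maximality on planted scenarios: counted loss edges are never nested
  for (i in 1:5) {
    tr <- simulate_tree(40, seed = 970 + i, height = 1)
    sc <- simulate_loss_scenario(tr, 3, min_clade = 3, seed = 980 + i)
    rec <- marginal_asr(tr, sc$column, mk_model(2, 0.001))
    ev <- count_events(call_states(rec), tr, tier = "HIGH")
    losses <- ev[ev$type == "loss", ]
    if (nrow(losses) >= 2) {
      below <- spiculevol:::.tips_below(tr)
      for (a in seq_len(nrow(losses) - 1))
        for (b in (a + 1):nrow(losses))
          expect_length(intersect(below[[losses$child[a]]],
                                  below[[losses$child[b]]]), 0)
    }
  }
})

test_that("independent origins count gain edges plus a root origin", {
  tr <- read_newick(
    text = "(((A:1,B:1):1,C:1):1,((D:1,E:1):1,F:1):1);")
  tier <- rep("HIGH", 11)
  # fixed present from the root: one origin, at the root
  orig <- independent_origins(make_calls(tr, rep(1L, 11), tier), tr)
  expect_equal(orig$count, 1L)
  expect_true(orig$root_origin)
  expect_equal(nrow(orig$events), 0L)

  # two disjoint gained clades, root absent
  st <- c(1L, 1L, 1L, 0L, 0L, 1L, 0L, 1L, 1L, 0L, 0L)
  orig2 <- independent_origins(make_calls(tr, st, tier), tr)
  expect_equal(orig2$count, 2L)
  expect_false(orig2$root_origin)

  # duality with count_events: origins of absence = losses of presence
  st3 <- c(0L, 0L, 0L, 1L, 1L, 1L, 1L, 0L, 0L, 1L, 1L)
  calls3 <- make_calls(tr, st3, tier)
  expect_equal(independent_origins(calls3, tr, state = 0L)$count,
               sum(count_events(calls3, tr)$type == "loss"))
})

test_that("depth stratification attributes events by descendant consensus", {
  tr <- read_newick(
    text = "(((A:1,B:1):1,C:1):1,((D:1,E:1):1,F:1):1);")
  tier <- rep("HIGH", 11)
  state <- c(0L, 0L, 0L, 1L, 1L, 1L, 1L, 0L, 0L, 1L, 1L)  # ABC lost
  ev <- count_events(make_calls(tr, state, tier), tr, tier = "HIGH")

  deep_meta <- data.frame(taxon = LETTERS[1:6],
                          habit = c("deep", "deep", "deep", "shallow",
                                    "shallow", "shallow"))
  expect_equal(stratify_by_depth(ev, deep_meta, tr)$habitat, "deep")

  mixed_meta <- deep_meta
  mixed_meta$habit[3] <- "shallow"
  expect_equal(stratify_by_depth(ev, mixed_meta, tr)$habitat, "mixed")

  # 'both' species are excluded from the consensus
  both_meta <- deep_meta
  both_meta$habit[3] <- "both"
  expect_equal(stratify_by_depth(ev, both_meta, tr)$habitat, "deep")

  expect_error(stratify_by_depth(ev, deep_meta[-2, ], tr), "B")
})

test_that("planted habitat-homogeneous losses stratify to planted counts", {
  tr <- simulate_tree(80, seed = 321, height = 1)
  sc <- simulate_loss_scenario(tr, 7, min_clade = 3, max_clade = 8,
                               seed = 322)
  below <- spiculevol:::.tips_below(tr)
  # habitats homogeneous within planted clades: 5 shallow, 2 deep
  habit <- stats::setNames(rep("shallow", 80), tr$tip.label)
  lost_tips <- lapply(sc$clade_nodes, function(v) below[[v]])
  for (j in 1:7)
    habit[lost_tips[[j]]] <- if (j <= 5) "shallow" else "deep"
  rec <- marginal_asr(tr, sc$column, mk_model(2, 0.001))
  ev <- count_events(call_states(rec), tr, tier = "HIGH")
  ev <- stratify_by_depth(ev, habit, tr)
  losses <- ev[ev$type == "loss", ]
  expect_equal(sum(losses$habitat == "shallow"), 5L)
  expect_equal(sum(losses$habitat == "deep"), 2L)
})

test_that("homoplasy report aggregates per character and per class", {
  tr <- simulate_tree(30, seed = 41, height = 1)
  # all-constant matrix: zero events everywhere
  const <- matrix(1L, 30, 3, dimnames = list(tr$tip.label,
                                             c("c1", "c2", "c3")))
  recs <- lapply(1:3, function(i)
    reconstruct_character(tr, stats::setNames(const[, i], rownames(const))))
  names(recs) <- colnames(const)
  rep0 <- homoplasy_report(recs, tr)
  expect_true(all(rep0$table[, c("losses_high", "gains_high",
                                 "losses_moderate", "gains_moderate")] == 0))

  # one planted loss per character: each row reports exactly one HIGH loss
  cols <- lapply(1:3, function(i)
    simulate_loss_scenario(tr, 1, min_clade = 3, seed = 50 + i)$column)
  recs <- lapply(cols, function(cl) marginal_asr(tr, cl, mk_model(2, 0.001)))
  names(recs) <- c("c1", "c2", "c3")
  meta <- assign_depth(tr, seed = 60)
  rep1 <- homoplasy_report(recs, tr, meta = meta,
                           classes = c(c1 = "megasclere", c2 = "megasclere",
                                       c3 = "microsclere"))
  expect_equal(rep1$table$losses_high, rep(1L, 3))
  # class totals equal the sum of per-character rows
  expect_equal(sum(rep1$class_totals$losses_high),
               sum(rep1$table$losses_high))
  mega <- rep1$class_totals[rep1$class_totals$class == "megasclere", ]
  expect_equal(mega$losses_high,
               sum(rep1$table$losses_high[rep1$table$class == "megasclere"]))
})
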