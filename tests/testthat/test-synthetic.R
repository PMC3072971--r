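test_that("tree simulation is seeded, ultrametric, and validated", {
  t1 <- simulate_tree(5, seed = 9)
  t2 <- simulate_tree(5, seed = 9)
  expect_equal(write_newick(t1), write_newick(t2))   # determinism
  expect_equal(ape::Ntip(t1), 5L)
  expect_match(t1$tip.label[1], "^T0001$")

  big <- simulate_tree(40, seed = 10, height = 1)
  depths <- ape::node.depth.edgelength(big)[1:40]
  expect_equal(depths, rep(1, 40), tolerance = 1e-9)   # ultrametric

  expect_error(simulate_tree(10, birth = 1, death = 1.2), "death")
  expect_error(simulate_tree(1), "n_tips")
})

test_that("Mk character simulation hits its limits and stationarity", {
  tr <- simulate_tree(12, seed = 21, height = 1)
  # rate 0: every tip inherits the root state
  c0 <- simulate_mk_character(tr, 2, rate = 0, seed = 22)
  expect_length(unique(c0), 1L)

  # large rate: tip states approach the uniform stationary distribution
  t5 <- simulate_tree(5, seed = 23, height = 1)
  reps <- vapply(1:2000, function(i)
    simulate_mk_character(t5, 2, rate = 50, seed = 10000 + i)[1],
    integer(1))
  p_hat <- mean(reps == 1)
  se <- sqrt(0.5 * 0.5 / 2000)
  expect_lt(abs(p_hat - 0.5), 3 * se)

  # determinism
  expect_equal(simulate_mk_character(tr, 2, 0.5, seed = 1),
               simulate_mk_character(tr, 2, 0.5, seed = 1))
})

test_that("loss scenarios plant disjoint identifiable clades", {
  tr <- simulate_tree(64, seed = 31, height = 1)
  sc0 <- simulate_loss_scenario(tr, 0, seed = 32)
  expect_true(all(sc0$column == 1L))

  sc <- simulate_loss_scenario(tr, 3, min_clade = 3, seed = 33)
  expect_equal(nrow(sc$stem_edges), 3L)
  below <- spiculevol:::.tips_below(tr)
  tipsets <- lapply(sc$clade_nodes, function(v) below[[v]])
  for (a in 1:2) for (b in (a + 1):3)
    expect_length(intersect(tipsets[[a]], tipsets[[b]]), 0L)
  expect_true(all(vapply(tipsets, length, 1L) >= 3))
  expect_equal(sum(sc$column == 0L), length(unlist(tipsets)))
  # stems are the edges subtending the planted clades
  expect_equal(sc$stem_edges$parent,
               tr$edge[match(sc$clade_nodes, tr$edge[, 2]), 1])

  # an impossible request errors
  small <- simulate_tree(6, seed = 34)
  expect_error(simulate_loss_scenario(small, 5, min_clade = 3, seed = 35),
               "does not admit")
})

test_that("depth assignment respects proportions and clustering", {
  tr <- simulate_tree(89, seed = 41, height = 1)
  all_sh <- assign_depth(tr, proportions = c(1, 0), seed = 42)
  expect_true(all(all_sh$habit == "shallow"))

  # i.i.d. draws at 43/89 vs 46/89: mean counts within 3 binomial SE
  n_sh <- vapply(1:200, function(i)
    sum(assign_depth(tr, proportions = c(43, 46), seed = 4000 + i)$habit ==
          "shallow"), integer(1))
  expect_lt(abs(mean(n_sh) - 43), 3 * sqrt(89 * (43 / 89) * (46 / 89) / 200))

  # clustered mode with zero flip rate: habit constant across the tree
  cl <- assign_depth(tr, clustered = TRUE, flip_rate = 0, seed = 43)
  expect_length(unique(cl$habit), 1L)

  expect_equal(attr(assign_depth(tr, seed = 1), "depth_threshold_m"), 100)
})

test_that("alignment simulation honors degenerate limits", {
  tr <- simulate_tree(6, seed = 51, height = 1)
  tr0 <- tr; tr0$edge.length[] <- 0
  a0 <- simulate_alignment(tr0, 50, seed = 52)
  expect_equal(as.integer(classify_sites(a0)$counts["constant"]), 50L)

  a_inv <- simulate_alignment(tr, 50, prop_invariant = 1, seed = 53)
  expect_equal(as.integer(classify_sites(a_inv)$counts["constant"]), 50L)

  expect_error(simulate_alignment(tr, 10, base_freq = c(1, 1, 0, 0)),
               "frequencies")
  expect_equal(simulate_alignment(tr, 30, seed = 5),
               simulate_alignment(tr, 30, seed = 5))
})

test_that("two-tip site patterns match analytic HKY probabilities", {
  skip_if_not_installed("Matrix")
  bf <- c(0.3, 0.2, 0.3, 0.2)
  kappa <- 3
  t_tot <- 0.4
  tr <- read_newick(text = "(A:0.2,B:0.2);")
  # analytic oracle: HKY rate matrix, normalised to mean rate 1, expm
  Q <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  ts_pair <- function(i, j) (i == "A" & j == "G") | (i == "G" & j == "A") |
    (i == "C" & j == "T") | (i == "T" & j == "C")
  for (i in 1:4) for (j in 1:4) if (i != j) {
    nm <- rownames(Q)
    Q[i, j] <- bf[j] * ifelse(ts_pair(nm[i], nm[j]), kappa, 1)
  }
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(-diag(Q) * bf)
  P <- as.matrix(Matrix::expm(Q * t_tot))
  joint <- diag(bf) %*% P          # P(x at A, y at B) on a 2-tip tree
  a <- simulate_alignment(tr, 4000, kappa = kappa, base_freq = bf,
                          seed = 61)
  emp <- table(factor(a["A", ], rownames(Q)), factor(a["B", ], rownames(Q)))
  emp <- emp / sum(emp)
  for (i in 1:4) for (j in 1:4) {
    p <- joint[i, j]
    se <- sqrt(p * (1 - p) / 4000)
    expect_lt(abs(emp[i, j] - p), max(3 * se, 1e-3))
  }
})

test_that("the fixture bundle has the study's shape and round-trips", {
  dir <- tempfile("fx")
  fx <- make_fixture(seed = 3, dir = dir)
  expect_equal(ape::Ntip(fx$tree), 89L)
  expect_equal(dim(fx$characters), c(89L, 13L))
  expect_setequal(unique(attr(fx$characters, "classes")),
                  c("megasclere", "microsclere"))
  expect_equal(vapply(fx$alignments, ncol, 1L), c(coi = 660L, rdna = 864L))

  # every artefact parses back through the package's own readers
  tr <- read_newick(fx$paths$tree)
  expect_equal(rf_distance(tr, fx$tree), 0L)
  cm <- read_character_matrix(fx$paths$characters)
  expect_equal(unname(cm), unname(fx$characters))
  expect_equal(attr(cm, "classes"), attr(fx$characters, "classes"))
  a <- read_alignment(fx$paths$alignment_coi, "fasta")
  expect_equal(a[rownames(fx$alignments$coi), ], fx$alignments$coi,
               ignore_attr = TRUE)
  meta <- utils::read.delim(fx$paths$depth)
  expect_setequal(meta$taxon, fx$tree$tip.label)

  # determinism of the whole bundle
  fx2 <- make_fixture(seed = 3)
  expect_equal(fx2$characters, fx$characters)
  expect_equal(write_newick(fx2$tree), write_newick(fx$tree))
})

test_that("simulation and rate fitting are jointly calibrated", {
  # pooled-MLE coverage: the 2-SE interval around the fitted log-rate
  # (curvature-based SE) covers the generating rate in 90-99% of replicates
  n_rep <- 100; n_chars <- 200; alpha0 <- 0.5
  tree <- simulate_tree(16, seed = 999, height = 1)
  cover <- 0L
  for (r in seq_len(n_rep)) {
    cols <- lapply(seq_len(n_chars), function(i)
      simulate_mk_character(tree, 2, alpha0, seed = 50000 + r * 1000 + i))
    f <- function(lr) sum(vapply(cols, function(cl)
      column_log_likelihood(tree, cl, mk_model(2, exp(lr))), numeric(1)))
    opt <- stats::optimize(f, c(log(1e-3), log(10)), maximum = TRUE,
                           tol = 1e-7)
    h <- 1e-3
    d2 <- (f(opt$maximum + h) - 2 * opt$objective + f(opt$maximum - h)) / h^2
    se_lr <- 1 / sqrt(-d2)
    cover <- cover + (abs(opt$maximum - log(alpha0)) <= 2 * se_lr)
  }
  expect_gte(cover / n_rep, 0.90)
  expect_lte(cover / n_rep, 0.99)
})
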