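test_that("similarity score is the max |dC| over parallel descendants", {
  tr <- two_node_tree(c(0.976, 0.024), c(0.976, 0.015))
  expect_equal(similarity_score(tr, 1, 1, 2), 0.009)
  tr2 <- two_node_tree(c(0.7, 0.3), c(0.7, 0.3))
  expect_equal(similarity_score(tr2, 1, 1, 2), 0)
  tr3 <- two_node_tree(c(1, 0), c(0, 1))
  expect_equal(similarity_score(tr3, 1, 1, 2), 1)
})

test_that("merge threshold is twice the random-walk SD of a proportion diff", {
  expect_equal(merge_threshold(100, 100), sqrt(0.02))
  expect_equal(merge_threshold(1, 1), sqrt(2))
  expect_lt(merge_threshold(1e8, 1e8), 2e-4)
  expect_warning(th <- merge_threshold(0, 10), "zero")
  expect_equal(th, Inf)
})

test_that("merging weights conditionals by haplotype counts", {
  tr <- two_node_tree(c(0.976, 0.024), c(0.976, 0.015), M1 = 100, M2 = 100)
  m <- merge_nodes(tr, 1, 1, 2)
  lev <- m$levels[[1]]
  expect_equal(nrow(lev), 1L)
  expect_equal(lev$M, 200)
  e <- m$edges[[2]]
  expect_equal(sort(e$C), sort(c(0.976, 0.0195)))
  # zero-weight node contributes nothing
  tr0 <- two_node_tree(c(0.9, 0.1), c(0.2, 0.8), M1 = 0, M2 = 50)
  m0 <- merge_nodes(tr0, 1, 1, 2)
  expect_equal(sort(m0$edges[[2]]$C), c(0.2, 0.8))
  # merging identical nodes doubles M, keeps probabilities
  tri <- two_node_tree(c(0.7, 0.3), c(0.7, 0.3), M1 = 60, M2 = 40)
  mi <- merge_nodes(tri, 1, 1, 2)
  expect_equal(mi$levels[[1]]$M, 100)
  expect_equal(sort(mi$edges[[2]]$C), c(0.3, 0.7))
})

test_that("level merging is greedy smallest-score-first with re-evaluation", {
  # three parallel A-nodes: the 0.001 pair merges first; after merging, the
  # merged node vs the third exceeds the tightened threshold, so it stays
  lev1 <- data.frame(id = 1:3, label = "A", M = c(1000, 1000, 1000))
  lev2 <- data.frame(id = 1:2, label = c("A", "B"), M = c(1200, 1800))
  e1 <- data.frame(from = 0L, to = 1:3, C = rep(1 / 3, 3), J = rep(1 / 3, 3))
  e2 <- data.frame(from = rep(1:3, each = 2), to = rep(1:2, 3),
                   C = c(0.4, 0.6, 0.401, 0.599, 0.45, 0.55),
                   J = rep(1 / 6, 6))
  tr <- make_tree(list(lev1, lev2), list(e1, e2), 3000)
  out <- merge_level(tr, 1)
  lev <- out$levels[[1]]
  expect_equal(nrow(lev), 2L)
  expect_setequal(lev$M, c(2000, 1000))
  merged_id <- lev$id[lev$M == 2000]
  ch <- out$edges[[2]]
  cm <- sort(ch$C[ch$from == merged_id])
  expect_equal(cm, c(0.4005, 0.5995))
  # with one node, nothing happens
  single <- make_tree(list(lev1[1, ], lev2),
                      list(e1[1, ], e2[e2$from == 1, ]), 1000)
  expect_equal(nrow(merge_level(single, 1)$levels[[1]]), 1L)
})

test_that("distance decay is exponential with the stated anchors", {
  expect_equal(decay(0, 1e8), 1)
  expect_equal(decay(1e5, 1e5), exp(-1))
  d <- seq(0, 5e5, length.out = 20)
  expect_true(all(diff(decay(d, 1e5)) < 0))
})

test_that("six-state expansion distributes each conditional total correctly", {
  params <- decay_params()
  # from a gain state with rho_var = 0.6 and C[A->A] = 1
  d <- -log(0.6) * params$D_var
  C1 <- matrix(c(1, 0, 0.3, 0.7), 2, 2, byrow = TRUE,
               dimnames = list(c("A", "B"), c("A", "B")))
  T6 <- expand_transitions(C1, d, params)
  expect_equal(T6["A+", "A+"], 0.6)
  expect_equal(T6["A+", "A"], 0.4)
  expect_equal(T6["A+", "A-"], 0)
  # zero-probability cells are exactly the 8 forbidden gain<->loss moves
  expect_equal(unname(T6 > 0)[, ], unname(allowed_transitions() & (C1[
    state_allele(allelic_states()), ][, state_allele(allelic_states())] > 0)))
  # d -> 0: aberrant mass from a normal state vanishes
  T0 <- expand_transitions(C1, 0, params)
  expect_equal(T0["A", "A+"], 0)
  expect_equal(T0["A", "A"], 1)
  # all rows stochastic for random tables and distances
  set.seed(1)
  for (k in 1:20) {
    p <- runif(2)
    Cr <- rbind(A = c(p[1], 1 - p[1]), B = c(p[2], 1 - p[2]))
    colnames(Cr) <- c("A", "B")
    Tr <- expand_transitions(Cr, runif(1, 0, 1e6), params)
    expect_equal(unname(rowSums(Tr)), rep(1, 6), tolerance = 1e-12)
  }
})

test_that("exactly 28 ordered transitions are allowed after branching", {
  C <- matrix(0.5, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  T6 <- expand_transitions(C, 5e4, decay_params())
  expect_equal(sum(T6 > 0), 28L)
  expect_true(all((T6 > 0) == allowed_transitions()))
})

test_that("the built tree reproduces the pairwise Markov chain", {
  set.seed(3)
  L <- 6L; n <- 40L
  genos <- matrix(sample(1:3, L * n, replace = TRUE, prob = c(.3, .4, .3)),
                  L, n)
  tables <- lapply(seq_len(L - 1), function(j) {
    conditional_probabilities(
      em_haplotype_proportions(count_genotype_pairs(genos, j)))
  })
  tree <- build_binary_tree(genos, tables)
  for (j in seq_len(L - 1)) {
    expect_equal(collapse_transitions(tree, j), tables[[j]]$C,
                 tolerance = 1e-12)
    # J on each branch equals the joint probability of the haplotype set
    e <- tree$edges[[j + 1]]
    lev_from <- tree$levels[[j]]; lev_to <- tree$levels[[j + 1]]
    for (r in seq_len(nrow(e))) {
      x <- lev_from$label[match(e$from[r], lev_from$id)]
      y <- lev_to$label[match(e$to[r], lev_to$id)]
      expect_equal(e$J[r], tables[[j]]$J[x, y], tolerance = 1e-9)
    }
  }
  # node counts are expected haplotype counts: level sums to 2N
  for (j in seq_len(L)) expect_equal(sum(tree$levels[[j]]$M), 2 * n)
  # outgoing probabilities sum to 1 from every node, and still do after
  # branching to six states
  hmm <- branch_aberrant(tree, seq_len(L) * 2000L, decay_params())
  expect_equal(sum(hmm$init), 1, tolerance = 1e-12)
  for (Tm in hmm$trans) {
    expect_equal(unname(rowSums(Tm)), rep(1, 6), tolerance = 1e-12)
  }
})
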