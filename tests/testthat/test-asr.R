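balanced4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

test_that("newick trees validate labels and branch lengths", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,(C:1,D:1):1):0;", f)
  tr <- read_newick_tree(f)
  expect_equal(length(tr$tip.label), 4)
  expect_equal(tr$Nnode, 3)

  writeLines("((A:1,A:1):1,C:1);", f)
  expect_error(read_newick_tree(f), "duplicate")

  writeLines("((A:0,B:1):1,C:1);", f)
  expect_warning(tr0 <- read_newick_tree(f), "non-positive")
  expect_true(all(tr0$edge.length > 0))

  ape::write.tree(tr, f)
  back <- read_newick_tree(f)
  expect_true(ape::all.equal.phylo(tr, back))
})

test_that("Mk transition matrix follows the closed form", {
  expect_equal(mk_transition(1, 0), diag(2), ignore_attr = TRUE)
  expect_equal(mk_transition(5, 1e6),
               matrix(0.5, 2, 2), ignore_attr = TRUE, tolerance = 1e-12)
  t_half <- log(2) / 2  # e^(-2qt) = 0.5 at q = 1
  expect_equal(mk_transition(1, t_half),
               matrix(c(0.75, 0.25, 0.25, 0.75), 2), ignore_attr = TRUE)
  P <- mk_transition(0.3, 0.7)
  expect_equal(rowSums(P), c(1, 1), ignore_attr = TRUE)
})

test_that("cherry likelihoods match hand enumeration", {
  cherry <- ape::read.tree(text = "(A:1,B:1);")
  # flip prob ~ 0: likelihood reduces to the 0.5 root prior
  expect_equal(exp(character_likelihood(cherry, c(A = 1, B = 1), 1e-9)), 0.5,
               tolerance = 1e-6)
  # flip prob 0.25 on each branch: 0.5 * (0.75^2 + 0.25^2)
  q25 <- log(2) / 2
  expect_equal(exp(character_likelihood(cherry, c(A = 1, B = 1), q25)),
               0.3125, tolerance = 1e-12)
})

test_that("pruning equals brute-force enumeration on all small topologies", {
  set.seed(61)
  for (n in 2:5) {
    trees <- phangorn::allTrees(n, rooted = TRUE,
                                tip.label = LETTERS[seq_len(n)])
    for (ti in seq_along(trees)) {
      tr <- trees[[ti]]
      tr$edge.length <- runif(nrow(tr$edge), 0.05, 1.5)
      q <- runif(1, 0.05, 3)
      states <- setNames(rbinom(n, 1, 0.5), tr$tip.label)
      expect_lt(abs(character_likelihood(tr, states, q) -
                    oracle_mk_loglik(tr, states, q)), 1e-10)
    }
  }
})

test_that("likelihood is invariant to tip rotation", {
  tr <- balanced4()
  states <- c(A = 1, B = 0, C = 1, D = 1)
  rot <- ape::rotate(tr, ape::getMRCA(tr, c("A", "B")))
  expect_equal(character_likelihood(tr, states, 0.7),
               character_likelihood(rot, states, 0.7), tolerance = 1e-12)
})

test_that("rate estimation finds a local optimum and flags constants", {
  set.seed(62)
  tr <- ape::rphylo(16, 1, 0)
  sim <- simulate_characters_mk(tr, q = 1, n_characters = 30, seed = 5)
  est <- estimate_rate(tr, sim$matrix)
  variable <- apply(sim$matrix$states, 2, function(v) length(unique(v)) > 1)
  expect_false(any(est$boundary[variable]))
  expect_true(all(est$boundary[!variable]))
  for (j in which(variable)[1:5]) {
    v <- sim$matrix$states[, j]
    ll <- function(q) character_likelihood(tr, v, q)
    expect_gte(est$loglik[j] + 1e-9, ll(est$q[j] / 2))
    expect_gte(est$loglik[j] + 1e-9, ll(est$q[j] * 2))
  }
})

test_that("marginal reconstruction matches brute-force conditionals", {
  set.seed(63)
  shapes <- phangorn::allTrees(4, rooted = TRUE, tip.label = LETTERS[1:4])
  for (si in seq_along(shapes)) {
    tr <- shapes[[si]]
    tr$edge.length <- runif(nrow(tr$edge), 0.1, 1.2)
    q <- runif(1, 0.1, 2)
    states <- setNames(rbinom(4, 1, 0.5), tr$tip.label)
    if (length(unique(states)) == 1) states["A"] <- 1 - states["A"]
    ma <- marginal_asr(tr, states, q)
    expect_equal(rowSums(ma$marginal), rep(1, 7), tolerance = 1e-12)
    for (node in 5:7)
      expect_lt(abs(ma$marginal[node, 2] -
                    oracle_mk_marginal(tr, states, q, node)), 1e-10)
  }
})

test_that("marginals behave at limits and under child reordering", {
  tr <- balanced4()
  all1 <- c(A = 1, B = 1, C = 1, D = 1)
  ma <- marginal_asr(tr, all1, 1e-8)
  expect_gt(ma$marginal[5, 2], 1 - 1e-6)  # root certainly present as q -> 0

  cherry <- ape::read.tree(text = "(A:1,B:1);")
  sym <- marginal_asr(cherry, c(A = 0, B = 1), 0.4)
  expect_equal(unname(sym$marginal[3, ]), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(sym$map[3], 0L)  # tie resolves to absent and is flagged
  expect_true(3 %in% sym$ties)

  states <- c(A = 1, B = 0, C = 1, D = 1)
  rot <- ape::rotate(tr, 5)
  m1 <- marginal_asr(tr, states, 0.8)$marginal
  m2 <- marginal_asr(rot, states, 0.8)$marginal
  expect_equal(m1[5:7, ], m2[5:7, ], tolerance = 1e-12)
})

test_that("origin counting reads gains and losses off labelled edges", {
  tr <- balanced4()  # nodes: tips 1-4, root 5, AB node 6, CD node 7
  expect_equal(count_origins(tr, rep(0L, 7)), list(gains = 0, losses = 0))
  one_clade <- c(1L, 1L, 0L, 0L, 0L, 1L, 0L)  # AB clade present
  expect_equal(count_origins(tr, one_clade), list(gains = 1, losses = 0))
  two_clades <- c(1L, 1L, 1L, 1L, 0L, 1L, 1L)
  expect_equal(count_origins(tr, two_clades), list(gains = 2, losses = 0))
  loss <- c(0L, 0L, 1L, 1L, 1L, 0L, 1L)
  expect_equal(count_origins(tr, loss), list(gains = 0, losses = 1))
})

test_that("synapomorphy/homoplasy calls follow the single-origin rule", {
  tr <- balanced4()
  tips <- c(A = 1, B = 1, C = 0, D = 0)
  single_gain <- c(1L, 1L, 0L, 0L, 0L, 1L, 0L)
  expect_identical(classify_character(tr, tips, single_gain, c("A", "B")),
                   "synapomorphy_present")
  # same state also gained on tip D elsewhere
  tips2 <- c(A = 1, B = 1, C = 0, D = 1)
  two_gain <- c(1L, 1L, 0L, 1L, 0L, 1L, 0L)
  expect_identical(classify_character(tr, tips2, two_gain, c("A", "B")),
                   "homoplasy_present")
  # clade uniformly lacking a state that is ancestral elsewhere
  tips3 <- c(A = 0, B = 0, C = 1, D = 1)
  absent <- c(0L, 0L, 1L, 1L, 1L, 0L, 1L)
  expect_identical(classify_character(tr, tips3, absent, c("A", "B")),
                   "synapomorphy_absent")
  # polymorphic clade is uninformative
  expect_identical(classify_character(tr, c(A = 1, B = 0, C = 0, D = 0),
                                      c(1L, 0L, 0L, 0L, 0L, 0L, 0L),
                                      c("A", "B")),
                   "uninformative")
  expect_error(classify_character(tr, tips, single_gain, c("A", "C")),
               "monophyletic")
})

test_that("run_asr reports every character and the ubiquitous set", {
  set.seed(64)
  cfg <- simulation_config(seed = 8, n_genera = 8, clades = 2)
  ds <- simulate_dataset(cfg)
  cm <- ds$characters$matrix
  cm$states[, 1] <- 1L  # force one ubiquitous character
  res <- run_asr(ds$tree, cm, clades = ds$clades)
  expect_equal(nrow(res$report), ncol(cm$states))
  expect_true(colnames(cm$states)[1] %in% res$ubiquitous)
  expect_identical(
    unname(res$characters[[colnames(cm$states)[1]]]$calls),
    rep("uninformative", length(ds$clades)))
  expect_s3_class(res$clade_table, "data.frame")

  # tree pruning to sampled genera
  sub <- character_matrix(cm$states[1:6, , drop = FALSE])
  res2 <- run_asr(ds$tree, sub, clades = ds$clades)
  expect_equal(length(res2$tree$tip.label), 6)
})

test_that("ML likelihood agrees with an independent Mk implementation", {
  set.seed(65)
  tr <- ape::rphylo(10, 1, 0)
  sim <- simulate_characters_mk(tr, q = 0.8, n_characters = 5, seed = 2)
  for (j in 1:5) {
    v <- sim$matrix$states[, j]
    if (length(unique(v)) == 1) next
    x <- setNames(factor(v), names(v))
    fit <- phytools::fitMk(tr, x, model = "ER", pi = "equal")
    q_hat <- fit$rates[1]
    if (q_hat <= 0) next
    expect_equal(character_likelihood(tr, v, q_hat)[1], fit$logLik,
                 tolerance = 1e-4)
  }
})

test_that("parsimony labelling matches ML on clean clade characters", {
  tr <- balanced4()
  tips <- c(A = 1, B = 1, C = 0, D = 0)
  ps <- chemophylo:::fitch_states(tr, tips)
  expect_equal(ps[6], 1L)  # AB ancestor present
  expect_equal(ps[5], 0L)  # root absent (tie resolved toward 0)
  oc <- count_origins(tr, ps)
  expect_equal(oc$gains, 1)
})
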