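test_that("fitch length matches hand cases and brute-force enumeration", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(fitch_length(tr, c(A = "0", B = "0", C = "1", D = "1")), 1L)
  expect_equal(fitch_length(tr, c(A = "0", B = "1", C = "0", D = "1")), 2L)
  expect_equal(fitch_length(tr, c(A = "0", B = "?", C = "0", D = "0")), 0L)
  # randomized cross-check against exhaustive internal labelings
  set.seed(5)
  for (i in 1:20) {
    nt <- sample(4:6, 1)
    tr <- ape::rtopology(nt, rooted = FALSE, tip.label = LETTERS[1:nt])
    nst <- sample(2:3, 1)
    col <- vapply(seq_len(nt), function(j) {
      if (runif(1) < 0.15) return("?")
      cell_from_states(unique(sample(0:(nst - 1),
                                     1 + (runif(1) < 0.2), TRUE)))
    }, "")
    names(col) <- tr$tip.label
    expect_equal(fitch_length(tr, col, nst),
                 brute_force_length(tr, col, nst, ordered = FALSE))
  }
})

test_that("sankoff length under linear costs matches exhaustive minima", {
  star <- ape::read.tree(text = "(A,B,C);")
  expect_equal(sankoff_length(star, c(A = "0", B = "2", C = "1"),
                              n_states = 3), 2L)
  expect_equal(sankoff_length(star, c(A = "0", B = "0/2", C = "2"),
                              n_states = 3), 2L)
  set.seed(6)
  for (i in 1:20) {
    nt <- sample(4:6, 1)
    tr <- ape::rtopology(nt, rooted = FALSE, tip.label = LETTERS[1:nt])
    nst <- sample(3:4, 1)
    col <- vapply(seq_len(nt), function(j) {
      if (runif(1) < 0.15) return("?")
      cell_from_states(unique(sample(0:(nst - 1),
                                     1 + (runif(1) < 0.2), TRUE)))
    }, "")
    names(col) <- tr$tip.label
    expect_equal(sankoff_length(tr, col, nst),
                 brute_force_length(tr, col, nst, ordered = TRUE))
  }
})

test_that("fitch and sankoff agree on binary columns; both match phangorn", {
  set.seed(8)
  for (i in 1:20) {
    nt <- sample(4:8, 1)
    tr <- ape::rtopology(nt, rooted = FALSE,
                         tip.label = sprintf("t%02d", 1:nt))
    col <- setNames(sample(c("0", "1"), nt, TRUE), tr$tip.label)
    f <- fitch_length(tr, col, 2)
    expect_equal(f, sankoff_length(tr, col, 2, ordered = TRUE))
    # independent implementation: phangorn's parsimony scorer
    dat <- phangorn::phyDat(matrix(col, ncol = 1,
                                   dimnames = list(names(col), NULL)),
                            type = "USER", levels = c("0", "1"))
    expect_equal(f, as.integer(phangorn::parsimony(tr, dat)))
  }
})

test_that("tree length is invariant under re-rooting and leaf permutation", {
  m <- rand_matrix(7, 12, 99)
  tr <- rand_tree(7, 99)
  base <- tree_score(tr, m)$steps
  for (og in sample(m$taxa, 3))
    expect_equal(tree_score(ape::root(tr, og, resolve.root = TRUE), m)$steps,
                 base)
  # the same labelled topology serialized and re-read (rotated clades,
  # different internal numbering) scores identically
  tr3 <- ape::read.tree(text = ape::write.tree(tr))
  expect_equal(tree_score(tr3, m)$steps, base)
})

test_that("minimum conceivable steps: hitting sets and morphocline spans", {
  expect_equal(min_steps(c("0", "1", "0/1"), 2, ordered = FALSE), 1L)
  expect_equal(min_steps(c("0", "0/1", "0/2"), 3, ordered = FALSE), 0L)
  expect_equal(min_steps(c("0", "3"), 4, ordered = TRUE), 3L)
  expect_equal(min_steps(c("?", "?"), 2, ordered = FALSE), 0L)
  # s >= m on every column, with equality attained on some tree (n <= 6)
  set.seed(12)
  for (i in 1:10) {
    m <- rand_matrix(6, 6, 300 + i)
    trees <- phangorn::allTrees(6, rooted = FALSE, tip.label = m$taxa)
    cols <- shellphylo:::prepare_columns(m)
    steps <- shellphylo:::steps_for_trees(
      lapply(seq_along(trees), function(k) trees[[k]]), cols)
    for (j in seq_along(cols$nstates)) {
      mj <- min_steps(cols$cells[, j], cols$nstates[j], cols$ordered[j])
      expect_true(all(steps[, j] >= mj))
      expect_equal(min(steps[, j]), mj)
    }
  }
})

test_that("implied weighting uses h/(h+K) and coincides with equal weights on clean data", {
  m <- rand_matrix(6, 8, 77)
  tr <- rand_tree(6, 77)
  sc <- tree_score(tr, m, K = 6)
  expect_equal(sc$fit$h, sc$fit$s - sc$fit$m)
  expect_equal(sc$fit$fit_cost, sc$fit$h / (sc$fit$h + 6))
  expect_equal(sc$implied_cost, sum(sc$fit$fit_cost))
  # single-character fixed points: h = 0 -> 0; h = K -> 1/2
  expect_equal(0 / (0 + 6), 0)
  tr4 <- ape::read.tree(text = "((A,B),(C,D));")
  m1 <- coded_matrix(LETTERS[1:4], character_defs(1, n_states = 2),
                     matrix(c("0", "1", "0", "1"), 4, 1))
  s1 <- tree_score(tr4, m1, K = 1)  # s = 2, m = 1, h = 1 -> cost 1/2
  expect_equal(s1$implied_cost, 0.5)
  # clean (compatible) matrix: equal-weights and implied-weights optima agree
  dat <- simulate_morph_dataset(sim_config(n_species = 6, n_characters = 40,
                                           minority_polymorphism_rate = 0,
                                           missingness_rate = 0,
                                           abnormality_rate = 0,
                                           change_prob = c(0.02, 0.03),
                                           rng_seed = 13))
  cm <- code_species(dat$specimens)
  ew <- heuristic_search(cm, search_config(n_ras = 3, rng_seed = 1))
  iw <- heuristic_search(cm, search_config(n_ras = 3, rng_seed = 1, K = 6))
  if (all(tree_score(ew$mpt_set[[1]], cm)$fit$h == 0)) {
    expect_equal(sort(vapply(ew$mpt_set, shellphylo:::topology_key, "")),
                 sort(vapply(iw$mpt_set, shellphylo:::topology_key, "")))
    expect_equal(iw$best_score, 0)
  }
})

test_that("heuristic search finds the exhaustive optimum and is seed-reproducible", {
  all7 <- phangorn::allTrees(7, rooted = FALSE,
                             tip.label = sprintf("t%02d", 1:7))
  for (s in 1:8) {
    m <- rand_matrix(7, 10, 400 + s)
    eb <- min(score_trees(all7, m))
    res <- heuristic_search(m, search_config(n_ras = 4, rng_seed = s))
    expect_equal(res$best_score, eb)
  }
  # bit-for-bit reproducibility under rng_seed
  m <- rand_matrix(8, 10, 500)
  r1 <- heuristic_search(m, search_config(n_ras = 4, rng_seed = 7))
  r2 <- heuristic_search(m, search_config(n_ras = 4, rng_seed = 7))
  expect_identical(vapply(r1$mpt_set, shellphylo:::topology_key, ""),
                   vapply(r2$mpt_set, shellphylo:::topology_key, ""))
  expect_identical(r1$best_score, r2$best_score)
  # perfect data recovers the generating tree uniquely
  dat <- simulate_morph_dataset(sim_config(n_species = 6, n_characters = 60,
                                           minority_polymorphism_rate = 0,
                                           missingness_rate = 0,
                                           abnormality_rate = 0,
                                           fraction_ontogeny = 0,
                                           change_prob = c(0.04, 0.06),
                                           rng_seed = 17))
  res <- heuristic_search(dat$truth$true_matrix,
                          search_config(n_ras = 3, rng_seed = 2))
  cmp <- average_over_mpts(res$mpt_set, dat$truth$species_tree)
  expect_equal(cmp$mean_sja_pct, 100)
})

test_that("NNI neighborhoods also reach the optimum on small matrices", {
  all6 <- phangorn::allTrees(6, rooted = FALSE,
                             tip.label = sprintf("t%02d", 1:6))
  for (s in 1:5) {
    m <- rand_matrix(6, 10, 600 + s)
    eb <- min(score_trees(all6, m))
    res <- heuristic_search(m, search_config(n_ras = 6, swap = "nni",
                                             rng_seed = s))
    expect_equal(res$best_score, eb)
  }
})

test_that("secondary rooting recovers a clade or reports the conflict", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  rooted <- root_by_clade(ape::unroot(tr), c("A", "B"))
  expect_true(ape::is.monophyletic(rooted, c("A", "B")))
  expect_error(root_by_clade(ape::unroot(tr), c("A", "C")),
               "clade not recoverable")
})

test_that("zero-change characters are exactly those with s = 0 on every optimum", {
  taxa <- sprintf("t%02d", 1:6)
  cells <- cbind(rep("0", 6),                       # constant
                 c("0", "0/1", "1", "?", "0", "0"), # can be hit by one state?
                 c("0", "1", "0", "1", "0", "1"))   # variable
  m <- coded_matrix(taxa, character_defs(1:3, n_states = 2), cells)
  res <- heuristic_search(m, search_config(n_ras = 4, rng_seed = 3))
  zc <- zero_change_characters(res$mpt_set, m)
  expect_true(1 %in% zc)
  expect_false(3 %in% zc)
  # column 2 needs one change at minimum (hitting set size 2), never zero
  expect_false(2 %in% zc)
})

test_that("strict consensus equals the bipartition-intersection oracle", {
  # identical trees -> the tree itself
  tr <- rand_tree(7, 1)
  cons <- strict_consensus(list(tr, tr))
  expect_identical(shellphylo:::topology_key(cons),
                   shellphylo:::topology_key(tr))
  # trees differing in one cherry lose exactly that node
  t1 <- ape::read.tree(text = "(((A,B),C),(D,E));")
  t2 <- ape::read.tree(text = "(((A,C),B),(D,E));")
  cons <- strict_consensus(list(t1, t2))
  sp <- tree_splits(ape::unroot(cons))
  expect_equal(nrow(sp), 1L)  # only the DE|ABC split survives
  # random sets vs split intersection
  for (s in 1:5) {
    trees <- lapply(1:3, function(i) rand_tree(8, 10 * s + i))
    cons <- strict_consensus(trees)
    taxa <- sort(trees[[1]]$tip.label)
    keys <- function(tr) apply(tree_splits(tr, taxa), 1, paste, collapse = "")
    shared <- Reduce(intersect, lapply(trees, keys))
    expect_setequal(keys(cons), shared)
  }
  expect_error(strict_consensus(list(rand_tree(5, 1), rand_tree(6, 1))),
               "leaf sets differ")
})
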