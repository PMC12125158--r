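test_that("state frequencies use display semantics and abnormality exclusion", {
  fr <- state_frequencies(c("0", "0", "0/1", "1"))
  expect_equal(fr$n_scored, 4L)
  expect_equal(fr$freq$fraction[fr$freq$state == 0], 0.75)
  expect_equal(fr$freq$fraction[fr$freq$state == 1], 0.5)
  # fractions may sum past 1 when polymorphic individuals exist
  expect_gt(sum(fr$freq$fraction), 1)
  fr2 <- state_frequencies(c("0", "0", "0", "0", "1"))
  expect_equal(fr2$freq$fraction[fr2$freq$state == 1], 0.20)
  # abnormal-flagged observation leaves the denominator
  fr3 <- state_frequencies(c("0", "0", "1"), abnormal = c(FALSE, FALSE, TRUE))
  expect_equal(fr3$n_scored, 2L)
  expect_false(1 %in% fr3$freq$state)
  # missing and inapplicable are never scored
  expect_equal(state_frequencies(c("?", "-"))$n_scored, 0L)
})

test_that("the 20% filter suppresses minority states; exact 20% depends on the comparator", {
  cfg <- coding_config()
  mk <- function(cells) state_frequencies(cells, config = cfg)
  expect_equal(code_frequency_filter(mk(c(rep("0", 17), rep("0/1", 3))), cfg), "0")
  expect_equal(code_frequency_filter(mk(c(rep("0", 3), rep("1", 2))), cfg), "0/1")
  # 1 displaying individual out of 5 is exactly 20%: suppressed under ">"
  five <- c(rep("0", 4), "1")
  expect_equal(code_frequency_filter(mk(five), cfg), "0")
  cfg_ge <- coding_config(threshold_comparator = "at_least")
  expect_equal(code_frequency_filter(state_frequencies(five, config = cfg_ge),
                                     cfg_ge), "0/1")
  # nothing passes -> modal state survives
  cfg_hi <- coding_config(frequency_threshold = 0.9)
  expect_equal(code_frequency_filter(state_frequencies(c("0", "0", "1"),
                                                       config = cfg_hi),
                                     cfg_hi), "0")
  expect_equal(code_frequency_filter(state_frequencies(character(0)),
                                     cfg), "?")
})

test_that("ontogenetic coding follows the most skeletally mature individuals", {
  cfg <- coding_config()
  # mature subset all state 2; juveniles at 0/1 are ignored
  cells <- c(rep("0", 4), rep("1", 4), rep("2", 4))
  mats <- c(30, 32, 35, 38, 50, 52, 55, 58, 90, 92, 95, 99)
  expect_equal(code_ontogenetic(cells, mats, config = cfg)$cell, "2")
  # similarly mature adults straddling a threshold -> species polymorphic
  cells2 <- c(rep("1", 8), "1", "1/2", "1/2", "1/2")
  expect_equal(code_ontogenetic(cells2, mats, config = cfg)$cell, "1/2")
  # a lone minority flip in one (non-top) mature specimen is not corroborated
  cells3 <- c(rep("0", 8), "1", "0/1", "1", "1")
  expect_equal(code_ontogenetic(cells3, mats, config = cfg)$cell, "1")
  # no maturity data -> flagged fallback to plain frequency coding
  res <- code_ontogenetic(c("0", "0", "0", "0", "1"), rep(NA_real_, 5),
                          config = cfg)
  expect_equal(res$rule, "fallback_frequency")
  expect_equal(res$cell, "0")
})

test_that("ontogenetic coding recovers the adult state in simulated species", {
  # adult state expressed above the maturity threshold, juveniles below
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    adult <- 3L
    mat <- runif(20, 30, 100)
    cells <- ifelse(mat >= 60, "3", as.character(sample(0:2, 20, TRUE)))
    if (code_ontogenetic(cells, mat)$cell == "3") hits <- hits + 1
  }
  expect_equal(hits, 100L)
})

test_that("maxpoly is the union of observed sets and contains minpoly", {
  expect_equal(code_maxpoly(c("0", "1", "0/1")), "0/1")
  expect_equal(code_maxpoly(c("?", "?")), "?")
  dat <- simulate_morph_dataset(sim_config(n_species = 6, n_characters = 15,
                                           rng_seed = 21))
  mn <- code_species(dat$specimens, variant = "minpoly")
  mx <- code_species(dat$specimens, variant = "maxpoly")
  for (i in seq_along(mn$cells)) {
    a <- cell_states(mn$cells[i]); b <- cell_states(mx$cells[i])
    if (!is.null(a)) expect_true(all(a %in% b))
  }
})

test_that("raising the frequency threshold never adds states", {
  dat <- simulate_morph_dataset(sim_config(n_species = 6, n_characters = 12,
                                           rng_seed = 31))
  lo <- code_species(dat$specimens, coding_config(frequency_threshold = 0.15))
  hi <- code_species(dat$specimens, coding_config(frequency_threshold = 0.35))
  for (i in seq_along(lo$cells)) {
    a <- cell_states(hi$cells[i]); b <- cell_states(lo$cells[i])
    if (!is.null(a) && !is.null(b)) expect_true(all(a %in% b))
  }
})

test_that("measurements discretize with polymorphic margins at bin edges", {
  # nuchal-callosity width: edges 30/50/70%, 3-point margin
  expect_equal(discretize_measurement(53, c(30, 50, 70), 3), "1/2")
  expect_equal(discretize_measurement(40, c(30, 50, 70), 3), "1")
  expect_equal(discretize_measurement(95, c(30, 50, 70), 3), "3")
  expect_equal(discretize_measurement(5, c(30, 50, 70), 3), "0")
  # entoplastral angle: edges 80/100 degrees, 3-degree margin
  expect_equal(discretize_measurement(79, c(80, 100), 3), "0/1")
  expect_equal(discretize_measurement(90, c(80, 100), 3), "1")
  expect_error(discretize_measurement(-1, c(30, 50), 3), "non-negative")
  # shipped character definition drives the same binning
  defs <- trionychid_characters()
  expect_equal(discretize_by_character(53, defs[defs$index == 10, ]), "1/2")
  # offset state labels (width bins labelled from 3 upward)
  expect_equal(discretize_measurement(45, c(40, 50, 60, 70), 2,
                                      min_state = 3L), "4")
})

test_that("overrides are applied last and logged; empty overrides reproduce pure rules", {
  dat <- simulate_morph_dataset(sim_config(n_species = 5, n_characters = 6,
                                           rng_seed = 41))
  base <- code_species(dat$specimens)
  ov <- data.frame(species = base$taxa[1], character = 2L, states = "0/1",
                   rationale = "taxon-specific exception")
  forced <- code_species(dat$specimens, coding_config(overrides = ov))
  expect_equal(unname(forced$cells[1, 2]), "0/1")
  expect_equal(forced$cells[-1, ], base$cells[-1, ])
  aud <- attr(forced, "audit")
  expect_equal(aud$rule[aud$species == base$taxa[1] & aud$character == 2],
               "override")
  same <- code_species(dat$specimens, coding_config(overrides = NULL))
  expect_identical(same$cells, base$cells)
  expect_error(code_species(dat$specimens, coding_config(
    overrides = data.frame(species = "nope", character = 1, states = "0"))),
    "unknown species")
})

test_that("inapplicable scores fold into state 0 only for configured characters", {
  chars <- character_defs(1:2, n_states = 2)
  meta <- data.frame(specimen_id = sprintf("s%d", 1:5), species_id = "sp")
  cells <- cbind(c("-", "-", "-", "-", "1"), c("-", "-", "-", "-", "1"))
  sp <- specimen_set(cells, meta, chars)
  cm <- code_species(sp, coding_config(inapplicable_to_zero = 1L))
  expect_equal(unname(cm$cells[1, 1]), "0")  # folded zeros dominate; 1/5 filtered
  expect_equal(unname(cm$cells[1, 2]), "1")  # untouched: only the observed cell counts
})

test_that("fontanelle helper column derives formation and closure characters", {
  chars <- character_defs(1:3, n_states = c(3, 5, 5),
                          active = c(TRUE, TRUE, FALSE))
  # species A: posteromedian pathway, closes mid-ontogeny
  # species B: posterolateral pathway, never closes in adults
  meta <- data.frame(
    specimen_id = sprintf("s%d", 1:8),
    species_id = rep(c("A", "B"), each = 4),
    relative_maturity_pct = c(25, 45, 65, 90, 30, 55, 75, 95))
  helper <- c("0", "1", "2", "2", "4", "4", "4", "4")
  cells <- cbind(rep("0", 8), rep("0", 8), helper)
  sp <- specimen_set(cells, meta, chars)
  ov <- derive_fontanelle_characters(sp, helper_index = 3L,
                                     pathway_index = 1L, closure_index = 2L)
  a <- ov[ov$species == "A", ]
  expect_equal(a$states[a$character == 1], "1")  # posteromedian
  expect_equal(a$states[a$character == 2], "1")  # closed at 45% -> mid band
  b <- ov[ov$species == "B", ]
  expect_equal(b$states[b$character == 1], "2")  # posterolateral
  expect_equal(b$states[b$character == 2], "4")  # open in adults
})
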