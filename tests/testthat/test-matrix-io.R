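test_that("all four polymorphism dialects canonicalize to one set representation", {
  tmp <- tempfile(fileext = ".nex")
  writeLines(c(
    "#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=2 NCHAR=4;",
    "FORMAT DATATYPE=STANDARD SYMBOLS=\"0123\" MISSING=? GAP=-;", "MATRIX",
    "spA__x1 0{12}?-",
    "spB__x2 0/1(23)0\\20", ";", "END;"), tmp)
  sp <- read_individual_nexus(tmp)
  expect_equal(unname(sp$cells[1, ]), c("0", "1/2", "?", "-"))
  expect_equal(unname(sp$cells[2, ]), c("0/1", "2/3", "0/2", "0"))
  expect_equal(sp$meta$species_id, c("spA", "spB"))
  expect_equal(sp$meta$specimen_id, c("x1", "x2"))
  # slash and backslash forms parse identically
  expect_identical(unname(sp$cells[2, 1]), "0/1")
})

test_that("parse errors name the offending row and detect ragged matrices", {
  tmp <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=1 NCHAR=3;",
               "FORMAT SYMBOLS=\"01\";", "MATRIX", "a 0Z1", ";", "END;"), tmp)
  expect_error(read_individual_nexus(tmp), "unknown symbol 'Z'.*'a'")
  writeLines(c("#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=2 NCHAR=3;",
               "FORMAT SYMBOLS=\"01\";", "MATRIX",
               "a 011", "b 01101", ";", "END;"), tmp)
  expect_error(read_individual_nexus(tmp), "ragged")
  writeLines(c("#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=3 NCHAR=3;",
               "FORMAT SYMBOLS=\"01\";", "MATRIX",
               "a 011", "b 010", ";", "END;"), tmp)
  expect_error(read_individual_nexus(tmp), "NTAX")
})

test_that("square-bracket comments are preserved on the specimen", {
  tmp <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=1 NCHAR=2;",
               "FORMAT SYMBOLS=\"01\";", "MATRIX",
               "sp__a 0[SCL 23.5 cm]1", ";", "END;"), tmp)
  sp <- read_individual_nexus(tmp)
  expect_match(sp$meta$comments[1], "SCL 23.5 cm")
  expect_equal(unname(sp$cells[1, ]), c("0", "1"))
})

test_that("write->read round-trips randomized matrices bit-exactly", {
  for (seed in 1:10) {
    m <- rand_matrix(sample(4:9, 1), sample(3:12, 1), seed)
    f <- tempfile(fileext = ".nex")
    write_species_matrix(m, f, "nexus")
    m2 <- read_species_nexus(f)
    expect_identical(unname(m2$cells), unname(m$cells))
    expect_identical(m2$taxa, m$taxa)
    expect_identical(m2$chars$ordered, m$chars$ordered)
  }
})

test_that("individual-level matrices round-trip through NEXUS", {
  dat <- simulate_morph_dataset(sim_config(n_species = 5, n_characters = 8,
                                           rng_seed = 3))
  f <- tempfile(fileext = ".nex")
  write_individual_nexus(dat$specimens, f)
  sp2 <- read_individual_nexus(f)
  expect_identical(unname(sp2$cells), unname(dat$specimens$cells))
  expect_identical(sp2$meta$species_id, dat$specimens$meta$species_id)
})

test_that("TNT output uses xread with bracketed polymorphism and 0-based ccode", {
  m <- coded_matrix(c("taxonA", "taxonB"),
                    character_defs(1, n_states = 2),
                    matrix(c("0", "0/1"), 2, 1))
  f <- tempfile(fileext = ".tnt")
  write_species_matrix(m, f, "tnt")
  lines <- readLines(f)
  expect_equal(lines[3], "1 2")
  expect_match(lines[4], "^taxonA\\s+0$")
  expect_match(lines[5], "^taxonB\\s+\\[01\\]$")
  # ordered characters emitted 0-based
  m$chars$ordered <- TRUE
  write_species_matrix(m, f, "tnt")
  expect_true(any(grepl("^ccode \\+ 0;$", readLines(f))))
})

test_that("states beyond the 32-symbol alphabet are rejected on write", {
  m <- coded_matrix("a", character_defs(1, n_states = 40),
                    matrix("35", 1, 1))
  expect_error(write_species_matrix(m, tempfile(), "tnt"),
               "unsupported symbol")
})

test_that("inactive helper columns are excluded from analysis output", {
  chars <- character_defs(1:3, n_states = 2, active = c(TRUE, FALSE, TRUE))
  m <- coded_matrix(c("a", "b"), chars,
                    matrix(c("0", "1", "1", "0", "0", "1"), 2, 3))
  f <- tempfile(fileext = ".nex")
  write_species_matrix(m, f, "nexus")
  m2 <- read_species_nexus(f)
  expect_equal(ncol(m2$cells), 2L)
})

test_that("shipped trionychid metadata flags exactly the morphocline set as ordered", {
  defs <- trionychid_characters()
  expect_equal(nrow(defs), 70L)
  morphoclines <- c(1, 3, 5, 6, 8, 10, 11, 17, 18, 21, 22, 24, 26, 31, 34, 35,
                    39, 41:44, 47, 48, 51:54, 56, 58:62, 65, 66, 68)
  expect_setequal(defs$index[defs$ordered], morphoclines)
  expect_false(defs$active[defs$index == 70])
  expect_equal(sum(defs$active), 69L)
  # measurement characters carry edges and margins within invariants
  c10 <- defs[defs$index == 10, ]
  expect_equal(shellphylo:::parse_bin_edges(c10$bin_edges), c(30, 50, 70))
  expect_equal(c10$margin, 3)
})

test_that("character metadata invariants are enforced", {
  expect_error(character_defs(1, n_states = 1), "at least 2")
  expect_error(character_defs(1, n_states = 3, bin_edges = "50;30"),
               "ascending")
  expect_error(character_defs(1, n_states = 3, bin_edges = "30;50",
                              margin = 10), "half the smallest")
  sidecar <- tempfile(fileext = ".csv")
  defs <- trionychid_characters()
  write_character_defs(defs, sidecar)
  defs2 <- read_character_defs(sidecar)
  expect_equal(defs2$ordered, defs$ordered)
  expect_equal(defs2$bin_edges, defs$bin_edges)
})
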