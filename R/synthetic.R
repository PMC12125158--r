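# Synthetic data with known ground truth ---------------------------------------
#
# Generates individual-level datasets that emulate the structure of a
# polymorphism-rich osteological sample: a known species tree, discrete
# characters evolved along it (unordered Markov or ordered nearest-neighbour
# walks respecting morphoclines), per-species samples of individuals whose
# expression of ontogeny-controlled characters is a monotone step function of
# relative skeletal maturity, minority-state polymorphism at a set rate,
# continuous measurements with noise for morphometric characters, missing
# data, and rare abnormal individuals. Sampling of maturities is adult-biased
# (Uniform[30, 100] by default), mirroring collections that strongly
# undersample juveniles.

#' Simulation configuration
#'
#' @param n_species number of species (>= 4).
#' @param n_characters number of characters.
#' @param fraction_ordered fraction of characters evolved (and scored) as
#'   ordered morphoclines.
#' @param fraction_ontogeny fraction of characters whose expression depends
#'   on skeletal maturity.
#' @param individuals_per_species specimens drawn per species (scalar or
#'   length-2 range).
#' @param minority_polymorphism_rate per-cell probability that an individual
#'   displays a neighbouring minority state in addition to its true state.
#' @param missingness_rate per-cell probability of a missing score.
#' @param abnormality_rate per-individual probability of being abnormal (one
#'   random character gets an aberrant, flagged score).
#' @param n_states states per character.
#' @param change_prob per-branch probability of state change, drawn per
#'   character from this range to yield a mix of clean and homoplastic
#'   columns.
#' @param maturity_range relative maturities are drawn Uniform over this
#'   range, percent (default `c(30, 100)`, adult-biased).
#' @param maturity_threshold maturity (percent) above which the adult state
#'   is expressed for ontogeny-controlled characters.
#' @param n_morphometric number of characters (taken from the end of the
#'   ordered block) treated as morphometric: individuals emit a continuous
#'   measurement (bin centre of the expressed state plus Gaussian noise)
#'   which is re-binned through [discretize_measurement()] with the
#'   character's margin, so edge-straddling polymorphism arises naturally.
#' @param measurement_noise_sd Gaussian noise of the continuous measurement,
#'   in bin-width units.
#' @param measurement_margin polymorphic band half-width around bin edges,
#'   in bin-width units.
#' @param rng_seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_species = 8L, n_characters = 20L,
                       fraction_ordered = 0.5, fraction_ontogeny = 0.25,
                       individuals_per_species = 20L,
                       minority_polymorphism_rate = 0.10,
                       missingness_rate = 0.05,
                       abnormality_rate = 0.02,
                       n_states = 3L,
                       change_prob = c(0.05, 0.4),
                       maturity_range = c(30, 100),
                       maturity_threshold = 60,
                       n_morphometric = 0L,
                       measurement_noise_sd = 0.15,
                       measurement_margin = 0.1,
                       rng_seed = 1L) {
  stopifnot(n_species >= 4, n_characters >= 1,
            minority_polymorphism_rate >= 0, minority_polymorphism_rate <= 1,
            missingness_rate >= 0, missingness_rate <= 1,
            abnormality_rate >= 0, abnormality_rate <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a species tree and true species codings
#'
#' Draws a random binary topology (uniform over labelled topologies) and
#' evolves each character along it: unordered characters under a symmetric
#' k-state Markov jump (change with a per-character branch probability, new
#' state uniform among the others), ordered characters under a
#' nearest-neighbour walk (single +-1 steps, clamped at the morphocline ends,
#' so a branch draw never moves the state by 2 or more).
#'
#' @param config a [sim_config()].
#' @return list of class `ground_truth`: `species_tree` (phylo),
#'   `true_matrix` (a [coded_matrix()] of the true codings), `chars`,
#'   `adult_state` (species x character true adult states),
#'   `change_prob` per character.
#' @export
simulate_species_characters <- function(config = sim_config()) {
  set.seed(config$rng_seed)
  n <- config$n_species
  taxa <- sprintf("sp%02d", seq_len(n))
  tree <- ape::rtopology(n, rooted = TRUE, tip.label = taxa)
  tree$edge.length <- NULL
  k <- config$n_characters
  ordered <- seq_len(k) <= round(config$fraction_ordered * k)
  onto <- rep(FALSE, k)
  if (config$fraction_ontogeny > 0)
    onto[sample.int(k, round(config$fraction_ontogeny * k))] <- TRUE
  bin_edges <- rep(NA_character_, k)
  margin <- rep(NA_real_, k)
  if (config$n_morphometric > 0) {
    # morphometric characters sit at the end of the ordered block: states are
    # unit bins [s, s+1) with edges 1..S-1
    morpho <- utils::tail(which(ordered), config$n_morphometric)
    bin_edges[morpho] <- paste(seq_len(config$n_states - 1L), collapse = ";")
    margin[morpho] <- config$measurement_margin
  }
  chars <- character_defs(seq_len(k), n_states = config$n_states,
                          ordered = ordered, ontogeny_controlled = onto,
                          bin_edges = bin_edges, margin = margin)
  p_change <- stats::runif(k, config$change_prob[1], config$change_prob[2])
  S <- config$n_states
  # evolve down the rooted tree
  edge <- stats::reorder(tree, "cladewise")$edge
  nnode <- max(edge)
  states <- matrix(NA_integer_, nnode, k)
  root <- setdiff(edge[, 1], edge[, 2])[1]
  states[root, ] <- sample.int(S, k, replace = TRUE) - 1L
  for (e in seq_len(nrow(edge))) {
    from <- states[edge[e, 1], ]
    change <- stats::runif(k) < p_change
    to <- from
    if (any(change)) {
      for (j in which(change)) {
        if (ordered[j]) {
          step <- if (from[j] == 0) 1L else if (from[j] == S - 1L) -1L
                  else sample(c(-1L, 1L), 1)
          to[j] <- from[j] + step
        } else {
          to[j] <- sample(setdiff(0:(S - 1L), from[j]), 1)
        }
      }
    }
    states[edge[e, 2], ] <- to
  }
  adult <- states[seq_len(n), , drop = FALSE]
  rownames(adult) <- tree$tip.label
  adult <- adult[match(taxa, rownames(adult)), , drop = FALSE]
  cells <- matrix(vapply(as.vector(adult), cell_from_states, ""),
                  n, k, dimnames = list(taxa, NULL))
  structure(list(
    species_tree = ape::unroot(tree),
    true_matrix = coded_matrix(taxa, chars, cells, "minpoly"),
    chars = chars, adult_state = adult, change_prob = p_change,
    config = config
  ), class = "ground_truth")
}

# expressed state of an ontogeny-controlled character: a monotone step
# function of maturity -- the juvenile state (morphocline origin, e.g.
# "structure not yet formed") below the maturity threshold, the adult state
# above it
expressed_state <- function(adult, maturity, threshold, juvenile = 0L) {
  if (maturity >= threshold) adult else juvenile
}

#' Simulate individual specimens from a ground truth
#'
#' Per species, relative maturities are drawn from the configured adult-biased
#' range; ontogeny-controlled characters express juvenile states below the
#' maturity threshold (a monotone step function climbing to the adult state);
#' every cell picks up a neighbouring minority state with the configured
#' polymorphism rate (recorded as a polymorphic observation containing the
#' true state: display semantics), is dropped with the missingness rate, and
#' abnormal individuals receive a flagged aberrant score on one character.
#'
#' @param truth a `ground_truth` from [simulate_species_characters()].
#' @param config optional [sim_config()] (default: the one inside `truth`).
#' @return a [specimen_set()].
#' @export
simulate_individuals <- function(truth, config = truth$config) {
  set.seed(config$rng_seed + 1L)
  chars <- truth$chars
  S <- config$n_states
  taxa <- truth$true_matrix$taxa
  nips <- config$individuals_per_species
  meta <- list(); cells <- list(); abnormal <- list()
  for (sp in taxa) {
    n_i <- if (length(nips) == 2) sample(nips[1]:nips[2], 1) else nips
    mat <- stats::runif(n_i, config$maturity_range[1], config$maturity_range[2])
    for (i in seq_len(n_i)) {
      row <- character(nrow(chars))
      ab <- rep(FALSE, nrow(chars))
      for (j in seq_len(nrow(chars))) {
        true_adult <- truth$adult_state[sp, j]
        st <- if (chars$ontogeny_controlled[j])
          expressed_state(true_adult, mat[i], config$maturity_threshold)
        else true_adult
        if (!is.na(chars$bin_edges[j])) {
          # morphometric: continuous measurement around the bin centre,
          # re-binned (with margin) into possibly edge-straddling states
          value <- st + 0.5 +
            stats::rnorm(1, 0, config$measurement_noise_sd)
          row[j] <- discretize_by_character(max(value, 0), chars[j, ])
          next
        }
        states <- st
        if (stats::runif(1) < config$minority_polymorphism_rate) {
          nb <- if (chars$ordered[j])
            intersect(st + c(-1L, 1L), 0:(S - 1L))
          else setdiff(0:(S - 1L), st)
          if (length(nb)) states <- c(st, sample(nb, 1))
        }
        row[j] <- cell_from_states(states)
      }
      # missingness
      drop <- stats::runif(nrow(chars)) < config$missingness_rate
      row[drop] <- "?"
      # abnormality: one character gets an aberrant flagged score
      if (stats::runif(1) < config$abnormality_rate) {
        j <- sample.int(nrow(chars), 1)
        row[j] <- cell_from_states(sample(0:(S - 1L), 1))
        ab[j] <- TRUE
      }
      meta[[length(meta) + 1L]] <- data.frame(
        specimen_id = sprintf("%s_i%03d", sp, i), species_id = sp,
        carapace_length_cm = round(mat[i] / 2, 1),  # species max 50 cm
        relative_maturity_pct = mat[i], comments = "",
        stringsAsFactors = FALSE)
      cells[[length(cells) + 1L]] <- row
      abnormal[[length(abnormal) + 1L]] <- ab
    }
  }
  specimen_set(do.call(rbind, cells), do.call(rbind, meta), chars,
               do.call(rbind, abnormal))
}

#' One-call simulation of a full dataset
#'
#' @param config a [sim_config()].
#' @return list with `truth` (ground truth) and `specimens`
#'   (a [specimen_set()]).
#' @export
simulate_morph_dataset <- function(config = sim_config()) {
  truth <- simulate_species_characters(config)
  list(truth = truth, specimens = simulate_individuals(truth, config))
}

#' Cell-level recovery of true codings
#'
#' Fraction of species x character cells whose coded state set equals the
#' true species coding.
#'
#' @param coded a [coded_matrix()] from [code_species()].
#' @param truth the `ground_truth` used to simulate.
#' @return fraction in `[0, 1]`.
#' @export
coding_recovery <- function(coded, truth) {
  true_cells <- truth$true_matrix$cells[match(coded$taxa, truth$true_matrix$taxa), ,
                                        drop = FALSE]
  mean(coded$cells == true_cells)
}
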