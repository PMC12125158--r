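# Species-level coding --------------------------------------------------------
#
# Collapses individual-level scorings into terminal-taxon codings. The primary
# ("MinPoly") strategy suppresses minor polymorphism with a frequency
# threshold and codes ontogeny-controlled characters from the most skeletally
# mature individuals; the secondary ("MaxPoly") strategy retains every state
# observed in the sample.

#' Configuration for species coding
#'
#' @param frequency_threshold fraction of scored individuals a state must
#'   reach to be retained (default 0.20).
#' @param threshold_comparator `"strict_greater"` (default; a state is kept if
#'   its display fraction is strictly above the threshold, i.e. "more than 1
#'   individual out of 5" at 20%) or `"at_least"`.
#' @param maturity_rule `"top_quantile"` (default) or `"top_k"`: how the "most
#'   skeletally mature individuals" are selected for ontogeny-controlled
#'   characters.
#' @param maturity_param the quantile (default 0.10 = top decile) or k.
#' @param min_mature minimum number of mature specimens used (default 3).
#' @param exclude_abnormal drop observations flagged abnormal for the
#'   character being coded (default TRUE).
#' @param inapplicable_to_zero integer vector of character indices whose
#'   inapplicable scores are folded into state 0 before counting (used for
#'   characters where absence of the substrate is itself the primitive state).
#' @param overrides data.frame with columns `species`, `character`, `states`
#'   (a canonical cell string) and optionally `rationale`; applied after all
#'   rules, and logged.
#' @return a list of class `coding_config`.
#' @export
coding_config <- function(frequency_threshold = 0.20,
                          threshold_comparator = c("strict_greater", "at_least"),
                          maturity_rule = c("top_quantile", "top_k"),
                          maturity_param = 0.10,
                          min_mature = 3L,
                          exclude_abnormal = TRUE,
                          inapplicable_to_zero = integer(0),
                          overrides = NULL) {
  stopifnot(frequency_threshold > 0, frequency_threshold < 1,
            maturity_param > 0)
  structure(list(
    frequency_threshold = frequency_threshold,
    threshold_comparator = match.arg(threshold_comparator),
    maturity_rule = match.arg(maturity_rule),
    maturity_param = maturity_param,
    min_mature = as.integer(min_mature),
    exclude_abnormal = exclude_abnormal,
    inapplicable_to_zero = as.integer(inapplicable_to_zero),
    overrides = overrides
  ), class = "coding_config")
}

#' Display frequencies of character states within one species
#'
#' A polymorphic individual "displays" every state in its cell set and counts
#' fully toward each, so fractions can sum to more than 1. Missing,
#' inapplicable and (if configured) abnormal-flagged observations are excluded
#' from the denominator.
#'
#' @param cells character vector of cell strings (one species, one character).
#' @param abnormal logical vector flagging abnormal observations.
#' @param config a [coding_config()].
#' @return a list with `n_scored` and `freq` (data.frame `state`, `count`,
#'   `fraction`).
#' @export
state_frequencies <- function(cells, abnormal = NULL, config = coding_config()) {
  if (is.null(abnormal)) abnormal <- rep(FALSE, length(cells))
  keep <- cell_is_observed(cells)
  if (config$exclude_abnormal) keep <- keep & !abnormal
  sets <- cells_state_list(cells[keep])
  n <- length(sets)
  if (n == 0)
    return(list(n_scored = 0L, freq = data.frame(state = integer(0),
                                                 count = integer(0),
                                                 fraction = numeric(0))))
  tab <- table(unlist(sets))
  freq <- data.frame(state = as.integer(names(tab)),
                     count = as.integer(tab),
                     fraction = as.numeric(tab) / n)
  freq <- freq[order(freq$state), , drop = FALSE]
  rownames(freq) <- NULL
  list(n_scored = n, freq = freq)
}

#' Apply the polymorphism frequency filter
#'
#' States whose display fraction passes the configured comparator against the
#' threshold are retained; if none passes, the single modal state is kept
#' (smallest state label on ties).
#'
#' @param freqs result of [state_frequencies()].
#' @param config a [coding_config()].
#' @return a canonical cell string (`"?"` if nothing was scored).
#' @export
code_frequency_filter <- function(freqs, config = coding_config()) {
  if (freqs$n_scored == 0) return("?")
  f <- freqs$freq
  pass <- if (config$threshold_comparator == "strict_greater")
    f$fraction > config$frequency_threshold
  else f$fraction >= config$frequency_threshold
  if (!any(pass)) {
    modal <- f$state[which.max(f$count)]  # which.max takes the first = smallest
    return(cell_from_states(modal))
  }
  cell_from_states(f$state[pass])
}

# Pick the most skeletally mature scored individuals for one character.
mature_subset <- function(keep_idx, maturities, config) {
  with_mat <- keep_idx[!is.na(maturities[keep_idx])]
  if (length(with_mat) == 0) return(integer(0))
  k <- if (config$maturity_rule == "top_quantile")
    ceiling(config$maturity_param * length(with_mat))
  else as.integer(config$maturity_param)
  k <- min(length(with_mat), max(k, config$min_mature))
  with_mat[order(maturities[with_mat], decreasing = TRUE)[seq_len(k)]]
}

#' Code an ontogeny-controlled character from the most mature individuals
#'
#' Candidate states are the union of the cell sets of the maturity-selected
#' subset (top decile of relative skeletal maturity by default, with a floor
#' of `min_mature` specimens), so juvenile-only states never enter the
#' coding. A candidate is retained when it passes the frequency filter
#' computed over all included individuals of the species (the polymorphism
#' threshold is a statement about individuals of the species; a 3-specimen
#' subset alone cannot support a 20% cut-off) and is corroborated within the
#' subset: displayed either by two or more similarly mature adults, or by the
#' single most skeletally mature individual itself. If no candidate passes
#' (e.g., the adult state is globally rare because sampling is
#' juvenile-heavy), the modal state of the mature subset is kept, so the
#' species still comes out polymorphic when similarly mature adults straddle
#' a measurement threshold frequently enough. Falls back to plain frequency
#' coding over all individuals (flagged in the audit) when no specimen
#' carries maturity data.
#'
#' @param cells cell strings for one species and character.
#' @param maturities relative maturities (percent), aligned with `cells`.
#' @param abnormal logical abnormality flags, aligned with `cells`.
#' @param config a [coding_config()].
#' @return list with `cell` (canonical string), `rule`, `n_used`.
#' @export
code_ontogenetic <- function(cells, maturities, abnormal = NULL,
                             config = coding_config()) {
  if (is.null(abnormal)) abnormal <- rep(FALSE, length(cells))
  keep <- which(cell_is_observed(cells) &
                  (!config$exclude_abnormal | !abnormal))
  sel <- mature_subset(keep, maturities, config)
  if (length(sel) == 0) {
    fr <- state_frequencies(cells, abnormal, config)
    return(list(cell = code_frequency_filter(fr, config),
                rule = "fallback_frequency", n_used = fr$n_scored))
  }
  subset_sets <- cells_state_list(cells[sel])
  candidates <- sort(unique(unlist(subset_sets)))
  # corroboration within the subset: a state counts if several similarly
  # mature adults display it, or if the single most mature individual does
  subset_count <- vapply(candidates, function(s)
    sum(vapply(subset_sets, function(x) s %in% x, logical(1))), 0L)
  top <- which.max(maturities[sel])
  top_states <- subset_sets[[top]]
  corroborated <- subset_count >= 2L | candidates %in% top_states
  fr_all <- state_frequencies(cells, abnormal, config)
  f <- fr_all$freq[match(candidates, fr_all$freq$state), , drop = FALSE]
  pass <- if (config$threshold_comparator == "strict_greater")
    f$fraction > config$frequency_threshold
  else f$fraction >= config$frequency_threshold
  states <- candidates[pass & corroborated]
  if (length(states) == 0) {
    # modal state within the mature subset (smallest label on ties)
    states <- candidates[which.max(subset_count)]
  }
  list(cell = cell_from_states(states), rule = "ontogenetic",
       n_used = length(sel))
}

#' Maximal-polymorphism coding
#'
#' Union of every state observed across the included individuals of a species.
#'
#' @inheritParams code_ontogenetic
#' @return a canonical cell string (`"?"` if nothing observed).
#' @export
code_maxpoly <- function(cells, abnormal = NULL, config = coding_config()) {
  if (is.null(abnormal)) abnormal <- rep(FALSE, length(cells))
  keep <- cell_is_observed(cells)
  if (config$exclude_abnormal) keep <- keep & !abnormal
  states <- unlist(cells_state_list(cells[keep]))
  if (length(states) == 0) return("?")
  cell_from_states(states)
}

#' Discretize a continuous measurement into (possibly polymorphic) states
#'
#' The base state is the index of the bin containing the value; when the value
#' approaches a bin edge within the character's margin, the two states on
#' either side of that edge are both scored (e.g., nuchal-callosity width 53%
#' against edges 30/50/70 and a 3-point margin scores 1/2). Values outside the
#' outer bins clamp to the extreme states.
#'
#' @param value non-negative measurement (same units as the edges).
#' @param bin_edges ascending numeric thresholds.
#' @param margin non-negative half-width of the polymorphic band (`NA` or 0
#'   for hard thresholds).
#' @param min_state label of the lowest bin (default 0).
#' @return a canonical cell string.
#' @export
discretize_measurement <- function(value, bin_edges, margin = NA_real_,
                                   min_state = 0L) {
  if (is.na(value)) return("?")
  if (value < 0) stop("measurements must be non-negative")
  stopifnot(length(bin_edges) >= 1, !is.unsorted(bin_edges, strictly = TRUE))
  base <- findInterval(value, bin_edges)
  if (!is.na(margin) && margin > 0) {
    d <- abs(value - bin_edges)
    k <- which.min(d)
    if (d[k] <= margin)
      return(cell_from_states(c(k - 1L, k) + min_state))
  }
  cell_from_states(base + min_state)
}

#' Discretize using a character's shipped bin definition
#'
#' @param value measurement.
#' @param character_row one row of a [character_defs()] table with `bin_edges`
#'   and `margin` set.
#' @param min_state label of the lowest bin.
#' @return a canonical cell string.
#' @export
discretize_by_character <- function(value, character_row, min_state = 0L) {
  edges <- parse_bin_edges(character_row$bin_edges)
  if (is.null(edges))
    stop("character ", character_row$index, " has no bin edges defined")
  discretize_measurement(value, edges, character_row$margin, min_state)
}

#' Code a full species-level matrix from individual observations
#'
#' Applies, per species and character: abnormality exclusion, optional
#' inapplicable-to-zero folding, the maturity rule for ontogeny-controlled
#' characters, the polymorphism frequency filter (MinPoly) or the observed
#' union (MaxPoly), and declarative per-cell overrides last. An audit log of
#' which rule fired for every cell is attached as attribute `"audit"`.
#'
#' @param specimens a [specimen_set()].
#' @param config a [coding_config()].
#' @param variant `"minpoly"` or `"maxpoly"`.
#' @return a [coded_matrix()] with attribute `"audit"`.
#' @export
code_species <- function(specimens, config = coding_config(),
                         variant = c("minpoly", "maxpoly")) {
  variant <- match.arg(variant)
  chars <- specimens$chars
  taxa <- unique(specimens$meta$species_id)
  out <- matrix("?", length(taxa), nrow(chars),
                dimnames = list(taxa, NULL))
  audit <- list()
  for (ti in seq_along(taxa)) {
    rows <- which(specimens$meta$species_id == taxa[ti])
    mats <- specimens$meta$relative_maturity_pct[rows]
    for (j in seq_len(nrow(chars))) {
      cells <- specimens$cells[rows, j]
      if (chars$index[j] %in% config$inapplicable_to_zero)
        cells[cell_is_inapplicable(cells)] <- "0"
      ab <- specimens$abnormal[rows, j]
      if (variant == "maxpoly") {
        cell <- code_maxpoly(cells, ab, config)
        rule <- "maxpoly"; n_used <- sum(cell_is_observed(cells) &
                                           (!config$exclude_abnormal | !ab))
      } else if (chars$ontogeny_controlled[j]) {
        res <- code_ontogenetic(cells, mats, ab, config)
        cell <- res$cell; rule <- res$rule; n_used <- res$n_used
      } else {
        fr <- state_frequencies(cells, ab, config)
        cell <- code_frequency_filter(fr, config)
        rule <- "frequency"; n_used <- fr$n_scored
      }
      out[ti, j] <- cell
      audit[[length(audit) + 1L]] <- data.frame(
        species = taxa[ti], character = chars$index[j], rule = rule,
        n_used = n_used, cell = cell, stringsAsFactors = FALSE)
    }
  }
  audit <- do.call(rbind, audit)
  if (!is.null(config$overrides) && nrow(config$overrides) > 0) {
    for (k in seq_len(nrow(config$overrides))) {
      ov <- config$overrides[k, ]
      ti <- match(ov$species, taxa)
      j <- match(ov$character, chars$index)
      if (is.na(ti) || is.na(j))
        stop("override references unknown species/character: ",
             ov$species, "/", ov$character)
      out[ti, j] <- ov$states
      hit <- audit$species == ov$species & audit$character == ov$character
      audit$rule[hit] <- "override"
      audit$cell[hit] <- ov$states
    }
  }
  cm <- coded_matrix(taxa, chars, out, variant)
  attr(cm, "audit") <- audit
  cm
}

#' Derive the fontanelle-formation and -closure characters from the helper
#' observation column
#'
#' One matrix column records, per individual, the state of the posterior
#' contacts of the nuchal callosity (0 = no contact, 1 = posteromedian
#' contact with laterally open fontanelles, 2 = contacts complete and
#' fontanelles closed, 3 = broad contact with paired circular fontanelles,
#' 4 = posterolateral contacts with medially confluent fontanelles). Two
#' species-level characters are extracted from the full sample: the formation
#' pathway (mode of the first-contact observations: posteromedian vs
#' posterolateral) and the closure timing (minimum relative maturity among
#' closed specimens, banded at 30/70% of adult size; species whose adults
#' never close score the "never/rarely closes" state, printed label 4).
#'
#' @param specimens a [specimen_set()] with maturities populated.
#' @param helper_index index of the helper observation column.
#' @param pathway_index,closure_index indices of the two derived characters.
#' @param closure_bands maturity band edges, percent (default `c(30, 70)`).
#' @return an overrides data.frame suitable for [coding_config()].
#' @export
derive_fontanelle_characters <- function(specimens, helper_index = 70L,
                                         pathway_index = 16L,
                                         closure_index = 17L,
                                         closure_bands = c(30, 70)) {
  j <- match(helper_index, specimens$chars$index)
  if (is.na(j)) stop("helper column ", helper_index, " not in matrix")
  taxa <- unique(specimens$meta$species_id)
  rows_out <- list()
  for (sp in taxa) {
    rows <- which(specimens$meta$species_id == sp)
    obs <- cells_state_list(specimens$cells[rows, j])
    mat <- specimens$meta$relative_maturity_pct[rows]
    flat <- unlist(obs)
    # pathway: first-contact mode among pathway-diagnostic observations
    n1 <- sum(flat == 1); n4 <- sum(flat == 4)
    pathway <- if (n1 == 0 && n4 == 0) {
      if (length(flat) > 0 && all(flat == 0)) "0" else "?"
    } else if (n1 > n4) "1" else if (n4 > n1) "2" else "1/2"
    # closure: minimum maturity among closed-fontanelle specimens
    closed <- vapply(obs, function(s) !is.null(s) && 2 %in% s, logical(1))
    open_adult <- vapply(obs, function(s) !is.null(s) && !(2 %in% s), logical(1)) &
      !is.na(mat) & mat > closure_bands[2]
    closure <- if (any(closed & !is.na(mat))) {
      m <- min(mat[closed & !is.na(mat)])
      if (m < closure_bands[1]) "0"
      else if (m <= closure_bands[2]) "1"
      else "2"
    } else if (any(open_adult)) "4" else "?"
    rows_out[[length(rows_out) + 1L]] <- data.frame(
      species = sp,
      character = c(pathway_index, closure_index),
      states = c(pathway, closure),
      rationale = "derived from fontanelle helper column",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows_out)
}
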