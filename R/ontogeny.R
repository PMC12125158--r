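# Ontogenetic screening --------------------------------------------------------
#
# Character expression in growing animals confounds species-level coding:
# a juvenile may genuinely lack a structure that every adult of its species
# possesses. The screen quantifies this with the Spearman rank-order
# correlation (SCC) between individual character scores and relative skeletal
# maturity, computed as average ranks followed by a Pearson correlation of the
# rank vectors (the tie-corrected Spearman; equivalently the spreadsheet
# RANK.AVG + CORREL recipe).

#' Relative skeletal maturity of a specimen
#'
#' Straight carapace length as a percentage of the largest documented straight
#' carapace length of the species -- a proxy for skeletal maturity. Specimens
#' whose size is only known as a range should be passed as the midpoint of the
#' estimate. Lengths exceeding the species maximum are clipped to 100% with a
#' warning.
#'
#' @param carapace_length_cm specimen length(s), cm.
#' @param species_max_cm largest documented length of the species, cm.
#' @return maturity in percent (`[0, 100]`); `NA` where either input is `NA`.
#' @examples
#' relative_maturity(23.75, 47.5)  # 50
#' @export
relative_maturity <- function(carapace_length_cm, species_max_cm) {
  stopifnot(all(is.na(carapace_length_cm) | carapace_length_cm > 0),
            all(is.na(species_max_cm) | species_max_cm > 0))
  pct <- 100 * carapace_length_cm / species_max_cm
  if (any(pct > 100, na.rm = TRUE)) {
    warning("specimen length exceeds the species maximum; clipping to 100%")
    pct <- pmin(pct, 100)
  }
  pct
}

#' Spearman rank correlation with average ranks
#'
#' Both vectors are ranked with ties receiving their average rank, and the
#' Pearson correlation of the two rank vectors is returned together with the
#' band classification of [classify_scc()]. Pairs with a missing side are
#' dropped; polymorphic cell scores should be scalarized with [cell_scalar()]
#' (mean of states) before calling.
#'
#' @param scores numeric character scores (or canonical cell strings, which
#'   are scalarized automatically).
#' @param maturities relative maturities, percent.
#' @param character_index,scope optional identifiers carried into the result.
#' @return a list of class `ontogeny_result` with elements `scc`, `n_pairs`,
#'   `classification`, `sign`, `character_index`, `scope`.
#' @export
scc <- function(scores, maturities, character_index = NA_integer_,
                scope = "all") {
  if (is.character(scores)) scores <- cell_scalar(scores)
  stopifnot(length(scores) == length(maturities))
  ok <- !is.na(scores) & !is.na(maturities)
  x <- scores[ok]; y <- maturities[ok]
  n <- length(x)
  if (n < 2 || length(unique(x)) < 2 || length(unique(y)) < 2) {
    val <- NA_real_
  } else {
    rx <- rank(x, ties.method = "average")
    ry <- rank(y, ties.method = "average")
    val <- stats::cor(rx, ry)
  }
  structure(list(
    character_index = character_index, scope = scope,
    scc = val, n_pairs = n,
    classification = classify_scc(val),
    sign = if (is.na(val) || val == 0) "none" else if (val > 0) "positive" else "negative"
  ), class = "ontogeny_result")
}

#' Classify an SCC value into correlation bands
#'
#' Magnitude bands: absent `[0, 0.25)`, weak `[0.25, 0.5)`, moderate
#' `[0.5, 0.75)`, strong `[0.75, 1]`. Boundary values fall into the upper
#' band; the sign is reported separately by [scc()].
#'
#' @param scc_value a correlation in `[-1, 1]` (or `NA`).
#' @return one of `"absent"`, `"weak"`, `"moderate"`, `"strong"`.
#' @export
classify_scc <- function(scc_value) {
  if (is.na(scc_value)) return("absent")
  a <- abs(scc_value)
  stopifnot(a <= 1 + 1e-12)
  if (a < 0.25) "absent" else if (a < 0.5) "weak" else if (a < 0.75) "moderate" else "strong"
}

#' Ontogenetic screen over a specimen set
#'
#' Computes the SCC of every requested character against relative maturity,
#' over configurable taxon scopes (all species pooled, or per species).
#'
#' @param specimens a [specimen_set()] with `relative_maturity_pct` populated.
#' @param characters character indices to screen (default: all active).
#' @param scopes named list of species-id vectors defining the specimen pools;
#'   default one pool `"all"` with every species.
#' @return a data.frame with one row per (character, scope): `character_index`,
#'   `scope`, `n_pairs`, `scc`, `classification`, `sign`.
#' @export
ontogeny_screen <- function(specimens, characters = NULL, scopes = NULL) {
  chars <- specimens$chars
  if (is.null(characters)) characters <- chars$index[chars$active]
  if (is.null(scopes)) scopes <- list(all = unique(specimens$meta$species_id))
  rows <- list()
  for (sc_name in names(scopes)) {
    in_scope <- specimens$meta$species_id %in% scopes[[sc_name]]
    mat <- specimens$meta$relative_maturity_pct[in_scope]
    for (ci in characters) {
      j <- match(ci, chars$index)
      res <- scc(specimens$cells[in_scope, j], mat,
                 character_index = ci, scope = sc_name)
      rows[[length(rows) + 1L]] <- data.frame(
        character_index = ci, scope = sc_name, n_pairs = res$n_pairs,
        scc = res$scc, classification = res$classification,
        sign = res$sign, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
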