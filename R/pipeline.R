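# Pipeline orchestration -------------------------------------------------------

#' Run a grid of parsimony settings and score each against a reference
#'
#' For every combination of matrix variant and search setting: run the
#' heuristic search, optionally root the optima so a named clade is
#' monophyletic, prune outgroup taxa, and compare the optimal trees with the
#' reference topology using quartets. One row per (variant, setting) is
#' returned, mirroring a settings-comparison table: number of optimal trees,
#' equal-weights tree length, best score, mean shared / conflicting quartet
#' counts and mean sja (percent).
#'
#' @param matrices named list of [coded_matrix()] objects (e.g.
#'   `list(minpoly = ..., maxpoly = ...)`).
#' @param settings list of [search_config()] objects; names label the rows.
#' @param reference reference `phylo` topology (on the ingroup taxa).
#' @param outgroup taxa pruned from the optima before comparison (they may be
#'   absent from the reference).
#' @param root_clade optional taxon set: optima are rooted to make it
#'   monophyletic (rooting does not affect quartet scores; it is reported for
#'   inspection via the returned tree sets).
#' @return a data.frame with one row per (variant, setting) and attribute
#'   `"searches"` holding the full search results.
#' @export
run_settings_grid <- function(matrices, settings, reference,
                              outgroup = character(0),
                              root_clade = NULL) {
  if (is.null(names(matrices)))
    names(matrices) <- paste0("matrix", seq_along(matrices))
  if (is.null(names(settings)))
    names(settings) <- paste0("setting", seq_along(settings))
  rows <- list(); searches <- list()
  for (vn in names(matrices)) {
    for (sn in names(settings)) {
      cfg <- settings[[sn]]
      res <- heuristic_search(matrices[[vn]], cfg)
      trees <- res$mpt_set
      if (length(outgroup) > 0)
        trees <- lapply(trees, function(t)
          ape::drop.tip(t, intersect(outgroup, t$tip.label)))
      if (!is.null(root_clade))
        trees_rooted <- lapply(trees, root_by_clade,
                               ingroup_taxa = intersect(root_clade,
                                                        trees[[1]]$tip.label))
      cmp <- average_over_mpts(trees, reference)
      key <- paste(vn, sn, sep = ".")
      searches[[key]] <- res
      rows[[key]] <- data.frame(
        variant = vn, setting = sn,
        K = if (is.null(cfg$K)) NA_real_ else cfg$K,
        swap = cfg$swap,
        n_trees = res$n_trees,
        tree_length = res$tree_length[1],
        best_score = res$best_score,
        Q = cmp$Q, mean_s = cmp$mean_s, mean_d = cmp$mean_d,
        mean_sja_pct = cmp$mean_sja_pct,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, unname(rows))
  rownames(out) <- NULL
  attr(out, "searches") <- searches
  out
}

#' The transcribed molecular consensus of extant softshell turtles
#'
#' A 29-taxon reference topology for the extant trionychid species sampled in
#' shell-morphology work (Pelodiscus lumped as one terminal). This fixture is
#' a transcription assembled from published molecular hypotheses (the
#' Engstrom/Thomson backbone, with Lissemys and Nilssonia resolved after Le
#' and colleagues and Pelochelys signifera placed as sister of P. bibroni);
#' it is shipped as a synthetic stand-in for comparative exercises, not as an
#' authoritative copy of any single published figure.
#'
#' @return a `phylo` with 29 tips.
#' @export
molecular_consensus_tree <- function() {
  path <- system.file("extdata", "molecular_consensus_synthetic.nwk",
                      package = "shellphylo", mustWork = TRUE)
  ape::read.tree(path)
}
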