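# Parsimony engine -------------------------------------------------------------
#
# Scoring of set-valued (polymorphic / missing) terminals under equal-weights
# and implied-weights parsimony. Polymorphic tips use uncertainty semantics:
# the tip may be assigned any member of its state set (the treatment TNT
# applies to bracketed states). Missing and inapplicable tips are scored as
# the full state set. Unordered characters are scored with set-valued Fitch
# (binary trees), ordered morphoclines with a Sankoff dynamic programme under
# linear |i-j| costs; both cores are compiled.

# Internal column representation of a coded matrix for fast scoring.
prepare_columns <- function(matrix_, ordered_set = NULL) {
  chars <- matrix_$chars
  keep <- which(chars$active)
  taxa <- sort(matrix_$taxa)
  cells <- matrix_$cells[match(taxa, matrix_$taxa), keep, drop = FALSE]
  nstates <- chars$n_states[keep]
  ordered <- if (is.null(ordered_set)) chars$ordered[keep]
             else chars$index[keep] %in% ordered_set
  tipsets <- matrix(0L, length(taxa), length(keep))
  for (j in seq_along(keep))
    tipsets[, j] <- vapply(cells[, j], cell_bitmask, 0L,
                           n_states = nstates[j])
  list(taxa = taxa, tipsets = tipsets, nstates = as.integer(nstates),
       ordered = ordered, char_index = chars$index[keep],
       cells = cells)
}

postorder_edge <- function(tree) stats::reorder(tree, "postorder")$edge

# Batch per-character steps for a list of trees sharing the same taxon set.
# Trees whose tip order differs are permuted into the reference order.
steps_for_trees <- function(trees, cols) {
  ntip <- length(cols$taxa)
  sig <- vapply(trees, function(t) paste(t$tip.label, collapse = "\r"), "")
  out <- matrix(0L, length(trees), ncol(cols$tipsets))
  for (s in unique(sig)) {
    idx <- which(sig == s)
    labs <- trees[[idx[1]]]$tip.label
    perm <- match(labs, cols$taxa)
    if (anyNA(perm)) stop("tree and matrix taxa differ")
    tips <- cols$tipsets[perm, , drop = FALSE]
    edges <- lapply(trees[idx], postorder_edge)
    out[idx, ] <- .steps_many_cpp(edges, ntip, tips, cols$nstates,
                                  cols$ordered)
  }
  out
}

#' Fitch length of an unordered character on a binary tree
#'
#' Set-valued Fitch postorder pass (intersection where possible, else union
#' with one step). Missing and inapplicable tips count as the full state set;
#' polymorphic tips as their state set.
#'
#' @param tree a binary `phylo` whose tip labels name the column entries.
#' @param column named character vector of canonical cell strings (names =
#'   taxa).
#' @param n_states size of the state space (default: max observed + 1).
#' @return integer number of steps.
#' @export
fitch_length <- function(tree, column, n_states = NULL) {
  check_binary(tree)
  tipsets <- column_tipsets(tree, column, n_states)
  edge <- postorder_edge(tree)
  .fitch_steps_cpp(edge, length(tree$tip.label), tipsets$mask)[1]
}

#' Sankoff length of an ordered character under linear costs
#'
#' Dynamic-programming minimum total cost with `cost(i, j) = |i - j|`; exact
#' on multifurcating trees as well.
#'
#' @inheritParams fitch_length
#' @param ordered score with linear morphocline costs (default TRUE); with
#'   `FALSE` a unit-cost matrix is used.
#' @return integer minimum cost.
#' @export
sankoff_length <- function(tree, column, n_states = NULL, ordered = TRUE) {
  tipsets <- column_tipsets(tree, column, n_states)
  edge <- postorder_edge(tree)
  .sankoff_steps_cpp(edge, length(tree$tip.label), tipsets$mask,
                     tipsets$n_states, ordered)[1]
}

check_binary <- function(tree) {
  if (!ape::is.binary(ape::unroot(tree)))
    stop("a binary tree is required (use sankoff_length for polytomies)")
}

column_tipsets <- function(tree, column, n_states = NULL) {
  labs <- tree$tip.label
  if (is.null(names(column))) {
    if (length(column) != length(labs))
      stop("unnamed column must match the number of tips")
    names(column) <- labs
  }
  if (!all(labs %in% names(column)))
    stop("leaf absent from column: ",
         paste(setdiff(labs, names(column)), collapse = ", "))
  column <- column[labs]
  if (is.null(n_states)) {
    mx <- suppressWarnings(max(c(-1L, unlist(cells_state_list(column)))))
    n_states <- max(2L, mx + 1L)
  }
  mask <- matrix(vapply(column, cell_bitmask, 0L, n_states = n_states),
                 ncol = 1)
  list(mask = mask, n_states = as.integer(n_states))
}

#' Minimum conceivable steps of a character over any tree
#'
#' For unordered characters this is the size of a minimum hitting set of the
#' tips' state sets minus one (computed exactly; state spaces here are small);
#' for ordered characters it is the span between the largest lower bound and
#' the smallest upper bound of the tip sets. Used as the homoplasy baseline
#' `h = s - m` of implied weighting.
#'
#' @param column character vector of canonical cell strings.
#' @param n_states state-space size.
#' @param ordered is the character an ordered morphocline?
#' @return integer minimum steps.
#' @export
min_steps <- function(column, n_states, ordered = FALSE) {
  sets <- cells_state_list(column[cell_is_observed(column)])
  if (length(sets) == 0) return(0L)
  if (ordered) {
    lo <- max(vapply(sets, min, 0))
    hi <- min(vapply(sets, max, 0))
    return(max(0L, as.integer(lo - hi)))
  }
  masks <- unique(vapply(sets, function(s) sum(bitwShiftL(1L, s)), 0L))
  for (k in seq_len(n_states)) {
    for (comb in utils::combn(n_states, k, simplify = FALSE)) {
      hit <- sum(bitwShiftL(1L, comb - 1L))
      if (all(bitwAnd(masks, hit) != 0L)) return(k - 1L)
    }
  }
  n_states - 1L
}

#' Score a tree against a coded matrix
#'
#' Sums per-character parsimony steps (Fitch for unordered characters,
#' Sankoff with linear costs for ordered morphoclines) over the active
#' characters, and, when a concavity constant is supplied, the implied-weights
#' cost `sum h / (h + K)` with `h = s - m` the extra steps of each character.
#'
#' @param tree a binary `phylo` on the matrix taxa.
#' @param matrix_ a [coded_matrix()].
#' @param K implied-weighting concavity (`NULL` = equal weights only).
#' @param ordered_set optional character indices to order (default: the
#'   matrix metadata's `ordered` flags).
#' @return list with `steps`, `implied_cost` (NA without `K`), and `fit`
#'   (per-character data.frame: `character`, `s`, `m`, `h`, `fit_cost`).
#' @export
tree_score <- function(tree, matrix_, K = NULL, ordered_set = NULL) {
  cols <- prepare_columns(matrix_, ordered_set)
  if (!setequal(tree$tip.label, cols$taxa))
    stop("tree and matrix taxa differ")
  s <- as.integer(steps_for_trees(list(tree), cols))
  m <- vapply(seq_along(s), function(j)
    min_steps(cols$cells[, j], cols$nstates[j], cols$ordered[j]), 0L)
  h <- s - m
  fit_cost <- if (is.null(K)) rep(NA_real_, length(h)) else h / (h + K)
  list(steps = sum(s),
       implied_cost = if (is.null(K)) NA_real_ else sum(fit_cost),
       fit = data.frame(character = cols$char_index, s = s, m = m, h = h,
                        fit_cost = fit_cost))
}

#' Score many trees at once
#'
#' Batched equivalent of [tree_score()] for scoring whole tree sets (e.g., an
#' exhaustive enumeration): the matrix is prepared once and all trees are
#' scored in compiled code.
#'
#' @param trees list (or `multiPhylo`) of binary trees on the matrix taxa.
#' @param matrix_ a [coded_matrix()].
#' @param K implied-weighting concavity (`NULL` = equal-weights steps).
#' @param ordered_set optional ordered character indices.
#' @return numeric vector: total steps (or implied cost when `K` is given)
#'   per tree.
#' @export
score_trees <- function(trees, matrix_, K = NULL, ordered_set = NULL) {
  trees <- lapply(seq_along(trees), function(i) trees[[i]])
  cols <- prepare_columns(matrix_, ordered_set)
  steps <- steps_for_trees(trees, cols)
  if (is.null(K)) return(rowSums(steps))
  m <- vapply(seq_along(cols$nstates), function(j)
    min_steps(cols$cells[, j], cols$nstates[j], cols$ordered[j]), 0L)
  score_vec(steps, m, K)
}

#' Search configuration
#'
#' Defaults are sized for the matrices this package targets; the study-scale
#' settings used for full empirical matrices (1000 random-addition replicates,
#' a 40,000-tree buffer, TBR) are reached by raising `n_ras` and
#' `tree_buffer`.
#'
#' @param n_ras number of random-addition-sequence replicates.
#' @param swap branch-swapping neighborhood: `"tbr"` (default; includes all
#'   SPR and NNI moves), `"spr"` (served by the TBR neighborhood) or `"nni"`.
#' @param tree_buffer maximum number of optimal trees retained.
#' @param K implied-weighting concavity; `NULL` = equal weights.
#' @param ordered_set character indices scored as ordered morphoclines
#'   (default `NULL`: use the matrix metadata).
#' @param rng_seed integer seed making the search bit-reproducible.
#' @param collapse_rule `"min_length_zero"` (collapse branches whose minimum
#'   optimal length is zero before counting trees) or `"none"`.
#' @return list of class `search_config`.
#' @export
search_config <- function(n_ras = 10L, swap = c("tbr", "spr", "nni"),
                          tree_buffer = 1000L, K = NULL, ordered_set = NULL,
                          rng_seed = NULL,
                          collapse_rule = c("min_length_zero", "none")) {
  swap <- match.arg(swap)
  stopifnot(n_ras >= 1, tree_buffer >= 1, is.null(K) || K > 0)
  structure(list(n_ras = as.integer(n_ras), swap = swap,
                 tree_buffer = as.integer(tree_buffer), K = K,
                 ordered_set = ordered_set, rng_seed = rng_seed,
                 collapse_rule = match.arg(collapse_rule)),
            class = "search_config")
}

neighbors_of <- function(tree, swap) {
  if (swap == "nni") nni_neighbors(tree) else tbr_neighbors(tree)
}

score_vec <- function(steps_mat, m, K) {
  if (is.null(K)) rowSums(steps_mat)
  else {
    h <- sweep(steps_mat, 2, m)
    rowSums(h / (h + K))
  }
}

#' Heuristic parsimony search
#'
#' Random-addition-sequence tree building followed by branch swapping to a
#' local optimum, repeated `n_ras` times; all distinct optimal trees are
#' retained (up to the tree buffer), then the optimum's neighborhood is
#' expanded to closure so that equal-score trees reachable by swapping are
#' collected. Under implied weighting the search optimizes `sum h/(h+K)`
#' directly and reports the equal-weights length of the optima alongside.
#'
#' @param matrix_ a [coded_matrix()] (at least 4 taxa).
#' @param config a [search_config()].
#' @return list of class `search_result`: `mpt_set` (list of `phylo`,
#'   collapsed per the collapse rule), `best_score`, `tree_length` (steps of
#'   the optima; vector if they differ under implied weights), `n_trees`.
#' @export
heuristic_search <- function(matrix_, config = search_config()) {
  if (length(matrix_$taxa) < 4) stop("need at least 4 taxa")
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  cols <- prepare_columns(matrix_, config$ordered_set)
  m <- vapply(seq_along(cols$nstates), function(j)
    min_steps(cols$cells[, j], cols$nstates[j], cols$ordered[j]), 0L)
  K <- config$K
  eps <- 1e-9

  best_score <- Inf
  pool <- new.env(parent = emptyenv())
  pool_add <- function(tree) {
    key <- topology_key(tree)
    if (is.null(pool[[key]]) &&
        length(ls(pool)) < config$tree_buffer) pool[[key]] <- tree
  }
  score_of <- function(trees) score_vec(steps_for_trees(trees, cols), m, K)

  for (rep in seq_len(config$n_ras)) {
    order_ <- sample(cols$taxa)
    # stepwise addition on the graph
    g <- list(edges = rbind(c(4, 1), c(4, 2), c(4, 3)),
              labels = stats::setNames(order_[1:3], 1:3))
    g$labels <- g$labels
    for (t in order_[-(1:3)]) {
      cands <- lapply(seq_len(nrow(g$edges)), function(e) {
        sd <- graph_subdivide(g, e)
        graph_add_leaf(sd$graph, sd$mid, t)
      })
      trees <- lapply(cands, graph_to_phylo)
      # score on the partial taxon set
      pcols <- cols
      perm <- match(sort(order_[1:match(t, order_)]), cols$taxa)
      pcols$taxa <- cols$taxa[perm]
      pcols$tipsets <- cols$tipsets[perm, , drop = FALSE]
      sc <- score_vec(steps_for_trees(trees, pcols), m, K)
      pick <- which(sc <= min(sc) + eps)
      g <- cands[[pick[sample.int(length(pick), 1)]]]
    }
    tree <- graph_to_phylo(g)
    cur <- score_of(list(tree))
    # swap to local optimum
    repeat {
      nb <- neighbors_of(tree, config$swap)
      sc <- score_of(nb)
      if (min(sc) < cur - eps) {
        pick <- which(sc <= min(sc) + eps)
        tree <- nb[[pick[sample.int(length(pick), 1)]]]
        cur <- min(sc)
      } else break
    }
    if (cur < best_score - eps) {
      best_score <- cur
      rm(list = ls(pool), envir = pool)
    }
    if (cur <= best_score + eps) pool_add(tree)
  }

  # closure: collect equal-score trees reachable from the optima
  frontier <- as.list(pool)
  while (length(frontier) > 0 && length(ls(pool)) < config$tree_buffer) {
    tree <- frontier[[1]]; frontier <- frontier[-1]
    nb <- neighbors_of(tree, config$swap)
    sc <- score_of(nb)
    for (i in which(sc <= best_score + eps)) {
      key <- topology_key(nb[[i]])
      if (is.null(pool[[key]])) {
        if (length(ls(pool)) >= config$tree_buffer) {
          warning("tree buffer full; optimal-tree set truncated")
          break
        }
        pool[[key]] <- nb[[i]]
        frontier[[length(frontier) + 1L]] <- nb[[i]]
      }
    }
  }

  mpts <- unname(as.list(pool))
  lengths_ <- rowSums(steps_for_trees(mpts, cols))
  if (config$collapse_rule == "min_length_zero") {
    mpts <- lapply(mpts, collapse_zero_edges, cols = cols)
    keys <- vapply(mpts, topology_key, "")
    keep <- !duplicated(keys)
    mpts <- mpts[keep]
    lengths_ <- lengths_[keep]
  }
  structure(list(mpt_set = mpts, best_score = best_score,
                 tree_length = if (length(unique(lengths_)) == 1)
                   lengths_[1] else lengths_,
                 n_trees = length(mpts)),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("search_result:", x$n_trees, "optimal tree(s), best score",
      format(x$best_score), "- tree length", x$tree_length[1], "\n")
  invisible(x)
}

# Collapse internal branches whose minimum optimal length is zero (contracting
# the branch does not change the tree's parsimony score). Scores use the
# Sankoff programme throughout since contraction creates polytomies.
collapse_zero_edges <- function(tree, cols) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  perm <- match(tree$tip.label, cols$taxa)
  tips <- cols$tipsets[perm, , drop = FALSE]
  dp_steps <- function(tr) sum(.sankoff_steps_cpp(postorder_edge(tr), ntip,
                                                  tips, cols$nstates,
                                                  cols$ordered))
  base <- dp_steps(tree)
  internal <- which(tree$edge[, 2] > ntip)
  zero <- internal[vapply(internal, function(e)
    dp_steps(contract_edges(tree, e)) == base, logical(1))]
  if (length(zero) == 0) return(tree)
  contract_edges(tree, zero)
}

#' Root an unrooted tree so that a clade is monophyletic
#'
#' If some edge of the tree bipartitions exactly `ingroup_taxa` against the
#' rest, the tree is rooted on that edge; otherwise an error lists the
#' conflict.
#'
#' @param tree an unrooted `phylo`.
#' @param ingroup_taxa nonempty proper subset of the tip labels.
#' @return a rooted `phylo` with the ingroup monophyletic.
#' @export
root_by_clade <- function(tree, ingroup_taxa) {
  taxa <- tree$tip.label
  stopifnot(length(ingroup_taxa) >= 1,
            all(ingroup_taxa %in% taxa),
            length(ingroup_taxa) < length(taxa))
  rest <- setdiff(taxa, ingroup_taxa)
  want <- taxa[1] %in% ingroup_taxa
  side <- sort(if (want) rest else ingroup_taxa)
  if (length(ingroup_taxa) > 1 && length(rest) > 1) {
    sp <- tree_splits(tree, sort(taxa))
    ok <- any(apply(sp, 1, function(r) identical(sort(colnames(sp)[r]), side)))
    if (!ok)
      stop("clade not recoverable: no edge separates {",
           paste(sort(ingroup_taxa), collapse = ", "), "} from the rest")
  }
  ape::root(tree, outgroup = rest, resolve.root = TRUE)
}

#' Characters with zero changes on every optimal tree
#'
#' The "list changes" diagnostic: characters whose steps are 0 on every tree
#' of the optimal set are parsimony-uninformative in that analysis.
#'
#' @param mpt_set list of `phylo` trees.
#' @param matrix_ the scored [coded_matrix()].
#' @param ordered_set optional ordered character indices.
#' @return integer vector of character indices.
#' @export
zero_change_characters <- function(mpt_set, matrix_, ordered_set = NULL) {
  stopifnot(length(mpt_set) > 0)
  cols <- prepare_columns(matrix_, ordered_set)
  steps <- vapply(mpt_set, function(tr) {
    perm <- match(tr$tip.label, cols$taxa)
    .sankoff_steps_cpp(postorder_edge(ape::unroot(tr)),
                       length(tr$tip.label),
                       cols$tipsets[perm, , drop = FALSE],
                       cols$nstates, cols$ordered)
  }, integer(ncol(cols$tipsets)))
  cols$char_index[rowSums(matrix(steps, ncol = length(mpt_set))) == 0]
}

#' Strict consensus of a tree set
#'
#' Retains exactly the bipartitions present in every input tree (delegates to
#' [ape::consensus()]).
#'
#' @param trees list of `phylo` on identical leaf sets.
#' @return a (possibly multifurcating) `phylo`.
#' @export
strict_consensus <- function(trees) {
  stopifnot(length(trees) >= 1)
  labs <- sort(trees[[1]]$tip.label)
  for (t in trees)
    if (!identical(sort(t$tip.label), labs)) stop("leaf sets differ")
  if (length(trees) == 1) return(trees[[1]])
  cls <- c("multiPhylo", "list")
  tl <- trees; class(tl) <- "multiPhylo"
  ape::consensus(tl, p = 1, rooted = FALSE)
}
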