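# Quartet comparison -----------------------------------------------------------
#
# Two trees on the same leaves are compared quartet by quartet. Each 4-taxon
# subset induces, in each tree, one of three resolved topologies or a star;
# the pair of inductions assigns the quartet to one of the five categories of
# Estabrook, McMorris & Meacham: s (same resolution), d (resolved in both but
# differently), r1/r2 (resolved in only one tree), u (unresolved in both).
# Strict Joint Assertions sja = s / (s + d) is the share of jointly resolved
# quartets that agree. Quartets are unrooted objects, so rooting is ignored.
#
# Resolution is computed from the trees' splits: quartet ab|cd is resolved in
# a tree iff some split has a,b on one side and c,d on the other. Splits are
# packed into integer bitmask chunks so that all C(n,4) quartets are
# classified with vectorized bit arithmetic; at the scales targeted here
# (n <= ~40, Q(29) = 23,751) direct enumeration is instant and doubles as its
# own oracle.

# per-pair split masks: for each ordered taxon pair, the set of splits on
# which the pair is together / on which the two taxa lie on opposite sides
split_masks <- function(tree, taxa) {
  sp <- tree_splits(tree, taxa)  # k x n logical
  k <- nrow(sp); n <- length(taxa)
  chunks <- if (k == 0) list() else split(seq_len(k), (seq_len(k) - 1) %/% 31)
  side <- lapply(chunks, function(rows) {
    # bitmask per taxon over <=31 splits
    vapply(seq_len(n), function(i)
      sum(bitwShiftL(1L, seq_along(rows) - 1L)[sp[rows, i]]), 0L)
  })
  full <- lapply(chunks, function(rows)
    sum(bitwShiftL(1L, seq_along(rows) - 1L)))
  list(side = side, full = full, n = n)
}

# resolution code (0 = star, 1..3 = pairing) for every quartet; `quartets` is
# a 4 x Q matrix of taxon indices
quartet_codes <- function(masks, quartets) {
  Q <- ncol(quartets)
  code <- integer(Q)
  pairings <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  for (ci in seq_along(masks$side)) {
    side <- masks$side[[ci]]; full <- masks$full[[ci]]
    for (p in 1:3) {
      pr <- pairings[[p]]
      a <- side[quartets[pr[1], ]]; b <- side[quartets[pr[2], ]]
      cc <- side[quartets[pr[3], ]]; dd <- side[quartets[pr[4], ]]
      same_ab <- bitwAnd(bitwXor(bitwXor(a, b), full), full)  # ~xor within chunk
      same_cd <- bitwAnd(bitwXor(bitwXor(cc, dd), full), full)
      diff_ac <- bitwXor(a, cc)
      hit <- bitwAnd(bitwAnd(same_ab, same_cd), diff_ac) != 0L
      code[hit] <- p  # at most one pairing can ever hit (splits compatible)
    }
  }
  code
}

#' Estabrook category of a single quartet
#'
#' @param tree1,tree2 `phylo` trees containing all four leaves.
#' @param quartet character vector of four taxon labels.
#' @return one of `"s"`, `"d"`, `"r1"`, `"r2"`, `"u"`.
#' @export
quartet_status <- function(tree1, tree2, quartet) {
  stopifnot(length(quartet) == 4)
  for (t in list(tree1, tree2))
    if (!all(quartet %in% t$tip.label)) stop("leaf missing from a tree")
  taxa <- sort(unique(c(tree1$tip.label, tree2$tip.label)))
  q <- matrix(match(quartet, taxa), 4, 1)
  c1 <- quartet_codes(split_masks(tree1, taxa), q)
  c2 <- quartet_codes(split_masks(tree2, taxa), q)
  if (c1 == 0 && c2 == 0) "u"
  else if (c1 == 0) "r2"
  else if (c2 == 0) "r1"
  else if (c1 == c2) "s" else "d"
}

#' Quartet comparison of two trees
#'
#' Enumerates all `C(n, 4)` quartets and tallies the Estabrook categories;
#' `sja = s / (s + d)` is reported when at least one quartet is resolved in
#' both trees (and `NA`, flagged, otherwise).
#'
#' @param tree1,tree2 `phylo` trees on identical leaf sets (prune outgroups
#'   first if needed).
#' @return list of class `quartet_summary`: `Q`, `s`, `d`, `r1`, `r2`, `u`,
#'   `sja`.
#' @export
compare_quartets <- function(tree1, tree2) {
  taxa <- sort(tree1$tip.label)
  if (!identical(sort(tree2$tip.label), taxa))
    stop("leaf sets differ: ",
         paste(c(setdiff(taxa, tree2$tip.label),
                 setdiff(tree2$tip.label, taxa)), collapse = ", "))
  n <- length(taxa)
  stopifnot(n >= 4)
  quartets <- utils::combn(n, 4)
  c1 <- quartet_codes(split_masks(tree1, taxa), quartets)
  c2 <- quartet_codes(split_masks(tree2, taxa), quartets)
  s <- sum(c1 != 0 & c1 == c2)
  d <- sum(c1 != 0 & c2 != 0 & c1 != c2)
  r1 <- sum(c1 != 0 & c2 == 0)
  r2 <- sum(c1 == 0 & c2 != 0)
  u <- sum(c1 == 0 & c2 == 0)
  structure(list(Q = ncol(quartets), s = s, d = d, r1 = r1, r2 = r2, u = u,
                 sja = if (s + d > 0) s / (s + d) else NA_real_),
            class = "quartet_summary")
}

#' @export
print.quartet_summary <- function(x, ...) {
  cat("quartets: Q =", x$Q, " s =", x$s, " d =", x$d, " r1 =", x$r1,
      " r2 =", x$r2, " u =", x$u, " sja =",
      if (is.na(x$sja)) "undefined" else format(x$sja), "\n")
  invisible(x)
}

#' Number of possible quartets for n taxa
#'
#' `Q(n) = n(n-1)(n-2)(n-3)/24`; e.g. `Q(29) = 23751`.
#'
#' @param n number of terminal taxa.
#' @return integer count.
#' @export
n_quartets <- function(n) choose(n, 4)

#' Average quartet accuracy of a tree set against a reference
#'
#' Every tree of an optimal set is compared with the reference topology and
#' arithmetic means are reported; the mean sja is the mean of per-tree ratios,
#' in percent.
#'
#' @param mpt_set nonempty list of `phylo` trees.
#' @param reference the reference `phylo` (e.g., a molecular consensus).
#' @return list of class `comparison_report`: `per_tree` (list of
#'   [compare_quartets()] summaries), `Q`, `mean_s`, `mean_d`, `mean_sja_pct`.
#' @export
average_over_mpts <- function(mpt_set, reference) {
  stopifnot(length(mpt_set) >= 1)
  per_tree <- lapply(mpt_set, compare_quartets, tree2 = reference)
  sjas <- vapply(per_tree, function(x) x$sja, 0)
  structure(list(
    per_tree = per_tree,
    Q = per_tree[[1]]$Q,
    mean_s = mean(vapply(per_tree, function(x) x$s, 0)),
    mean_d = mean(vapply(per_tree, function(x) x$d, 0)),
    mean_sja_pct = 100 * mean(sjas)
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison over", length(x$per_tree), "tree(s): Q =", x$Q,
      " mean s =", format(x$mean_s), " mean d =", format(x$mean_d),
      " mean sja =", paste0(format(round(x$mean_sja_pct, 1)), "%"), "\n")
  invisible(x)
}
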