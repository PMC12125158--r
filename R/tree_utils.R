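# Tree utilities ---------------------------------------------------------------
#
# Trees are ape "phylo" objects throughout. Search-time surgery (taxon
# insertion, NNI/TBR rearrangement, edge contraction) is done on a neutral
# graph form -- a 2-column matrix of arbitrary vertex ids plus a leaf-label
# map -- and converted back with graph_to_phylo(), which always numbers tips
# in sorted label order so that one tip-state matrix serves every tree on the
# same taxon set.

phylo_to_graph <- function(tree) {
  ntip <- length(tree$tip.label)
  labels <- stats::setNames(tree$tip.label, seq_len(ntip))
  g <- list(edges = tree$edge, labels = labels)
  graph_suppress_deg2(g)
}

# collapse degree-2 vertices (e.g., leftovers of a root) into single edges
graph_suppress_deg2 <- function(g) {
  repeat {
    ids <- unique(as.vector(g$edges))
    deg <- table(factor(as.vector(g$edges), levels = ids))
    bad <- as.numeric(names(deg)[deg == 2 & !(names(deg) %in% names(g$labels))])
    if (length(bad) == 0) return(g)
    v <- bad[1]
    inc <- which(g$edges[, 1] == v | g$edges[, 2] == v)
    nb <- setdiff(as.vector(g$edges[inc, ]), v)
    g$edges <- rbind(g$edges[-inc, , drop = FALSE], nb)
  }
}

graph_new_id <- function(g) max(g$edges) + 1

# subdivide edge row `e` with a fresh vertex; returns list(graph, mid = id)
graph_subdivide <- function(g, e) {
  a <- g$edges[e, 1]; b <- g$edges[e, 2]
  mid <- graph_new_id(g)
  g$edges <- rbind(g$edges[-e, , drop = FALSE], c(a, mid), c(mid, b))
  list(graph = g, mid = mid)
}

graph_add_leaf <- function(g, at_vertex, label) {
  id <- graph_new_id(g)
  g$edges <- rbind(g$edges, c(at_vertex, id))
  g$labels[as.character(id)] <- label
  g
}

# Convert a graph (all internal vertices degree >= 3 after suppression) into a
# phylo object with tips numbered in sorted label order.
graph_to_phylo <- function(g) {
  g <- graph_suppress_deg2(g)
  leaf_ids <- as.numeric(names(g$labels))
  leaf_ids <- leaf_ids[leaf_ids %in% as.vector(g$edges)]
  labs <- unname(g$labels[as.character(leaf_ids)])
  ord <- order(labs)
  leaf_ids <- leaf_ids[ord]; labs <- labs[ord]
  ntip <- length(leaf_ids)
  all_ids <- unique(as.vector(g$edges))
  internal_ids <- setdiff(all_ids, leaf_ids)
  # adjacency
  adj <- split(c(g$edges[, 2], g$edges[, 1]), c(g$edges[, 1], g$edges[, 2]))
  # BFS from an internal vertex adjacent to the first leaf (root)
  root <- if (length(internal_ids)) {
    cand <- adj[[as.character(leaf_ids[1])]]
    cand[cand %in% internal_ids][1]
  } else stop("graph has no internal vertex")
  newid <- stats::setNames(seq_len(ntip), leaf_ids)
  nxt <- ntip + 1L
  parent <- integer(0); child <- integer(0)
  queue <- list(c(root, NA))
  newid[as.character(root)] <- nxt; nxt <- nxt + 1L
  head <- 1L
  while (head <= length(queue)) {
    v <- queue[[head]][1]; p <- queue[[head]][2]; head <- head + 1L
    for (w in adj[[as.character(v)]]) {
      if (!is.na(p) && w == p) next
      if (is.na(newid[as.character(w)])) {
        newid[as.character(w)] <- nxt; nxt <- nxt + 1L
      }
      parent <- c(parent, newid[[as.character(v)]])
      child <- c(child, newid[[as.character(w)]])
      if (!w %in% leaf_ids) queue[[length(queue) + 1L]] <- c(w, v)
    }
  }
  tr <- list(edge = cbind(parent, child, deparse.level = 0),
             tip.label = labs, Nnode = length(internal_ids))
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  tr
}

# canonical string key of an unrooted topology (label-sorted, polytomy-safe)
topology_key <- function(tree) {
  g <- phylo_to_graph(tree)
  adj <- split(c(g$edges[, 2], g$edges[, 1]), c(g$edges[, 1], g$edges[, 2]))
  leaf_ids <- as.numeric(names(g$labels))
  first_leaf <- leaf_ids[order(unname(g$labels))][1]
  root <- adj[[as.character(first_leaf)]][1]
  key <- function(v, p) {
    nb <- adj[[as.character(v)]]
    nb <- nb[nb != p]
    if (length(nb) == 0) return(unname(g$labels[as.character(v)]))
    paste0("(", paste(sort(vapply(nb, key, "", p = v)), collapse = ","), ")")
  }
  key(root, -1)
}

# tip index sets below every edge (child side), in the tree's own numbering
tips_under_edges <- function(tree) {
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  under <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) under[[i]] <- i
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    under[[p]] <- c(under[[p]], under[[ch]])
  }
  list(tree = tree, under = under)
}

#' Bipartitions (splits) of an unrooted tree
#'
#' @param tree a `phylo` object.
#' @param taxa taxon order defining split columns (default: sorted tip labels).
#' @return logical matrix, one row per non-trivial split, columns = taxa;
#'   canonicalized so the first taxon is always `FALSE`.
#' @export
tree_splits <- function(tree, taxa = sort(tree$tip.label)) {
  tu <- tips_under_edges(ape::unroot(tree))
  tree2 <- tu$tree
  ntip <- length(tree2$tip.label)
  res <- list()
  for (e in seq_len(nrow(tree2$edge))) {
    ch <- tree2$edge[e, 2]
    if (ch <= ntip) next
    side <- logical(length(taxa))
    side[match(tree2$tip.label[tu$under[[ch]]], taxa)] <- TRUE
    k <- sum(side)
    if (k < 2 || k > length(taxa) - 2) next
    if (side[1]) side <- !side
    res[[paste(as.integer(side), collapse = "")]] <- side
  }
  out <- do.call(rbind, unname(res))
  if (is.null(out)) out <- matrix(FALSE, 0, length(taxa))
  colnames(out) <- taxa
  out
}

# Neighborhoods -----------------------------------------------------------------

# All trees obtained by one nearest-neighbor interchange.
nni_neighbors <- function(tree) {
  g <- phylo_to_graph(ape::unroot(tree))
  leaf_ids <- as.numeric(names(g$labels))
  adj <- function(v) {
    inc <- which(g$edges[, 1] == v | g$edges[, 2] == v)
    setdiff(as.vector(g$edges[inc, ]), v)
  }
  out <- list()
  for (e in seq_len(nrow(g$edges))) {
    u <- g$edges[e, 1]; v <- g$edges[e, 2]
    if (u %in% leaf_ids || v %in% leaf_ids) next
    a <- setdiff(adj(u), v)[1]
    for (cc in setdiff(adj(v), u)) {
      g2 <- g
      ru <- which((g2$edges[, 1] == u & g2$edges[, 2] == a) |
                    (g2$edges[, 1] == a & g2$edges[, 2] == u))
      rv <- which((g2$edges[, 1] == v & g2$edges[, 2] == cc) |
                    (g2$edges[, 1] == cc & g2$edges[, 2] == v))
      g2$edges[ru, ] <- c(u, cc)
      g2$edges[rv, ] <- c(v, a)
      out[[length(out) + 1L]] <- graph_to_phylo(g2)
    }
  }
  out
}

# All trees obtained by tree bisection and reconnection (includes SPR and NNI
# moves): every branch is cut, the two fragments rejoined across all edge
# pairs. Tip-edge cuts reduce to re-insertion of the tip on every edge.
tbr_neighbors <- function(tree) {
  tree <- ape::unroot(tree)
  taxa <- sort(tree$tip.label)
  out <- list()
  # internal-edge bisections
  splits <- tree_splits(tree, taxa)
  if (nrow(splits) > 0) {
    for (s in seq_len(nrow(splits))) {
      A <- taxa[splits[s, ]]; B <- taxa[!splits[s, ]]
      gA <- fragment_graph(tree, A)
      gB <- fragment_graph(tree, B)
      for (ea in seq_len(nrow(gA$edges))) {
        sa <- graph_subdivide(gA, ea)
        for (eb in seq_len(nrow(gB$edges))) {
          g2 <- sa$graph
          # bring gB in with shifted ids to avoid collisions
          shift <- graph_new_id(g2)
          edgesB <- gB$edges + shift
          sb_a <- edgesB[eb, 1]; sb_b <- edgesB[eb, 2]
          mid <- max(edgesB) + 1
          edgesB <- rbind(edgesB[-eb, , drop = FALSE],
                          c(sb_a, mid), c(mid, sb_b))
          g2$edges <- rbind(g2$edges, edgesB, c(sa$mid, mid))
          g2$labels <- c(g2$labels,
                         stats::setNames(unname(gB$labels),
                                         as.numeric(names(gB$labels)) + shift))
          out[[length(out) + 1L]] <- graph_to_phylo(g2)
        }
      }
    }
  }
  # tip reinsertions
  for (tip in tree$tip.label) {
    rest <- ape::drop.tip(tree, tip)
    if (is.null(rest) || length(rest$tip.label) < 3) next
    g <- phylo_to_graph(ape::unroot(rest))
    for (e in seq_len(nrow(g$edges))) {
      sd <- graph_subdivide(g, e)
      out[[length(out) + 1L]] <-
        graph_to_phylo(graph_add_leaf(sd$graph, sd$mid, tip))
    }
  }
  out
}

# induced subtree on a tip subset, as a graph (2+ tips)
fragment_graph <- function(tree, tips) {
  if (length(tips) == 2) {
    g <- list(edges = matrix(c(1, 2), 1, 2),
              labels = stats::setNames(sort(tips), 1:2))
    return(g)
  }
  phylo_to_graph(ape::unroot(ape::keep.tip(tree, tips)))
}

# contract internal edges (by row index of the unrooted tree's edge matrix)
contract_edges <- function(tree, edge_rows) {
  g <- phylo_to_graph(tree)
  # map phylo edges to graph edges via tip-set identity is fragile; instead
  # work directly: contract in the phylo edge matrix, then rebuild
  edge <- tree$edge
  keep <- setdiff(seq_len(nrow(edge)), edge_rows)
  # union-find on vertices joined by contracted edges
  parent_of <- seq_len(max(edge))
  find <- function(x) { while (parent_of[x] != x) x <- parent_of[x]; x }
  for (e in edge_rows) {
    a <- find(edge[e, 1]); b <- find(edge[e, 2])
    if (a != b) parent_of[b] <- a
  }
  ntip <- length(tree$tip.label)
  new_edges <- cbind(vapply(edge[keep, 1], find, 0), vapply(edge[keep, 2], find, 0))
  labels <- stats::setNames(tree$tip.label, seq_len(ntip))
  graph_to_phylo(list(edges = new_edges, labels = labels))
}
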