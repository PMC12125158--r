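# Shared fixtures and independent oracles used across the suite.

# random coded matrix: mixed ordered/unordered, ~10% polymorphic cells,
# ~5% missing
rand_matrix <- function(ntaxa, nchar, seed, poly = 0.10, miss = 0.05) {
  set.seed(seed)
  taxa <- sprintf("t%02d", seq_len(ntaxa))
  nst <- sample(2:4, nchar, TRUE)
  ord <- stats::runif(nchar) < 0.5
  cells <- sapply(seq_len(nchar), function(j) {
    sapply(seq_len(ntaxa), function(i) {
      if (stats::runif(1) < miss) return("?")
      s <- sample(0:(nst[j] - 1), 1)
      if (stats::runif(1) < poly) s <- unique(c(s, sample(0:(nst[j] - 1), 1)))
      cell_from_states(s)
    })
  })
  coded_matrix(taxa, character_defs(seq_len(nchar), n_states = nst,
                                    ordered = ord), cells)
}

# random unrooted topology, optionally with polytomies
rand_tree <- function(ntaxa, seed, polytomies = FALSE) {
  set.seed(seed)
  tr <- ape::rtopology(ntaxa, rooted = FALSE,
                       tip.label = sprintf("t%02d", seq_len(ntaxa)))
  if (polytomies && tr$Nnode > 1) {
    tr$edge.length <- stats::runif(nrow(tr$edge))
    internal <- tr$edge[, 2] > length(tr$tip.label)
    tr$edge.length[internal][stats::runif(sum(internal)) < 0.4] <- 0
    tr <- ape::di2multi(tr, tol = 1e-8)
  }
  tr$edge.length <- NULL
  tr
}

# brute-force parsimony length of one character by enumerating every internal
# state assignment (tiny trees only); linear costs when ordered
brute_force_length <- function(tree, column, n_states, ordered = FALSE) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  sets <- lapply(column[tree$tip.label], function(cc) {
    st <- cell_states(cc)
    if (is.null(st)) 0:(n_states - 1) else st
  })
  grid <- do.call(expand.grid, c(rep(list(0:(n_states - 1)), nint),
                                 rep(list(0), 0)))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    int_states <- as.integer(grid[g, ])
    state_of <- function(v) if (v <= ntip) NA else int_states[v - ntip]
    # tips: minimize over their allowed sets given fixed internal states
    total <- 0
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      ps <- state_of(p)
      if (ch <= ntip) {
        costs <- vapply(sets[[ch]], function(s)
          if (ordered) abs(s - ps) else as.numeric(s != ps), 0)
        total <- total + min(costs)
      } else {
        cs <- state_of(ch)
        total <- total + if (ordered) abs(cs - ps) else as.numeric(cs != ps)
      }
    }
    best <- min(best, total)
  }
  as.integer(best)
}

# independent quartet category via pruning and path distances
brute_quartet_status <- function(tree1, tree2, quartet) {
  res <- function(tr) {
    t4 <- ape::unroot(ape::keep.tip(tr, quartet))
    if (t4$Nnode < 2) return(0L)  # star
    t4$edge.length <- rep(1, nrow(t4$edge))
    D <- ape::cophenetic.phylo(t4)[quartet, quartet]
    sums <- c(D[1, 2] + D[3, 4], D[1, 3] + D[2, 4], D[1, 4] + D[2, 3])
    which.min(sums)
  }
  c1 <- res(tree1); c2 <- res(tree2)
  if (c1 == 0 && c2 == 0) "u"
  else if (c1 == 0) "r2"
  else if (c2 == 0) "r1"
  else if (c1 == c2) "s" else "d"
}

# naive average-rank + product-moment correlation, written without rank()/cor()
naive_spearman <- function(x, y) {
  avg_rank <- function(v) vapply(v, function(a)
    sum(v < a) + (sum(v == a) + 1) / 2, 0)
  rx <- avg_rank(x); ry <- avg_rank(y)
  mx <- sum(rx) / length(rx); my <- sum(ry) / length(ry)
  num <- sum((rx - mx) * (ry - my))
  num / sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}
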