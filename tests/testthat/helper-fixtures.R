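# Shared fixtures and independent brute-force oracles. Oracles are
# deliberately written as naive enumerations, separate from the package
# implementations they check.

toy_survey <- function() {
  tibble::tribble(
    ~plot_id, ~stage, ~layer, ~species, ~count, ~dominance, ~subplot_hits, ~n_subplots,
    "p1", "BF", "tree", "oak", 6, 120, 1, 1,
    "p1", "BF", "tree", "pine", 2, 40, 1, 1,
    "p1", "BF", "shrub", "holly", 3, 10, 2, 5,
    "p1", "BF", "shrub", "azalea", 1, 10, 1, 5,
    "p1", "BF", "herb", "fern", 10, 30, 8, 25,
    "p2", "LM", "tree", "oak", 4, 90, 1, 1,
    "p2", "LM", "shrub", "holly", 5, 25, 4, 5,
    "p2", "LM", "herb", "fern", 6, 20, 5, 25,
    "p2", "LM", "herb", "sedge", 4, 10, 6, 25
  )
}

small_config <- function(...) {
  gradient_config(
    species_per_layer = c(tree = 10, shrub = 12, herb = 12),
    ...
  )
}

# three-tip reference tree: ((A:1,B:1):1,C:2);
abc_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

random_tree <- function(n, seed, scale = 10) {
  withr::with_seed(seed, {
    tr <- ape::rcoal(n, tip.label = paste0("s", seq_len(n)))
    tr$edge.length <- tr$edge.length * scale
    tr
  })
}

# --- oracles ---------------------------------------------------------

# patristic distance by shortest path on the edge graph (igraph)
oracle_patristic <- function(tree) {
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character))
  igraph::E(g)$weight <- tree$edge.length
  d <- igraph::distances(g)
  tip_ids <- as.character(seq_along(tree$tip.label))
  m <- d[tip_ids, tip_ids]
  dimnames(m) <- list(tree$tip.label, tree$tip.label)
  m
}

# Faith PD by union of root-to-tip node paths (ape::nodepath)
oracle_pd <- function(tree, community) {
  root <- length(tree$tip.label) + 1L
  edges <- unique(do.call(rbind, lapply(match(community, tree$tip.label), function(tip) {
    np <- ape::nodepath(tree, root, tip)
    cbind(np[-length(np)], np[-1])
  })))
  sum(apply(edges, 1, function(e) {
    tree$edge.length[which(tree$edge[, 1] == e[1] & tree$edge[, 2] == e[2])]
  }))
}

oracle_mpd <- function(d, comm) {
  tot <- 0; k <- 0
  for (i in seq_along(comm)) {
    for (j in seq_along(comm)) {
      if (i < j) { tot <- tot + d[comm[i], comm[j]]; k <- k + 1 }
    }
  }
  tot / k
}

oracle_mntd <- function(d, comm) {
  mean(vapply(seq_along(comm), function(i) {
    min(vapply(setdiff(seq_along(comm), i), function(j) d[comm[i], comm[j]],
               numeric(1)))
  }, numeric(1)))
}

# exact SES by equal-weight enumeration of all same-size communities
oracle_ses <- function(d, comm) {
  pool <- rownames(d)
  sets <- combn(pool, length(comm), simplify = FALSE)
  null_mpd <- vapply(sets, function(s) oracle_mpd(d, s), numeric(1))
  null_mntd <- vapply(sets, function(s) oracle_mntd(d, s), numeric(1))
  list(
    nri = -(oracle_mpd(d, comm) - mean(null_mpd)) / sd(null_mpd),
    nti = -(oracle_mntd(d, comm) - mean(null_mntd)) / sd(null_mntd),
    mpd_null_mean = mean(null_mpd), mpd_null_sd = sd(null_mpd),
    mntd_null_mean = mean(null_mntd), mntd_null_sd = sd(null_mntd)
  )
}

oracle_theil_sen <- function(x, y) {
  s <- c()
  for (i in seq_along(x)) {
    for (j in seq_along(x)) {
      if (i < j && x[i] != x[j]) s <- c(s, (y[j] - y[i]) / (x[j] - x[i]))
    }
  }
  median(s)
}

all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_permutations(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

kendall_s <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) {
    for (j in seq_along(x)) {
      if (i < j) s <- s + sign(x[j] - x[i]) * sign(y[j] - y[i])
    }
  }
  s
}

# step-up BH oracle
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}
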