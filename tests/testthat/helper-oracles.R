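# Independent oracles used across the test files.

# triad census via igraph (independent of the package's lookup table)
igraph_census <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  stats::setNames(igraph::triad_census(g), triad_labels)
}

# brute-force three-trail count: enumerate ordered triples of distinct arcs
brute_three_trails <- function(adj, distinct_units = FALSE) {
  arcs <- which(adj == 1L, arr.ind = TRUE)
  na <- nrow(arcs)
  if (na < 3) return(0)
  cnt <- 0
  for (i in seq_len(na)) for (j in seq_len(na)) for (k in seq_len(na)) {
    if (i == j || j == k || i == k) next
    if (arcs[i, 2] == arcs[j, 1] && arcs[j, 2] == arcs[k, 1]) {
      if (distinct_units) {
        u <- c(arcs[i, 1], arcs[i, 2], arcs[j, 2], arcs[k, 2])
        if (anyDuplicated(u)) next
      }
      cnt <- cnt + 1
    }
  }
  cnt
}

# exhaustive minimum of the blockmodeling criterion over all K=2 partitions
exhaustive_fit_k2 <- function(adj, image) {
  n <- nrow(adj)
  best <- Inf
  for (code in 1:(2^n - 2)) {  # skip the two one-cluster assignments
    part <- as.integer(intToBits(code))[seq_len(n)] + 1L
    if (length(unique(part)) < 2) next
    best <- min(best, criterion(adj, part, image))
  }
  best
}

# expected count of a triad type in a uniform digraph with exactly m arcs:
# npatterns arc-configurations per triple, each requiring q specific arcs
# present and (6 - q) specific arcs absent among the triple's 6 ordered slots
hypergeom_triad_mean <- function(n, m, q, npatterns = 1) {
  slots <- n * (n - 1)
  p <- choose(slots - 6, m - q) / choose(slots, m)
  choose(n, 3) * npatterns * p
}
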