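# Independent brute-force oracles. These deliberately avoid the package's
# own traversal code (and ape's cophenetic): distances come from explicit
# per-pair LCA walks on the edge matrix, PD from a direct union of
# root-path edges, MPD/MNTD from naive pair loops.

oracle_node_tables <- function(tree) {
  nmax <- max(tree$edge)
  parent <- integer(nmax)
  plen <- numeric(nmax)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  plen[tree$edge[, 2]] <- tree$edge.length
  list(parent = parent, plen = plen, root = length(tree$tip.label) + 1L)
}

oracle_root_path <- function(tab, v) {
  path <- v
  while (v != tab$root) {
    v <- tab$parent[v]
    path <- c(path, v)
  }
  path
}

oracle_depth <- function(tab, v) {
  d <- 0
  while (v != tab$root) {
    d <- d + tab$plen[v]
    v <- tab$parent[v]
  }
  d
}

# cophenetic distance via per-pair LCA walk: depth(i) + depth(j) - 2 depth(lca)
oracle_cophenetic <- function(tree) {
  tab <- oracle_node_tables(tree)
  n <- length(tree$tip.label)
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    pi <- oracle_root_path(tab, i)
    for (j in seq(i + 1, n)) {
      pj <- oracle_root_path(tab, j)
      lca <- pi[pi %in% pj][1]
      d <- oracle_depth(tab, i) + oracle_depth(tab, j) - 2 * oracle_depth(tab, lca)
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

# root-inclusive PD: sum of branch lengths of edges whose child node lies
# on some taxon's root path
oracle_pd <- function(tree, taxa) {
  tab <- oracle_node_tables(tree)
  idx <- match(taxa, tree$tip.label)
  covered <- unique(unlist(lapply(idx, function(i) {
    p <- oracle_root_path(tab, i)
    p[p != tab$root]
  })))
  sum(tab$plen[covered])
}

oracle_mpd <- function(D, taxa) {
  idx <- match(taxa, rownames(D))
  tot <- 0; np <- 0
  for (a in seq_along(idx)) {
    for (b in seq_along(idx)) {
      if (b <= a) next
      tot <- tot + D[idx[a], idx[b]]
      np <- np + 1
    }
  }
  tot / np
}

oracle_mntd <- function(D, taxa) {
  idx <- match(taxa, rownames(D))
  mean(vapply(seq_along(idx), function(a) {
    min(D[idx[a], idx[-a]])
  }, numeric(1)))
}

# random test topologies with assorted branch lengths
random_test_tree <- function(n_tips) {
  tr <- ape::rtree(n_tips)
  tr$edge.length <- round(stats::runif(nrow(tr$edge), 0.05, 3), 3)
  tr
}
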