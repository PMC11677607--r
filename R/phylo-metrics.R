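#' Parse a newick string into a phylogeny
#'
#' Thin, validating wrapper around [ape::read.tree()]. The returned tree is
#' the standard `"phylo"` object used throughout the package. Beyond parsing,
#' this enforces the invariants every downstream metric assumes: unique
#' non-empty tip labels, branch lengths present and non-negative, and at
#' least two tips. Zero-length branches (polytomy grafts) are allowed.
#'
#' @param text a newick string (must end in `;`).
#' @return an [ape] `"phylo"` tree.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) {
      stop("newick parse error: unmatched ')' at position ", i)
    }
  }
  if (depth != 0L) {
    stop("newick parse error: ", depth, " unclosed '(' by position ",
         length(chars))
  }
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("newick parse error: ", conditionMessage(e))
  )
  if (is.null(tree)) stop("newick parse error: input could not be read")
  validate_phylogeny(tree)
  tree
}

#' Validate a phylogeny for metric computation
#'
#' @param tree a `"phylo"` object.
#' @return the tree, invisibly, if valid; otherwise an error.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (length(tree$tip.label) < 2L) stop("tree must have at least 2 tips")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(tree$tip.label))) stop("empty tip labels are not allowed")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) stop("missing branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths are not allowed")
  invisible(tree)
}

#' Write a phylogeny as a newick string
#'
#' @param tree a `"phylo"` object.
#' @param digits significant digits for branch lengths.
#' @return a newick string.
#' @export
write_newick <- function(tree, digits = 12L) {
  ape::write.tree(tree, digits = digits)
}

#' Cophenetic (patristic) distance matrix of a phylogeny
#'
#' Distance between two tips is the sum of branch lengths along the unique
#' path joining them. Rows and columns are ordered as `tree$tip.label`.
#'
#' @param tree a `"phylo"` object.
#' @return a symmetric numeric matrix with zero diagonal, dimnames = tip labels.
#' @export
cophenetic_matrix <- function(tree) {
  validate_phylogeny(tree)
  D <- ape::cophenetic.phylo(tree)
  D[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Precomputed traversal context for fast repeated metrics
#'
#' Computes once, for a given tree, everything the diversity metrics and
#' their randomization nulls need per evaluation: the cophenetic matrix,
#' per-tip root paths (edge index lists) and branch lengths. Passing the
#' context to [faith_pd()] and the SES functions avoids recomputation
#' inside null loops.
#'
#' @param tree a `"phylo"` object.
#' @return a list of class `"phylo_context"`.
#' @export
phylo_context <- function(tree) {
  validate_phylogeny(tree)
  ntip <- length(tree$tip.label)
  nnode <- max(tree$edge)
  root <- ntip + 1L
  parent_edge <- integer(nnode)
  parent_edge[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  paths <- vector("list", ntip)
  for (tip in seq_len(ntip)) {
    path <- integer(0)
    node <- tip
    while (node != root) {
      e <- parent_edge[node]
      path <- c(path, e)
      node <- tree$edge[e, 1L]
    }
    paths[[tip]] <- path
  }
  structure(
    list(tree = tree, tip_labels = tree$tip.label, ntip = ntip,
         edge_length = tree$edge.length, tip_paths = paths,
         D = cophenetic_matrix(tree)),
    class = "phylo_context"
  )
}

as_phylo_context <- function(x) {
  if (inherits(x, "phylo_context")) x else phylo_context(x)
}

match_taxa <- function(taxa, labels) {
  idx <- match(taxa, labels)
  if (anyNA(idx)) {
    stop("taxa not found in tree: ", paste(taxa[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Faith's phylogenetic diversity of a taxa set
#'
#' Sum of the branch lengths of the minimal subtree spanning the given taxa.
#' By default the subtree is connected to the tree root (the convention of
#' the classic community-phylogenetics software lineage), so a single taxon
#' has PD equal to its root-to-tip depth. With `include_root = FALSE` only
#' branches below the taxa's most recent common ancestor are counted, and a
#' single taxon has PD 0.
#'
#' @param tree a `"phylo"` object or a [phylo_context()].
#' @param taxa character vector of tip labels, length >= 1.
#' @param include_root include the stem path up to the tree root (default TRUE).
#' @return numeric PD in branch-length units.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' faith_pd(tr, c("A", "B"))  # 3: both cherry branches plus their stem
#' @export
faith_pd <- function(tree, taxa, include_root = TRUE) {
  ctx <- as_phylo_context(tree)
  idx <- match_taxa(taxa, ctx$tip_labels)
  if (length(idx) < 1L) stop("need at least one taxon")
  .faith_pd_idx(ctx, idx, include_root)
}

.faith_pd_idx <- function(ctx, idx, include_root = TRUE) {
  edges <- unlist(ctx$tip_paths[idx], use.names = FALSE)
  if (include_root) {
    sum(ctx$edge_length[unique(edges)])
  } else {
    # drop edges shared by every taxon's root path: those lie on or above
    # the MRCA stem, outside the spanning subtree of the taxa themselves
    tab <- tabulate(edges, nbins = length(ctx$edge_length))
    sum(ctx$edge_length[tab > 0L & tab < length(idx)])
  }
}

#' Mean pairwise phylogenetic distance (MPD)
#'
#' Unweighted mean of the cophenetic distances over all unordered pairs of
#' distinct taxa (presence/absence; abundance weighting is deliberately not
#' implemented).
#'
#' @param D a cophenetic distance matrix (see [cophenetic_matrix()]).
#' @param taxa character vector of tip labels, length >= 2.
#' @return numeric MPD.
#' @export
mpd <- function(D, taxa) {
  idx <- match_taxa(taxa, rownames(D))
  .mpd_idx(D, idx)
}

.mpd_idx <- function(D, idx) {
  r <- length(idx)
  if (r < 2L) stop("MPD undefined for fewer than 2 taxa")
  sum(D[idx, idx]) / (r * (r - 1))
}

#' Mean nearest taxon distance (MNTD)
#'
#' Mean, over taxa, of each taxon's distance to its closest other taxon in
#' the set.
#'
#' @inheritParams mpd
#' @return numeric MNTD.
#' @export
mntd <- function(D, taxa) {
  idx <- match_taxa(taxa, rownames(D))
  .mntd_idx(D, idx)
}

.mntd_idx <- function(D, idx) {
  r <- length(idx)
  if (r < 2L) stop("MNTD undefined for fewer than 2 taxa")
  S <- D[idx, idx]
  diag(S) <- Inf
  mean(apply(S, 1L, min))
}
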