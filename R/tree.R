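# Rooted trees are stored as a flat parent-vector structure ("rtree"):
#   parent : integer vector, parent[i] is the parent node of node i (0 = root)
#   label  : character vector of node labels (tips and internal nodes)
#   length : numeric vector, branch length above each node (NA at the root)
# Node ids are positions 1..n. The root is unique. Children are derived.

new_rtree <- function(parent, label, length = rep(NA_real_, base::length(parent))) {
  stopifnot(base::length(parent) == base::length(label),
            sum(parent == 0L) == 1L)
  structure(list(parent = as.integer(parent),
                 label  = as.character(label),
                 length = as.numeric(length)),
            class = "rtree")
}

rtree_n <- function(tree) length(tree$parent)

rtree_root <- function(tree) which(tree$parent == 0L)

rtree_children <- function(tree) {
  kids <- vector("list", rtree_n(tree))
  for (i in seq_along(tree$parent)) {
    p <- tree$parent[i]
    if (p > 0L) kids[[p]] <- c(kids[[p]], i)
  }
  kids
}

rtree_tips <- function(tree) {
  has_child <- rep(FALSE, rtree_n(tree))
  has_child[tree$parent[tree$parent > 0L]] <- TRUE
  which(!has_child)
}

# Preorder (parent before child); deterministic: children visited in id order.
rtree_preorder <- function(tree) {
  kids <- rtree_children(tree)
  out <- integer(0)
  stack <- rtree_root(tree)
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    out <- c(out, v)
    stack <- c(kids[[v]], stack)
  }
  out
}

rtree_postorder <- function(tree) rev(rtree_preorder(tree))

# Depth (sum of branch lengths) from root to every node; NA lengths count 0.
rtree_depths <- function(tree) {
  d <- numeric(rtree_n(tree))
  for (v in rtree_preorder(tree)) {
    p <- tree$parent[v]
    if (p > 0L) d[v] <- d[p] + ifelse(is.na(tree$length[v]), 0, tree$length[v])
  }
  d
}

# Patristic distance matrix between tips, by label.
rtree_patristic <- function(tree) {
  tips <- rtree_tips(tree)
  n <- length(tips)
  depth <- rtree_depths(tree)
  # ancestor chains
  chain <- function(v) {
    out <- v
    while (tree$parent[v] > 0L) { v <- tree$parent[v]; out <- c(out, v) }
    out
  }
  chains <- lapply(tips, chain)
  D <- matrix(0, n, n, dimnames = list(tree$label[tips], tree$label[tips]))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      mrca <- intersect(chains[[i]], chains[[j]])[1]
      D[i, j] <- D[j, i] <- depth[tips[i]] + depth[tips[j]] - 2 * depth[mrca]
    }
  }
  D
}

# Conversion to ape::phylo (for Newick serialization and plotting).
rtree_to_phylo <- function(tree) {
  tips <- rtree_tips(tree)
  internals <- setdiff(seq_len(rtree_n(tree)), tips)
  root <- rtree_root(tree)
  # ape wants tips 1..ntip, then root, then other internals
  internals <- c(root, setdiff(internals, root))
  newid <- integer(rtree_n(tree))
  newid[tips] <- seq_along(tips)
  newid[internals] <- length(tips) + seq_along(internals)
  nonroot <- which(tree$parent > 0L)
  edge <- cbind(newid[tree$parent[nonroot]], newid[nonroot])
  o <- order(edge[, 1], edge[, 2])
  lens <- tree$length[nonroot]
  lens[is.na(lens)] <- 0
  structure(list(edge = edge[o, , drop = FALSE],
                 edge.length = lens[o],
                 tip.label = tree$label[tips],
                 node.label = tree$label[internals],
                 Nnode = length(internals)),
            class = "phylo", order = "cladewise")
}

phylo_to_rtree <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  n <- ntip + nnode
  parent <- integer(n)
  lens <- rep(NA_real_, n)
  for (k in seq_len(nrow(phy$edge))) {
    parent[phy$edge[k, 2]] <- phy$edge[k, 1]
    if (!is.null(phy$edge.length)) lens[phy$edge[k, 2]] <- phy$edge.length[k]
  }
  labs <- c(phy$tip.label,
            if (!is.null(phy$node.label)) phy$node.label
            else paste0("N", seq_len(nnode)))
  new_rtree(parent, labs, lens)
}

#' Serialize a rooted tree to a Newick string
#'
#' Branch lengths are written as-is (integers stay integers); internal node
#' labels are preserved. Deterministic: children appear in node-id order.
#' @param tree an internal `rtree` object or an [ape::phylo] tree
#' @return a single Newick string terminated by `";"`
#' @keywords internal
rtree_newick <- function(tree) {
  kids <- rtree_children(tree)
  fmt_len <- function(v) {
    l <- tree$length[v]
    if (is.na(l)) "" else paste0(":", format(l, scientific = FALSE, trim = TRUE))
  }
  rec <- function(v) {
    if (length(kids[[v]]) == 0) return(paste0(tree$label[v], fmt_len(v)))
    paste0("(", paste(vapply(kids[[v]], rec, ""), collapse = ","),
           ")", tree$label[v], fmt_len(v))
  }
  paste0(rec(rtree_root(tree)), ";")
}
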