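# Maximum-parsimony clone phylogeny over binary genotypes, rooted at an
# explicit all-zero germline outgroup; Fitch ancestral reconstruction with a
# parent-state (late-change) resolution; mutation-to-branch mapping; and the
# contraction of the clone phylogeny into a mutational tree.

GERMLINE <- "Germline"

# Fitch state sets for binary characters are encoded as integers:
# 1 = {0}, 2 = {1}, 3 = {0,1}. Vectorized across SNVs.

# Postorder Sankoff cost matrices for binary characters: for every node,
# the minimum number of changes in its subtree when the node is in state 0
# (c0) or 1 (c1). Exact for any node degree (the germline root can carry its
# own fixed state next to two children). Vectorized across SNVs.
sankoff_costs <- function(tips, tree) {
  tip_ids <- rtree_tips(tree)
  root <- rtree_root(tree)
  labs <- tree$label[tip_ids]
  constrained <- c(labs, if (tree$label[root] %in% rownames(tips))
    tree$label[root])
  if (!setequal(constrained, rownames(tips)))
    stop("tip genotypes do not match tree leaves")
  n <- rtree_n(tree)
  n_snv <- ncol(tips)
  kids <- rtree_children(tree)
  BIG <- 1e9
  c0 <- matrix(0, n, n_snv)
  c1 <- matrix(0, n, n_snv)
  clamp <- function(v, states) {       # observed state at node v
    c0[v, ] <<- ifelse(states == 0L, 0, BIG)
    c1[v, ] <<- ifelse(states == 1L, 0, BIG)
  }
  for (i in seq_along(tip_ids)) clamp(tip_ids[i], tips[labs[i], ])
  for (v in rtree_postorder(tree)) {
    ch <- kids[[v]]
    if (length(ch) == 0) next
    a0 <- rep(0, n_snv); a1 <- rep(0, n_snv)
    if (tree$label[v] %in% rownames(tips)) {   # the germline root's own state
      s <- tips[tree$label[v], ]
      a0 <- ifelse(s == 0L, 0, BIG); a1 <- ifelse(s == 1L, 0, BIG)
    }
    for (c2 in ch) {
      a0 <- a0 + pmin(c0[c2, ], c1[c2, ] + 1)
      a1 <- a1 + pmin(c1[c2, ], c0[c2, ] + 1)
    }
    c0[v, ] <- a0; c1[v, ] <- a1
  }
  list(c0 = c0, c1 = c1)
}

#' Small-parsimony score of binary genotypes on a rooted topology
#'
#' Minimum total number of state changes over all SNVs (unit-cost Sankoff,
#' identical to Fitch parsimony on binary trees but exact for polytomies and
#' for the germline root carrying its own all-zero state).
#'
#' @param tips binary matrix (tips x SNVs) with rownames matching the tip
#'   labels of `tree`; a row named like the root (the germline outgroup)
#'   supplies the root's observed state
#' @param tree an `rtree` topology (internal structure; see
#'   [clone_phylogeny()] for the user-facing container)
#' @return integer: the minimum total number of state changes over all SNVs
#' @export
fitch_score <- function(tips, tree) {
  sc <- sankoff_costs(tips, tree)
  root <- rtree_root(tree)
  as.integer(sum(pmin(sc$c0[root, ], sc$c1[root, ])))
}

#' Reconstruct ancestral genotypes on a clone phylogeny
#'
#' Postorder Sankoff cost pass followed by a preorder resolution pass: the
#' root (germline) is forced to the all-zero genotype, and when both states
#' of a node are optimal the parent's state is kept. This places changes as
#' late as possible (mutations arise, rarely revert) and is fully
#' deterministic; the implied number of changes equals [fitch_score()].
#'
#' @inheritParams fitch_score
#' @return binary matrix (nodes x SNVs) of genotypes at every node, rows in
#'   node-id order of `tree`.
#' @export
reconstruct_ancestral <- function(tips, tree) {
  sc <- sankoff_costs(tips, tree)
  geno <- matrix(0L, rtree_n(tree), ncol(tips))
  root <- rtree_root(tree)
  for (v in rtree_preorder(tree)) {
    if (v == root) { geno[v, ] <- 0L; next }
    p <- tree$parent[v]
    pg <- geno[p, ]
    # cost of assigning v each state, given the parent's resolved state
    t0 <- sc$c0[v, ] + (pg != 0L)
    t1 <- sc$c1[v, ] + (pg != 1L)
    pick1 <- t1 < t0 | (t1 == t0 & pg == 1L)   # tie -> parent's state
    geno[v, ] <- as.integer(pick1)
  }
  colnames(geno) <- colnames(tips)
  geno
}

# --- topology search ---------------------------------------------------------

# A search topology is grown from the germline root downward: the root is the
# germline tip; clone tips are inserted one at a time by subdividing an edge.
# Recursive insertion in a fixed clone order generates every rooted topology
# exactly once: 1 * 3 * 5 * ... ways.

make_start_tree <- function(clones) {
  # germline root with the first clone as its single child
  new_rtree(parent = c(0L, 1L), label = c(GERMLINE, clones[1]))
}

insert_tip <- function(tree, edge_child, lab) {
  # subdivide the edge above `edge_child`, attach new tip to the new node
  n <- rtree_n(tree)
  parent <- c(tree$parent, tree$parent[edge_child], n + 1L)
  parent[edge_child] <- n + 1L
  new_rtree(parent, c(tree$label, paste0("N", n + 1L), lab))
}

all_topologies <- function(clones) {
  trees <- list(make_start_tree(clones))
  for (lab in clones[-1]) {
    nxt <- list()
    for (tr in trees) {
      for (v in which(tr$parent > 0L))
        nxt[[length(nxt) + 1L]] <- insert_tip(tr, v, lab)
    }
    trees <- nxt
  }
  trees
}

# Canonical Newick of a topology (no lengths, internal labels stripped,
# children sorted) — used for deterministic tie-breaking.
canonical_newick <- function(tree) {
  kids <- rtree_children(tree)
  rec <- function(v) {
    if (length(kids[[v]]) == 0) return(tree$label[v])
    parts <- sort(vapply(kids[[v]], rec, ""))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(rtree_root(tree)), ";")
}

nni_neighbors <- function(tree) {
  # NNI on each internal edge (u,v) where both u and v are internal and u is
  # not the root: swap one child of v with v's sibling.
  out <- list()
  kids <- rtree_children(tree)
  root <- rtree_root(tree)
  for (v in seq_len(rtree_n(tree))) {
    u <- tree$parent[v]
    if (u == 0L || u == root || length(kids[[v]]) == 0) next
    sibs <- setdiff(kids[[u]], v)
    for (s in sibs) for (c in kids[[v]]) {
      pr <- tree$parent
      pr[s] <- v; pr[c] <- u
      out[[length(out) + 1L]] <- new_rtree(pr, tree$label, tree$length)
    }
  }
  out
}

#' Search for a maximum-parsimony topology over clone genotypes
#'
#' Clones plus an all-zero germline outgroup. With at most 7 clones every
#' rooted topology is scored exhaustively (10,395 topologies at 7 clones);
#' score ties are broken by the lexicographically smallest canonical Newick
#' string. Larger clone sets use deterministic stepwise addition followed by
#' nearest-neighbor-interchange hill climbing to a local optimum.
#'
#' @param M binary genotype matrix (clones x SNVs) with unique non-empty rows
#'   and clone names as rownames
#' @return list with `tree` (an `rtree`, germline-rooted), `score` (its Fitch
#'   parsimony score), and `exhaustive` (logical).
#' @export
search_mp_tree <- function(M) {
  clones <- rownames(M)
  stopifnot(!is.null(clones), !anyDuplicated(clones))
  tips <- rbind(M, matrix(0L, 1, ncol(M), dimnames = list(GERMLINE)))
  if (length(clones) == 1) {
    tr <- make_start_tree(clones)
    return(list(tree = tr, score = fitch_score(tips, tr), exhaustive = TRUE))
  }
  if (length(clones) <= 7) {
    cand <- all_topologies(clones)
    scores <- vapply(cand, function(tr) fitch_score(tips, tr), 0L)
    best <- which(scores == min(scores))
    if (length(best) > 1) {
      keys <- vapply(cand[best], canonical_newick, "")
      best <- best[order(keys)[1]]
    }
    return(list(tree = cand[[best]], score = min(scores), exhaustive = TRUE))
  }
  # stepwise addition, clones in deterministic (mutation count, genotype) order
  ord <- order(rowSums(M), apply(M, 1, paste, collapse = ""))
  clones <- clones[ord]
  tr <- make_start_tree(clones)
  for (lab in clones[-1]) {
    cand <- lapply(which(tr$parent > 0L), function(v) insert_tip(tr, v, lab))
    sub_tips <- tips[unique(c(tr$label[rtree_tips(tr)], lab, GERMLINE)), ,
                     drop = FALSE]
    scores <- vapply(cand, function(t2) fitch_score(sub_tips, t2), 0L)
    tr <- cand[[which.min(scores)]]
  }
  best_score <- fitch_score(tips, tr)
  repeat {
    neigh <- nni_neighbors(tr)
    if (length(neigh) == 0) break
    scores <- vapply(neigh, function(t2) fitch_score(tips, t2), 0L)
    if (min(scores) < best_score) {
      tr <- neigh[[which.min(scores)]]
      best_score <- min(scores)
    } else break
  }
  list(tree = tr, score = best_score, exhaustive = FALSE)
}

#' Build a clone phylogeny with ancestral genotypes and branch mutations
#'
#' Runs the maximum-parsimony topology search, reconstructs genotypes at all
#' internal nodes, and maps every SNV to the branch(es) where its state
#' changes. Branch length = number of mutations on the branch.
#'
#' @param M binary clone genotype matrix (clones x SNVs), rownames = clones,
#'   colnames = SNV ids
#' @param tree optionally, a fixed `rtree` topology (germline-rooted) to use
#'   instead of searching
#' @return a `clone_phylogeny`: list with `tree` (branch lengths filled in),
#'   `genotypes` (nodes x SNVs), `branch_mutations` (per-node list of SNV ids
#'   on the branch above that node), `score`.
#' @export
clone_phylogeny <- function(M, tree = NULL) {
  if (is.null(colnames(M))) colnames(M) <- paste0("snv", seq_len(ncol(M)))
  tips <- rbind(M, matrix(0L, 1, ncol(M),
                          dimnames = list(GERMLINE, colnames(M))))
  if (is.null(tree)) {
    fit <- search_mp_tree(M)
    tree <- fit$tree
  }
  geno <- reconstruct_ancestral(tips, tree)
  bm <- map_mutations_to_branches(tree, geno)
  tree$length <- vapply(seq_len(rtree_n(tree)), function(v)
    if (tree$parent[v] == 0L) NA_real_ else length(bm[[v]]), 0)
  structure(list(tree = tree, genotypes = geno, branch_mutations = bm,
                 score = fitch_score(tips, tree)),
            class = "clone_phylogeny")
}

#' Map SNVs to the branches where their state changes
#'
#' An SNV belongs to branch (parent, child) iff its reconstructed state
#' differs between the two nodes; with homoplasy one SNV can map to several
#' branches.
#'
#' @param tree an `rtree`
#' @param genotypes node genotype matrix from [reconstruct_ancestral()]
#' @return list indexed by node id: SNV ids (colnames of `genotypes`) mapped
#'   to the branch above that node; empty character vector at the root.
#' @export
map_mutations_to_branches <- function(tree, genotypes) {
  snvs <- colnames(genotypes)
  lapply(seq_len(rtree_n(tree)), function(v) {
    p <- tree$parent[v]
    if (p == 0L) return(character(0))
    snvs[genotypes[v, ] != genotypes[p, ]]
  })
}

#' Contract a clone phylogeny into a mutational tree
#'
#' Nodes of the mutational tree are groups of mutations that occurred on the
#' same branch of the clone phylogeny; zero-mutation branches are contracted
#' (their children reattach to the nearest mutation-bearing ancestor group).
#' Groups are numbered G1, G2, ... in preorder for stable output. Driver
#' mutations are placed on the group containing their SNV; drivers whose SNV
#' maps to no branch are reported unplaced.
#'
#' @param cp a `clone_phylogeny`
#' @param drivers optional driver data.frame (snv_id, gene, label)
#' @return a `mutation_tree`: `groups` data.frame (id, node, count, clones),
#'   `members` (list of SNV ids), `group_parent` (0 = attached at germline),
#'   `depth` (preorder rank), `drivers` (placements, with NA group when
#'   unplaced).
#' @export
build_mutation_tree <- function(cp, drivers = NULL) {
  tree <- cp$tree
  bm <- cp$branch_mutations
  pre <- rtree_preorder(tree)
  kids <- rtree_children(tree)
  # nearest mutation-bearing ancestor group for each node (0 = none/germline)
  node_group <- integer(rtree_n(tree))
  gid <- 0L
  group_node <- integer(0)
  group_parent <- integer(0)
  for (v in pre) {
    p <- tree$parent[v]
    up <- if (p == 0L) 0L else node_group[p]
    if (length(bm[[v]]) > 0) {
      gid <- gid + 1L
      group_node <- c(group_node, v)
      group_parent <- c(group_parent, up)
      node_group[v] <- gid
    } else {
      node_group[v] <- up
    }
  }
  ids <- paste0("G", seq_len(gid))
  members <- lapply(group_node, function(v) bm[[v]])
  # clones (tip labels) below each group's branch — used for display
  tips <- rtree_tips(tree)
  below <- function(v) {
    out <- character(0); stack <- v
    while (length(stack)) {
      x <- stack[1]; stack <- stack[-1]
      if (x %in% tips) out <- c(out, tree$label[x])
      stack <- c(stack, kids[[x]])
    }
    out
  }
  groups <- data.frame(id = ids, node = group_node,
                       count = vapply(members, length, 0L),
                       clones = vapply(group_node, function(v)
                         paste(sort(below(v)), collapse = ","), ""),
                       stringsAsFactors = FALSE)
  placed <- NULL
  if (!is.null(drivers) && nrow(drivers) > 0) {
    grp <- vapply(drivers$snv_id, function(s) {
      hit <- which(vapply(members, function(m) s %in% m, TRUE))
      if (length(hit)) ids[hit[1]] else NA_character_
    }, "")
    placed <- cbind(drivers, group = unname(grp), stringsAsFactors = FALSE)
  }
  structure(list(groups = groups, members = members,
                 group_parent = group_parent,
                 depth = seq_len(gid), drivers = placed),
            class = "mutation_tree")
}
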