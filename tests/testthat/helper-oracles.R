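# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force / enumeration, staying independent of the code
# paths they check.

# minimum number of state changes of binary tip states on a rooted tree,
# by exhaustive enumeration of internal-node labelings (root fixed to 0 when
# `root_zero`); tree is an rtree-like list(parent, label)
oracle_min_changes <- function(parent, tip_states, root_zero = TRUE) {
  n <- length(parent)
  root <- which(parent == 0L)
  is_tip <- !(seq_len(n) %in% parent)
  free <- which(!is_tip & seq_len(n) != root)
  states <- integer(n)
  states[is_tip] <- tip_states
  states[root] <- 0L
  if (!length(free)) {
    return(sum(states[parent > 0] != states[parent[parent > 0]]))
  }
  best <- Inf
  grid <- expand.grid(rep(list(0:1), length(free)))
  for (r in seq_len(nrow(grid))) {
    states[free] <- as.integer(grid[r, ])
    if (!root_zero) for (rs in 0:1) {
      states[root] <- rs
      ch <- sum(states[parent > 0] != states[parent[parent > 0]])
      best <- min(best, ch)
    } else {
      states[root] <- 0L
      ch <- sum(states[parent > 0] != states[parent[parent > 0]])
      best <- min(best, ch)
    }
  }
  best
}

# grid search over the probability simplex (step h) for the constrained
# least-squares refit; returns the best activity vector found
oracle_grid_simplex <- function(C, s, h = 0.01) {
  k <- ncol(C)
  stopifnot(k <= 3)
  steps <- seq(0, 1, by = h)
  best <- NULL; best_v <- Inf
  if (k == 2) {
    for (a in steps) {
      v <- sum((C %*% c(a, 1 - a) - s)^2)
      if (v < best_v) { best_v <- v; best <- c(a, 1 - a) }
    }
  } else {
    for (a in steps) for (b in steps[steps <= 1 - a + 1e-12]) {
      v <- sum((C %*% c(a, b, 1 - a - b) - s)^2)
      if (v < best_v) { best_v <- v; best <- c(a, b, 1 - a - b) }
    }
  }
  list(activities = best, value = best_v)
}

# exact site-marginals on a leaf-labeled tree by enumerating every labeling
# of the non-leaf nodes; potential: 1 if branch endpoints agree else p_mig;
# uniform root prior
oracle_site_marginals <- function(parent, leaf_site, K, p_mig) {
  n <- length(parent)
  free <- which(is.na(leaf_site))
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), length(free))))
  R <- nrow(grid)
  S <- matrix(rep(leaf_site, each = R), R, n)
  S[, free] <- grid
  mism <- matrix(0L, R, 1)
  for (v in which(parent > 0))
    mism <- mism + (S[, v] != S[, parent[v]])
  w <- p_mig^as.numeric(mism)
  marg <- matrix(0, n, K)
  for (v in seq_len(n)) for (k in seq_len(K))
    marg[v, k] <- sum(w[S[, v] == k])
  marg / rowSums(marg)
}

# random observation-tree-like structure for enumeration tests: a rooted
# binary tree with `n_leaves` site-labeled leaves
random_obs_tree <- function(n_leaves, n_sites, seed) {
  set.seed(seed)
  phy <- ape::rtree(n_leaves)
  tr <- cloneflow:::phylo_to_rtree(phy)
  leaf_site <- rep(NA_character_, length(tr$parent))
  sites <- paste0("Site", seq_len(n_sites))
  tips <- cloneflow:::rtree_tips(tr)
  leaf_site[tips] <- sample(sites, length(tips), TRUE)
  structure(list(tree = tr, leaf_site = leaf_site,
                 site_levels = sites), class = "observation_tree")
}

# independent Sankoff: minimum number of discordant branches given leaf sites
oracle_sankoff <- function(parent, leaf_site, K) {
  n <- length(parent)
  kids <- vector("list", n)
  for (v in which(parent > 0)) kids[[parent[v]]] <- c(kids[[parent[v]]], v)
  cost <- matrix(0, n, K)
  for (v in which(!is.na(leaf_site)))
    cost[v, ] <- ifelse(seq_len(K) == leaf_site[v], 0, Inf)
  post <- rev(order(vapply(seq_len(n), function(v) {   # depth-based postorder
    d <- 0L; while (parent[v] > 0L) { v <- parent[v]; d <- d + 1L }; d
  }, 0L)))
  for (v in post) for (c in kids[[v]])
    cost[v, ] <- cost[v, ] + vapply(seq_len(K), function(a)
      min(cost[c, ] + as.numeric(seq_len(K) != a)), 0)
  min(cost[which(parent == 0L), ])
}

# random additive distance matrix from a random unrooted tree; returns both
random_additive_case <- function(ntips, seed) {
  set.seed(seed)
  phy <- ape::rtree(ntips, rooted = FALSE,
                    br = function(n) stats::runif(n, 0.2, 1.5))
  phy$tip.label <- paste0("t", seq_len(ntips))
  D <- cophenetic(phy)
  D <- D[phy$tip.label, phy$tip.label]
  list(phy = phy, D = D)
}

# node ids on the path from the i-th tip (row order of truth$M) to the root
path_to_root <- function(tr, i) {
  v <- cloneflow:::rtree_tips(tr)[i]
  out <- integer(0)
  while (tr$parent[v] > 0L) { out <- c(out, v); v <- tr$parent[v] }
  out
}

# rooted-topology fingerprint: the set of tip-label clades, one per node
clade_set <- function(tr) {
  kids <- cloneflow:::rtree_children(tr)
  tips <- cloneflow:::rtree_tips(tr)
  below <- function(v) {
    if (v %in% tips) return(tr$label[v])
    sort(unlist(lapply(kids[[v]], below)))
  }
  out <- vapply(seq_along(tr$parent), function(v)
    paste(below(v), collapse = "|"), "")
  unique(out)
}

# small well-formed profile fixture built in code
toy_profile <- function(n_samples = 4) {
  snv <- paste0("s", 1:6)
  ref <- c("C", "C", "T", "G", "A", "C")
  alt <- c("A", "T", "G", "T", "C", "G")
  ctx <- c("ACA", "TCT", "ATG", "TGT", "CAG", "GCC")
  alt_c <- matrix(10L, 6, n_samples)
  ref_c <- matrix(90L, 6, n_samples)
  colnames(alt_c) <- colnames(ref_c) <- paste0("S", seq_len(n_samples))
  cloneflow:::new_mutation_profile(snv, ref, alt, ctx, ref_c, alt_c)
}

write_toy_profile_file <- function(path, n_samples = 4) {
  write_mutation_profile(toy_profile(n_samples), path)
}
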