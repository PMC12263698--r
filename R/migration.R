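# Metastatic migration inference: each clone tip of the phylogeny is expanded
# into one leaf per tumor sample where the clone is present; anatomical sites
# are then inferred at ancestral nodes by exact sum-product (marginals) and
# max-product (MAP) message passing under a pairwise model where a branch
# whose endpoints disagree is penalized by a migration probability p_mig.

#' Expand clone tips into per-sample observation leaves
#'
#' A clone present (frequency > `presence_threshold`) in k samples becomes an
#' internal node with k zero-length leaves, one per sample, each labeled with
#' that sample's anatomical site.
#'
#' @param cp a `clone_phylogeny`
#' @param f clone frequency matrix (samples x clones)
#' @param sites named character vector mapping sample name -> site name
#' @param presence_threshold minimum frequency counted as presence
#' @return an `observation_tree`: list with `tree` (rtree; expansion branches
#'   have length 0), `leaf_site` (site per node, NA for non-leaves), and
#'   `site_levels` (unique sites in first-appearance order of `sites`).
#' @export
expand_tips <- function(cp, f, sites, presence_threshold = 0.02) {
  tree <- cp$tree
  stopifnot(all(rownames(f) %in% names(sites)))
  parent <- tree$parent; label <- tree$label; len <- tree$length
  leaf_site <- rep(NA_character_, length(parent))
  for (tip in rtree_tips(tree)) {
    clone <- tree$label[tip]
    if (!clone %in% colnames(f)) next
    present <- rownames(f)[f[, clone] > presence_threshold]
    if (length(present) == 0)
      stop("clone present in no sample: ", clone)
    for (s in present) {
      parent <- c(parent, tip)
      label <- c(label, paste0(clone, "@", s))
      len <- c(len, 0)
      leaf_site <- c(leaf_site, unname(sites[s]))
    }
  }
  # a clone observed at exactly one site is located there: the sampled cells
  # are the clone, so its tip node is clamped directly. Clones spanning
  # several sites keep a free tip (their location is genuinely uncertain and
  # zero-mutation migrations to the observation leaves may be inferred).
  for (tip in rtree_tips(tree)) {
    clone <- tree$label[tip]
    if (!clone %in% colnames(f)) next
    present <- rownames(f)[f[, clone] > presence_threshold]
    clone_sites <- unique(unname(sites[present]))
    if (length(clone_sites) == 1) leaf_site[tip] <- clone_sites
  }
  tr <- new_rtree(parent, label, len)
  structure(list(tree = tr, leaf_site = leaf_site,
                 site_levels = unique(unname(sites[rownames(f)]))),
            class = "observation_tree")
}

# Branch potential: psi(a, b) = 1 if a == b else p_mig. The germline root
# has a uniform prior over sites.
site_potential <- function(K, p_mig) {
  psi <- matrix(p_mig, K, K)
  diag(psi) <- 1
  psi
}

#' Posterior anatomical locations of ancestral clones
#'
#' Exact marginal posteriors at every node via two-pass sum-product (belief
#' propagation on the tree), and a MAP site labeling via max-product with
#' deterministic tie-breaking in site order (first-appearance order of the
#' input samples). Leaves are clamped to their observed sites.
#'
#' @param obs an `observation_tree`
#' @param p_mig migration probability per branch, in (0, 1); default 0.1
#' @return a `location_posterior`: `marginals` (nodes x sites, rows sum to
#'   1), `map` (site per node), `ambiguous` (nodes whose MAP was a tie).
#' @export
infer_locations <- function(obs, p_mig = 0.1) {
  stopifnot(p_mig > 0, p_mig < 1)
  tree <- obs$tree
  sites <- obs$site_levels
  K <- length(sites)
  n <- rtree_n(tree)
  psi <- site_potential(K, p_mig)
  kids <- rtree_children(tree)
  leaf_like <- matrix(1, n, K)
  for (v in which(!is.na(obs$leaf_site)))
    leaf_like[v, ] <- as.numeric(sites == obs$leaf_site[v])
  # upward sum-product: mu_up[v, a] = message from subtree(v) to parent about
  # parent state a; beta[v, b] = product of children messages * own evidence
  beta <- leaf_like
  mu_up <- matrix(1, n, K)
  post_ord <- rtree_postorder(tree)
  for (v in post_ord) {
    for (c in kids[[v]]) beta[v, ] <- beta[v, ] * mu_up[c, ]
    beta[v, ] <- beta[v, ] / max(beta[v, ])        # guard underflow
    mu_up[v, ] <- as.numeric(psi %*% beta[v, ])
  }
  # downward: alpha[v, b] = message arriving at v from above
  root <- rtree_root(tree)
  alpha <- matrix(1, n, K)
  for (v in rtree_preorder(tree)) {
    if (v == root) { alpha[v, ] <- 1 / K; next }
    p <- tree$parent[v]
    inc <- alpha[p, ] * beta[p, ] / pmax(mu_up[v, ], 1e-300)
    alpha[v, ] <- as.numeric(t(psi) %*% inc)
    alpha[v, ] <- alpha[v, ] / max(alpha[v, ])
  }
  marg <- alpha * beta
  marg <- marg / rowSums(marg)
  colnames(marg) <- sites
  rownames(marg) <- tree$label
  # max-product MAP with back-pointers; ties -> lowest site index
  delta <- log(leaf_like + 1e-300)
  argmax <- array(0L, c(n, K))
  lpsi <- log(psi)
  for (v in post_ord) {
    for (c in kids[[v]]) {
      # message from child c: max_b lpsi[a,b] + delta[c,b]
      m <- sweep(lpsi, 2, delta[c, ], "+")
      best <- apply(m, 1, which.max)
      delta[v, ] <- delta[v, ] + m[cbind(seq_len(K), best)]
      argmax[c, ] <- best
    }
  }
  map <- integer(n)
  map[root] <- which.max(delta[root, ])
  amb <- logical(n)
  amb[root] <- sum(abs(delta[root, ] - max(delta[root, ])) < 1e-9) > 1
  for (v in rtree_preorder(tree)) {
    if (v == root) next
    map[v] <- argmax[v, map[tree$parent[v]]]
    cand <- lpsi[map[tree$parent[v]], ] + delta[v, ]
    amb[v] <- sum(abs(cand - max(cand)) < 1e-9) > 1
  }
  structure(list(marginals = marg, map = stats::setNames(sites[map], tree$label),
                 ambiguous = stats::setNames(amb, tree$label),
                 p_mig = p_mig, sites = sites),
            class = "location_posterior")
}

#' Build the metastatic cell-migration graph
#'
#' One directed edge per phylogeny branch whose endpoint MAP sites differ,
#' annotated with the branch's mutation count (0 is allowed and flagged: a
#' migration without associated mutations carries little directional
#' information and needs careful inspection). Parallel same-direction edges
#' are merged with their counts listed. A "Primary" pseudo-node attaches to
#' the root's MAP site; when the root posterior is multimodal every site with
#' posterior above `origin_cut` is attached and flagged.
#'
#' @param obs an `observation_tree`
#' @param loc a `location_posterior` from [infer_locations()]
#' @param origin_cut root-posterior mass needed to report an origin site
#' @return a `migration_graph`: data.frame `edges` (from, to, counts,
#'   n_events, low_confidence), `origin` (sites), `multimodal_origin`.
#' @export
build_migration_graph <- function(obs, loc, origin_cut = 0.3) {
  tree <- obs$tree
  root <- rtree_root(tree)
  map <- loc$map
  from <- to <- character(0); cnt <- numeric(0); amb <- logical(0)
  for (v in seq_len(rtree_n(tree))) {
    p <- tree$parent[v]
    if (p == 0L) next
    if (map[p] != map[v]) {
      from <- c(from, map[p]); to <- c(to, map[v])
      l <- tree$length[v]
      cnt <- c(cnt, ifelse(is.na(l), 0, l))
      amb <- c(amb, loc$ambiguous[v] || loc$ambiguous[p])
    }
  }
  key <- paste(from, to, sep = "->")
  edges <- data.frame(from = character(0), to = character(0),
                      counts = character(0), n_events = integer(0),
                      low_confidence = logical(0), stringsAsFactors = FALSE)
  for (k in unique(key)) {
    i <- which(key == k)
    edges <- rbind(edges, data.frame(
      from = from[i[1]], to = to[i[1]],
      counts = paste(sort(cnt[i], decreasing = TRUE), collapse = ","),
      n_events = length(i),
      low_confidence = any(cnt[i] == 0) || any(amb[i]),
      stringsAsFactors = FALSE))
  }
  rootmarg <- loc$marginals[root, ]
  origin <- names(rootmarg)[rootmarg > origin_cut]
  if (length(origin) == 0) origin <- unname(loc$map[root])
  structure(list(edges = edges, origin = origin,
                 multimodal_origin = length(origin) > 1,
                 sites = loc$sites),
            class = "migration_graph")
}

# Sankoff minimum-migration count (small parsimony on sites, unit cost for
# site changes); used as the p_mig -> 0 limit of the MAP labeling.
sankoff_migrations <- function(obs) {
  tree <- obs$tree
  sites <- obs$site_levels
  K <- length(sites)
  n <- rtree_n(tree)
  kids <- rtree_children(tree)
  cost <- matrix(0, n, K)
  for (v in which(!is.na(obs$leaf_site)))
    cost[v, ] <- ifelse(sites == obs$leaf_site[v], 0, Inf)
  for (v in rtree_postorder(tree)) {
    for (c in kids[[v]]) {
      # min over child state b of cost[c,b] + (a != b)
      child_contrib <- vapply(seq_len(K), function(a)
        min(cost[c, ] + as.numeric(seq_len(K) != a)), 0)
      cost[v, ] <- cost[v, ] + child_contrib
    }
  }
  min(cost[rtree_root(tree), ])
}
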