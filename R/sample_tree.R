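# Clone-composition distances between tumor samples on the clone phylogeny
# (abundance-weighted UniFrac and mean nearest taxon distance) and a
# neighbor-joining sample tree.

# fraction of each sample's clone abundance descending from every branch
branch_abundance <- function(cp, f_norm) {
  tree <- cp$tree
  tips <- rtree_tips(tree)
  n <- rtree_n(tree)
  p <- matrix(0, n, nrow(f_norm))              # nodes x samples
  tip_of <- stats::setNames(tips, tree$label[tips])
  for (cl in colnames(f_norm)) if (cl %in% names(tip_of))
    p[tip_of[[cl]], ] <- f_norm[, cl]
  for (v in rtree_postorder(tree)) {
    u <- tree$parent[v]
    if (u > 0L) p[u, ] <- p[u, ] + p[v, ]
  }
  p
}

#' Weighted UniFrac distance between two samples' clone compositions
#'
#' \deqn{d = \frac{\sum_b L_b\,|p_A(b) - p_B(b)|}{\sum_b L_b\,(p_A(b) + p_B(b))}}
#' where the sum runs over branches of the clone phylogeny, \eqn{L_b} is the
#' branch length (mutation count) and \eqn{p_X(b)} the fraction of sample
#' X's clone abundance descending from the branch. Frequencies are first
#' renormalized over clones (the normal-cell fraction is ignored: distances
#' reflect tumor composition only). Result lies in [0, 1]: 0 for identical
#' compositions, 1 for compositions on disjoint subtrees.
#'
#' @param cp a `clone_phylogeny`
#' @param f_A,f_B named clone-frequency vectors for the two samples
#' @return the distance (scalar)
#' @export
weighted_unifrac <- function(cp, f_A, f_B) {
  if (sum(f_A) <= 0 || sum(f_B) <= 0)
    stop("weighted UniFrac undefined for a sample with no tumor clones")
  f <- rbind(A = f_A / sum(f_A), B = f_B / sum(f_B))
  colnames(f) <- names(f_A)
  p <- branch_abundance(cp, f)
  L <- ifelse(is.na(cp$tree$length), 0, cp$tree$length)
  num <- sum(L * abs(p[, 1] - p[, 2]))
  den <- sum(L * (p[, 1] + p[, 2]))
  if (den == 0) 0 else num / den
}

#' Mean nearest taxon distance between two samples' clone sets
#'
#' Mean over clones present in A of the patristic distance to the nearest
#' clone present in B, averaged symmetrically with the B-to-A direction.
#'
#' @param cp a `clone_phylogeny`
#' @param present_A,present_B character vectors of clone names
#' @return the distance (scalar)
#' @export
mntd <- function(cp, present_A, present_B) {
  if (length(present_A) == 0 || length(present_B) == 0)
    stop("MNTD undefined for an empty clone set")
  D <- rtree_patristic(cp$tree)
  stopifnot(all(c(present_A, present_B) %in% rownames(D)))
  ab <- mean(vapply(present_A, function(a) min(D[a, present_B]), 0))
  ba <- mean(vapply(present_B, function(b) min(D[b, present_A]), 0))
  (ab + ba) / 2
}

#' Pairwise sample distance matrix
#'
#' @param cp a `clone_phylogeny`
#' @param f clone frequency matrix (samples x clones)
#' @param metric `"unifrac"` (abundance-weighted, default) or `"mntd"`
#'   (presence/absence, threshold `presence_threshold`)
#' @param presence_threshold presence cut for the MNTD metric
#' @return symmetric distance matrix with samples as dimnames; samples whose
#'   frequencies are all zero are excluded with a warning.
#' @export
sample_distances <- function(cp, f, metric = c("unifrac", "mntd"),
                             presence_threshold = 0.02) {
  metric <- match.arg(metric)
  keep <- rowSums(f) > 0
  if (!all(keep)) {
    warning("excluding sample(s) with no tumor clones: ",
            paste(rownames(f)[!keep], collapse = ", "))
    f <- f[keep, , drop = FALSE]
  }
  n <- nrow(f)
  D <- matrix(0, n, n, dimnames = list(rownames(f), rownames(f)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    d <- if (metric == "unifrac")
      weighted_unifrac(cp, f[i, ], f[j, ])
    else
      mntd(cp, colnames(f)[f[i, ] > presence_threshold],
           colnames(f)[f[j, ] > presence_threshold])
    D[i, j] <- D[j, i] <- d
  }
  attr(D, "metric") <- metric
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion. Ties in Q are
#' broken deterministically by the lowest index pair; negative branch
#' lengths are clamped to 0 with a warning. With fewer than three taxa a
#' degenerate two-tip tree is returned with a warning.
#'
#' @param D symmetric distance matrix with taxon dimnames
#' @return an unrooted [ape::phylo] tree with the taxa at its tips
#' @export
nj_tree <- function(D) {
  labs <- rownames(D)
  n <- length(labs)
  if (n < 3) {
    warning("fewer than 3 taxa: returning degenerate 2-tip tree")
    return(structure(list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                          edge.length = c(D[1, 2] / 2, D[1, 2] / 2),
                          tip.label = labs, Nnode = 1L),
                     class = "phylo", order = "cladewise"))
  }
  # active nodes carry ape ids: tips 1..n, internals n+1, n+2, ...
  ids <- seq_len(n)
  next_id <- n + 1L
  edges <- matrix(0L, 0, 2)
  elen <- numeric(0)
  Dm <- D
  clamped <- FALSE
  while (length(ids) > 3) {
    m <- length(ids)
    tot <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(tot, tot, "+")
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[1]; j <- best[2]
    li <- Dm[i, j] / 2 + (tot[i] - tot[j]) / (2 * (m - 2))
    lj <- Dm[i, j] - li
    if (li < 0 || lj < 0) clamped <- TRUE
    li <- max(li, 0); lj <- max(lj, 0)
    edges <- rbind(edges, c(next_id, ids[i]), c(next_id, ids[j]))
    elen <- c(elen, li, lj)
    dnew <- (Dm[i, ] + Dm[j, ] - Dm[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    ids <- c(ids[keep], next_id)
    next_id <- next_id + 1L
  }
  # final 3-taxon star: closed-form branch lengths
  d12 <- Dm[1, 2]; d13 <- Dm[1, 3]; d23 <- Dm[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  if (any(c(l1, l2, l3) < 0)) clamped <- TRUE
  edges <- rbind(edges, c(next_id, ids[1]), c(next_id, ids[2]),
                 c(next_id, ids[3]))
  elen <- c(elen, max(l1, 0), max(l2, 0), max(l3, 0))
  if (clamped) warning("negative NJ branch length(s) clamped to 0")
  # renumber internals so the final join is the ape root (n+1)
  ninternal <- next_id - n
  remap <- c(seq_len(n), rev(n + seq_len(ninternal)))
  edges <- matrix(remap[edges], ncol = 2)
  structure(list(edge = edges, edge.length = elen, tip.label = labs,
                 Nnode = ninternal),
            class = "phylo")
}
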