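# Ground-truth patient simulator. Generates a random clone tree, per-branch
# mutations drawn from known signature mixtures, sparse per-sample clone
# compositions, a migration history over anatomical sites, and binomial read
# counts, so every pipeline stage can be tested without external data.

#' Build a small synthetic signature catalog
#'
#' Concentrated, well-separated probability vectors over the 96 SBS channels
#' (each signature puts most mass on its own block of channels), plus an
#' optional flat column to exercise the known flat-signature confounding.
#'
#' @param n_signatures number of concentrated signatures (default 3)
#' @param flat add one near-uniform column (default FALSE)
#' @param seed integer seed
#' @return a `signature_catalog` with names `SigA`, `SigB`, ... (`SigFlat`)
#' @export
simulate_catalog <- function(n_signatures = 3, flat = FALSE, seed = 1) {
  set.seed(seed)
  canon <- sbs_channels()
  cols <- matrix(0, 96, n_signatures)
  for (k in seq_len(n_signatures)) {
    w <- stats::rgamma(96, 0.08)
    block <- ((k - 1) * floor(96 / n_signatures)) + seq_len(floor(96 / n_signatures))
    w[block] <- w[block] + stats::rgamma(length(block), 2)
    cols[, k] <- w / sum(w)
  }
  colnames(cols) <- paste0("Sig", LETTERS[seq_len(n_signatures)])
  if (flat) {
    u <- stats::rgamma(96, 50); u <- u / sum(u)
    cols <- cbind(cols, SigFlat = u)
  }
  rownames(cols) <- canon
  new_signature_catalog(cols)
}

channel_to_mutation <- function(channel, strand_flip) {
  ref <- substr(channel, 3, 3)
  alt <- substr(channel, 5, 5)
  ctx <- paste0(substr(channel, 1, 1), ref, substr(channel, 7, 7))
  if (strand_flip) {
    comp <- function(b) chartr("ACGT", "TGCA", b)
    list(ref = comp(ref), alt = comp(alt), ctx = revcomp(ctx))
  } else list(ref = ref, alt = alt, ctx = ctx)
}

# random rooted clone tree (Yule shape): start with one lineage, repeatedly
# split a uniformly chosen tip until n_clones tips exist
yule_clone_tree <- function(n_clones) {
  parent <- c(0L, 1L)                  # germline root + first lineage
  is_tip <- c(FALSE, TRUE)
  while (sum(is_tip) < n_clones) {
    tips <- which(is_tip)
    v <- if (length(tips) == 1) tips else sample(tips, 1)
    parent <- c(parent, v, v)
    is_tip[v] <- FALSE
    is_tip <- c(is_tip, TRUE, TRUE)
  }
  labs <- character(length(parent))
  labs[1] <- GERMLINE
  labs[is_tip] <- paste0("Clone", seq_len(sum(is_tip)))
  inner <- which(!is_tip)[-1]
  labs[inner] <- paste0("N", inner)
  new_rtree(parent, labs)
}

#' Simulate a patient with known ground truth
#'
#' Draws a Yule-shaped clone tree; assigns each branch a mutation count and a
#' signature mixture and samples mutation channels from it (strand chosen at
#' random); builds sparse per-sample clone compositions in which every clone
#' is the dominant ("resident") clone of at least one sample and co-occurring
#' clones prefer the resident's ancestors (the locally-spreading pattern seen
#' in real multi-region data); evolves anatomical sites down the tree with
#' migration probability `p_true_migration`; and emits binomial read counts
#' at the given depth under V = f M / 2.
#'
#' @param n_clones,n_samples,n_sites problem dimensions (defaults 5, 6, 3)
#' @param n_snvs total SNVs, partitioned over branches (default 200)
#' @param depth mean sequencing depth per site (default 1000); `Inf` gives
#'   noiseless counts at an effective depth of 1e7
#' @param catalog a `signature_catalog` for channel sampling (default: a
#'   3-signature synthetic catalog from the same seed)
#' @param branch_mixtures optional list mapping branch index to a named
#'   activity vector; default: each branch mixes two adjacent catalog columns
#' @param p_true_migration per-branch probability of a site change (0.2)
#' @param dirichlet_conc concentration for sample compositions (1.5)
#' @param n_drivers SNVs labeled as drivers (default 5)
#' @param homoplasy_rate fraction of SNVs additionally placed on a second
#'   random branch (default 0: perfect phylogeny)
#' @param seed integer seed (mandatory; all randomness derives from it)
#' @return list with `profile` (a `mutation_profile`), `drivers`
#'   (data.frame), `catalog`, `sites` (sample -> site map) and `truth`
#'   (tree, M, f, branch mutation sets and mixtures, node sites, migration
#'   edges).
#' @export
simulate_patient <- function(n_clones = 5, n_samples = 6, n_sites = 3,
                             n_snvs = 200, depth = 1000,
                             catalog = NULL, branch_mixtures = NULL,
                             p_true_migration = 0.2, dirichlet_conc = 1.5,
                             n_drivers = 5, homoplasy_rate = 0,
                             seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(n_clones >= 2, n_samples >= 4, n_sites >= 1, n_snvs >= n_clones)
  set.seed(seed)
  if (is.null(catalog)) catalog <- simulate_catalog(seed = seed)
  tree <- yule_clone_tree(n_clones)
  nodes <- rtree_n(tree)
  root <- rtree_root(tree)
  branches <- setdiff(seq_len(nodes), root)
  # mutation counts per branch: at least 2, multinomial around equal shares
  base <- rep(2L, length(branches))
  extra <- stats::rmultinom(1, n_snvs - 2L * length(branches),
                            rep(1, length(branches)))[, 1]
  n_mut <- base + extra
  # signature mixtures per branch
  sig_names <- catalog$signature_names
  if (is.null(branch_mixtures)) {
    branch_mixtures <- lapply(seq_along(branches), function(b) {
      k <- 1 + (b - 1) %% max(1, length(sig_names) - 1)
      w <- stats::runif(1, 0.55, 0.85)
      stats::setNames(c(w, 1 - w), sig_names[c(k, k + 1)])
    })
  }
  # draw mutations
  snv_ids <- paste0("s", seq_len(sum(n_mut)))
  ref <- alt <- ctx <- character(sum(n_mut))
  branch_of <- integer(sum(n_mut))
  pos <- 0L
  canon <- sbs_channels()
  for (b in seq_along(branches)) {
    mix <- branch_mixtures[[b]]
    p <- as.numeric(catalog$probs[, names(mix), drop = FALSE] %*% mix)
    ch <- sample(canon, n_mut[b], replace = TRUE, prob = p)
    for (m in seq_len(n_mut[b])) {
      mut <- channel_to_mutation(ch[m], stats::runif(1) < 0.5)
      pos <- pos + 1L
      ref[pos] <- mut$ref; alt[pos] <- mut$alt; ctx[pos] <- mut$ctx
      branch_of[pos] <- branches[b]
    }
  }
  # optional homoplasy: re-place some SNVs on a second branch
  branch_sets <- lapply(seq_len(nodes), function(v) snv_ids[branch_of == v])
  if (homoplasy_rate > 0) {
    extra_ids <- sample(snv_ids, ceiling(homoplasy_rate * length(snv_ids)))
    for (s in extra_ids) {
      b2 <- sample(branches, 1)
      branch_sets[[b2]] <- union(branch_sets[[b2]], s)
    }
  }
  # genotypes: union of branch sets along the root-to-node path (presence
  # toggles once per placement; with homoplasy a second placement only adds)
  geno <- matrix(0L, nodes, length(snv_ids),
                 dimnames = list(tree$label, snv_ids))
  for (v in rtree_preorder(tree)) {
    if (v == root) next
    g <- geno[tree$parent[v], ]
    g[match(branch_sets[[v]], snv_ids)] <- 1L
    geno[v, ] <- g
  }
  tips <- rtree_tips(tree)
  M <- geno[tips, , drop = FALSE]
  clone_names <- tree$label[tips]
  # migration history first: single-source (monoclonal) seeding — each
  # metastatic site is colonized exactly once, by one migration into a
  # not-yet-used site; a seeded site must retain at least one clone tip
  # (only sampled sites can enter the analysis at all). Histories violating
  # that observability are redrawn.
  site_names <- paste0("Site", seq_len(n_sites))
  draw_history <- function() {
    node_site <- character(nodes)
    node_site[root] <- site_names[1]
    mig <- data.frame(from = character(0), to = character(0),
                      branch = integer(0), stringsAsFactors = FALSE)
    unused <- site_names[-1]
    for (v in rtree_preorder(tree)) {
      if (v == root) next
      p_site <- node_site[tree$parent[v]]
      if (length(unused) > 0 && stats::runif(1) < p_true_migration) {
        node_site[v] <- unused[1]
        unused <- unused[-1]
        mig <- rbind(mig, data.frame(from = p_site, to = node_site[v],
                                     branch = v, stringsAsFactors = FALSE))
      } else node_site[v] <- p_site
    }
    list(node_site = node_site, mig = mig)
  }
  # Accept a history only if (i) every seeded site retains >= 1 clone tip
  # (unsampled sites cannot enter an analysis) and (ii) the history is
  # identifiable: the tip sites admit a unique minimum-migration labeling,
  # which then necessarily equals the truth. Ambiguous histories (e.g. a
  # symmetric root) are redrawn — no inference could recover them and the
  # pipeline reports such ambiguity through posteriors instead.
  kids <- rtree_children(tree)
  count_optima <- function(tip_site) {
    K <- length(site_names)
    cost <- matrix(0, nodes, K); cnt <- matrix(1, nodes, K)
    for (i in seq_along(tips))
      cost[tips[i], ] <- ifelse(site_names == tip_site[i], 0, Inf)
    for (v in rtree_postorder(tree)) {
      for (c in kids[[v]]) {
        tot <- outer(rep(1, K), cost[c, ]) + (1 - diag(K))
        m <- apply(tot, 1, min)
        nb <- vapply(seq_len(K), function(a)
          sum(cnt[c, abs(tot[a, ] - m[a]) < 1e-9]), 0)
        cost[v, ] <- cost[v, ] + m
        cnt[v, ] <- cnt[v, ] * nb
      }
    }
    r <- rtree_root(tree)
    best <- min(cost[r, ])
    list(min = best, n = sum(cnt[r, abs(cost[r, ] - best) < 1e-9]))
  }
  hist <- draw_history()
  for (try in 1:200) {
    seeded <- unique(c(site_names[1], hist$mig$to))
    ts <- hist$node_site[tips]
    if (all(seeded %in% ts)) {
      opt <- count_optima(ts)
      if (opt$n == 1 && opt$min == nrow(hist$mig)) break
    }
    hist <- draw_history()
  }
  node_site <- hist$node_site
  mig_edges <- hist$mig
  tip_site <- node_site[tips]
  # sparse site-consistent compositions: every clone is the dominant
  # ("resident") clone of at least one sample; a sample is a physical biopsy
  # of the resident's anatomical site, so any co-occurring clone must live
  # at the same site (ancestors of the resident preferred)
  f <- matrix(0, n_samples, n_clones,
              dimnames = list(paste0("S", seq_len(n_samples)), clone_names))
  resident <- c(seq_len(n_clones),
                sample(seq_len(n_clones), max(0, n_samples - n_clones),
                       replace = TRUE))[seq_len(n_samples)]
  anc_of <- lapply(tips, function(v) {
    out <- integer(0)
    while (tree$parent[v] > 0L) { v <- tree$parent[v]; out <- c(out, v) }
    out
  })
  for (s in seq_len(n_samples)) {
    r <- resident[s]
    same_site <- setdiff(which(tip_site == tip_site[r]), r)
    is_anc <- vapply(same_site, function(k)
      tips[k] %in% anc_of[[r]] ||
        any(vapply(anc_of[[r]], function(a)
          all(geno[a, ] == M[k, ]), TRUE)), TRUE)
    pool <- c(same_site[is_anc], same_site[!is_anc])   # ancestors first
    n_extra <- min(sample(0:2, 1), length(pool))
    others <- if (n_extra > 0) pool[seq_len(n_extra)] else integer(0)
    members <- c(r, others)
    w <- stats::rgamma(length(members), dirichlet_conc)
    w[1] <- w[1] + 2 * dirichlet_conc          # resident dominates
    w <- w / sum(w)
    purity <- 1 - stats::runif(1, 0.1, 0.5)
    f[s, members] <- w * purity
  }
  # a sample reports the site it was taken from (= its resident clone's)
  sites <- stats::setNames(tip_site[resident], rownames(f))
  # read counts
  eff_depth <- if (is.infinite(depth)) 1e7 else depth
  Vtrue <- t(f %*% M) / 2                       # SNVs x samples
  dp <- matrix(stats::rpois(length(Vtrue), eff_depth), nrow(Vtrue))
  altc <- matrix(stats::rbinom(length(Vtrue), as.integer(dp), as.numeric(Vtrue)),
                 nrow(Vtrue))
  if (is.infinite(depth))
    altc <- matrix(as.integer(round(dp * Vtrue)), nrow(Vtrue))
  # guarantee every SNV is mutant somewhere (profile invariant); at default
  # depths a truly present SNV failing this is a astronomically rare event
  zero <- rowSums(altc) == 0
  if (any(zero)) {
    s_best <- apply(Vtrue[zero, , drop = FALSE], 1, which.max)
    altc[cbind(which(zero), s_best)] <- 1L
  }
  refc <- dp - altc
  dimnames(altc) <- dimnames(refc) <- list(snv_ids, rownames(f))
  profile <- new_mutation_profile(snv_ids, ref, alt, ctx, refc, altc)
  drv_ids <- sort(sample(snv_ids, min(n_drivers, length(snv_ids))))
  drivers <- data.frame(snv_id = drv_ids,
                        gene = paste0("GENE", seq_along(drv_ids)),
                        label = LETTERS[seq_along(drv_ids)],
                        stringsAsFactors = FALSE)
  truth <- list(tree = tree, newick = rtree_newick(tree), M = M, f = f,
                branch_sets = branch_sets, branch_mixtures = branch_mixtures,
                branch_nodes = branches, node_sites = stats::setNames(
                  node_site, tree$label),
                migration_edges = mig_edges, resident = resident)
  list(profile = profile, drivers = drivers, catalog = catalog,
       sites = sites, truth = truth)
}

#' Match inferred clones to truth and score recovery
#'
#' Greedy bipartite matching of inferred to true clone genotypes by Hamming
#' distance (each inferred clone used at most once; unmatched true clones are
#' compared against the all-zero genotype and frequency 0).
#'
#' @param M_true,f_true ground-truth genotype (clones x SNVs) and frequency
#'   (samples x clones) matrices
#' @param M_inf,f_inf inferred counterparts (SNV columns in the same order)
#' @return list with `genotype_accuracy` (mean per-entry agreement over true
#'   clones), `freq_rmse` (root-mean-square frequency error over the matched
#'   sample x clone entries) and `matching`.
#' @export
score_recovery <- function(M_true, f_true, M_inf, f_inf) {
  stopifnot(ncol(M_true) == ncol(M_inf))
  kT <- nrow(M_true); kI <- nrow(M_inf)
  Dh <- matrix(0L, kT, kI)
  for (i in seq_len(kT)) for (j in seq_len(kI))
    Dh[i, j] <- sum(M_true[i, ] != M_inf[j, ])
  match_of <- rep(NA_integer_, kT)
  used <- logical(kI)
  for (step in seq_len(min(kT, kI))) {
    Dm <- Dh
    Dm[!is.na(match_of), ] <- .Machine$integer.max
    Dm[, used] <- .Machine$integer.max
    ij <- which(Dm == min(Dm), arr.ind = TRUE)[1, ]
    match_of[ij[1]] <- ij[2]
    used[ij[2]] <- TRUE
  }
  acc <- mean(vapply(seq_len(kT), function(i) {
    if (is.na(match_of[i])) mean(M_true[i, ] == 0L)
    else mean(M_true[i, ] == M_inf[match_of[i], ])
  }, 0))
  sq <- vapply(seq_len(kT), function(i) {
    fi <- if (is.na(match_of[i])) numeric(nrow(f_true))
    else f_inf[rownames(f_true), match_of[i]]
    mean((f_true[, i] - fi)^2)
  }, 0)
  list(genotype_accuracy = acc, freq_rmse = sqrt(mean(sq)),
       matching = match_of)
}
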