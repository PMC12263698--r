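test_that("channel mapping strand-normalizes onto pyrimidine channels", {
  expect_equal(sbs_channel_of("C", "A", "ACA"), "A[C>A]A")
  # purine reference: (G,T,"TGT") is the reverse complement of (C,A,"ACA")
  expect_equal(sbs_channel_of("G", "T", "TGT"), "A[C>A]A")
  expect_equal(sbs_channel_of("A", "G", "CAG"), "C[T>C]G")
  sp <- spectrum_from_mutations(rep("C", 10), rep("A", 10), rep("ACA", 10))
  expect_equal(sum(sp), 10)
  expect_equal(unname(sp["A[C>A]A"]), 10L)
  expect_error(spectrum_from_mutations("C", "A", "ATA"), "")
})

test_that("refit recovers exact mixtures to high precision", {
  cat2 <- simulate_catalog(n_signatures = 3, seed = 2)
  C <- cat2$probs
  # pure signature
  fit <- refit_qp(C[, 1] * 1000, cat2)
  expect_equal(unname(fit$activities),
               c(1, 0, 0), tolerance = 1e-6)
  # noiseless 0.7/0.3 mixture
  s <- 0.7 * C[, 1] + 0.3 * C[, 2]
  fit <- refit_qp(s * 5000, cat2)
  expect_equal(unname(fit$activities[1:2]), c(0.7, 0.3), tolerance = 1e-6)
  expect_equal(sum(fit$activities), 1, tolerance = 1e-9)
  expect_gt(fit$fit_cosine, 0.999999)
  # empty spectrum flagged
  empty <- refit_qp(numeric(96), cat2)
  expect_true(empty$empty)
  expect_equal(sum(empty$activities), 0)
})

test_that("multinomial refits match the grid-search oracle within 0.1", {
  cat2 <- simulate_catalog(n_signatures = 2, seed = 3)
  C <- cat2$probs
  set.seed(21)
  for (rep in 1:5) {
    mix <- c(0.5, 0.5)
    counts <- stats::rmultinom(1, 500, C %*% mix)[, 1]
    fit <- refit_qp(counts, cat2)
    oracle <- oracle_grid_simplex(C, counts / sum(counts), h = 0.01)
    expect_lt(mean(abs(fit$activities - oracle$activities)), 0.1)
    expect_lt(mean(abs(fit$activities - mix)), 0.1)
  }
})

test_that("spurious-signature filtering behaves as documented", {
  cat3 <- simulate_catalog(n_signatures = 3, seed = 4)
  C <- cat3$probs
  s <- as.numeric(C %*% c(0.6, 0.4, 0)) * 2000
  res <- filter_spurious(s, cat3)
  # the zero-activity signature is always dropped
  expect_false(cat3$signature_names[3] %in% res$retained)
  expect_setequal(res$retained, cat3$signature_names[1:2])
  expect_gte(res$fit_cosine, res$full_cosine - 0.01)

  # two near-collinear columns: data from one of them keeps exactly one
  base <- as.numeric(C[, 1])
  twin <- 0.97 * base + 0.03 * (1 / 96)
  twin <- twin / sum(twin)
  cc <- cloneflow:::new_signature_catalog(
    cbind(SigX = base, SigY = twin, SigZ = as.numeric(C[, 2])),
    channels = rownames(C))
  res2 <- filter_spurious(base * 1000, cc)
  expect_equal(length(intersect(res2$retained, c("SigX", "SigY"))), 1)

  # epsilon 0: only fit-preserving drops are accepted
  res3 <- filter_spurious(s, cat3, epsilon_cos = 0)
  expect_true(all(cat3$signature_names[1:2] %in% res3$retained))
})

test_that("harmonization prunes isolated weak signatures only", {
  catF <- simulate_catalog(n_signatures = 3, seed = 6)
  # build a 3-group chain mutation tree by hand
  chain <- function() {
    M <- rbind(c1 = c(rep(1L, 40), rep(0L, 80)),
               c2 = c(rep(1L, 80), rep(0L, 40)),
               c3 = rep(1L, 120))
    colnames(M) <- paste0("s", 1:120)
    build_mutation_tree(clone_phylogeny(M))
  }
  mt <- chain()
  C <- catF$probs
  mixes <- list(c(0.8, 0.2, 0), c(0.75, 0.25, 0), c(0.7, 0.25, 0.05))
  mk_profile <- function(mixes) {
    set.seed(31)
    ref <- alt <- ctx <- character(0)
    canon <- sbs_channels()
    for (g in 1:3) {
      p <- as.numeric(C %*% mixes[[g]])
      ch <- sample(canon, 40, TRUE, prob = p)
      for (x in ch) {
        m <- cloneflow:::channel_to_mutation(x, FALSE)
        ref <- c(ref, m$ref); alt <- c(alt, m$alt); ctx <- c(ctx, m$ctx)
      }
    }
    snvs <- paste0("s", 1:120)
    altc <- matrix(50L, 120, 4, dimnames = list(snvs, paste0("S", 1:4)))
    cloneflow:::new_mutation_profile(snvs, ref, alt, ctx, altc * 2L, altc)
  }
  prof <- mk_profile(mixes)
  bs <- fit_branch_signatures(mt, prof, catF, min_branch_mutations = 10)
  # identical retained sets everywhere are a fixed point: rerun changes nothing
  bs2 <- fit_branch_signatures(mt, prof, catF, min_branch_mutations = 10)
  expect_identical(branch_activity_table(bs), branch_activity_table(bs2))
  # activities on the simplex, cosine surfaced for every fitted group
  tab <- branch_activity_table(bs)
  for (g in unique(tab$group))
    expect_equal(sum(tab$activity[tab$group == g]), 1, tolerance = 1e-6)
  expect_true(all(is.finite(tab$fit_cosine)))
})

test_that("isolated weak signature is removed, strong one kept", {
  catF <- simulate_catalog(n_signatures = 3, seed = 8)
  C <- catF$probs
  sigs <- catF$signature_names
  mt <- list(groups = data.frame(id = c("G1", "G2", "G3"),
                                 node = 1:3, count = c(300L, 300L, 300L),
                                 clones = ""),
             members = list(character(0), character(0), character(0)),
             group_parent = c(0L, 1L, 2L), depth = 1:3, drivers = NULL)
  class(mt) <- "mutation_tree"
  # fake fit path: call the filter/harmonize internals through the public
  # function with a profile whose middle branch carries a 5% isolated extra
  set.seed(41)
  canon <- sbs_channels()
  mixes <- list(stats::setNames(c(1, 0, 0), sigs),
                stats::setNames(c(0.95, 0, 0.05), sigs),
                stats::setNames(c(1, 0, 0), sigs))
  ref <- alt <- ctx <- character(0)
  for (g in 1:3) {
    p <- as.numeric(C %*% mixes[[g]])
    ch <- sample(canon, 300, TRUE, prob = p)
    for (x in ch) {
      m <- cloneflow:::channel_to_mutation(x, FALSE)
      ref <- c(ref, m$ref); alt <- c(alt, m$alt); ctx <- c(ctx, m$ctx)
    }
  }
  snvs <- paste0("s", 1:900)
  mt$members <- split(snvs, rep(1:3, each = 300))
  altc <- matrix(50L, 900, 4, dimnames = list(snvs, paste0("S", 1:4)))
  prof <- cloneflow:::new_mutation_profile(snvs, ref, alt, ctx, altc * 2L, altc)
  bs <- fit_branch_signatures(mt, prof, catF, isolation_threshold = 0.10,
                              epsilon_cos = 0.002)
  # if the 5% signature survived filtering on G2, harmonization must have
  # removed it (absent from both neighbors, activity < 0.10)
  expect_false(sigs[3] %in% bs$fits[[2]]$retained)

  # a 60% isolated signature is kept: signal too strong to prune
  mixes2 <- list(stats::setNames(c(1, 0, 0), sigs),
                 stats::setNames(c(0.4, 0, 0.6), sigs),
                 stats::setNames(c(1, 0, 0), sigs))
  ref <- alt <- ctx <- character(0)
  set.seed(42)
  for (g in 1:3) {
    p <- as.numeric(C %*% mixes2[[g]])
    ch <- sample(canon, 300, TRUE, prob = p)
    for (x in ch) {
      m <- cloneflow:::channel_to_mutation(x, FALSE)
      ref <- c(ref, m$ref); alt <- c(alt, m$alt); ctx <- c(ctx, m$ctx)
    }
  }
  prof2 <- cloneflow:::new_mutation_profile(snvs, ref, alt, ctx,
                                            altc * 2L, altc)
  bs2 <- fit_branch_signatures(mt, prof2, catF, isolation_threshold = 0.10)
  expect_true(sigs[3] %in% bs2$fits[[2]]$retained)
  expect_gt(bs2$fits[[2]]$activities[sigs[3]], 0.4)
})

test_that("small branches inherit the parent's retained set and are flagged", {
  sim <- simulate_patient(n_snvs = 150, seed = 12)
  dec <- infer_clones(sim$profile)
  mt <- build_mutation_tree(dec$phylogeny)
  bs <- fit_branch_signatures(mt, sim$profile, sim$catalog,
                              min_branch_mutations = 40)
  small <- which(mt$groups$count < 40 & mt$group_parent > 0)
  for (g in small) {
    expect_equal(bs$flags[g], "low_confidence")
    expect_setequal(bs$fits[[g]]$retained,
                    bs$fits[[mt$group_parent[g]]]$retained)
  }
})
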