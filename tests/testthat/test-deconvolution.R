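test_that("compute_vaf handles counts and missing depth", {
  prof <- toy_profile()
  prof$alt_count[1, 1] <- 30L; prof$ref_count[1, 1] <- 70L
  prof$alt_count[2, 1] <- 0L;  prof$ref_count[2, 1] <- 0L
  prof$alt_count[3, 1] <- 50L; prof$ref_count[3, 1] <- 50L
  v <- compute_vaf(prof)
  expect_equal(v$V[1, 1], 0.30)
  expect_true(is.na(v$V[2, 1]))
  expect_equal(v$V[3, 1], 0.50)
  expect_true(all(v$V >= 0 & v$V <= 1, na.rm = TRUE))
})

test_that("estimate_frequencies solves the noiseless system exactly", {
  M <- rbind(c(1L, 0L), c(1L, 1L))
  f <- estimate_frequencies(M, c(0.5, 0.3))
  expect_equal(unname(f), c(0.4, 0.6), tolerance = 1e-6)
  expect_equal(unname(estimate_frequencies(M, c(0, 0))), c(0, 0))
})

test_that("estimate_frequencies matches a grid-search minimizer", {
  M <- rbind(c(1L, 0L), c(1L, 1L))
  V_s <- c(0.45, 0.33)
  f <- estimate_frequencies(M, V_s)
  # brute-force 0.001-step search over the constrained simplex
  best <- NULL; best_v <- Inf
  for (a in seq(0, 1, by = 0.001)) for (b in seq(0, 1 - a, by = 0.001)) {
    v <- sum((c(a + b, b) / 2 - V_s)^2)
    if (v < best_v) { best_v <- v; best <- c(a, b) }
  }
  expect_lt(max(abs(f - best)), 0.005)
})

test_that("frequency estimates always respect the simplex constraints", {
  set.seed(11)
  for (rep in 1:25) {
    k <- sample(2:5, 1); n <- sample(5:30, 1)
    M <- matrix(rbinom(k * n, 1, 0.5), k, n)
    M[1, ] <- 1L  # avoid all-zero clones
    V_s <- runif(n, 0, 0.6)
    f <- estimate_frequencies(M, V_s, depth_s = sample(50:500, n, TRUE))
    expect_true(all(f >= 0))
    expect_lte(sum(f), 1 + 1e-9)
  }
})

test_that("noiseless nested-chain patient is recovered exactly", {
  # 3 nested clones (chain), 5 samples each dominated by one clone
  snvs <- paste0("m", 1:30)
  M_true <- rbind(Clone1 = c(rep(1L, 10), rep(0L, 20)),
                  Clone2 = c(rep(1L, 20), rep(0L, 10)),
                  Clone3 = rep(1L, 30))
  colnames(M_true) <- snvs
  f_true <- matrix(0, 5, 3, dimnames = list(paste0("S", 1:5),
                                            rownames(M_true)))
  f_true[1, ] <- c(0.8, 0, 0)
  f_true[2, ] <- c(0, 0.8, 0)
  f_true[3, ] <- c(0, 0, 0.8)
  f_true[4, ] <- c(0.5, 0.3, 0)
  f_true[5, ] <- c(0, 0.4, 0.4)
  V <- t(f_true %*% M_true) / 2
  depth <- 100000L
  alt <- matrix(as.integer(round(V * depth)), nrow(V),
                dimnames = list(snvs, rownames(f_true)))
  prof <- cloneflow:::new_mutation_profile(
    snvs, rep("C", 30), rep("A", 30), rep("ACA", 30),
    depth - alt, alt)
  dec <- infer_clones(prof)
  sc <- score_recovery(M_true, f_true, dec$clones$M[, snvs, drop = FALSE],
                       dec$clones$f)
  expect_equal(nrow(dec$clones$M), 3)
  expect_equal(sc$genotype_accuracy, 1)
  expect_lt(max(abs(sc$freq_rmse)), 1e-3)
})

test_that("a 50/50 two-clone mixture does not spawn a hybrid clone", {
  snvs <- paste0("m", 1:30)
  # two sibling clones sharing a 10-SNV trunk
  M_true <- rbind(CloneA = c(rep(1L, 10), rep(1L, 10), rep(0L, 10)),
                  CloneB = c(rep(1L, 10), rep(0L, 10), rep(1L, 10)))
  colnames(M_true) <- snvs
  f_true <- matrix(0, 5, 2, dimnames = list(paste0("S", 1:5),
                                            rownames(M_true)))
  f_true[1, ] <- c(0.8, 0)
  f_true[2, ] <- c(0, 0.8)
  f_true[3, ] <- c(0.4, 0.4)   # the 50/50 mixture sample
  f_true[4, ] <- c(0.7, 0)
  f_true[5, ] <- c(0, 0.7)
  V <- t(f_true %*% M_true) / 2
  depth <- 100000L
  alt <- matrix(as.integer(round(V * depth)), nrow(V),
                dimnames = list(snvs, rownames(f_true)))
  prof <- cloneflow:::new_mutation_profile(
    snvs, rep("C", 30), rep("A", 30), rep("ACA", 30), depth - alt, alt)
  dec <- infer_clones(prof)
  expect_equal(nrow(dec$clones$M), 2)
  sc <- score_recovery(M_true, f_true, dec$clones$M[, snvs, drop = FALSE],
                       dec$clones$f)
  expect_equal(sc$genotype_accuracy, 1)
})

test_that("identical genotype in all samples collapses to one clone", {
  snvs <- paste0("m", 1:12)
  alt <- matrix(0L, 12, 4, dimnames = list(snvs, paste0("S", 1:4)))
  depth <- 1000L
  cell <- c(0.6, 0.5, 0.8, 0.4)
  for (s in 1:4) alt[, s] <- as.integer(round(depth * cell[s] / 2))
  prof <- cloneflow:::new_mutation_profile(
    snvs, rep("C", 12), rep("T", 12), rep("ACG", 12), depth - alt, alt)
  dec <- infer_clones(prof)
  expect_equal(nrow(dec$clones$M), 1)
  expect_true(all(dec$clones$M == 1L))
  expect_equal(unname(dec$clones$f[, 1]), cell, tolerance = 0.01)
})

test_that("no clonal signal raises the documented error", {
  snvs <- paste0("m", 1:3)
  alt <- matrix(1L, 3, 4, dimnames = list(snvs, paste0("S", 1:4)))
  ref <- matrix(5000L, 3, 4, dimnames = list(snvs, paste0("S", 1:4)))
  prof <- cloneflow:::new_mutation_profile(
    snvs, rep("C", 3), rep("T", 3), rep("ACG", 3), ref, alt)
  expect_error(infer_clones(prof), "no clonal signal")
})
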