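make_tips <- function(M) {
  rbind(M, matrix(0L, 1, ncol(M), dimnames = list("Germline")))
}

test_that("fitch_score handles the canonical small cases", {
  # two identical tips -> 0 changes beyond any germline difference
  M <- rbind(a = c(1L, 1L, 0L), b = c(1L, 1L, 0L))
  fit <- search_mp_tree(M)
  expect_equal(fitch_score(make_tips(M), fit$tree), 2L)

  # (a,b),(c,d) with one character 0,0,1,1 and all-zero root -> 1 change
  tr <- cloneflow:::new_rtree(parent = c(0L, 1L, 2L, 2L, 1L, 5L, 5L),
                              label = c("Germline", "n1", "a", "b",
                                        "n2", "c", "d"))
  tips <- matrix(c(0L, 0L, 1L, 1L, 0L), ncol = 1,
                 dimnames = list(c("a", "b", "c", "d", "Germline")))
  expect_equal(fitch_score(tips, tr), 1L)
})

test_that("fitch_score equals brute-force enumeration on random instances", {
  set.seed(42)
  for (rep in 1:20) {
    n <- 5
    M <- matrix(sample(0:1, n * 8, TRUE), n, 8,
                dimnames = list(paste0("c", 1:n), NULL))
    M <- M[, colSums(M) > 0, drop = FALSE]
    if (ncol(M) == 0) next
    trees <- cloneflow:::all_topologies(rownames(M))
    tr <- trees[[sample(length(trees), 1)]]
    got <- fitch_score(make_tips(M), tr)
    want <- sum(vapply(seq_len(ncol(M)), function(j) {
      tipstates <- M[tr$label[cloneflow:::rtree_tips(tr)], j]
      oracle_min_changes(tr$parent, tipstates)
    }, 0))
    expect_equal(got, want)
  }
})

test_that("search_mp_tree is exact on perfect phylogenies and tiny cases", {
  # nested mutation sets: chain topology, score = distinct mutations
  M <- rbind(c1 = c(1L, 0L, 0L), c2 = c(1L, 1L, 0L), c3 = c(1L, 1L, 1L))
  fit <- search_mp_tree(M)
  expect_equal(fit$score, 3L)
  expect_true(fit$exhaustive)
  # chain: c3's path from root passes through ancestors of c2 and c1's state
  cp <- clone_phylogeny(M)
  expect_equal(sum(vapply(cp$branch_mutations, length, 0L)), 3)

  # 2 clones: unique topology
  M2 <- rbind(x = c(1L, 0L), y = c(1L, 1L))
  expect_equal(search_mp_tree(M2)$score, 2L)
})

test_that("search_mp_tree equals the phangorn minimum over all topologies", {
  skip_if_not_installed("phangorn")
  set.seed(7)
  for (rep in 1:10) {
    k <- sample(4:6, 1)
    M <- matrix(sample(0:1, k * 10, TRUE, prob = c(0.6, 0.4)), k, 10,
                dimnames = list(paste0("c", 1:k), paste0("s", 1:10)))
    M <- M[!duplicated(M) & rowSums(M) > 0, , drop = FALSE]
    if (nrow(M) < 2) next
    fit <- search_mp_tree(M)
    tips <- make_tips(M)
    dat <- phangorn::phyDat(tips, type = "USER", levels = c(0, 1))
    all_tr <- phangorn::allTrees(nrow(tips), rooted = FALSE,
                            tip.label = rownames(tips))
    want <- min(vapply(all_tr, function(t)
      phangorn::parsimony(t, dat), 0))
    expect_equal(fit$score, want)
  }
})

test_that("ancestral reconstruction follows the documented conventions", {
  M <- rbind(a = c(1L, 1L, 0L), b = c(1L, 0L, 0L), c = c(1L, 0L, 1L))
  colnames(M) <- paste0("s", 1:3)
  cp <- clone_phylogeny(M)
  root <- cloneflow:::rtree_root(cp$tree)
  # root forced all-zero
  expect_true(all(cp$genotypes[root, ] == 0L))
  # SNV 1 present in every clone: state 1 at all internal nodes below root,
  # assigned once to the trunk
  internal <- setdiff(seq_len(cloneflow:::rtree_n(cp$tree)),
                      c(cloneflow:::rtree_tips(cp$tree), root))
  expect_true(all(cp$genotypes[internal, 1] == 1L))
  carrying <- which(vapply(cp$branch_mutations, function(b)
    colnames(M)[1] %in% b, TRUE))
  expect_length(carrying, 1)
  # a private mutation is 0 at all internal nodes
  expect_true(all(cp$genotypes[internal, 3] == 0L))
  # implied changes equal the parsimony score
  expect_equal(sum(vapply(cp$branch_mutations, length, 0L)), cp$score)
})

test_that("parent-state resolution picks one of the minimum-change labelings", {
  set.seed(9)
  for (rep in 1:15) {
    k <- sample(3:5, 1)
    M <- matrix(sample(0:1, k * 6, TRUE), k, 6,
                dimnames = list(paste0("c", 1:k), paste0("s", 1:6)))
    M <- M[!duplicated(M) & rowSums(M) > 0, , drop = FALSE]
    if (nrow(M) < 2) next
    cp <- clone_phylogeny(M)
    implied <- sum(vapply(cp$branch_mutations, length, 0L))
    expect_equal(implied, cp$score)
    # per character, implied changes match the enumeration oracle
    for (j in seq_len(ncol(M))) {
      tr <- cp$tree
      tipstates <- M[tr$label[cloneflow:::rtree_tips(tr)], j]
      want <- oracle_min_changes(tr$parent, tipstates)
      got <- sum(vapply(seq_len(cloneflow:::rtree_n(tr)), function(v) {
        p <- tr$parent[v]
        if (p == 0L) 0L else as.integer(cp$genotypes[v, j] != cp$genotypes[p, j])
      }, 0L))
      expect_equal(got, want)
    }
  }
})

test_that("every distinguishing SNV appears on at least one branch", {
  set.seed(13)
  M <- matrix(sample(0:1, 5 * 12, TRUE), 5, 12,
              dimnames = list(paste0("c", 1:5), paste0("s", 1:12)))
  M <- M[!duplicated(M) & rowSums(M) > 0, , drop = FALSE]
  cp <- clone_phylogeny(M)
  mapped <- unique(unlist(cp$branch_mutations))
  varying <- colnames(M)[colSums(M) > 0]
  expect_true(all(varying %in% mapped))
})

test_that("mutation tree contracts zero-mutation branches and places drivers", {
  # chain phylogeny with 3 mutation-bearing branches -> path of 3 groups
  M <- rbind(c1 = c(1L, 0L, 0L), c2 = c(1L, 1L, 0L), c3 = c(1L, 1L, 1L))
  colnames(M) <- paste0("s", 1:3)
  cp <- clone_phylogeny(M)
  drv <- data.frame(snv_id = "s1", gene = "TP53", label = "A")
  mt <- build_mutation_tree(cp, drv)
  expect_equal(nrow(mt$groups), 3)
  expect_equal(sum(mt$group_parent == 0), 1)       # a single path from root
  expect_equal(sum(mt$groups$count), cp$score)
  # the trunk mutation s1 is on the first (root-attached) group
  expect_equal(mt$drivers$group, mt$groups$id[mt$group_parent == 0])

  # a zero-mutation internal branch does not create a group; children
  # reattach to the nearest mutation-bearing ancestor group
  tr <- cloneflow:::new_rtree(parent = c(0L, 1L, 2L, 2L, 1L, 5L, 5L),
                              label = c("Germline", "n1", "a", "b",
                                        "n2", "c", "d"))
  tips <- rbind(a = c(1L, 1L, 0L), b = c(1L, 1L, 1L),
                c = c(1L, 0L, 0L), d = c(1L, 0L, 0L),
                Germline = c(0L, 0L, 0L))
  colnames(tips) <- paste0("s", 1:3)
  cp2 <- clone_phylogeny(tips[1:4, , drop = FALSE], tree = tr)
  mt2 <- build_mutation_tree(cp2)
  zero_branches <- sum(vapply(cp2$branch_mutations, length, 0L) == 0) -
    1  # root has no branch
  expect_gte(zero_branches, 1)
  expect_equal(sum(mt2$groups$count), cp2$score)
  expect_equal(nrow(mt2$groups),
               sum(vapply(cp2$branch_mutations, length, 0L) > 0))
})

test_that("simulated homoplasy-free topologies are recovered exactly", {
  skip_if_not_installed("phangorn")
  for (seed in 1:5) {
    sim <- simulate_patient(n_clones = 5, n_snvs = 120, seed = seed)
    fit <- search_mp_tree(sim$truth$M)
    expect_setequal(clade_set(fit$tree), clade_set(sim$truth$tree))
  }
})
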