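test_that("p-distance reproduces the printed mismatch fractions", {
  # 18 shared loci with 1 mismatch -> 0.0556; 7 shared with 1 -> 0.1429
  dos <- rbind(q4 = rep(0L, 31), nc9 = rep(0L, 31),
               q5 = rep(0L, 31), ne6 = rep(0L, 31),
               q8 = rep(0L, 31), nc12 = rep(0L, 31))
  g <- make_matrix_from_dosage(dos, ref = rep("A", 31), alt = rep("C", 31))
  g$calls["q4", 19:31] <- NA
  g$calls["nc9", 1] <- "C/C"
  g$calls["q5", c(1:18, 26:31)] <- NA
  g$calls["ne6", 19] <- "C/C"
  d <- p_distance_matrix(g)
  expect_equal(round(d$d["nc9", "q4"], 4), 0.0556)
  expect_equal(d$shared["nc9", "q4"], 18L)
  expect_equal(round(d$d["ne6", "q5"], 4), 0.1429)
  expect_equal(d$shared["ne6", "q5"], 7L)
  expect_equal(d$d["nc12", "q8"], 0)
})

test_that("p-distance flags pairs with no shared calls as uncomparable", {
  dos <- matrix(0L, 2, 2)
  g <- make_matrix_from_dosage(dos)
  g$calls[1, 1] <- NA
  g$calls[2, 2] <- NA
  d <- p_distance_matrix(g)
  expect_true(is.na(d$d[1, 2]))
  expect_equal(nrow(d$uncomparable), 1)
})

test_that("zero p-distance coincides with fingerprint indistinguishability", {
  fx <- default_fixture()
  g <- fx$g[1:20, 1:60]
  g$calls[2, ] <- g$calls[1, ]       # plant one identical pair
  d <- p_distance_matrix(g)
  pd <- pairwise_distinguishability(build_fingerprint(g, g$loci$id))
  zero_d <- !is.na(d$d) & d$d == 0 & upper.tri(d$d)
  zero_mm <- !is.na(pd$mismatches) & pd$mismatches == 0 &
    upper.tri(pd$mismatches)
  expect_identical(which(zero_d), which(zero_mm))
  expect_true(any(zero_d))
})

test_that("NJ recovers additive matrices exactly", {
  # fixed 4-taxon additive matrix from a known tree
  set.seed(2)
  ref <- random_additive_tree(4)
  tr <- nj_tree(ref$d)
  expect_equal(ape::dist.topo(ape::unroot(ref$tree), tr), 0,
               ignore_attr = TRUE)
  got <- ape::cophenetic.phylo(tr)[rownames(ref$d), colnames(ref$d)]
  expect_equal(got, ref$d, tolerance = 1e-8)
  # property: random additive trees, 5..8 taxa
  for (rep in 1:20) {
    x <- random_additive_tree(sample(5:8, 1))
    tr <- nj_tree(x$d)
    got <- ape::cophenetic.phylo(tr)[rownames(x$d), colnames(x$d)]
    expect_equal(got, x$d, tolerance = 1e-8)
  }
})

test_that("NJ handles the 3-taxon closed form and input order", {
  d <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  tr <- nj_tree(d)
  # closed form: x = (dab + dac - dbc)/2 etc.
  bl <- setNames(tr$edge.length[order(tr$edge[, 2])][1:3], tr$tip.label)
  expect_equal(unname(bl["a"]), 1)
  expect_equal(unname(bl["b"]), 2)
  expect_equal(unname(bl["c"]), 3)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")

  set.seed(6)
  x <- random_additive_tree(6)
  perm <- sample(6)
  t1 <- nj_tree(x$d)
  t2 <- nj_tree(x$d[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
})

test_that("negative NJ branch lengths are clamped and flagged", {
  d <- matrix(c(0, 1, 1, 10,
                1, 0, 1, 9,
                1, 1, 0, 2,
                10, 9, 2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(d)
  expect_true(all(tr$edge.length >= 0))
  expect_gte(attr(tr, "clamped"), 1)
})

test_that("bootstrap supports are seeded, bounded and strong for clean splits", {
  cfg <- sim_config(n_chrom = 2, chrom_len = 30000, n_loci = 200,
                    pop_sizes = c(QTP = 8L, NW = 8L),
                    pop_f = c(QTP = 0.4, NW = 0.4),
                    missing_rate = 0, seed = 33)
  sim <- simulate_genotypes(cfg)
  t1 <- bootstrap_support(sim$g, replicates = 50, seed = 9)
  t2 <- bootstrap_support(sim$g, replicates = 50, seed = 9)
  expect_identical(t1$node.label, t2$node.label)
  expect_true(all(t1$node.label >= 0 & t1$node.label <= 100))
  # the two populations are strongly diverged: their bipartition is stable
  split_support <- max(t1$node.label)
  expect_gte(split_support, 95)

  tr1 <- bootstrap_support(sim$g[1:6, 1:50], replicates = 1, seed = 1)
  expect_true(all(tr1$node.label %in% c(0, 100)))
})

test_that("dosage PCA orders variance, separates populations, fixes signs", {
  cfg <- sim_config(n_chrom = 2, chrom_len = 80000, n_loci = 500,
                    pop_sizes = c(QTP = 20L, NW = 20L),
                    pop_f = c(QTP = 0.3, NW = 0.3),
                    missing_rate = 0, seed = 13)
  sim <- simulate_genotypes(cfg)
  pc <- pca_dosage(sim$g, 5)
  expect_true(all(diff(pc$var_explained) <= 1e-12))
  expect_lte(sum(pc$var_explained), 1 + 1e-12)
  qtp <- sim$meta$population == "QTP"
  # PC1 separates the two diverged populations with no overlap
  expect_true(max(pc$scores[qtp, 1]) < min(pc$scores[!qtp, 1]) ||
                min(pc$scores[qtp, 1]) > max(pc$scores[!qtp, 1]))
  # coordinates are invariant (not just up to sign) under sample reordering
  perm <- sample(n_samples(sim$g))
  pc2 <- pca_dosage(sim$g[perm, ], 5)
  expect_equal(pc2$scores[sim$g$samples, ], pc$scores, tolerance = 1e-6)
  # duplicated samples land on identical coordinates
  g2 <- sim$g
  g2$calls[2, ] <- g2$calls[1, ]
  pc3 <- pca_dosage(g2, 2)
  expect_equal(pc3$scores[1, ], pc3$scores[2, ], tolerance = 1e-9)
  expect_error(pca_dosage(make_matrix_from_dosage(matrix(1L, 3, 3))),
               "constant")
})

test_that("population assignment calls nearest population with margins", {
  d <- matrix(c(0, 0.05, 0.4, 0.41,
                0.05, 0, 0.42, 0.4,
                0.4, 0.42, 0, 0.06,
                0.41, 0.4, 0.06, 0),
              4, 4, dimnames = list(c("q1", "q2", "n1", "n2"),
                                    c("q1", "q2", "n1", "n2")))
  meta <- data.frame(sample = c("q1", "q2", "n1", "n2"),
                     population = c("QTP", "QTP", "NW", "NW"))
  res <- assign_population(d, meta, c("q1", "n2"))
  expect_identical(res$call, c("QTP", "NW"))
  expect_true(all(res$margin > 0))
  # equidistant query is ambiguous
  d2 <- matrix(0.3, 3, 3, dimnames = list(c("x", "a", "b"),
                                          c("x", "a", "b")))
  diag(d2) <- 0
  meta2 <- data.frame(sample = c("a", "b"), population = c("QTP", "NW"))
  expect_identical(assign_population(d2, meta2, "x")$call, "AMBIGUOUS")
})
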