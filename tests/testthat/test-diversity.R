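test_that("alpha diversity matches hand-computed oracles", {
  m <- matrix(c(1L, 1L, 2L, 3L), 4,
              dimnames = list(paste0("t", 1:4), "s1"))
  ## force a second sample so the container is happy, then check s1
  m <- cbind(m, s2 = c(2L, 2L, 2L, 2L))
  a <- alpha_diversity(community_table(m))
  ## S_obs = 4, F1 = 2, F2 = 1 -> chao1 = 4 + 2*1/(2*2) = 4.5
  expect_equal(a$chao1[a$sample_id == "s1"], 4.5)
  expect_equal(a$observed_otus[a$sample_id == "s1"], 4L)

  ## two equal categories -> 1 bit
  m2 <- matrix(c(8L, 8L, 1L, 1L), 2,
               dimnames = list(c("A", "B"), c("s1", "s2")))
  a2 <- alpha_diversity(community_table(m2))
  expect_equal(a2$shannon, c(1, 1))

  ## single present tip A on ((A:1,B:1):1,C:2): rooted PD = 2
  m3 <- matrix(c(4L, 0L, 0L, 1L, 1L, 1L), 3,
               dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  a3 <- alpha_diversity(community_table(m3), tree = small_tree())
  expect_equal(a3$faith_pd[a3$sample_id == "s1"], 2)
  ## all three tips: whole tree length = 1+1+1+2 = 5
  expect_equal(a3$faith_pd[a3$sample_id == "s2"], 5)
})

test_that("chao1 >= observed, equal only without singletons", {
  for (seed in 1:5) {
    ct <- random_table(seed = seed)
    a <- alpha_diversity(ct)
    expect_true(all(a$chao1 >= a$observed_otus))
    no_singletons <- colSums(ct$counts == 1) == 0
    expect_equal(a$chao1[no_singletons],
                 as.numeric(a$observed_otus[no_singletons]))
  }
  expect_error(alpha_diversity(
    community_table(matrix(c(0.5, 0.5), 2,
                           dimnames = list(c("A", "B"), "s1")),
                    allow_proportions = TRUE)), "integer")
})

test_that("Bray-Curtis matches hand values and bounds", {
  m <- matrix(c(5L, 5L, 0L, 2L, 6L, 0L), 3,
              dimnames = list(c("A", "B", "C"), c("x", "y")))
  d <- bray_curtis(community_table(m))
  ## relabund x = (.5,.5,0), y = (.25,.75,0) -> (|.25|+|.25|)/2 = 0.25
  expect_equal(d$m["x", "y"], 0.25)

  disjoint <- matrix(c(3L, 0L, 0L, 4L), 2,
                     dimnames = list(c("A", "B"), c("x", "y")))
  expect_equal(bray_curtis(community_table(disjoint))$m["x", "y"], 1)

  same <- matrix(c(3L, 1L, 6L, 2L), 2,
                 dimnames = list(c("A", "B"), c("x", "y")))
  expect_equal(bray_curtis(community_table(same))$m["x", "y"], 0)
})

test_that("beta-MNTD matches hand values, symmetry and the picante oracle", {
  tr <- small_tree()
  m <- matrix(c(1L, 0L, 0L, 0L, 0L, 1L), 3,
              dimnames = list(c("A", "B", "C"), c("x", "y")))
  d <- beta_mntd(community_table(m), tr)
  expect_equal(d$m["x", "y"], 4)  # patristic(A, C)

  same <- matrix(c(2L, 1L, 0L, 4L, 2L, 0L), 3,
                 dimnames = list(c("A", "B", "C"), c("x", "y")))
  expect_equal(beta_mntd(community_table(same), tr)$m["x", "y"], 0)

  ## larger random case against picante::comdistnt
  tr2 <- simulate_tree(25, seed = 8)
  ct <- random_table(n_otu = 25, n_samp = 5, seed = 8)
  rownames(ct$counts) <- rownames(ct$relabund) <- tr2$tip.label
  mine <- beta_mntd(ct, tr2)$m
  D <- ape::cophenetic.phylo(tr2)
  ref <- as.matrix(picante::comdistnt(t(ct$counts), D,
                                      abundance.weighted = TRUE))
  expect_equal(mine[rownames(ref), colnames(ref)], ref, tolerance = 1e-12)
  expect_equal(mine, t(mine))
})

test_that("distance matrices are invariant to OTU ordering", {
  tr <- simulate_tree(15, seed = 3)
  ct <- random_table(n_otu = 15, n_samp = 4, seed = 3)
  rownames(ct$counts) <- rownames(ct$relabund) <- tr$tip.label
  perm <- withr::with_seed(1, sample(15))
  ct2 <- community_table(ct$counts[perm, ])
  expect_equal(bray_curtis(ct)$m, bray_curtis(ct2)$m)
  expect_equal(beta_mntd(ct, tr)$m, beta_mntd(ct2, tr)$m)
})

test_that("Faith PD is monotone in added tips", {
  tr <- simulate_tree(20, seed = 4)
  base <- matrix(0L, 20, 2, dimnames = list(tr$tip.label, c("s1", "s2")))
  base[1:5, 1] <- 1L
  base[1:6, 2] <- 1L   # s2 = s1 plus one tip
  a <- alpha_diversity(community_table(base + 0L), tree = tr)
  expect_gte(a$faith_pd[2], a$faith_pd[1])
})

test_that("Levins niche width follows the formula and its bounds", {
  even <- matrix(1L, 1, 23, dimnames = list("A", paste0("s", 1:23)))
  even <- rbind(even, B = 1L)  # second OTU so columns are fine
  nw <- niche_width(community_table(even))
  expect_equal(nw$b[nw$otu_id == "A"], 23)

  single <- matrix(c(7L, 1L, 0L, 1L), 2,
                   dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_equal(niche_width(community_table(single))$b[1], 1)

  half <- matrix(c(3L, 1L, 3L, 1L, 0L, 1L), 2,
                 dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
  expect_equal(niche_width(community_table(half))$b[1], 2)

  ## scaling an OTU's counts leaves B unchanged; B always in [1, n]
  ct <- random_table(seed = 9)
  nw1 <- niche_width(ct)
  scaled <- ct$counts
  scaled[3, ] <- scaled[3, ] * 10L
  nw2 <- niche_width(community_table(scaled))
  expect_equal(nw1$b[3], nw2$b[3])
  expect_true(all(nw1$b >= 1 & nw1$b <= ncol(ct$counts)))
})

test_that("PCoA recovers Euclidean geometry and reports eigenvalues", {
  pts <- matrix(c(0, 0, 3, 0, 0, 4, 3, 4), ncol = 2, byrow = TRUE,
                dimnames = list(paste0("s", 1:4), NULL))
  d <- as.matrix(stats::dist(pts))
  pc <- pcoa_ordination(dist_matrix(d, "euclidean"), k = 2)
  rec <- as.matrix(stats::dist(as.matrix(pc$coords[, c("axis1", "axis2")])))
  expect_equal(unname(rec), unname(d), tolerance = 1e-9)

  two <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  pc2 <- pcoa_ordination(dist_matrix(two, "test"), k = 2)
  expect_equal(abs(diff(pc2$coords$axis1)), 1, tolerance = 1e-9)

  zero <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  pc3 <- pcoa_ordination(dist_matrix(zero, "test"))
  expect_true(all(abs(pc3$eigenvalues) < 1e-9))

  ## Bray-Curtis dissimilarities may yield negative eigenvalues: reported
  ct <- random_table(n_otu = 10, n_samp = 8, seed = 12)
  pc4 <- pcoa_ordination(bray_curtis(ct))
  expect_true(length(pc4$eigenvalues) >= 7)

  asym <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(dist_matrix(asym), "symmetric")
})

test_that("group comparisons agree with exact rank enumeration", {
  df <- data.frame(v = c(1, 2, 3, 101, 102, 103),
                   g = rep(c("x", "y"), each = 3))
  res <- compare_groups(df, "v", "g", test = "wilcoxon")
  ## full separation at n = 3, 3: exact two-sided p = 2/choose(6,3) = 0.1
  expect_equal(res$p_value, 0.1)

  swapped <- df
  swapped$g <- rev(swapped$g)
  expect_equal(compare_groups(swapped, "v", "g")$p_value, res$p_value)

  same <- data.frame(v = rep(c(5, 6, 7), 2), g = rep(c("x", "y"), each = 3))
  expect_gt(compare_groups(same, "v", "g")$p_value, 0.9)

  expect_error(compare_groups(data.frame(v = rep(1, 4),
                                         g = c("x", "y", "x", "y")),
                              "v", "g", test = "t_test"), "constant")
})
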