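test_that("sampled bNTI null agrees with the exhaustive tip-permutation oracle", {
  tr <- small_tree()
  ## two distinct singleton communities: A vs C
  m <- matrix(c(1L, 0L, 0L, 0L, 0L, 1L), 3,
              dimnames = list(c("A", "B", "C"), c("x", "y")))
  ct <- community_table(m)
  D <- ape::cophenetic.phylo(tr)[otu_ids(ct), otu_ids(ct)]
  W <- ct$relabund

  ## exact null: all 3! assignments of taxa to tips
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  exact <- vapply(perms, function(p) {
    Dp <- D[p, p]
    dimnames(Dp) <- dimnames(D)
    r_bmntd(W, Dp)["x", "y"]
  }, numeric(1))
  obs <- r_bmntd(W, D)["x", "y"]
  exact_bnti <- (obs - mean(exact)) / stats::sd(exact)

  res <- bnti(ct, tr, reps = 999, seed = 42)
  expect_equal(res$observed_bmntd, obs)
  ## sampled null mean within 3 standard errors of the exact mean
  se <- stats::sd(exact) / sqrt(999)
  expect_lt(abs(res$null_mean - mean(exact)), 3 * se)
  expect_lt(abs(res$bnti - exact_bnti), 0.35)
})

test_that("bNTI flags degenerate nulls and orders identical communities", {
  tr <- small_tree()
  same <- matrix(c(1L, 1L, 0L, 2L, 2L, 0L), 3,
                 dimnames = list(c("A", "B", "C"), c("x", "y")))
  res <- bnti(community_table(same), tr, reps = 99, seed = 1)
  ## identical communities: observed bMNTD 0 <= every null value, and the
  ## null is degenerate (shared taxa stay shared under a joint shuffle)
  expect_equal(res$observed_bmntd, 0)
  expect_lte(res$observed_bmntd, res$null_mean)
  expect_true(res$degenerate)
  expect_true(is.na(res$bnti))
})

test_that("bNTI on a larger table agrees with a plain-R implementation and is seeded", {
  tr <- simulate_tree(20, seed = 6)
  ct <- random_table(n_otu = 20, n_samp = 5, seed = 6)
  rownames(ct$counts) <- rownames(ct$relabund) <- tr$tip.label

  r1 <- bnti(ct, tr, reps = 199, seed = 7)
  r2 <- bnti(ct, tr, reps = 199, seed = 7)
  expect_identical(r1, r2)

  ## independent R null with its own shuffles: same distributional location
  D <- ape::cophenetic.phylo(tr)[otu_ids(ct), otu_ids(ct)]
  W <- ct$relabund
  nulls <- withr::with_seed(8, replicate(199, {
    p <- sample(20)
    Dp <- D[p, p]; dimnames(Dp) <- dimnames(D)
    r_bmntd(W, Dp)
  }))
  mu <- apply(nulls, 1:2, mean)
  sdv <- apply(nulls, 1:2, stats::sd)
  pair_mu <- mu[cbind(match(r1$sample_a, sample_ids(ct)),
                      match(r1$sample_b, sample_ids(ct)))]
  pair_sd <- sdv[cbind(match(r1$sample_a, sample_ids(ct)),
                       match(r1$sample_b, sample_ids(ct)))]
  expect_true(all(abs(r1$null_mean - pair_mu) < 4 * pair_sd / sqrt(199) + 1e-9))
  expect_error(bnti(ct, tr, reps = 0), "reps")
})

test_that("Raup-Crick hits its sign limits and stays in [-1, 1]", {
  ## identical pair inside a larger pool: obs Bray = 0, nulls > 0 -> RC -1
  withr::with_seed(10, {
    m <- matrix(rpois(20 * 4, 3), 20, 4,
                dimnames = list(paste0("t", 1:20), paste0("s", 1:4)))
    m[, 2] <- m[, 1]
    m[1, ] <- m[1, ] + 1L
    ct <- community_table(m)
  })
  rc <- raup_crick(ct, reps = 199, seed = 3)
  pair <- rc[rc$sample_a == "s1" & rc$sample_b == "s2", ]
  expect_equal(pair$observed_bray, 0)
  expect_equal(pair$rc_bray, -1)

  ## disjoint pair in a large pool -> RC near +1
  withr::with_seed(11, {
    m2 <- matrix(rpois(40 * 6, 2), 40, 6,
                 dimnames = list(paste0("t", 1:40), paste0("s", 1:6)))
    m2[, ] <- m2 + 1L
    m2[1:20, 1] <- 0L
    m2[21:40, 2] <- 0L
    ct2 <- community_table(m2)
  })
  rc2 <- raup_crick(ct2, reps = 199, seed = 4)
  pair2 <- rc2[rc2$sample_a == "s1" & rc2$sample_b == "s2", ]
  expect_equal(pair2$observed_bray, 1)
  expect_gt(pair2$rc_bray, 0.9)

  ## bound holds on random tables, and runs are seeded
  ct3 <- random_table(n_otu = 15, n_samp = 6, seed = 13)
  rc3 <- raup_crick(ct3, reps = 99, seed = 5)
  expect_true(all(rc3$rc_bray >= -1 & rc3$rc_bray <= 1))
  expect_identical(rc3, raup_crick(ct3, reps = 99, seed = 5))
})

test_that("the five-way process rules are applied exactly", {
  mk <- function(b, rc) {
    list(
      bnti = tibble::tibble(sample_a = "x", sample_b = "y", bnti = b,
                            degenerate = FALSE),
      rc = tibble::tibble(sample_a = "x", sample_b = "y", rc_bray = rc)
    )
  }
  lab <- function(b, rc) {
    with(mk(b, rc), partition_processes(bnti, rc))$process
  }
  expect_equal(lab(3, 0.99), "heterogeneous_selection")
  expect_equal(lab(3, -0.99), "heterogeneous_selection")
  expect_equal(lab(-2.5, 0), "homogeneous_selection")
  expect_equal(lab(0, 0.99), "dispersal_limitation")
  expect_equal(lab(0, -0.99), "homogenizing_dispersal")
  expect_equal(lab(0, 0), "undominated")
  expect_equal(lab(1.99, 0.5), "undominated")
  ## boundary policy: equality counts as the non-null class
  expect_equal(lab(2, 0), "heterogeneous_selection")
  expect_equal(lab(-2, 0), "homogeneous_selection")
  expect_equal(lab(0, 0.95), "dispersal_limitation")
  expect_equal(lab(0, -0.95), "homogenizing_dispersal")
})

test_that("fractions sum to one and ignore pair ordering and labels", {
  tr <- simulate_tree(20, seed = 21)
  ct <- random_table(n_otu = 20, n_samp = 6, seed = 21)
  rownames(ct$counts) <- rownames(ct$relabund) <- tr$tip.label
  b <- bnti(ct, tr, reps = 99, seed = 1)
  r <- raup_crick(ct, reps = 99, seed = 1)
  p <- partition_processes(b, r)
  fr <- process_fractions(p)
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-12)
  expect_setequal(fr$process,
                  c("heterogeneous_selection", "homogeneous_selection",
                    "dispersal_limitation", "homogenizing_dispersal",
                    "undominated"))

  ## shuffle the rc rows: same fractions
  r_shuf <- r[withr::with_seed(2, sample(nrow(r))), ]
  fr2 <- process_fractions(partition_processes(b, r_shuf))
  expect_equal(fr, fr2)

  ## mismatched pair sets error
  expect_error(partition_processes(b[-1, ], r), "different sample pairs")
})

test_that("per-habitat partitions never mix groups", {
  cfg <- sim_config(n_lakes = 4, n_otus = 50, regime = "neutral_mix",
                    seed = 77, depth = 2000)
  ds <- simulate_dataset(cfg)
  part <- assembly_partition(ds$table, ds$tree, ds$metadata, reps = 49,
                             seed = 1)
  hab <- ds$metadata$habitat[match(part$sample_a, ds$metadata$sample_id)]
  hab_b <- ds$metadata$habitat[match(part$sample_b, ds$metadata$sample_id)]
  expect_true(all(hab == hab_b))
  expect_true(all(hab == part$group))
  fr <- process_fractions(part)
  sums <- tapply(fr$fraction, fr$group, sum)
  expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-12)
})
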