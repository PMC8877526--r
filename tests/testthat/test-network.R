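test_that("OTU filtering applies strict abundance and prevalence rules", {
  ## 10 OTUs, 23 samples, engineered means/prevalences
  n_s <- 23
  m <- matrix(0L, 10, n_s,
              dimnames = list(paste0("t", 1:10), paste0("s", 1:n_s)))
  m[1, ] <- 100L                  # abundant, everywhere: kept
  m[2, 1:6] <- 100L               # abundant but in exactly 6 samples: removed
  m[3, 1:7] <- 100L               # abundant, 7 samples: kept
  m[4, ] <- 1L                    # everywhere but rare: depends on mean
  m[5, 1:10] <- 50L
  m[10, ] <- m[10, ] + 1000L      # dominant filler so relabund is meaningful
  ct <- community_table(m)
  keep_oracle <- rownames(m)[rowMeans(ct$relabund) > 1e-4 &
                             rowSums(m > 0) >= 7]
  filt <- filter_otus(ct)
  expect_setequal(otu_ids(filt), keep_oracle)
  expect_false("t2" %in% otu_ids(filt))
  expect_true("t3" %in% otu_ids(filt))

  ## an OTU at exactly 0.01% mean relative abundance is removed (strict >)
  exact <- matrix(c(1L, 9999L, 1L, 9999L, 1L, 9999L, 1L, 9999L,
                    1L, 9999L, 1L, 9999L, 1L, 9999L), 2,
                  dimnames = list(c("edge", "bulk"), paste0("s", 1:7)))
  f2 <- filter_otus(community_table(exact))
  expect_false("edge" %in% otu_ids(f2))

  tiny <- community_table(matrix(c(1L, 1L), 2,
                                 dimnames = list(c("a", "b"), "s1")))
  expect_error(filter_otus(tiny), "no OTU passes")
})

test_that("correlation edges find exactly the planted monotone pairs", {
  withr::with_seed(99, {
    n_s <- 20
    base <- matrix(rpois(20 * n_s, 20), 20, n_s,
                   dimnames = list(paste0("t", 1:20), paste0("s", 1:n_s)))
    grad <- seq_len(n_s)
    ## plant three strongly monotone pairs
    base[1, ] <- 10L + grad                  # t1 ~ t2 positive
    base[2, ] <- 20L + 2L * grad
    base[3, ] <- 10L + grad                  # t3 ~ t4 negative
    base[4, ] <- 100L - 2L * grad
    base[5, ] <- c(10L + grad[1:19], 40L)    # t5 ~ t6 positive (near-perfect)
    base[6, ] <- c(15L + grad[1:19], 44L)
    ct <- community_table(base)
  })
  edges <- correlation_edges(ct, rho_threshold = 0.6, alpha = 0.01)
  planted <- c("t1|t2", "t3|t4", "t5|t6")
  found <- paste(edges$otu_a, edges$otu_b, sep = "|")
  expect_true(all(planted %in% found))

  ## oracle: brute force over all pairs with cor.test
  rel <- t(ct$relabund)
  oracle_p <- oracle_r <- c()
  combs <- utils::combn(colnames(rel), 2)
  for (i in seq_len(ncol(combs))) {
    ht <- suppressWarnings(stats::cor.test(rel[, combs[1, i]],
                                           rel[, combs[2, i]],
                                           method = "spearman"))
    oracle_r[i] <- unname(ht$estimate)
    oracle_p[i] <- ht$p.value
  }
  oracle_q <- stats::p.adjust(oracle_p, "BH")
  oracle_keep <- sort(paste(pmin(combs[1, ], combs[2, ]),
                            pmax(combs[1, ], combs[2, ]),
                            sep = "|")[abs(oracle_r) > 0.6 & oracle_q < 0.01])
  expect_equal(sort(found), oracle_keep)
  expect_equal(edges$sign, ifelse(edges$rho > 0, "positive", "negative"))
})

test_that("correlation edge cases: perfect monotones and constant vectors", {
  ## equal column sums keep 'flat' constant in relative abundance too
  m <- matrix(c(1L, 2L, 3L, 4L,
                4L, 3L, 2L, 1L,
                5L, 5L, 5L, 5L,
                10L, 10L, 10L, 10L), byrow = TRUE, nrow = 4,
              dimnames = list(c("up", "down", "flat", "filler"),
                              paste0("s", 1:4)))
  expect_warning(
    edges <- correlation_edges(community_table(m), rho_threshold = 0.5,
                               alpha = 1),
    "constant OTU vector")
  dn_pair <- edges[edges$otu_a == "down" & edges$otu_b == "up", ]
  expect_equal(dn_pair$rho, -1)
  expect_false(any(edges$otu_a == "flat" | edges$otu_b == "flat"))
  expect_error(correlation_edges(toy_table()), "at least 4")
})

test_that("topology matches hand-enumerated values and printed identities", {
  tri <- build_network(tibble::tibble(
    otu_a = c("a", "a", "b"), otu_b = c("b", "c", "c"),
    rho = 0.9, p_value = 0, q_value = 0, sign = "positive"))
  g <- glance(network_topology(tri))
  expect_equal(g$graph_density, 1)
  expect_equal(g$clustering_coefficient, 1)
  expect_equal(g$average_path_length, 1)
  expect_equal(g$diameter, 1)

  path <- build_network(tibble::tibble(
    otu_a = c("a", "b"), otu_b = c("b", "c"),
    rho = 0.9, p_value = 0, q_value = 0, sign = "positive"))
  gp <- glance(network_topology(path))
  expect_equal(gp$clustering_coefficient, 0)
  expect_equal(gp$average_path_length, 4 / 3)
  expect_equal(gp$diameter, 2)

  ## the identities behind the printed network sizes: a graph with
  ## n = 284, m = 458 must report average degree 3.225 and density 0.011
  g284 <- withr::with_seed(1, igraph::sample_gnm(284, 458))
  t284 <- glance(network_topology(g284, node_level = FALSE))
  expect_equal(round(t284$average_degree, 3), 3.225)
  expect_equal(round(t284$graph_density, 3), 0.011)
})

test_that("degree and density identities hold on random graphs", {
  for (seed in 1:10) {
    g <- withr::with_seed(seed, igraph::sample_gnp(40, 0.1))
    top <- glance(network_topology(g, node_level = FALSE))
    n <- top$n_nodes; e <- top$n_edges
    expect_identical(top$average_degree, 2 * e / n)
    expect_identical(top$graph_density, 2 * e / (n * (n - 1)))
  }
})

test_that("ER ensembles behave as theory forces", {
  ## complete graph: every replicate identical
  full <- er_ensemble(6, 15, reps = 20, seed = 1)
  expect_equal(full$mean[full$metric == "average_path_length"], 1)
  expect_equal(full$sd[full$metric == "average_path_length"], 0)
  expect_equal(full$mean[full$metric == "clustering_coefficient"], 1)

  ## mean transitivity approaches the edge density
  ens <- er_ensemble(60, 180, reps = 60, seed = 2)
  dens <- 2 * 180 / (60 * 59)
  expect_lt(abs(ens$mean[ens$metric == "clustering_coefficient"] - dens),
            0.02)
  ## determinism and feasibility check
  expect_identical(er_ensemble(20, 30, reps = 5, seed = 9),
                   er_ensemble(20, 30, reps = 5, seed = 9))
  expect_error(er_ensemble(5, 11), "more edges")
})

test_that("modules follow the Newman-Girvan arithmetic and size ranking", {
  two_k3 <- tibble::tibble(
    otu_a = c("a", "a", "b", "x", "x", "y"),
    otu_b = c("b", "c", "c", "y", "z", "z"),
    rho = 0.9, p_value = 0, q_value = 0, sign = "positive")
  net <- detect_modules(build_network(two_k3))
  expect_equal(attr(net$modules, "modularity"), 0.5)
  expect_equal(length(unique(net$modules$module)), 2)

  k4 <- tibble::tibble(
    otu_a = c("a", "a", "a", "b", "b", "c"),
    otu_b = c("b", "c", "d", "c", "d", "d"),
    rho = 0.9, p_value = 0, q_value = 0, sign = "positive")
  netk <- detect_modules(build_network(k4))
  expect_equal(attr(netk$modules, "modularity"), 0)
  expect_equal(length(unique(netk$modules$module)), 1)

  lonely <- detect_modules(build_network(two_k3[0, ], nodes = c("p", "q")))
  expect_equal(sort(lonely$modules$module), 1:2)
  expect_equal(attr(lonely$modules, "modularity"), 0)
})

test_that("major-module subtables use the strict >30 rule and partition nodes", {
  clique_edges <- function(ids) {
    cmb <- utils::combn(ids, 2)
    tibble::tibble(otu_a = cmb[1, ], otu_b = cmb[2, ], rho = 0.9,
                   p_value = 0, q_value = 0, sign = "positive")
  }
  big <- paste0("B", sprintf("%02d", 1:31))    # 31 nodes: major
  small <- paste0("S", sprintf("%02d", 1:30))  # 30 nodes: not major
  edges <- dplyr::bind_rows(clique_edges(big), clique_edges(small))
  net <- detect_modules(build_network(edges))
  expect_setequal(net$modules$otu_id, c(big, small))
  expect_equal(anyDuplicated(net$modules$otu_id), 0L)

  counts <- matrix(rep(c(3L, 1L), length.out = 61 * 8), 61, 8,
                   dimnames = list(c(big, small), paste0("s", 1:8)))
  ct <- community_table(counts)
  mods <- module_subtables(net, ct)
  expect_equal(length(mods), 1)
  expect_setequal(mods[[1]]$otus, big)
  expect_true(all(colSums(mods[[1]]$table$counts) <= colSums(ct$counts)))
})

test_that("node-feature contrasts match exact enumeration", {
  mk_report <- function(vals) {
    structure(list(node_level = tibble::tibble(
      otu_id = paste0("o", seq_along(vals)), degree = vals,
      betweenness = vals, closeness = vals, eccentricity = vals,
      local_clustering = vals)), class = "topology_report")
  }
  a <- mk_report(1:10)
  b <- mk_report(101:110)
  res <- compare_node_features(a, b)
  ## complete separation at n = 10, 10: exact two-sided p = 2 / C(20, 10)
  expect_equal(unique(res$p_value), 2 / choose(20, 10))
  res_sw <- compare_node_features(b, a)
  expect_equal(res$p_value, res_sw$p_value)

  same <- compare_node_features(a, a)
  expect_true(all(same$p_value > 0.99))

  const <- compare_node_features(mk_report(rep(1, 5)), mk_report(rep(1, 5)))
  expect_true(all(is.na(const$p_value)))
  expect_equal(unique(const$note), "constant in both")
})
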