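#' Simulation configuration for synthetic study designs
#'
#' Bundles the parameters of the synthetic-data generator, which emulates a
#' regional survey of lakes sampled in two habitats (sediment and water)
#' with a shared species pool, habitat-specific environmental gradients and
#' a choice of community-assembly regime with known ground truth.
#'
#' Regimes:
#' * `homogeneous_selection` - every sample filtered toward one shared
#'   trait optimum (Gaussian niche filter of width `selection_sd` on a
#'   phylogenetically conserved trait), with per-sample colonization
#'   lottery inside the selected clade.
#' * `heterogeneous_selection` - as above, but lake optima follow the TP
#'   gradient, so environmentally distant lakes are filtered toward
#'   different clades.
#' * `dispersal_limitation` - independent Wright-Fisher drift per sample
#'   (community size `community_size`, `drift_steps` generations) with a
#'   small residual migration `migration` from the regional pool.
#' * `homogenizing_dispersal` - mass effects: one realized regional
#'   community (multinomial of size `regional_size` from the pool) mixed
#'   into every sample at migration `migration` (near 1), plus a small
#'   local lottery component.
#' * `neutral_mix` - drift with intermediate migration.
#'
#' @param n_lakes Number of lakes (default 23).
#' @param habitats Habitat labels (default sediment and water).
#' @param n_otus Species-pool size (default 500).
#' @param regime Assembly regime; see Details.
#' @param selection_sd Niche-filter width sigma (> 0) in standardized trait
#'   units; smaller = stronger selection. Default 0.15.
#' @param migration Migration rate in \[0, 1\]; `NULL` picks the regime
#'   default (0.01 for dispersal limitation, 0.95 for homogenizing
#'   dispersal, 0.3 for the neutral mix).
#' @param depth Target reads per sample (default 10000).
#' @param seed Integer seed; mandatory, every stochastic stage derives its
#'   stream from it.
#' @param pool_sdlog Lognormal shape of the regional species-abundance
#'   distribution.
#' @param conservatism Depth-transform exponent in (0, 1\] applied to node
#'   heights before trait evolution; values < 1 concentrate trait variance
#'   toward the root so habitat preference is conserved at clade level.
#' @param colonization Per-sample Bernoulli colonization probability of
#'   pool members in lottery components.
#' @param lottery_sd Lognormal sd of the per-sample abundance lottery.
#' @param drift_steps,community_size Wright-Fisher generations and
#'   community size for drift regimes.
#' @param regional_size Individuals in the realized regional community of
#'   the homogenizing regime.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_lakes = 23,
                       habitats = c("sediment", "water"),
                       n_otus = 500,
                       regime = c("homogeneous_selection",
                                  "heterogeneous_selection",
                                  "dispersal_limitation",
                                  "homogenizing_dispersal",
                                  "neutral_mix"),
                       selection_sd = 0.15,
                       migration = NULL,
                       depth = 10000,
                       seed = NULL,
                       pool_sdlog = 1,
                       conservatism = 0.2,
                       colonization = 0.6,
                       lottery_sd = 0.5,
                       drift_steps = 50,
                       community_size = 500,
                       regional_size = 2000) {
  regime <- match.arg(regime)
  if (is.null(seed)) stop("a seed is mandatory for simulation", call. = FALSE)
  if (n_lakes < 1 || n_otus < 2) stop("need n_lakes >= 1 and n_otus >= 2",
                                      call. = FALSE)
  if (regime %in% c("homogeneous_selection", "heterogeneous_selection") &&
      selection_sd <= 0) {
    stop("selection regimes need selection_sd > 0 (degenerate niche weights)",
         call. = FALSE)
  }
  if (is.null(migration)) {
    migration <- switch(regime,
                        dispersal_limitation = 0.01,
                        homogenizing_dispersal = 0.95,
                        neutral_mix = 0.3,
                        0)
  }
  if (migration < 0 || migration > 1) stop("migration must be in [0, 1]",
                                           call. = FALSE)
  if (depth < 1) stop("depth must be positive", call. = FALSE)
  structure(list(
    n_lakes = n_lakes, habitats = habitats, n_otus = n_otus, regime = regime,
    selection_sd = selection_sd, migration = migration, depth = depth,
    seed = as.integer(seed), pool_sdlog = pool_sdlog,
    conservatism = conservatism, colonization = colonization,
    lottery_sd = lottery_sd, drift_steps = drift_steps,
    community_size = community_size, regional_size = regional_size
  ), class = "sim_config")
}

sub_seed <- function(seed, offset) as.integer((seed + offset) %% (2^31 - 1))

#' Simulate a random Yule phylogeny
#'
#' @param n_otus Number of tips (>= 2), labeled `OTU_1 .. OTU_n`.
#' @param seed Integer seed.
#' @return A rooted ultrametric `phylo` tree with positive branch lengths.
#' @export
simulate_tree <- function(n_otus, seed) {
  if (n_otus < 2) stop("need at least 2 OTUs", call. = FALSE)
  tree <- withr::with_seed(seed, ape::rphylo(n_otus, birth = 1, death = 0))
  tree$tip.label <- paste0("OTU_", seq_len(n_otus))
  validate_tree(tree)
}

## Concentrate node heights toward the root (depth^delta transform) so a
## Brownian trait on the transformed tree is conserved at clade level.
deep_conserved_tree <- function(tree, delta) {
  nd <- ape::node.depth.edgelength(tree)
  H <- max(nd)
  nd2 <- H * (nd / H)^delta
  tree$edge.length <- nd2[tree$edge[, 2]] - nd2[tree$edge[, 1]]
  tree
}

#' Evolve a phylogenetically conserved niche trait
#'
#' Brownian motion on a depth-transformed copy of the tree (see
#' [sim_config()]'s `conservatism`), standardized to mean 0, sd 1 across
#' tips.
#'
#' @param tree A `phylo` tree.
#' @param conservatism Depth-transform exponent.
#' @param seed Integer seed.
#' @return Named numeric vector of tip traits.
#' @export
simulate_traits <- function(tree, conservatism = 0.2, seed = NULL) {
  run <- function() ape::rTraitCont(deep_conserved_tree(tree, conservatism),
                                    model = "BM", sigma = 1)
  z <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  (z - mean(z)) / stats::sd(z)
}

#' Simulate sample metadata with environmental gradients
#'
#' One row per lake x habitat. Total phosphorus (TP) is the selective axis:
#' constant across lakes under `homogeneous_selection` (variance 0),
#' a uniform gradient on \[0.02, 0.5\] mg/L under `heterogeneous_selection`,
#' and independent noise otherwise. The remaining variables (pH,
#' conductivity, organic carbon, TN) are habitat-specific independent noise.
#'
#' @param config A [sim_config()].
#' @return Metadata tibble: `sample_id`, `habitat`, `lake_id`, `ph`,
#'   `conductivity`, `organic_carbon`, `tn`, `tp`.
#' @export
simulate_environment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(sub_seed(config$seed, 1), {
    rows <- list()
    for (h in config$habitats) {
      n <- config$n_lakes
      tp <- switch(config$regime,
                   homogeneous_selection = rep(0.26, n),
                   heterogeneous_selection = seq(0.02, 0.5, length.out = n),
                   stats::runif(n, 0.02, 0.5))
      rows[[h]] <- tibble::tibble(
        sample_id = sprintf("L%02d_%s", seq_len(n), h),
        habitat = h,
        lake_id = sprintf("L%02d", seq_len(n)),
        ph = stats::rnorm(n, if (h == "sediment") 7.6 else 8.3, 0.4),
        conductivity = stats::rlnorm(n, if (h == "sediment") 5.5 else 6.3, 0.5),
        organic_carbon = stats::rlnorm(n, if (h == "sediment") 2.5 else 1.2, 0.6),
        tn = stats::rlnorm(n, -0.5, 0.5),
        tp = tp
      )
    }
    dplyr::bind_rows(rows)
  })
}

## Map TP to a trait optimum in [-1.5, 1.5] (the span of the standardized
## trait): the selective environmental axis seen by the niche filter.
tp_to_optimum <- function(tp) {
  lo <- 0.02; hi <- 0.5
  pmin(pmax((tp - lo) / (hi - lo), 0), 1) * 3 - 1.5
}

#' Simulate communities under a known assembly regime
#'
#' Draws `depth` individuals per sample from regime-specific composition
#' vectors built on a shared lognormal species pool; see [sim_config()]
#' for the regime mechanics.
#'
#' @param config A [sim_config()].
#' @param tree Phylogeny whose tips form the species pool (tips must be at
#'   least the configured `n_otus`).
#' @param env Metadata from [simulate_environment()].
#' @return A [community_table()] (OTUs x samples).
#' @export
simulate_communities <- function(config, tree, env) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_otus
  if (length(tree$tip.label) < n) {
    stop("tree has fewer tips than the configured species pool", call. = FALSE)
  }
  z <- simulate_traits(tree, config$conservatism,
                       seed = sub_seed(config$seed, 2))
  withr::with_seed(sub_seed(config$seed, 3), {
    pool <- stats::rlnorm(n, 0, config$pool_sdlog)
    pool <- pool / sum(pool)
    lottery <- function() {
      w <- pool * stats::rbinom(n, 1, config$colonization) *
        exp(config$lottery_sd * stats::rnorm(n))
      w / sum(w)
    }
    drift <- function(m) {
      q <- pool
      for (t in seq_len(config$drift_steps)) {
        q <- stats::rmultinom(1, config$community_size, q)[, 1] /
          config$community_size
        q <- (1 - m) * q + m * pool
      }
      q
    }
    regional <- NULL
    if (config$regime == "homogenizing_dispersal") {
      ## one realized regional community per run: mass effects share it
      regional <- stats::rmultinom(1, config$regional_size, pool)[, 1] /
        config$regional_size
    }
    qs <- lapply(seq_len(nrow(env)), function(i) {
      switch(config$regime,
        homogeneous_selection = ,
        heterogeneous_selection = {
          opt <- tp_to_optimum(env$tp[i])
          w <- lottery() * exp(-(z - opt)^2 / (2 * config$selection_sd^2))
          if (sum(w) == 0) stop("niche filter removed every taxon",
                                call. = FALSE)
          w / sum(w)
        },
        dispersal_limitation = ,
        neutral_mix = drift(config$migration),
        homogenizing_dispersal = {
          config$migration * regional + (1 - config$migration) * lottery()
        })
    })
    counts <- vapply(qs, function(q) stats::rmultinom(1, config$depth, q)[, 1],
                     numeric(n))
    dimnames(counts) <- list(tree$tip.label[seq_len(n)], env$sample_id)
    community_table(counts)
  })
}

#' Assign a clade-based synthetic taxonomy
#'
#' Cuts the tree into `n_supergroups` deep clades and `n_lineages` finer
#' clades by average-linkage clustering of patristic distances, yielding a
#' two-rank lineage string per OTU.
#'
#' @param tree A `phylo` tree.
#' @param n_supergroups,n_lineages Number of groups per rank.
#' @return Tibble: `otu_id`, `supergroup`, `lineage`.
#' @export
simulate_taxonomy <- function(tree, n_supergroups = 11, n_lineages = 25) {
  D <- ape::cophenetic.phylo(tree)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  sg <- stats::cutree(hc, k = min(n_supergroups, length(tree$tip.label)))
  lg <- stats::cutree(hc, k = min(n_lineages, length(tree$tip.label)))
  tibble::tibble(
    otu_id = names(sg),
    supergroup = sprintf("Supergroup_%02d", sg),
    lineage = sprintf("Lineage_%02d", lg)
  )
}

#' Simulate a complete synthetic dataset
#'
#' Tree, environment, communities and taxonomy from one seeded
#' configuration.
#'
#' @param config A [sim_config()].
#' @return List with `table`, `tree`, `metadata`, `taxonomy`, `traits`,
#'   `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tree <- simulate_tree(config$n_otus, seed = sub_seed(config$seed, 0))
  env <- simulate_environment(config)
  table <- simulate_communities(config, tree, env)
  taxonomy <- simulate_taxonomy(tree)
  list(table = table, tree = tree, metadata = env, taxonomy = taxonomy,
       traits = simulate_traits(tree, config$conservatism,
                                seed = sub_seed(config$seed, 2)),
       config = config)
}

#' Write a simulated dataset to a directory
#'
#' Emits `otu_table.tsv`, `tree.nwk`, `metadata.tsv`, `taxonomy.tsv`.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_otu_table(dataset$table, file.path(dir, "otu_table.tsv"))
  ape::write.tree(dataset$tree, file.path(dir, "tree.nwk"))
  readr::write_tsv(dataset$metadata, file.path(dir, "metadata.tsv"),
                   progress = FALSE)
  readr::write_tsv(dataset$taxonomy, file.path(dir, "taxonomy.tsv"),
                   progress = FALSE)
  invisible(dir)
}
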