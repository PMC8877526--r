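#' Filter OTUs for network construction
#'
#' Keeps OTUs whose mean relative abundance across the supplied samples is
#' strictly greater than `min_mean_relabund` (default 0.01%) and that are
#' present (count > 0) in at least `min_prevalence` samples (default 7,
#' i.e. "more than 6 samples"). Relative abundances are computed within
#' the supplied sample set only, so per-habitat filtering sees
#' habitat-local proportions.
#'
#' @param table A [community_table()], typically already restricted to one
#'   habitat via [subset_community()].
#' @param min_mean_relabund Strict lower bound on mean relative abundance.
#' @param min_prevalence Minimum number of samples with non-zero count.
#' @return A filtered [community_table()].
#' @export
filter_otus <- function(table, min_mean_relabund = 1e-4, min_prevalence = 7) {
  stopifnot(inherits(table, "community_table"))
  keep <- rowMeans(table$relabund) > min_mean_relabund &
    rowSums(table$counts > 0) >= min_prevalence
  if (!any(keep)) {
    stop("no OTU passes the abundance/prevalence filter; relax the thresholds",
         call. = FALSE)
  }
  subset_community(table, otus = otu_ids(table)[keep])
}

#' Spearman correlation edges between OTUs
#'
#' All-against-all Spearman rank correlations across samples (average ranks
#' for ties), two-sided p-values from the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}}, Benjamini-Hochberg correction
#' across all upper-triangle pairs, and retention of strong
#' (|rho| > `rho_threshold`) and significant (q < `alpha`) pairs.
#'
#' @param table A filtered [community_table()] with >= 4 samples.
#' @param rho_threshold Strict threshold on |rho| (default 0.6).
#' @param alpha Threshold on the FDR-adjusted p (default 0.01 per the
#'   methods convention; 0.05 is the common relaxed alternative).
#' @return Tibble of retained edges: `otu_a`, `otu_b` (a < b), `rho`,
#'   `p_value`, `q_value`, `sign`. Constant OTU vectors yield undefined
#'   correlations; such pairs are skipped with a warning.
#' @export
correlation_edges <- function(table, rho_threshold = 0.6, alpha = 0.01) {
  stopifnot(inherits(table, "community_table"))
  n <- ncol(table$counts)
  if (n < 4) stop("need at least 4 samples for correlation edges",
                  call. = FALSE)
  ## Spearman on per-sample relative abundances; ranks are identical to
  ## ranks of counts because the per-sample normalization is monotone.
  m <- t(table$relabund)
  constant <- apply(m, 2, function(v) stats::sd(v) == 0)
  if (any(constant)) {
    warning(sum(constant), " constant OTU vector(s) skipped in correlations",
            call. = FALSE)
  }
  ok <- which(!constant)
  rho <- suppressWarnings(stats::cor(m[, ok, drop = FALSE],
                                     method = "spearman"))
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[idx]
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  q <- stats::p.adjust(p, method = "BH")
  ids <- colnames(rho)
  keep <- abs(r) > rho_threshold & q < alpha
  tibble::tibble(
    otu_a = pmin(ids[idx[, 1]], ids[idx[, 2]])[keep],
    otu_b = pmax(ids[idx[, 1]], ids[idx[, 2]])[keep],
    rho = r[keep],
    p_value = p[keep],
    q_value = q[keep],
    sign = ifelse(r[keep] > 0, "positive", "negative")
  ) |> dplyr::arrange(.data$otu_a, .data$otu_b)
}

#' Build a co-occurrence network from retained edges
#'
#' @param edges Edge tibble from [correlation_edges()].
#' @param nodes Optional character vector of node ids (defaults to the
#'   OTUs appearing in `edges`); isolated nodes are allowed.
#' @param taxonomy Optional taxonomy tibble; lineages are attached to the
#'   nodes (unknown OTUs become `"unclassified"`).
#' @return A `cooccurrence_network`: an undirected simple igraph graph plus
#'   the edge tibble; [detect_modules()] adds module membership.
#' @export
build_network <- function(edges, nodes = NULL, taxonomy = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$otu_a, edges$otu_b)))
  g <- igraph::graph_from_data_frame(
    edges[, c("otu_a", "otu_b", "rho", "q_value", "sign")],
    directed = FALSE,
    vertices = data.frame(name = nodes)
  )
  if (igraph::any_multiple(g) || igraph::any_loop(g)) {
    stop("edge list contains self-loops or duplicate pairs", call. = FALSE)
  }
  if (!is.null(taxonomy)) {
    igraph::V(g)$lineage <- taxonomy_lookup(taxonomy, nodes, "lineage")
    igraph::V(g)$supergroup <- taxonomy_lookup(taxonomy, nodes, "supergroup")
  }
  igraph::V(g)$degree <- igraph::degree(g)
  structure(list(graph = g, edges = edges, modules = NULL),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("<cooccurrence_network> ", igraph::vcount(x$graph), " nodes, ",
      igraph::ecount(x$graph), " edges (",
      sum(x$edges$sign == "negative"), " negative)\n", sep = "")
  invisible(x)
}

#' @export
tidy.cooccurrence_network <- function(x, ...) x$edges

#' Network- and node-level topology
#'
#' Unweighted, unsigned topology of a (possibly disconnected) graph:
#' average path length and diameter over reachable pairs only, global
#' transitivity (3 x triangles / connected triples), Freeman
#' centralizations (closeness on the largest connected component), and
#' Newman-Girvan modularity of the greedy partition. Negative edges
#' participate as ordinary edges and are additionally counted.
#'
#' @param network A `cooccurrence_network` or bare igraph graph.
#' @param node_level Also compute per-node features.
#' @return A `topology_report`: `glance()` gives the one-row network-level
#'   tibble, `tidy()` the node-level features (degree, betweenness,
#'   closeness, eccentricity, local clustering).
#' @export
network_topology <- function(network, node_level = TRUE) {
  g <- if (inherits(network, "cooccurrence_network")) network$graph else network
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  n_neg <- if (inherits(network, "cooccurrence_network")) {
    sum(network$edges$sign == "negative")
  } else if ("sign" %in% igraph::edge_attr_names(g)) {
    sum(igraph::E(g)$sign == "negative")
  } else NA_integer_
  small <- n < 2
  apl <- if (small || e == 0) NA_real_ else
    igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
  diam <- if (small || e == 0) NA_real_ else
    igraph::diameter(g, directed = FALSE, unconnected = TRUE)
  trans <- igraph::transitivity(g, type = "global")
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  mod <- if (e > 0) {
    igraph::modularity(igraph::cluster_fast_greedy(g))
  } else 0
  net <- tibble::tibble(
    n_nodes = n,
    n_edges = e,
    n_negative_edges = n_neg,
    average_degree = if (n > 0) 2 * e / n else NA_real_,
    graph_density = if (n > 1) 2 * e / (n * (n - 1)) else NA_real_,
    average_path_length = apl,
    diameter = diam,
    clustering_coefficient = ifelse(is.nan(trans), NA_real_, trans),
    centralization_degree = if (n > 2)
      igraph::centr_degree(g, loops = FALSE)$centralization else NA_real_,
    centralization_betweenness = if (n > 2)
      igraph::centr_betw(g, directed = FALSE)$centralization else NA_real_,
    centralization_closeness = if (igraph::vcount(giant) > 2)
      suppressWarnings(igraph::centr_clo(giant)$centralization) else NA_real_,
    modularity = mod
  )
  nodes <- NULL
  if (node_level && n > 0) {
    ecc <- igraph::eccentricity(g)  # within component
    lc <- igraph::transitivity(g, type = "local", isolates = "zero")
    nodes <- tibble::tibble(
      otu_id = igraph::V(g)$name,
      degree = unname(igraph::degree(g)),
      betweenness = unname(igraph::betweenness(g, directed = FALSE)),
      closeness = unname(suppressWarnings(
        igraph::closeness(g, mode = "all"))),
      eccentricity = unname(ecc),
      local_clustering = lc
    )
  }
  structure(list(network_level = net, node_level = nodes),
            class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat("<topology_report>\n")
  print(x$network_level)
  invisible(x)
}

#' @export
glance.topology_report <- function(x, ...) x$network_level

#' @export
tidy.topology_report <- function(x, ...) {
  if (is.null(x$node_level)) stop("report has no node-level features",
                                  call. = FALSE)
  x$node_level
}

#' Erdos-Renyi G(n, m) random-network ensemble
#'
#' Generates `reps` uniform random graphs with exactly the observed node
#' and edge counts and summarizes the topology metrics across the
#' ensemble, the standard baseline for deciding whether an observed
#' network is more structured than chance.
#'
#' @param n_nodes,n_edges Size of each random graph.
#' @param reps Ensemble size (default 999).
#' @param seed Optional integer seed.
#' @param metrics Which metrics to track per replicate.
#' @return Tibble with `metric`, `mean`, `sd`, `n_reps`; the per-replicate
#'   values are attached as attribute `"replicates"`.
#' @export
er_ensemble <- function(n_nodes, n_edges, reps = 999, seed = NULL,
                        metrics = c("average_degree", "graph_density",
                                    "average_path_length", "diameter",
                                    "clustering_coefficient", "modularity")) {
  if (n_edges > n_nodes * (n_nodes - 1) / 2) {
    stop("more edges than a simple graph on ", n_nodes, " nodes can hold",
         call. = FALSE)
  }
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  run <- function() {
    vals <- matrix(NA_real_, reps, length(metrics),
                   dimnames = list(NULL, metrics))
    for (r in seq_len(reps)) {
      g <- igraph::sample_gnm(n_nodes, n_edges)
      rep_row <- network_topology(g, node_level = FALSE)$network_level
      vals[r, ] <- unlist(rep_row[metrics])
    }
    vals
  }
  vals <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out <- tibble::tibble(
    metric = metrics,
    mean = unname(colMeans(vals, na.rm = TRUE)),
    sd = unname(apply(vals, 2, stats::sd, na.rm = TRUE)),
    n_reps = as.integer(reps)
  )
  attr(out, "replicates") <- tibble::as_tibble(vals)
  out
}

#' Detect modules by greedy modularity optimization
#'
#' Deterministic fast-greedy agglomeration on the unsigned graph;
#' modularity Q follows the standard Newman-Girvan definition. An edgeless
#' network puts every node in its own module with Q = 0.
#'
#' @param network A `cooccurrence_network`.
#' @return The network with `modules` filled in: a tibble `otu_id`,
#'   `module` (ranked by size: module 1 is largest), plus attribute
#'   `modularity`.
#' @export
detect_modules <- function(network) {
  stopifnot(inherits(network, "cooccurrence_network"))
  g <- network$graph
  if (igraph::ecount(g) == 0) {
    mem <- seq_len(igraph::vcount(g))
    q <- 0
  } else {
    cl <- igraph::cluster_fast_greedy(g)
    mem <- igraph::membership(cl)
    q <- igraph::modularity(cl)
    if (q <= 1e-12) {
      ## no community structure beyond chance: one module by convention
      mem <- rep(1L, igraph::vcount(g))
      q <- 0
    }
  }
  ## rank module ids by size, ties broken by original id
  sizes <- table(mem)
  ranked <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- integer(length(sizes))
  relabel[ranked] <- seq_along(ranked)
  modules <- tibble::tibble(
    otu_id = igraph::V(g)$name,
    module = relabel[match(as.integer(mem), as.integer(names(sizes)))]
  )
  attr(modules, "modularity") <- q
  igraph::V(network$graph)$module <- modules$module
  network$modules <- modules
  network
}

#' Per-module community subtables for the major modules
#'
#' "Major" modules have more than `min_nodes` nodes (default: more than
#' 30). For each, returns the sample x member-OTU subtable, its
#' Bray-Curtis matrix and a taxonomy composition summary.
#'
#' @param network A `cooccurrence_network` with modules detected.
#' @param table The habitat-level [community_table()] the network was
#'   built from.
#' @param taxonomy Optional taxonomy tibble for composition summaries.
#' @param min_nodes Strict lower bound on module size.
#' @return Named list (``module_<k>``) of lists with `otus`, `table`,
#'   `bray`, `composition`.
#' @export
module_subtables <- function(network, table, taxonomy = NULL, min_nodes = 30) {
  stopifnot(inherits(network, "cooccurrence_network"))
  if (is.null(network$modules)) stop("run detect_modules() first", call. = FALSE)
  mods <- split(network$modules$otu_id, network$modules$module)
  mods <- mods[vapply(mods, length, 1L) > min_nodes]
  out <- lapply(mods, function(otus) {
    sub <- subset_community(table, otus = intersect(otu_ids(table), otus),
                            drop_empty_samples = TRUE)
    comp <- NULL
    if (!is.null(taxonomy)) {
      comp <- tibble::tibble(
        lineage = taxonomy_lookup(taxonomy, otu_ids(sub), "lineage"),
        relabund = rowSums(sub$relabund) / ncol(sub$relabund)
      ) |>
        dplyr::group_by(.data$lineage) |>
        dplyr::summarise(relabund = sum(.data$relabund), .groups = "drop")
    }
    list(otus = otu_ids(sub), table = sub, bray = bray_curtis(sub),
         composition = comp)
  })
  names(out) <- paste0("module_", names(mods))
  out
}

#' Compare node-level features between two networks
#'
#' Two-sided Wilcoxon rank-sum (default) or Welch t-test per feature.
#'
#' @param report_a,report_b `topology_report`s with node-level features.
#' @param test `"wilcoxon"` or `"t_test"`.
#' @return Tibble: `feature`, `statistic`, `p_value` (NA with a note when
#'   the feature is constant in both groups).
#' @export
compare_node_features <- function(report_a, report_b,
                                  test = c("wilcoxon", "t_test")) {
  test <- match.arg(test)
  a <- tidy(report_a)
  b <- tidy(report_b)
  feats <- setdiff(intersect(names(a), names(b)), "otu_id")
  purrr::map_dfr(feats, function(f) {
    x <- a[[f]]; y <- b[[f]]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      return(tibble::tibble(feature = f, statistic = NA_real_,
                            p_value = NA_real_, note = "constant in both"))
    }
    ht <- if (test == "wilcoxon") {
      suppressWarnings(stats::wilcox.test(x, y))
    } else {
      stats::t.test(x, y, var.equal = FALSE)
    }
    tibble::tibble(feature = f, statistic = unname(ht$statistic),
                   p_value = ht$p.value, note = NA_character_)
  })
}
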