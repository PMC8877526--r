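#' Alpha diversity per sample
#'
#' Computes observed OTUs, bias-corrected Chao1, Shannon diversity and
#' Faith's phylogenetic diversity for every sample.
#'
#' Chao1 uses the bias-corrected form
#' \eqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))} with \eqn{F_1, F_2} the
#' singleton and doubleton counts, so it is defined when no doubletons are
#' present. Shannon is \eqn{-\sum p \log_2 p} (base 2, matching the
#' QIIME-era convention; set `shannon_base` for natural log). Faith's PD is
#' the total branch length of the minimal rooted subtree spanning the
#' present tips, including the path to the root ("PD whole tree").
#'
#' @param table A [community_table()] of integer counts.
#' @param tree Optional rooted `phylo` tree; required for `faith_pd`.
#'   OTUs absent from the tree are dropped from the PD computation with a
#'   warning (taxonomic metrics keep them).
#' @param shannon_base Logarithm base for Shannon diversity.
#' @return A tibble with one row per sample: `sample_id`, `observed_otus`,
#'   `chao1`, `shannon`, and `faith_pd` (NA if no tree given).
#' @export
alpha_diversity <- function(table, tree = NULL, shannon_base = 2) {
  stopifnot(inherits(table, "community_table"))
  counts <- table$counts
  if (any(counts != round(counts))) {
    stop("Chao1 requires integer counts, not proportions", call. = FALSE)
  }
  obs <- colSums(counts > 0)
  f1 <- colSums(counts == 1)
  f2 <- colSums(counts == 2)
  chao1 <- obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  shannon <- apply(table$relabund, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log(p, base = shannon_base))
  })
  faith <- rep(NA_real_, ncol(counts))
  if (!is.null(tree)) {
    validate_tree(tree)
    pruned <- prune_to_tree(table, tree)
    comm <- t(pruned$table$counts)            # picante wants samples x taxa
    if (any(rowSums(comm > 0) == 0)) {
      bad <- rownames(comm)[rowSums(comm > 0) == 0][1]
      stop("sample '", bad, "' has no OTUs on the tree; cannot compute PD",
           call. = FALSE)
    }
    pd <- picante::pd(comm, pruned$tree, include.root = TRUE)
    faith <- pd$PD[match(colnames(counts), rownames(pd))]
  }
  tibble::tibble(
    sample_id = colnames(counts),
    observed_otus = as.integer(unname(obs)),
    chao1 = unname(chao1),
    shannon = unname(shannon),
    faith_pd = unname(faith)
  )
}

## Drop table OTUs missing from the tree (warning with a count) and prune
## tree tips not in the table. Phylogenetic metrics only.
prune_to_tree <- function(table, tree) {
  in_tree <- otu_ids(table) %in% tree$tip.label
  if (!all(in_tree)) {
    warning(sum(!in_tree), " OTU(s) absent from the tree dropped from ",
            "phylogenetic metrics", call. = FALSE)
    table <- subset_community(table, otus = otu_ids(table)[in_tree])
  }
  extra <- setdiff(tree$tip.label, otu_ids(table))
  if (length(extra) > 0) {
    tree <- ape::drop.tip(tree, extra)
  }
  list(table = table, tree = tree)
}

#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} computed on
#' per-sample relative abundances, so the result is in \[0, 1\].
#'
#' @param table A [community_table()].
#' @return A [dist_matrix()] tagged `"bray_curtis"`.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "community_table"))
  d <- as.matrix(vegan::vegdist(t(table$relabund), method = "bray"))
  dist_matrix(d, metric = "bray_curtis")
}

#' Beta mean nearest taxon distance between samples
#'
#' For each taxon in one community, the patristic distance to its nearest
#' relative in the other community; the two directed, abundance-weighted
#' means are averaged:
#' \deqn{\beta MNTD(k,m) = \frac12 \left[ \sum_{i \in k} w_i \min_{j \in m}
#'   d_{ij} + \sum_{j \in m} w_j \min_{i \in k} d_{ji} \right]}
#' Shared taxa have nearest-taxon distance zero.
#'
#' @param table A [community_table()]; all counted OTUs must be tips of
#'   `tree` (others are dropped with a warning).
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param abundance_weighted Weight each taxon by its relative abundance
#'   (the framework norm); `FALSE` weights each present taxon equally.
#' @return A [dist_matrix()] tagged `"beta_mntd"`.
#' @export
beta_mntd <- function(table, tree, abundance_weighted = TRUE) {
  stopifnot(inherits(table, "community_table"))
  validate_tree(tree)
  pruned <- prune_to_tree(table, tree)
  W <- weight_matrix(pruned$table, abundance_weighted)
  D <- ape::cophenetic.phylo(pruned$tree)
  D <- D[otu_ids(pruned$table), otu_ids(pruned$table)]
  m <- cpp_bmntd(D, W)
  dimnames(m) <- list(sample_ids(pruned$table), sample_ids(pruned$table))
  dist_matrix(m, metric = "beta_mntd")
}

weight_matrix <- function(table, abundance_weighted) {
  if (abundance_weighted) {
    table$relabund
  } else {
    pa <- (table$counts > 0) * 1
    sweep(pa, 2, colSums(pa), "/")
  }
}

#' Levins niche width per OTU
#'
#' \eqn{B_i = 1 / \sum_{j=1}^{n} p_{ij}^2}, where \eqn{p_{ij}} is the
#' proportion of OTU \eqn{i}'s abundance found in community \eqn{j}
#' (normalized so the proportions sum to one across the \eqn{n}
#' communities). \eqn{B = 1} for an OTU restricted to a single community
#' and \eqn{B = n} for one spread perfectly evenly.
#'
#' @param table A [community_table()].
#' @return A tibble with `otu_id`, `b` (niche width) and `n_communities`.
#'   All-zero OTUs are excluded with a warning.
#' @export
niche_width <- function(table) {
  stopifnot(inherits(table, "community_table"))
  counts <- table$counts
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " all-zero OTU(s) excluded from niche width",
            call. = FALSE)
    counts <- counts[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  p <- sweep(counts, 1, tot, "/")
  tibble::tibble(
    otu_id = rownames(counts),
    b = unname(1 / rowSums(p^2)),
    n_communities = ncol(counts)
  )
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a distance matrix. Negative eigenvalues
#' (possible for non-Euclidean dissimilarities such as Bray-Curtis) are
#' reported as-is, not corrected.
#'
#' @param dm A [dist_matrix()].
#' @param k Number of axes to return.
#' @return An `eco_pcoa` object: `coords` tibble (sample_id, axis scores),
#'   `eigenvalues` (all of them, descending), `var_explained` (share of the
#'   sum of positive eigenvalues), and the metric tag.
#' @export
pcoa_ordination <- function(dm, k = 2) {
  stopifnot(inherits(dm, "dist_matrix"))
  n <- length(dm$ids)
  k <- min(k, n - 1)
  fit <- stats::cmdscale(stats::as.dist(dm$m), k = k, eig = TRUE)
  pts <- fit$points
  if (is.null(pts) || ncol(pts) == 0) {
    pts <- matrix(0, n, k, dimnames = list(dm$ids, NULL))
  } else if (ncol(pts) < k) {
    pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
  }
  coords <- tibble::as_tibble(pts, .name_repair = ~ paste0("axis", seq_len(k)))
  coords <- dplyr::bind_cols(tibble::tibble(sample_id = dm$ids), coords)
  eig <- fit$eig
  pos <- sum(eig[eig > 0])
  structure(list(
    coords = coords,
    eigenvalues = eig,
    var_explained = if (pos > 0) pmax(eig, 0)[seq_len(k)] / pos else rep(0, k),
    metric = dm$metric
  ), class = "eco_pcoa")
}

#' @export
print.eco_pcoa <- function(x, ...) {
  cat("<eco_pcoa> ", nrow(x$coords), " samples, metric = ", x$metric,
      ", axis 1-", length(x$var_explained), " explain ",
      round(100 * sum(x$var_explained), 1), "% of positive inertia\n",
      sep = "")
  invisible(x)
}

#' Compare a numeric feature between two groups
#'
#' Two-sided Wilcoxon rank-sum (default, with the normal approximation when
#' ties are present) or Welch t-test. For beta-diversity contrasts the
#' natural units are within-group pairwise distances; those pairs are not
#' independent, so treat the resulting p as descriptive.
#'
#' @param data A data frame.
#' @param value,group Column names (strings) of the numeric feature and the
#'   two-level grouping factor.
#' @param test `"wilcoxon"` or `"t_test"`.
#' @return One-row tibble: group sizes, statistic, two-sided `p_value`.
#' @export
compare_groups <- function(data, value, group, test = c("wilcoxon", "t_test")) {
  test <- match.arg(test)
  v <- data[[value]]
  g <- as.factor(data[[group]])
  if (nlevels(g) != 2) stop("`group` must have exactly two levels", call. = FALSE)
  x <- v[g == levels(g)[1]]
  y <- v[g == levels(g)[2]]
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (test == "wilcoxon") {
    ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  } else {
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      stop("both groups are constant; t-test undefined", call. = FALSE)
    }
    ht <- stats::t.test(x, y, alternative = "two.sided", var.equal = FALSE)
  }
  tibble::tibble(
    group_a = levels(g)[1], group_b = levels(g)[2],
    n_a = length(x), n_b = length(y),
    test = test,
    statistic = unname(ht$statistic),
    p_value = ht$p.value
  )
}
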