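#' Beta nearest taxon index (bNTI) for all sample pairs
#'
#' Standardized effect size of the observed beta-MNTD against a
#' tip-shuffling null: taxa labels are permuted across the whole phylogeny
#' (every OTU in the table), beta-MNTD is recomputed per shuffle, and
#' \deqn{\beta NTI = (\beta MNTD_{obs} - \overline{\beta MNTD_{null}}) /
#'   sd(\beta MNTD_{null})}
#' One shared shuffle sequence per repetition is reused for all pairs.
#' |bNTI| > 2 signals selection: observed phylogenetic turnover
#' significantly lower (homogeneous selection, bNTI < -2) or higher
#' (heterogeneous selection, bNTI > +2) than the null expects.
#'
#' @param table A [community_table()].
#' @param tree Rooted `phylo` tree covering the counted OTUs.
#' @param reps Number of null shuffles (>= 1).
#' @param seed Optional integer seed; the RNG state is restored afterwards.
#' @param abundance_weighted Weight beta-MNTD by relative abundance.
#' @return A tibble with one row per unordered sample pair: `sample_a`,
#'   `sample_b`, `observed_bmntd`, `null_mean`, `null_sd`, `bnti`,
#'   `n_reps`, `degenerate`. Pairs whose null distribution has zero spread
#'   are flagged degenerate with `bnti = NA` and are excluded from process
#'   fractions downstream.
#' @export
bnti <- function(table, tree, reps = 999, seed = NULL,
                 abundance_weighted = TRUE) {
  stopifnot(inherits(table, "community_table"))
  validate_tree(tree)
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  pruned <- prune_to_tree(table, tree)
  W <- weight_matrix(pruned$table, abundance_weighted)
  D <- ape::cophenetic.phylo(pruned$tree)
  D <- D[otu_ids(pruned$table), otu_ids(pruned$table)]
  obs <- cpp_bmntd(D, W)
  run <- function() cpp_bnti_null(D, W, as.integer(reps))
  nul <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  ids <- sample_ids(pruned$table)
  pairs <- pair_index(ids)
  idx <- cbind(match(pairs$a, ids), match(pairs$b, ids))
  null_mean <- nul$mean[idx]
  null_sd <- nul$sd[idx]
  degenerate <- null_sd <= 0
  tibble::tibble(
    sample_a = pairs$a,
    sample_b = pairs$b,
    observed_bmntd = obs[idx],
    null_mean = null_mean,
    null_sd = null_sd,
    bnti = ifelse(degenerate, NA_real_, (obs[idx] - null_mean) / null_sd),
    n_reps = as.integer(reps),
    degenerate = degenerate
  )
}

#' Raup-Crick metric on Bray-Curtis (RC_Bray) for all sample pairs
#'
#' For each pair, `reps` null community pairs are assembled preserving each
#' sample's observed richness and total abundance: species identities are
#' drawn without replacement with probability proportional to occupancy
#' frequency across all samples; each drawn species receives one
#' individual and the remaining individuals are assigned by a multinomial
#' draw proportional to the species' total relative abundance across all
#' samples. Bray-Curtis is computed per null pair and
#' \deqn{RC = 2 \left[ \#(null < obs) + \tfrac12 \#(null = obs) \right] /
#'   reps - 1}
#' RC > 0.95 marks turnover higher than chance (dispersal limitation in
#' the partition), RC < -0.95 lower than chance (homogenizing dispersal).
#'
#' @param table A [community_table()] of integer counts.
#' @param reps Number of null pairs per observed pair.
#' @param seed Optional integer seed.
#' @return A tibble with `sample_a`, `sample_b`, `observed_bray`,
#'   `rc_bray` (in \[-1, 1\]) and `n_reps`.
#' @export
raup_crick <- function(table, reps = 999, seed = NULL) {
  stopifnot(inherits(table, "community_table"))
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  if (any(table$counts != round(table$counts))) {
    stop("Raup-Crick requires integer counts", call. = FALSE)
  }
  cm <- table$counts
  storage.mode(cm) <- "integer"
  run <- function() cpp_raup_crick(cm, as.integer(reps))
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  ids <- sample_ids(table)
  pairs <- pair_index(ids)
  idx <- cbind(match(pairs$a, ids), match(pairs$b, ids))
  tibble::tibble(
    sample_a = pairs$a,
    sample_b = pairs$b,
    observed_bray = res$obs[idx],
    rc_bray = res$rc[idx],
    n_reps = as.integer(reps)
  )
}

#' Partition pairwise turnover into assembly processes
#'
#' Applies the two-stage rule set: |bNTI| beyond the selection boundary
#' assigns selection (sign gives direction); otherwise RC_Bray beyond the
#' dispersal boundary assigns dispersal limitation (positive) or
#' homogenizing dispersal (negative); pairs inside both null envelopes are
#' "undominated". Boundary values themselves (|bNTI| = 2, |RC| = 0.95)
#' count as the respective non-null class so that no pair is
#' unclassifiable.
#'
#' @param bnti_tbl Output of [bnti()].
#' @param rc_tbl Output of [raup_crick()] over the same pairs.
#' @param bnti_threshold Selection boundary (default 2).
#' @param rc_threshold Dispersal boundary (default 0.95).
#' @return An `assembly_partition`: tibble of pairs with a `process`
#'   column; `glance()`/[process_fractions()] give per-process fractions
#'   summing to one over the classified (non-degenerate) pairs.
#' @export
partition_processes <- function(bnti_tbl, rc_tbl,
                                bnti_threshold = 2, rc_threshold = 0.95) {
  key_b <- paste(bnti_tbl$sample_a, bnti_tbl$sample_b)
  key_r <- paste(rc_tbl$sample_a, rc_tbl$sample_b)
  if (length(key_b) != length(key_r) || !setequal(key_b, key_r)) {
    stop("bNTI and RC_Bray results cover different sample pairs", call. = FALSE)
  }
  rc <- rc_tbl$rc_bray[match(key_b, key_r)]
  b <- bnti_tbl$bnti
  process <- dplyr::case_when(
    is.na(b) ~ NA_character_,
    b >= bnti_threshold ~ "heterogeneous_selection",
    b <= -bnti_threshold ~ "homogeneous_selection",
    rc >= rc_threshold ~ "dispersal_limitation",
    rc <= -rc_threshold ~ "homogenizing_dispersal",
    TRUE ~ "undominated"
  )
  if (anyNA(process)) {
    warning(sum(is.na(process)),
            " degenerate pair(s) excluded from process fractions",
            call. = FALSE)
  }
  out <- tibble::tibble(
    sample_a = bnti_tbl$sample_a,
    sample_b = bnti_tbl$sample_b,
    bnti = b,
    rc_bray = rc,
    process = process
  )
  class(out) <- c("assembly_partition", class(out))
  out
}

process_levels <- c("heterogeneous_selection", "homogeneous_selection",
                    "dispersal_limitation", "homogenizing_dispersal",
                    "undominated")

#' Process fractions of an assembly partition
#'
#' @param partition An `assembly_partition` (possibly with a grouping
#'   column `group` when produced by [assembly_partition()]).
#' @return Tibble of per-process fractions; fractions sum to one within
#'   each group over classified pairs.
#' @export
process_fractions <- function(partition) {
  stopifnot(inherits(partition, "assembly_partition"))
  df <- tibble::as_tibble(partition)
  df <- df[!is.na(df$process), ]
  grp <- if ("group" %in% names(df)) "group" else character(0)
  df$process <- factor(df$process, levels = process_levels)
  out <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::count(.data$process, .drop = FALSE) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  out$process <- as.character(out$process)
  out
}

#' @export
glance.assembly_partition <- function(x, ...) process_fractions(x)

#' Per-group assembly partition from raw inputs
#'
#' Runs [bnti()] and [raup_crick()] within each level of a metadata group
#' (habitats are analyzed separately: pairs never straddle groups) and
#' partitions the pairs.
#'
#' @param table A [community_table()].
#' @param tree Rooted `phylo` tree.
#' @param metadata Metadata tibble with `sample_id` and the group column.
#' @param group Name of the grouping column (default `"habitat"`).
#' @param reps Null repetitions for both null models.
#' @param seed Optional integer seed.
#' @param ... Passed on to [partition_processes()].
#' @return An `assembly_partition` tibble with a `group` column.
#' @export
assembly_partition <- function(table, tree, metadata, group = "habitat",
                               reps = 999, seed = NULL, ...) {
  validate_metadata(metadata, table)
  levels <- unique(metadata[[group]])
  parts <- lapply(seq_along(levels), function(i) {
    g <- levels[i]
    ids <- metadata$sample_id[metadata[[group]] == g]
    ## keep the full OTU set: the bNTI null shuffles tip labels across all
    ## OTUs of the study table, not only those present in this group
    sub <- subset_community(table, samples = intersect(sample_ids(table), ids))
    sub_seed <- if (is.null(seed)) NULL else (seed + i - 1) %% .Machine$integer.max
    b <- bnti(sub, tree, reps = reps, seed = sub_seed)
    r <- raup_crick(sub, reps = reps, seed = sub_seed)
    p <- partition_processes(b, r, ...)
    p$group <- g
    p
  })
  out <- dplyr::bind_rows(parts)
  class(out) <- c("assembly_partition", class(out))
  out
}
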