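#' Environmental distance matrix for one variable
#'
#' Pairwise absolute differences \eqn{d(i,j) = |x_i - x_j|} of one
#' environmental variable. Samples with missing values are dropped with a
#' warning.
#'
#' @param metadata Metadata tibble with `sample_id` and the variable.
#' @param variable Column name.
#' @param samples Optional sample ids (and ordering) to use.
#' @return A [dist_matrix()] tagged `"env_abs_diff"`.
#' @export
env_distance <- function(metadata, variable, samples = NULL) {
  if (!variable %in% names(metadata)) {
    stop("metadata has no variable '", variable, "'", call. = FALSE)
  }
  md <- metadata
  if (!is.null(samples)) md <- md[match(samples, md$sample_id), ]
  x <- md[[variable]]
  ok <- !is.na(x)
  if (!all(ok)) {
    warning(sum(!ok), " sample(s) with missing '", variable, "' dropped",
            call. = FALSE)
    md <- md[ok, ]
    x <- x[ok]
  }
  m <- abs(outer(x, x, "-"))
  dimnames(m) <- list(md$sample_id, md$sample_id)
  dist_matrix(m, metric = "env_abs_diff")
}

#' Two-sided permutation Mantel test
#'
#' Correlation (Spearman by default) between the upper triangles of two
#' distance matrices; significance by jointly permuting the row/column
#' labels of the second matrix, counting permutations with
#' \eqn{|r_{perm}| \ge |r_{obs}|}, with the +1 correction:
#' \eqn{p = (1 + \#\{|r_{perm}| \ge |r_{obs}|\}) / (n_{perms} + 1)}.
#' The two-sided count matters here because environment-community
#' associations can be significantly negative.
#'
#' @param dm_a,dm_b [dist_matrix()] objects (or bare matrices) over the
#'   same ids in the same order. `dm_b` may also be a distance-like matrix
#'   such as a bNTI pair matrix; it is used as-is.
#' @param method `"spearman"` or `"pearson"`.
#' @param n_perms Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @return A `mantel_result`; `tidy()` gives a one-row tibble with
#'   `r`, `p_value`, `n`, `n_perms`, `method`. Degenerate inputs (constant
#'   upper triangle) are flagged with an NA statistic.
#' @export
mantel_test <- function(dm_a, dm_b, method = c("spearman", "pearson"),
                        n_perms = 999, seed = NULL) {
  method <- match.arg(method)
  a <- if (inherits(dm_a, "dist_matrix")) dm_a$m else as.matrix(dm_a)
  b <- if (inherits(dm_b, "dist_matrix")) dm_b$m else as.matrix(dm_b)
  if (!identical(dim(a), dim(b))) stop("matrices differ in size", call. = FALSE)
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b))) {
    stop("matrices cover different ids or orderings", call. = FALSE)
  }
  n <- nrow(a)
  if (n < 4) stop("Mantel test needs at least 4 samples", call. = FALSE)
  ut <- upper.tri(a)
  va <- a[ut]
  vb <- b[ut]
  ## entries that are NA in either matrix (e.g. degenerate bNTI pairs) are
  ## excluded pairwise, from the permutations too
  mask <- is.finite(va) & is.finite(vb)
  degenerate <- sum(mask) < 3 || stats::sd(va[mask]) == 0 ||
    stats::sd(vb[mask]) == 0
  res <- if (degenerate) {
    list(r = NA_real_, p = NA_real_)
  } else {
    r_obs <- stats::cor(va[mask], vb[mask], method = method)
    run <- function() {
      hits <- 0L
      for (i in seq_len(n_perms)) {
        perm <- sample.int(n)
        r_perm <- stats::cor(va[mask], b[perm, perm][ut][mask],
                             method = method, use = "pairwise.complete.obs")
        if (is.na(r_perm) || abs(r_perm) >= abs(r_obs) - 1e-12) {
          hits <- hits + 1L
        }
      }
      (1 + hits) / (n_perms + 1)
    }
    p <- if (is.null(seed)) run() else withr::with_seed(seed, run())
    list(r = r_obs, p = p)
  }
  structure(list(
    r = res$r, p_value = res$p, n = n, n_perms = as.integer(n_perms),
    method = method, degenerate = degenerate,
    name_a = if (inherits(dm_a, "dist_matrix")) dm_a$metric else "dm_a",
    name_b = if (inherits(dm_b, "dist_matrix")) dm_b$metric else "dm_b"
  ), class = "mantel_result")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.mantel_result <- function(x, ...) {
  if (x$degenerate) {
    cat("<mantel_result> degenerate (constant distances)\n")
  } else {
    cat(sprintf("<mantel_result> r = %.3f, p = %.4g (%s, %d permutations)\n",
                x$r, x$p_value, x$method, x$n_perms))
  }
  invisible(x)
}

#' @export
tidy.mantel_result <- function(x, ...) {
  tibble::tibble(r = x$r, p_value = x$p_value, n = x$n, n_perms = x$n_perms,
                 method = x$method, degenerate = x$degenerate)
}

#' @export
glance.mantel_result <- function(x, ...) tidy(x)

#' Per-lineage community subtables
#'
#' Groups OTUs by a taxonomy rank and returns the member subtable per
#' requested lineage. Lineages with no member OTUs in the table yield
#' `NULL` (the "not applicable" rows of the association table).
#'
#' @param table A [community_table()].
#' @param taxonomy Taxonomy tibble.
#' @param lineages Character vector of lineage names (default: all
#'   observed).
#' @param rank Taxonomy column to group by.
#' @return Named list of [community_table()]s (or `NULL` for absent
#'   lineages).
#' @export
lineage_subtables <- function(table, taxonomy, lineages = NULL,
                              rank = "lineage") {
  lin <- taxonomy_lookup(taxonomy, otu_ids(table), rank)
  if (is.null(lineages)) lineages <- sort(unique(lin))
  out <- lapply(lineages, function(l) {
    otus <- otu_ids(table)[lin == l & rowSums(table$counts) > 0]
    if (length(otus) == 0) return(NULL)
    subset_community(table, otus = otus, drop_empty_samples = TRUE)
  })
  names(out) <- lineages
  out
}

#' Environment-community association table
#'
#' Mantel r between each environmental variable's distance matrix and a
#' set of community dissimilarity targets: bNTI (the pair matrix used
#' as-is, distance-like), beta-MNTD, Bray-Curtis, the Bray-Curtis matrix
#' of each major network module, and of each taxonomy lineage. Lineages or
#' modules absent from the habitat yield NA rows. Stars mark p < 0.05 (*)
#' and p < 0.01 (**); no multiple-testing correction is applied across
#' cells, mirroring common practice.
#'
#' @param table Habitat-level [community_table()].
#' @param tree Rooted phylogeny (for beta-MNTD and bNTI).
#' @param metadata Metadata tibble covering the table's samples.
#' @param env_vars Environmental variable names.
#' @param taxonomy Optional taxonomy tibble (adds lineage rows).
#' @param modules Optional output of [module_subtables()] (adds module
#'   rows).
#' @param bnti_tbl Optional precomputed [bnti()] tibble for these samples
#'   (computed on the fly if missing).
#' @param reps Null-model repetitions when `bnti_tbl` must be computed.
#' @param n_perms Mantel permutations.
#' @param seed Optional integer seed.
#' @return A tibble: `target`, one `r` and `p` column pair per variable,
#'   plus star-annotated character columns.
#' @export
association_table <- function(table, tree, metadata, env_vars,
                              taxonomy = NULL, modules = NULL,
                              bnti_tbl = NULL, reps = 999, n_perms = 999,
                              seed = NULL) {
  ids <- sample_ids(table)
  md <- metadata[match(ids, metadata$sample_id), ]
  if (is.null(bnti_tbl)) {
    bnti_tbl <- bnti(table, tree, reps = reps, seed = seed)
  }
  bnti_m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  ia <- match(bnti_tbl$sample_a, ids)
  ib <- match(bnti_tbl$sample_b, ids)
  bnti_m[cbind(ia, ib)] <- bnti_tbl$bnti
  bnti_m[cbind(ib, ia)] <- bnti_tbl$bnti
  targets <- list(
    bnti = bnti_m,
    beta_mntd = beta_mntd(table, tree),
    bray_curtis = bray_curtis(table)
  )
  if (!is.null(modules)) {
    for (nm in names(modules)) targets[[nm]] <- modules[[nm]]$bray
  }
  if (!is.null(taxonomy)) {
    subs <- lineage_subtables(table, taxonomy)
    for (nm in names(subs)) {
      targets[nm] <- if (is.null(subs[[nm]])) list(NULL) else
        list(bray_curtis(subs[[nm]]))
    }
  }
  rows <- purrr::imap_dfr(targets, function(tgt, nm) {
    row <- tibble::tibble(target = nm)
    tgt_ids <- if (inherits(tgt, "dist_matrix")) tgt$ids else rownames(tgt)
    for (v in env_vars) {
      ## lineages/modules absent from (enough of) this habitat: NA cell
      if (is.null(tgt) || length(tgt_ids) < 4) {
        row[[paste0(v, "_r")]] <- NA_real_
        row[[paste0(v, "_p")]] <- NA_real_
        next
      }
      ed <- env_distance(md[match(tgt_ids, md$sample_id), ], v,
                         samples = tgt_ids)
      mt <- mantel_test(ed, tgt, n_perms = n_perms, seed = seed)
      row[[paste0(v, "_r")]] <- mt$r
      row[[paste0(v, "_p")]] <- mt$p_value
    }
    row
  })
  for (v in env_vars) {
    r <- rows[[paste0(v, "_r")]]
    p <- rows[[paste0(v, "_p")]]
    stars <- dplyr::case_when(
      is.na(p) ~ "NA",
      p < 0.01 ~ sprintf("%.3f **", r),
      p < 0.05 ~ sprintf("%.3f *", r),
      TRUE ~ sprintf("%.3f", r)
    )
    rows[[paste0(v, "_label")]] <- stars
  }
  rows
}
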