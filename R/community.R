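#' Community table of OTU counts
#'
#' The central container of the package: a matrix of non-negative integer
#' counts with OTUs as rows and samples as columns, together with per-sample
#' relative abundances. Every analysis function accepts a `community_table`
#' and returns tibbles.
#'
#' @param x A numeric matrix (OTUs x samples) with unique dimnames, or a
#'   data frame whose first column holds OTU ids and remaining columns hold
#'   per-sample counts.
#' @param otus_as_rows If `FALSE`, `x` is transposed before validation.
#' @param allow_proportions Accept non-integer values. By default the
#'   constructor insists on integer counts because richness estimators
#'   (Chao1) are undefined on proportions.
#'
#' @return An object of class `community_table` with elements `counts`
#'   (integer-valued matrix) and `relabund` (columns sum to 1).
#' @export
#' @examples
#' m <- matrix(c(5, 5, 0, 0, 10, 10), nrow = 3,
#'             dimnames = list(paste0("OTU_", 1:3), c("s1", "s2")))
#' ct <- community_table(m)
#' colSums(ct$relabund)
community_table <- function(x, otus_as_rows = TRUE, allow_proportions = FALSE) {
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    rownames(m) <- ids
    x <- m
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix or a data frame of counts", call. = FALSE)
  }
  if (!otus_as_rows) x <- t(x)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("counts must carry OTU ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  validate_counts(x, allow_proportions = allow_proportions)
  relabund <- sweep(x, 2, colSums(x), "/")
  structure(list(counts = x, relabund = relabund), class = "community_table")
}

validate_counts <- function(x, allow_proportions = FALSE) {
  if (anyDuplicated(rownames(x))) {
    dup <- rownames(x)[duplicated(rownames(x))][1]
    stop("duplicated OTU id: '", dup, "'", call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    dup <- colnames(x)[duplicated(colnames(x))][1]
    stop("duplicated sample id: '", dup, "'", call. = FALSE)
  }
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1, ]
    stop("missing count at OTU '", rownames(x)[idx[1]], "', sample '",
         colnames(x)[idx[2]], "'", call. = FALSE)
  }
  if (any(x < 0)) {
    idx <- which(x < 0, arr.ind = TRUE)[1, ]
    stop("negative count at OTU '", rownames(x)[idx[1]], "', sample '",
         colnames(x)[idx[2]], "'", call. = FALSE)
  }
  if (!allow_proportions && any(x != round(x))) {
    idx <- which(x != round(x), arr.ind = TRUE)[1, ]
    stop("non-integer count at OTU '", rownames(x)[idx[1]], "', sample '",
         colnames(x)[idx[2]],
         "' (use allow_proportions = TRUE for proportion tables)", call. = FALSE)
  }
  zero <- colSums(x) == 0
  if (any(zero)) {
    stop("sample '", colnames(x)[zero][1], "' has zero total count",
         call. = FALSE)
  }
  invisible(x)
}

#' @export
print.community_table <- function(x, ...) {
  cat("<community_table> ", nrow(x$counts), " OTUs x ", ncol(x$counts),
      " samples, total count ", sum(x$counts), "\n", sep = "")
  invisible(x)
}

#' @export
dim.community_table <- function(x) dim(x$counts)

#' OTU and sample identifiers of a community table
#' @param table A `community_table`.
#' @return Character vector of ids.
#' @export
otu_ids <- function(table) rownames(table$counts)

#' @rdname otu_ids
#' @export
sample_ids <- function(table) colnames(table$counts)

#' @export
as_tibble.community_table <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$counts), rownames = "otu_id")
}

#' Restrict a community table to a subset of OTUs or samples
#'
#' Subsetting re-normalizes relative abundances within the retained sample
#' set, so per-habitat analyses see habitat-local proportions.
#'
#' @param table A `community_table`.
#' @param otus,samples Character vectors of ids to keep (default: all).
#' @param drop_empty_otus Drop OTUs with zero counts across the retained
#'   samples.
#' @param drop_empty_samples Drop samples with zero counts across the
#'   retained OTUs (useful for lineage or module subtables whose members
#'   are absent from some samples).
#' @return A `community_table`.
#' @export
subset_community <- function(table, otus = NULL, samples = NULL,
                             drop_empty_otus = FALSE,
                             drop_empty_samples = FALSE) {
  stopifnot(inherits(table, "community_table"))
  m <- table$counts
  if (!is.null(otus)) {
    missing <- setdiff(otus, rownames(m))
    if (length(missing) > 0) {
      stop("unknown OTU id: '", missing[1], "'", call. = FALSE)
    }
    m <- m[otus, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(m))
    if (length(missing) > 0) {
      stop("unknown sample id: '", missing[1], "'", call. = FALSE)
    }
    m <- m[, samples, drop = FALSE]
  }
  if (drop_empty_otus) m <- m[rowSums(m) > 0, , drop = FALSE]
  if (drop_empty_samples) m <- m[, colSums(m) > 0, drop = FALSE]
  community_table(m)
}

#' Pairwise distance matrix with a metric tag
#'
#' Thin wrapper around a symmetric matrix with zero diagonal, tagged with
#' the metric that produced it. `tidy()` turns it into a long tibble of
#' unordered pairs.
#'
#' @param m Symmetric numeric matrix with identical row/column names.
#' @param metric Metric tag, e.g. `"bray_curtis"`.
#' @return A `dist_matrix`.
#' @export
dist_matrix <- function(m, metric = "unknown") {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (is.null(rownames(m))) stop("distance matrix needs ids", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-12) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  diag(m) <- 0
  structure(list(m = m, ids = rownames(m), metric = metric),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("<dist_matrix> ", length(x$ids), " ids, metric = ", x$metric, "\n",
      sep = "")
  invisible(x)
}

#' @export
as.matrix.dist_matrix <- function(x, ...) x$m

#' @export
as.dist.dist_matrix <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$m, diag = diag, upper = upper)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.dist_matrix <- function(x, ...) {
  m <- x$m
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(
    id_a = x$ids[idx[, 1]],
    id_b = x$ids[idx[, 2]],
    distance = m[idx],
    metric = x$metric
  )
}

## shared helper: upper-triangle pair index in a stable order
pair_index <- function(ids) {
  idx <- which(upper.tri(diag(length(ids))), arr.ind = TRUE)
  tibble::tibble(a = ids[idx[, 1]], b = ids[idx[, 2]])
}
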