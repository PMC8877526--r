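#' Read an OTU abundance table
#'
#' Reads a tab-separated OTU table in the classic BIOM/QIIME dialect: first
#' column OTU ids (a leading `#OTU ID` header is tolerated), remaining
#' columns one per sample. Malformed input is rejected with an error naming
#' the offending record rather than silently coerced.
#'
#' @param path Path to a TSV file.
#' @param orientation `"otus_as_rows"` (the default emitted by QIIME-era
#'   tools) or `"samples_as_rows"`.
#' @param allow_proportions Accept non-integer abundances.
#' @return A [community_table()].
#' @export
read_otu_table <- function(path,
                           orientation = c("otus_as_rows", "samples_as_rows"),
                           allow_proportions = FALSE) {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  ## BIOM-classic files open with "# Constructed from biom file" then "#OTU ID"
  skip <- 0
  while (skip < length(lines) && startsWith(lines[skip + 1], "#") &&
         !grepl("^#\\s*OTU", lines[skip + 1], ignore.case = TRUE)) {
    skip <- skip + 1
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = skip,
                          comment.char = "", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2) stop("OTU table needs an id column and >= 1 sample",
                         call. = FALSE)
  ids <- df[[1]]
  num <- df[, -1, drop = FALSE]
  m <- matrix(NA_real_, nrow(num), ncol(num),
              dimnames = list(ids, colnames(num)))
  for (j in seq_len(ncol(num))) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    bad <- which(is.na(v) & !is.na(num[[j]]))
    if (length(bad) > 0) {
      stop("non-numeric value '", num[[j]][bad[1]], "' at row '",
           ids[bad[1]], "', column '", colnames(num)[j], "'", call. = FALSE)
    }
    m[, j] <- v
  }
  community_table(m, otus_as_rows = orientation == "otus_as_rows",
                  allow_proportions = allow_proportions)
}

#' Write an OTU table as TSV
#'
#' @param table A `community_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "community_table"))
  df <- data.frame(`#OTU ID` = rownames(table$counts), table$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny from a Newick file
#'
#' @param path Path to a single-tree Newick file.
#' @return An `ape::phylo` tree, validated: at least 2 tips, branch lengths
#'   present and non-negative.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("failed to parse Newick: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("failed to parse Newick file '", path, "'",
                          call. = FALSE)
  if (inherits(tree, "multiPhylo")) {
    stop("expected a single tree, found ", length(tree), call. = FALSE)
  }
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylogeny", call. = FALSE)
  if (length(tree$tip.label) < 2) {
    stop("tree has fewer than 2 tips", call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("tree has missing or negative branch lengths", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicated tip label: '",
         tree$tip.label[duplicated(tree$tip.label)][1], "'", call. = FALSE)
  }
  tree
}

#' Read sample metadata
#'
#' Expects a TSV with columns `sample_id`, `habitat`, `lake_id` and any
#' number of numeric environmental variables (pH, conductivity, organic
#' carbon, TN, TP, ...).
#'
#' @param path Path to a TSV file.
#' @param table Optional `community_table`; if given, every sample in the
#'   table must have exactly one metadata row.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path, table = NULL) {
  md <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample_id", "habitat", "lake_id")
  missing <- setdiff(required, names(md))
  if (length(missing) > 0) {
    stop("metadata lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(md$sample_id)) {
    stop("duplicated sample_id in metadata: '",
         md$sample_id[duplicated(md$sample_id)][1], "'", call. = FALSE)
  }
  if (!is.null(table)) validate_metadata(md, table)
  md
}

validate_metadata <- function(metadata, table) {
  missing <- setdiff(sample_ids(table), metadata$sample_id)
  if (length(missing) > 0) {
    stop("sample '", missing[1], "' has no metadata row", call. = FALSE)
  }
  invisible(metadata)
}

#' Read an OTU taxonomy table
#'
#' @param path TSV with first column `otu_id` and further columns naming
#'   ranked lineages (e.g. `supergroup`, `lineage`).
#' @return A tibble.
#' @export
read_taxonomy <- function(path) {
  tx <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"otu_id" %in% names(tx)) {
    stop("taxonomy lacks an 'otu_id' column", call. = FALSE)
  }
  tx
}

#' Look up lineages for OTUs, with an explicit sentinel for unknowns
#'
#' @param taxonomy Taxonomy tibble as from [read_taxonomy()].
#' @param otus Character vector of OTU ids.
#' @param rank Which taxonomy column to return.
#' @return Character vector; OTUs absent from the taxonomy are returned as
#'   `"unclassified"` rather than `NA`.
#' @export
taxonomy_lookup <- function(taxonomy, otus, rank = "lineage") {
  if (!rank %in% names(taxonomy)) {
    stop("taxonomy has no rank '", rank, "'", call. = FALSE)
  }
  out <- taxonomy[[rank]][match(otus, taxonomy$otu_id)]
  out[is.na(out)] <- "unclassified"
  out
}

#' Write a co-occurrence network to disk
#'
#' Nodes carry OTU id, taxonomy, module id and degree; edges carry the
#' Spearman rho, its sign and the FDR q-value.
#'
#' @param network A `cooccurrence_network`.
#' @param path Output path.
#' @param format `"graphml"` or `"edgelist"` (TSV).
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("graphml", "edgelist")) {
  stopifnot(inherits(network, "cooccurrence_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network$graph, path, format = "graphml")
  } else {
    readr::write_tsv(network$edges, path, progress = FALSE)
  }
  invisible(path)
}
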