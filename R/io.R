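# Readers/writers for the plain-text formats the pipeline touches: TSV
# feature tables, metadata, distance matrices, long-format measurement
# tables, and Newick trees (via ape). All round-trips are lossless at the
# declared precision and all validation errors carry row/column context.

#' Parse a Newick string into a rooted phylogenetic tree
#'
#' Thin validation layer over [ape::read.tree()]: requires balanced
#' parentheses, branch lengths and unique leaf names.
#'
#' @param text a single Newick string
#' @return an [ape::phylo] tree
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    stop("text must be a single Newick string", call. = FALSE)
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    stop(sprintf("unbalanced parentheses in Newick (%d '(' vs %d ')')",
                 n_open, n_close), call. = FALSE)
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("Newick parse error: empty or malformed input", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    dup <- tree$tip.label[duplicated(tree$tip.label)][1]
    stop(sprintf("duplicate leaf name '%s' in Newick", dup), call. = FALSE)
  }
  if (is.null(tree$edge.length))
    stop("Newick tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("negative branch length in Newick", call. = FALSE)
  tree
}

#' Serialize a tree to Newick
#' @param tree an [ape::phylo] tree
#' @param digits decimal digits for branch lengths
#' @return a Newick string
#' @export
write_newick <- function(tree, digits = 12L) {
  ape::write.tree(tree, digits = digits)
}

#' Read / write a feature table (TSV, samples as rows)
#'
#' First column `sample_id`, remaining columns one per feature, integer
#' counts. Ids are preserved in file order.
#'
#' @param path file path
#' @return `read_feature_table()`: validated integer matrix (see
#'   [as_feature_table()])
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (names(df)[1] != "sample_id")
    stop("feature table must start with a 'sample_id' column", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))), arr.ind = TRUE)
    stop(sprintf("non-numeric count at row '%s', column '%s' in %s",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]], path), call. = FALSE)
  }
  tryCatch(as_feature_table(m),
           error = function(e) stop(conditionMessage(e), " (file: ", path, ")",
                                    call. = FALSE))
}

#' @rdname read_feature_table
#' @param table feature table matrix
#' @export
write_feature_table <- function(table, path) {
  table <- as_feature_table(table)
  df <- data.frame(sample_id = rownames(table), table, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata (TSV)
#'
#' Columns `sample_id`, `site_id`, `sample_type`, `region`, `spatial_role`,
#' `year`, `month`. The derived `period` column is recomputed on read from
#' `intervention_date`, never trusted from disk.
#'
#' @param path file path
#' @param intervention_date `c(year, month)` boundary, default `c(2016, 1)`
#' @export
read_metadata <- function(path, intervention_date = c(2016L, 1L)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  tryCatch(as_sample_metadata(df, intervention_date),
           error = function(e) stop(conditionMessage(e), " (file: ", path, ")",
                                    call. = FALSE))
}

#' @rdname read_metadata
#' @param metadata metadata data.frame
#' @export
write_metadata <- function(metadata, path) {
  md <- metadata
  md$period <- NULL  # derived; recomputed on read
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a distance matrix (TSV, 12 decimal places)
#'
#' @param dm distance matrix
#' @param path file path
#' @export
write_distance_matrix <- function(dm, path) {
  m <- as_distance_matrix(dm)
  df <- data.frame(sample_id = rownames(m),
                   format(m, digits = NULL, nsmall = 12, scientific = FALSE,
                          trim = TRUE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  storage.mode(m) <- "double"
  as_distance_matrix(m)
}

#' Read / write long-format measurement tables (TSV)
#'
#' Used for the fecal-coliform series (`site_id`, `year`, `month`,
#' `cfu_per_100ml`) and the physicochemical table (`variable`, `unit`,
#' `site_id`, `year`, `month`, `value`).
#'
#' @param df data.frame
#' @param path file path
#' @export
write_measurements <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Cross-file consistency validation of a study
#'
#' Checks that every sample in the feature table appears in the metadata and
#' that every feature is a leaf of the tree.
#'
#' @param table feature table
#' @param metadata sample metadata
#' @param tree phylogenetic tree
#' @return invisibly TRUE; errors name the offending ids
#' @export
validate_study <- function(table, metadata, tree) {
  table <- as_feature_table(table)
  miss <- setdiff(rownames(table), metadata$sample_id)
  if (length(miss) > 0)
    stop("samples absent from metadata: ", paste(utils::head(miss, 5), collapse = ", "),
         call. = FALSE)
  miss <- setdiff(colnames(table), tree$tip.label)
  if (length(miss) > 0)
    stop("features absent from tree: ", paste(utils::head(miss, 5), collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}
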