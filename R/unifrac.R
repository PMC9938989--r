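# Phylogenetic beta diversity: unweighted and weighted UniFrac, computed
# from a branch (edge) decomposition of a rooted tree. Each branch is
# classified by the leaves that descend from it; unweighted UniFrac is the
# unshared fraction of branch length over the union, weighted UniFrac is the
# length-weighted L1 distance between the proportions of each community
# flowing through every branch.

#' Branch decomposition of a rooted tree
#'
#' Precomputes, for every edge, its length and the set of leaves descending
#' from it (postorder accumulation). All UniFrac computation runs against
#' this table; callers computing many distances on one tree should build it
#' once and pass it along.
#'
#' @param tree an [ape::phylo] tree with branch lengths
#' @return list with `length` (numeric per edge) and `leaves`
#'   (edges x tips 0/1 matrix, columns named by tip label)
#' @export
branch_table <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch lengths", call. = FALSE)
  ntip <- length(tree$tip.label)
  po <- stats::reorder(tree, "postorder")
  desc <- vector("list", ntip + po$Nnode)
  for (t in seq_len(ntip)) desc[[t]] <- t
  for (i in seq_len(nrow(po$edge))) {
    par <- po$edge[i, 1]; ch <- po$edge[i, 2]
    desc[[par]] <- c(desc[[par]], desc[[ch]])
  }
  E <- matrix(0, nrow(po$edge), ntip, dimnames = list(NULL, po$tip.label))
  for (i in seq_len(nrow(po$edge))) E[i, desc[[po$edge[i, 2]]]] <- 1
  list(length = po$edge.length, leaves = E)
}

# Resolve a community spec (character set, or named numeric/logical vector)
# into a named abundance vector over the tree's tips; errors name missing taxa.
.community_vector <- function(x, tips, arg = "sample") {
  if (is.character(x)) {
    v <- stats::setNames(rep(1, length(x)), x)
  } else if ((is.numeric(x) || is.logical(x)) && !is.null(names(x))) {
    v <- stats::setNames(as.numeric(x), names(x))
  } else stop(arg, " must be a character vector of taxa or a named numeric vector",
              call. = FALSE)
  if (any(v < 0)) stop(arg, " has negative abundances", call. = FALSE)
  v <- v[v > 0]
  if (length(v) == 0) stop(arg, " is empty (no taxa present)", call. = FALSE)
  miss <- setdiff(names(v), tips)
  if (length(miss) > 0)
    stop("taxon missing from tree: ", paste(miss, collapse = ", "), call. = FALSE)
  full <- stats::setNames(numeric(length(tips)), tips)
  full[names(v)] <- v
  full
}

#' Unweighted UniFrac distance between two communities
#'
#' Fraction of branch length leading only to one community's leaves, over the
#' branch length leading to the union of both leaf sets.
#'
#' @param a,b communities: character vectors of present taxa, or named
#'   numeric vectors (presence is abundance > 0)
#' @param tree rooted [ape::phylo] tree whose tips cover the taxa
#' @param bt optional precomputed [branch_table()]
#' @return distance in \[0, 1\]
#' @export
unweighted_unifrac <- function(a, b, tree, bt = NULL) {
  bt <- bt %||% branch_table(tree)
  tips <- colnames(bt$leaves)
  va <- .community_vector(a, tips, "a") > 0
  vb <- .community_vector(b, tips, "b") > 0
  in_a <- (bt$leaves %*% va) > 0
  in_b <- (bt$leaves %*% vb) > 0
  union_len <- sum(bt$length[in_a | in_b])
  if (union_len == 0) return(0)
  sum(bt$length[xor(in_a, in_b)]) / union_len
}

#' Weighted UniFrac distance between two communities
#'
#' Sum over branches of length times the absolute difference between the
#' proportions of each community's total abundance descending through the
#' branch. The normalized variant (default) divides by the same sum of
#' length times the proportion total, giving range \[0, 1\].
#'
#' @inheritParams unweighted_unifrac
#' @param normalized divide by the maximum attainable value (default TRUE)
#' @return distance (in \[0, 1\] when `normalized = TRUE`)
#' @export
weighted_unifrac <- function(a, b, tree, normalized = TRUE, bt = NULL) {
  bt <- bt %||% branch_table(tree)
  tips <- colnames(bt$leaves)
  va <- .community_vector(a, tips, "a"); va <- va / sum(va)
  vb <- .community_vector(b, tips, "b"); vb <- vb / sum(vb)
  pa <- as.numeric(bt$leaves %*% va)
  pb <- as.numeric(bt$leaves %*% vb)
  raw <- sum(bt$length * abs(pa - pb))
  if (!normalized) return(raw)
  denom <- sum(bt$length * (pa + pb))
  if (denom == 0) return(0)
  raw / denom
}

#' All-pairs UniFrac distance matrix for a feature table
#'
#' Vectorized over branches; entries equal the pairwise single-distance
#' calls exactly (up to floating-point associativity, < 1e-12).
#'
#' @param table feature table (samples x features); every sample needs at
#'   least one positive count
#' @param tree rooted [ape::phylo] tree covering the features
#' @param metric `"unweighted"` or `"weighted"`
#' @param normalized for the weighted metric, use the normalized variant
#' @param bt optional precomputed [branch_table()]
#' @return symmetric distance matrix with sample ids
#' @export
unifrac_matrix <- function(table, tree, metric = c("unweighted", "weighted"),
                           normalized = TRUE, bt = NULL) {
  metric <- match.arg(metric)
  table <- as_feature_table(table)
  if (any(rowSums(table) == 0))
    stop("sample(s) with all-zero counts: ",
         paste(rownames(table)[rowSums(table) == 0], collapse = ", "), call. = FALSE)
  bt <- bt %||% branch_table(tree)
  tips <- colnames(bt$leaves)
  miss <- setdiff(colnames(table), tips)
  if (length(miss) > 0)
    stop("taxon missing from tree: ", paste(utils::head(miss, 5), collapse = ", "),
         call. = FALSE)
  n <- nrow(table)
  # leaves x samples abundance matrix aligned to the tree tips
  M <- matrix(0, length(tips), n, dimnames = list(tips, rownames(table)))
  M[colnames(table), ] <- t(table)
  len <- bt$length
  if (metric == "unweighted") {
    B <- (bt$leaves %*% (M > 0)) > 0      # edges x samples branch occupancy
    storage.mode(B) <- "double"
    L <- as.numeric(crossprod(B, len))    # per-sample occupied length
    both <- crossprod(B, B * len)         # shared occupied length
    tot <- outer(L, L, "+")
    D <- (tot - 2 * both) / (tot - both)
  } else {
    P <- sweep(M, 2, colSums(M), "/")
    A <- bt$leaves %*% P                  # edges x samples branch proportions
    raw <- matrix(0, n, n)
    for (j in seq_len(n))
      raw[, j] <- as.numeric(crossprod(abs(A - A[, j]), len))
    if (normalized) {
      LA <- as.numeric(crossprod(A, len))
      D <- raw / outer(LA, LA, "+")
    } else D <- raw
  }
  dimnames(D) <- list(rownames(table), rownames(table))
  diag(D) <- 0
  D[D < 0] <- 0
  as_distance_matrix(D)
}
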