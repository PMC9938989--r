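# Alpha diversity, rarefaction, PCoA, PERMANOVA, beta dispersion and
# nonparametric group comparisons. Standard steps lean on vegan and base
# stats; only the plumbing and validation live here.

#' Shannon diversity (natural log)
#'
#' H = -sum p_i ln p_i over taxa with positive counts.
#'
#' @param counts non-negative count vector with at least one positive entry
#' @return Shannon index in nats
#' @export
shannon <- function(counts) {
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(counts) == 0) stop("all-zero count vector", call. = FALSE)
  as.numeric(vegan::diversity(counts, index = "shannon"))
}

#' Rarefy a feature table to fixed depth
#'
#' Subsamples each sample without replacement to exactly `depth` total
#' counts (single draw, via [vegan::rrarefy()]); samples with fewer reads
#' than `depth` are removed and reported in the `"dropped"` attribute.
#' Default depth follows the study convention of 1285 reads.
#'
#' @param table feature table (samples x features)
#' @param depth target depth, >= 1
#' @param seed RNG seed (deterministic per seed)
#' @return rarefied integer feature table with attribute `dropped`
#' @export
rarefy_table <- function(table, depth = 1285L, seed = 0L) {
  table <- as_feature_table(table)
  if (length(depth) != 1L || depth < 1) stop("depth must be >= 1", call. = FALSE)
  tot <- rowSums(table)
  keep <- tot >= depth
  dropped <- rownames(table)[!keep]
  if (length(dropped) > 0)
    message(length(dropped), " sample(s) below depth ", depth, " removed: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  out <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(table[keep, , drop = FALSE], depth),
    # rrarefy's "observed counts" heuristic misfires on valid integer tables
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  out <- as_feature_table(out)
  attr(out, "dropped") <- dropped
  out
}

#' Remove low-prevalence features
#'
#' Drops ASVs observed (count > 0) in fewer than `min_samples` samples;
#' the study's pre-processing convention is `min_samples = 10`.
#'
#' @param table feature table
#' @param min_samples minimum number of samples a feature must appear in
#' @return filtered feature table
#' @export
filter_rare_features <- function(table, min_samples = 10L) {
  table <- as_feature_table(table)
  keep <- colSums(table > 0) >= min_samples
  table[, keep, drop = FALSE]
}

#' Principal coordinates analysis
#'
#' Eigendecomposition of the Gower-centered -D^2/2 matrix. Negative
#' eigenvalues are reported but their axes are excluded from the returned
#' coordinates; axes are ordered by decreasing eigenvalue.
#'
#' @param dm distance matrix
#' @return list of class `riverseason_pcoa`: `coordinates` (samples x
#'   positive axes), `eigenvalues` (all, sorted descending),
#'   `proportion_explained` (relative to the positive eigenvalue total)
#' @export
pcoa <- function(dm) {
  m <- as_distance_matrix(dm)
  n <- nrow(m)
  A <- -0.5 * m^2
  G <- A - outer(rowMeans(A), rep(1, n)) - outer(rep(1, n), colMeans(A)) + mean(A)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  ev <- e$values
  tol <- max(abs(ev), 0) * 1e-9
  pos <- which(ev > tol)
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev[pos]), length(pos))
  dimnames(coords) <- list(rownames(m),
                           if (length(pos)) paste0("Axis", seq_along(pos)))
  pos_sum <- sum(ev[ev > tol])
  structure(list(
    coordinates = coords,
    eigenvalues = ev,
    proportion_explained = if (pos_sum > 0) pmax(ev, 0) / pos_sum else rep(0, n)),
    class = "riverseason_pcoa")
}

#' PERMANOVA on a distance matrix
#'
#' Pseudo-F test of group differences via [vegan::adonis2()] with free
#' permutation of sample labels; the permutation p-value uses the
#' bias-safe (1 + hits)/(n_perm + 1) convention.
#'
#' @param dm distance matrix
#' @param groups group labels, >= 2 groups with >= 2 members each
#' @param n_perm number of permutations (default 999)
#' @param seed RNG seed
#' @return [test_result()] with the pseudo-F statistic
#' @export
permanova <- function(dm, groups, n_perm = 999L, seed = 0L) {
  m <- as_distance_matrix(dm)
  g <- factor(groups)
  if (length(g) != nrow(m)) stop("groups length must match distance matrix", call. = FALSE)
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2))
    stop("every group needs >= 2 members; too small: ",
         paste(names(which(table(g) < 2)), collapse = ", "), call. = FALSE)
  fit <- with_seed(seed,
    vegan::adonis2(stats::as.dist(m) ~ g, data = data.frame(g = g),
                   permutations = n_perm))
  test_result(statistic = fit$F[1], p_value = fit$`Pr(>F)`[1],
              method = "PERMANOVA (pseudo-F, free permutation)",
              n_resamples = n_perm, seed = seed,
              df = fit$Df[1], r_squared = fit$R2[1])
}

#' Beta dispersion: mean distance to the group centroid in PCoA space
#'
#' Samples are embedded by [pcoa()]; within each group the Euclidean
#' distance of every member to the group centroid is averaged.
#'
#' @param dm distance matrix
#' @param groups group labels (>= 1 member each)
#' @return named numeric vector of per-group mean centroid distances
#' @export
beta_dispersion <- function(dm, groups) {
  m <- as_distance_matrix(dm)
  g <- factor(groups)
  if (length(g) != nrow(m)) stop("groups length must match distance matrix", call. = FALSE)
  coords <- pcoa(m)$coordinates
  if (ncol(coords) == 0) return(stats::setNames(rep(0, nlevels(g)), levels(g)))
  vapply(levels(g), function(lev) {
    x <- coords[g == lev, , drop = FALSE]
    cen <- colMeans(x)
    mean(sqrt(rowSums(sweep(x, 2, cen)^2)))
  }, numeric(1))
}

#' Compare alpha diversity across groups
#'
#' Omnibus Kruskal-Wallis rank test (tie-corrected) plus all pairwise
#' Wilcoxon rank-sum tests with BH adjustment.
#'
#' @param values per-sample numeric values (e.g. Shannon indices)
#' @param groups group labels
#' @return list with `omnibus` ([test_result()]) and `pairwise`
#'   (data.frame: group1, group2, statistic, p_value, p_adjusted)
#' @export
compare_alpha_groups <- function(values, groups) {
  g <- factor(groups)
  if (length(values) != length(g)) stop("values/groups length mismatch", call. = FALSE)
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) == 0)) stop("empty group", call. = FALSE)
  if (stats::var(values) == 0) {
    omni <- test_result(0, 1, "Kruskal-Wallis rank sum test (degenerate: all values tied)")
  } else {
    kw <- stats::kruskal.test(values, g)
    omni <- test_result(unname(kw$statistic), kw$p.value,
                        "Kruskal-Wallis rank sum test", df = unname(kw$parameter))
  }
  pairs <- utils::combn(levels(g), 2)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   statistic = NA_real_, p_value = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    x <- values[g == pairs[1, i]]; y <- values[g == pairs[2, i]]
    if (stats::var(c(x, y)) == 0) {
      pw$statistic[i] <- length(x) * length(y) / 2; pw$p_value[i] <- 1
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y))
      pw$statistic[i] <- unname(wt$statistic); pw$p_value[i] <- wt$p.value
    }
  }
  pw$p_adjusted <- bh_adjust(pw$p_value)
  list(omnibus = omni, pairwise = pw)
}
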