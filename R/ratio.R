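# Seasonal ASV log-ratio index: identify the ASVs most associated with the
# two seasonal extremes (March vs August) by mean centered-log-ratio
# difference, then track ln(sum March-associated / sum August-associated)
# across every sample, with a pseudocount of one applied to the table
# before the ratio.

#' Rank month-associated ASVs by CLR difference
#'
#' Differential score per feature = mean CLR abundance in `month_a` samples
#' minus mean CLR abundance in `month_b` samples (pseudocount 1 before the
#' log-ratio transform). The top-k features are the `month_a`-associated
#' set, the bottom-k the `month_b`-associated set; ties break by feature id.
#' A deterministic ranking stand-in for multinomial-regression differential
#' ranking: only the ranked list is needed downstream.
#'
#' @param table feature table
#' @param metadata sample metadata
#' @param month_a,month_b contrasted calendar months (defaults March, August)
#' @param k set size (default 10); must satisfy 2k <= number of features
#' @param sample_types sample types used to train the contrast
#' @return list of class `seasonal_asv_sets`: `march_asvs` (month_a set),
#'   `august_asvs` (month_b set), `scores` (named, all features)
#' @export
rank_month_associated_asvs <- function(table, metadata, month_a = 3L,
                                       month_b = 8L, k = 10L,
                                       sample_types = c("water", "effluent")) {
  table <- as_feature_table(table)
  if (2 * k > ncol(table))
    stop("k too large: need 2k <= number of features", call. = FALSE)
  md <- metadata[metadata$sample_id %in% rownames(table) &
                 metadata$sample_type %in% sample_types, , drop = FALSE]
  ids_a <- md$sample_id[md$month == month_a]
  ids_b <- md$sample_id[md$month == month_b]
  if (length(ids_a) < 2 || length(ids_b) < 2)
    stop("need >= 2 samples in each month group", call. = FALSE)
  lg <- log(table[c(ids_a, ids_b), , drop = FALSE] + 1)
  clr <- lg - rowMeans(lg)
  score <- colMeans(clr[ids_a, , drop = FALSE]) - colMeans(clr[ids_b, , drop = FALSE])
  if (max(abs(score)) < 1e-8)
    warning("month groups are indistinguishable; selection is non-informative",
            call. = FALSE)
  ord_a <- order(-score, names(score))
  ord_b <- order(score, names(score))
  structure(list(march_asvs = names(score)[ord_a[seq_len(k)]],
                 august_asvs = names(score)[ord_b[seq_len(k)]],
                 scores = score,
                 months = c(month_a, month_b)),
            class = "seasonal_asv_sets")
}

#' Seasonal log-ratio index per sample
#'
#' With a pseudocount of one added to every count, returns per sample
#' ln(sum of the March-associated set / sum of the August-associated set).
#' Defined for every sample: the pseudocount keeps both sums positive.
#'
#' @param table feature table
#' @param sets a [rank_month_associated_asvs()] result (or list with
#'   `march_asvs` and `august_asvs`)
#' @return data.frame: sample_id, ln_ratio, numerator_sum, denominator_sum
#' @export
seasonal_log_ratio <- function(table, sets) {
  table <- as_feature_table(table)
  for (s in c("march_asvs", "august_asvs")) {
    miss <- setdiff(sets[[s]], colnames(table))
    if (length(miss) > 0)
      stop("feature id missing from table: ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  num <- rowSums(table[, sets$march_asvs, drop = FALSE] + 1)
  den <- rowSums(table[, sets$august_asvs, drop = FALSE] + 1)
  data.frame(sample_id = rownames(table), ln_ratio = log(num / den),
             numerator_sum = unname(num), denominator_sum = unname(den),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Monthly mean of the seasonal log-ratio
#'
#' @param ratio a [seasonal_log_ratio()] result
#' @param metadata sample metadata
#' @return data.frame: month, mean_ln_ratio, n
#' @export
monthly_ratio_summary <- function(ratio, metadata) {
  mon <- metadata$month[match(ratio$sample_id, metadata$sample_id)]
  agg <- stats::aggregate(ratio$ln_ratio, list(month = mon),
                          function(x) c(mean = mean(x), n = length(x)))
  data.frame(month = agg$month, mean_ln_ratio = agg$x[, "mean"],
             n = as.integer(agg$x[, "n"]))
}
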