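# Lightweight containers shared by all modules: feature tables, sample
# metadata, distance matrices, and test results. Plain base-R structures
# (matrix / data.frame) with validators, in the style of vegan and picante.

SAMPLE_TYPES  <- c("water", "sediment", "sewage", "effluent")
SPATIAL_ROLES <- c("upstream", "immediate_downstream", "further_downstream",
                   "effluent", "other")
REGIONS       <- c("Calumet", "OBrien", "other")

#' Validate (and coerce) a feature table
#'
#' A feature table is a samples x features matrix of non-negative integer
#' counts with unique row (sample) and column (ASV) names -- the unit of all
#' community-level computation in the package.
#'
#' @param counts numeric matrix or data.frame, samples in rows
#' @return an integer matrix with validated dimnames
#' @export
as_feature_table <- function(counts) {
  m <- as.matrix(counts)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("feature table needs sample (row) and feature (column) names", call. = FALSE)
  if (anyDuplicated(rownames(m))) stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(colnames(m))) stop("duplicate feature ids", call. = FALSE)
  if (!is.numeric(m)) stop("counts must be numeric", call. = FALSE)
  if (anyNA(m)) stop("counts must not contain NA", call. = FALSE)
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("negative or non-integer count at sample '%s', feature '%s'",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]), call. = FALSE)
  storage.mode(m) <- "integer"
  m
}

#' Validate sample metadata
#'
#' Checks the per-sample columns used throughout the pipeline and (re)derives
#' the `period` column (pre/post intervention) from the collection date.
#' Samples dated strictly before the intervention month are `pre`; the
#' intervention month itself and everything later is `post`.
#'
#' @param metadata data.frame with columns `sample_id`, `site_id`,
#'   `sample_type`, `region`, `spatial_role`, `year`, `month`
#' @param intervention_date length-2 integer `c(year, month)`; default
#'   `c(2016, 1)`
#' @return the validated data.frame with a `period` factor column
#' @export
as_sample_metadata <- function(metadata, intervention_date = c(2016L, 1L)) {
  req <- c("sample_id", "site_id", "sample_type", "region", "spatial_role",
           "year", "month")
  miss <- setdiff(req, names(metadata))
  if (length(miss) > 0)
    stop("metadata missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  md <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (anyDuplicated(md$sample_id)) stop("duplicate sample_id in metadata", call. = FALSE)
  bad <- setdiff(unique(md$sample_type), SAMPLE_TYPES)
  if (length(bad) > 0)
    stop("unknown sample_type: ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(md$spatial_role), SPATIAL_ROLES)
  if (length(bad) > 0)
    stop("unknown spatial_role: ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(md$month < 1 | md$month > 12))
    stop("month must be in 1..12", call. = FALSE)
  md$year <- as.integer(md$year)
  md$month <- as.integer(md$month)
  cut <- ym_index(intervention_date[1], intervention_date[2])
  md$period <- factor(ifelse(ym_index(md$year, md$month) < cut, "pre", "post"),
                      levels = c("pre", "post"))
  md
}

#' Validate a distance matrix
#'
#' @param dm square numeric matrix with matching, unique row/column names,
#'   zero diagonal, symmetric, all entries non-negative
#' @param tol tolerance for the symmetry / zero-diagonal checks
#' @return the validated matrix
#' @export
as_distance_matrix <- function(dm, tol = 1e-8) {
  m <- as.matrix(dm)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square", call. = FALSE)
  if (is.null(rownames(m))) stop("distance matrix needs sample ids", call. = FALSE)
  if (anyDuplicated(rownames(m))) stop("duplicate ids in distance matrix", call. = FALSE)
  if (!identical(rownames(m), colnames(m)))
    stop("row and column ids differ", call. = FALSE)
  if (any(m < -tol)) stop("negative distances", call. = FALSE)
  if (max(abs(m - t(m))) > tol) stop("distance matrix not symmetric", call. = FALSE)
  if (max(abs(diag(m))) > tol) stop("nonzero diagonal", call. = FALSE)
  m[m < 0] <- 0
  diag(m) <- 0
  (m + t(m)) / 2
}

#' Construct a test result
#'
#' Common return value of every inferential procedure in the package:
#' statistic, raw p-value, optional BH-adjusted p, method label, resample
#' count and seed (NA for analytic tests).
#'
#' @param statistic numeric test statistic
#' @param p_value raw p-value in (0, 1]
#' @param method character method label
#' @param n_resamples resample count for permutation/bootstrap tests (NA otherwise)
#' @param seed RNG seed used (NA for analytic tests)
#' @param p_adjusted optional adjusted p-value
#' @param ... further named fields (e.g. `effect_size`, `df`) stored verbatim
#' @return object of class `riverseason_test`
#' @export
test_result <- function(statistic, p_value, method, n_resamples = NA_integer_,
                        seed = NA_integer_, p_adjusted = NA_real_, ...) {
  if (!is.na(p_value) && (p_value <= 0 || p_value > 1))
    stop("p_value must be in (0, 1]", call. = FALSE)
  if (!is.na(n_resamples) && !is.na(p_value) && p_value < 1 / (n_resamples + 1) - 1e-12)
    stop("resampling p-value below its attainable floor", call. = FALSE)
  structure(
    list(statistic = as.numeric(statistic), p_value = as.numeric(p_value),
         p_adjusted = as.numeric(p_adjusted), method = method,
         n_resamples = as.integer(n_resamples), seed = as.integer(seed), ...),
    class = "riverseason_test")
}

#' @export
print.riverseason_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.6g, p = %.4g", x$statistic, x$p_value))
  if (!is.na(x$p_adjusted)) cat(sprintf(", BH-adjusted p = %.4g", x$p_adjusted))
  cat("\n")
  if (!is.na(x$n_resamples))
    cat(sprintf("  resamples = %d, seed = %d\n", x$n_resamples, x$seed))
  invisible(x)
}
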