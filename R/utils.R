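# Internal helpers shared across modules.

#' Linear month index
#'
#' Maps a (year, month) pair to a single integer so that consecutive calendar
#' months differ by exactly 1. Used for ordering, gap detection and
#' interpolation of monthly series.
#'
#' @param year integer year(s)
#' @param month integer month(s), 1--12
#' @return integer vector
#' @export
ym_index <- function(year, month) {
  stopifnot(is.numeric(year), is.numeric(month))
  if (any(month < 1 | month > 12)) stop("month must be in 1..12", call. = FALSE)
  as.integer(year) * 12L + (as.integer(month) - 1L)
}

#' @rdname ym_index
#' @param index integer linear month index as returned by `ym_index()`
#' @return `ym_from_index()`: a data.frame with columns `year` and `month`
#' @export
ym_from_index <- function(index) {
  index <- as.integer(index)
  data.frame(year = index %/% 12L, month = index %% 12L + 1L)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Column medians of a numeric matrix (used heavily by the bootstrap tests).
col_medians <- function(m) {
  n <- nrow(m)
  s <- apply(m, 2L, sort.int, method = "quick")
  if (n == 1L) return(as.numeric(s))
  if (n %% 2L == 1L) s[(n + 1L) %/% 2L, ] else (s[n %/% 2L, ] + s[n %/% 2L + 1L, ]) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
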