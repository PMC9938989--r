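# Independent UniFrac oracle: exhaustive branch enumeration, one edge at a
# time, with descendant tip sets resolved by phangorn::Descendants (a
# different traversal than the package's own postorder accumulation).

oracle_unifrac <- function(a, b, tree, weighted = FALSE, normalized = TRUE) {
  tips <- tree$tip.label
  av <- if (is.character(a)) stats::setNames(rep(1, length(a)), a) else a
  bv <- if (is.character(b)) stats::setNames(rep(1, length(b)), b) else b
  pa <- stats::setNames(numeric(length(tips)), tips)
  pb <- pa
  pa[names(av)] <- av / sum(av)
  pb[names(bv)] <- bv / sum(bv)
  shared <- 0; unique_len <- 0; union_len <- 0; raw <- 0; denom <- 0
  for (i in seq_len(nrow(tree$edge))) {
    node <- tree$edge[i, 2]
    dtips <- tips[unlist(phangorn::Descendants(tree, node, "tips"))]
    len <- tree$edge.length[i]
    wa <- sum(pa[dtips]); wb <- sum(pb[dtips])
    in_a <- wa > 0; in_b <- wb > 0
    if (in_a && in_b) shared <- shared + len
    if (xor(in_a, in_b)) unique_len <- unique_len + len
    if (in_a || in_b) union_len <- union_len + len
    raw <- raw + len * abs(wa - wb)
    denom <- denom + len * (wa + wb)
  }
  if (weighted) {
    if (!normalized) return(raw)
    if (denom == 0) return(0)
    return(raw / denom)
  }
  if (union_len == 0) return(0)
  unique_len / union_len
}

# Random tree + pair of random communities over it, for property tests.
random_unifrac_case <- function(n_tips, seed) {
  tree <- with_seed_test(seed, {
    tr <- ape::rtree(n_tips, br = function(n) stats::runif(n, 0.1, 2))
    tr$tip.label <- paste0("t", seq_len(n_tips))
    tr
  })
  counts <- with_seed_test(seed + 1, {
    m <- matrix(stats::rpois(2 * n_tips, 2), 2,
                dimnames = list(c("A", "B"), tree$tip.label))
    # guarantee non-empty communities
    m[1, sample(n_tips, 1)] <- m[1, sample(n_tips, 1)] + 1L
    m[2, sample(n_tips, 1)] <- m[2, sample(n_tips, 1)] + 1L
    m
  })
  list(tree = tree, counts = counts)
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
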