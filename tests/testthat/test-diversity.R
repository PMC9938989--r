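test_that("Shannon index uses natural log and matches direct summation", {
  expect_equal(shannon(c(5, 5, 5, 5)), log(4), tolerance = 1e-9)
  expect_equal(shannon(10), 0)
  p <- c(1, 2, 3, 4) / 10
  expect_equal(shannon(c(1, 2, 3, 4)), -sum(p * log(p)), tolerance = 1e-12)
  expect_error(shannon(c(0, 0)), "all-zero")
})

test_that("rarefaction conserves depth, drops shallow samples, and is hypergeometric in mean", {
  tab <- rbind(S1 = c(900L, 100L), S2 = c(30L, 20L), S3 = c(60L, 40L))
  colnames(tab) <- c("F1", "F2")
  out <- suppressMessages(rarefy_table(tab, depth = 100, seed = 1))
  expect_true(all(rowSums(out) == 100))
  expect_equal(attr(out, "dropped"), "S2")
  expect_false("S2" %in% rownames(out))
  expect_equal(unname(out["S3", ]), unname(tab["S3", ]))  # total == depth: unchanged
  expect_true(all(out <= tab[rownames(out), ]))

  # identical seed, identical draw
  out2 <- suppressMessages(rarefy_table(tab, depth = 100, seed = 1))
  expect_identical(out, out2)

  # mean rarefied count of taxon 2 over many seeds ~ hypergeometric mean 10
  draws <- vapply(1:1000, function(s)
    suppressMessages(rarefy_table(tab[1, , drop = FALSE], 100, seed = s))[1, 2],
    numeric(1))
  se <- sqrt(100 * 0.1 * 0.9 * (1000 - 100) / (1000 - 1)) / sqrt(1000)
  expect_lt(abs(mean(draws) - 10), 3 * se)
  expect_error(rarefy_table(tab, depth = 0), ">= 1")
})

test_that("prevalence filter removes features seen in too few samples", {
  tab <- matrix(0L, 12, 2, dimnames = list(paste0("S", 1:12), c("rare", "common")))
  tab[1:9, "rare"] <- 1L
  tab[, "common"] <- 5L
  expect_equal(colnames(filter_rare_features(tab, min_samples = 10)), "common")
  expect_equal(ncol(filter_rare_features(tab, min_samples = 9)), 2)
})

test_that("PCoA reconstructs Euclidean-embeddable distances and orders axes", {
  # 3 collinear points at 0, 1, 3
  m <- as.matrix(dist(c(0, 1, 3)))
  dimnames(m) <- list(paste0("P", 1:3), paste0("P", 1:3))
  res <- pcoa(m)
  expect_equal(sum(res$eigenvalues > 1e-8), 1)
  expect_equal(sort(res$eigenvalues, decreasing = TRUE), res$eigenvalues)
  rec <- as.matrix(dist(res$coordinates))
  expect_lt(max(abs(rec - m)), 1e-6)

  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_true(all(abs(pcoa(z)$coordinates) == 0) || ncol(pcoa(z)$coordinates) == 0)

  set.seed(3)
  x <- matrix(rnorm(40), 8)
  m2 <- as.matrix(dist(x)); dimnames(m2) <- list(paste0("S", 1:8), paste0("S", 1:8))
  res2 <- pcoa(m2)
  expect_lt(max(abs(as.matrix(dist(res2$coordinates)) - m2)), 1e-6)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2,
                           dimnames = list(c("a", "b"), c("a", "b")))),
               "symmetric")
})

test_that("PERMANOVA detects separation, saturates at the floor, and degenerates to p = 1", {
  set.seed(5)
  x <- rbind(matrix(rnorm(10 * 3), 10), matrix(rnorm(10 * 3, 30), 10))
  m <- as.matrix(dist(x))
  dimnames(m) <- list(paste0("S", 1:20), paste0("S", 1:20))
  g <- rep(c("a", "b"), each = 10)
  res <- permanova(m, g, n_perm = 999, seed = 1)
  expect_equal(res$p_value, 1 / 1000)

  eq <- matrix(1, 6, 6); diag(eq) <- 0
  dimnames(eq) <- list(paste0("S", 1:6), paste0("S", 1:6))
  res_eq <- permanova(eq, rep(c("a", "b"), 3), n_perm = 199, seed = 1)
  expect_equal(res_eq$p_value, 1)

  expect_error(permanova(m, c("a", rep("b", 19))), ">= 2 members")
})

test_that("beta dispersion matches explicit centroid geometry", {
  # identical samples: zero dispersion
  eq <- matrix(0, 3, 3, dimnames = list(paste0("S", 1:3), paste0("S", 1:3)))
  expect_equal(unname(beta_dispersion(eq, rep("g", 3))), 0)

  # 2-member group: each member is half the embedded pair distance from the centroid
  x <- c(0, 4, 10, 11)
  m <- as.matrix(dist(x)); dimnames(m) <- list(paste0("S", 1:4), paste0("S", 1:4))
  disp <- beta_dispersion(m, c("g1", "g1", "g2", "g2"))
  expect_equal(unname(disp["g1"]), 2, tolerance = 1e-6)
  expect_equal(unname(disp["g2"]), 0.5, tolerance = 1e-6)

  # 4-point configuration against hand-computed coordinates
  pts <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
  m4 <- as.matrix(dist(pts)); dimnames(m4) <- list(paste0("S", 1:4), paste0("S", 1:4))
  disp4 <- beta_dispersion(m4, rep("g", 4))
  expect_equal(unname(disp4), sqrt(2), tolerance = 1e-6)
})

test_that("alpha-group comparison: omnibus + exact pairwise tails + BH", {
  # completely separated ranks, n = 4 vs 4: exact two-sided rank-sum tail 2/70
  v <- c(1, 2, 3, 4, 11, 12, 13, 14)
  g <- rep(c("lo", "hi"), each = 4)
  res <- compare_alpha_groups(v, g)
  expect_equal(res$pairwise$p_value, 2 / choose(8, 4), tolerance = 1e-12)

  # identical values in every group: degenerate, p = 1
  res_eq <- compare_alpha_groups(rep(5, 9), rep(c("a", "b", "c"), 3))
  expect_equal(res_eq$omnibus$statistic, 0)
  expect_equal(res_eq$omnibus$p_value, 1)
  expect_equal(nrow(res_eq$pairwise), 3)  # three groups -> three pairs
  expect_true(all(res_eq$pairwise$p_adjusted >= res_eq$pairwise$p_value))
})

test_that("PERMANOVA type-I error is nominal under a random-label null", {
  set.seed(9)
  rej <- vapply(1:400, function(i) {
    x <- matrix(rnorm(12 * 3), 12)
    m <- as.matrix(dist(x))
    dimnames(m) <- list(paste0("S", 1:12), paste0("S", 1:12))
    permanova(m, rep(c("a", "b"), each = 6), n_perm = 99,
              seed = i)$p_value <= 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})
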