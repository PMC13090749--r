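test_that("occurrence matrix has one row per dataset x type", {
  col <- small_collection(seed = 61, n_datasets = 3)
  occ <- suppressWarnings(build_occurrence_matrix(col))
  expect_equal(nrow(occ), 9)
  m <- ednacongr:::occ_binary(occ)
  expect_true(all(m %in% c(0, 1)))
  # row support equals the input species list
  ds <- harmonize_collection(col)$datasets
  row1 <- m[paste0(ds$dataset_id[1], ".original"), ]
  expect_setequal(names(row1)[row1 == 1], ds$original_species[[1]])
  # statistics are invariant to row reordering
  d <- jaccard_matrix(occ)
  perm <- sample(nrow(occ))
  occ2 <- occ[perm, ]
  attr(occ2, "meta_cols") <- attr(occ, "meta_cols")
  d2 <- jaccard_matrix(occ2)
  p1 <- permanova(d, occ$continent, n_perm = 99, seed = 4)
  p2 <- permanova(d2, occ2$continent, n_perm = 99, seed = 4)
  expect_equal(p1$statistic, p2$statistic, tolerance = 1e-12)
  expect_equal(p1$r2, p2$r2, tolerance = 1e-12)
})

test_that("jaccard distances follow the set formula", {
  m <- rbind(a = c(1, 1, 0), b = c(0, 1, 1), c = c(1, 1, 0), d = c(0, 0, 1))
  d <- as.matrix(jaccard_matrix(m))
  expect_equal(d["a", "b"], 2 / 3)   # {A,B} vs {B,C}
  expect_equal(d["a", "c"], 0)       # identical
  expect_equal(d["a", "d"], 1)       # disjoint
  expect_error(jaccard_matrix(rbind(c(1, 0), c(0, 0))), "all-zero")
})

test_that("permanova and anosim statistics agree with vegan", {
  skip_if_not_installed("vegan")
  set.seed(71)
  x <- matrix(rnorm(20 * 5), 20)
  d <- dist(x)
  g <- factor(rep(c("p", "q"), each = 10))
  mine <- permanova(d, g, n_perm = 499, seed = 9)
  vg <- vegan::adonis2(d ~ g, permutations = 999)
  expect_equal(mine$statistic, vg$F[1], tolerance = 1e-10)
  expect_equal(mine$r2, vg$R2[1], tolerance = 1e-10)

  va <- vegan::anosim(d, g, permutations = 99)
  mina <- anosim(d, g, n_perm = 99, seed = 9)
  expect_equal(mina$statistic, unname(va$statistic), tolerance = 1e-10)
})

test_that("constant distance matrices give the analytic pseudo-F and p near 1", {
  n <- 9; k <- 3
  dm <- matrix(0.6, n, n); diag(dm) <- 0
  g <- factor(rep(1:3, each = 3))
  res <- permanova(as.dist(dm), g, n_perm = 199, seed = 2)
  c2 <- 0.6^2
  ss_tot <- choose(n, 2) * c2 / n
  ss_within <- 3 * choose(3, 2) * c2 / 3
  f_expect <- ((ss_tot - ss_within) / (k - 1)) / (ss_within / (n - k))
  expect_equal(res$statistic, f_expect, tolerance = 1e-12)
  expect_equal(res$r2, 1 - ss_within / ss_tot, tolerance = 1e-12)
  expect_gt(res$p, 0.9)
})

test_that("exact permutation p-values match an independent enumeration oracle", {
  skip_if_not_installed("vegan")
  set.seed(73)
  x <- matrix(rnorm(6 * 3), 6)
  d <- dist(x)
  g <- factor(rep(c("u", "v"), each = 3))
  # oracle: every distinct 3+3 assignment, F and R computed by vegan
  combos <- utils::combn(6, 3)
  f_all <- r_all <- numeric(ncol(combos))
  for (j in seq_len(ncol(combos))) {
    gj <- factor(ifelse(seq_len(6) %in% combos[, j], "u", "v"))
    f_all[j] <- suppressMessages(vegan::adonis2(d ~ gj, permutations = 1))$F[1]
    r_all[j] <- unname(suppressWarnings(vegan::anosim(d, gj, permutations = 0))$statistic)
  }
  f_obs <- vegan::adonis2(d ~ g, permutations = 1)$F[1]
  r_obs <- unname(vegan::anosim(d, g, permutations = 0)$statistic)
  p_f_oracle <- mean(f_all >= f_obs - 1e-12)
  p_r_oracle <- mean(r_all >= r_obs - 1e-12)

  expect_equal(permanova(d, g, exact = TRUE)$p, p_f_oracle, tolerance = 1e-12)
  expect_equal(anosim(d, g, exact = TRUE)$p, p_r_oracle, tolerance = 1e-12)

  # Monte-Carlo estimate is consistent with the exact value
  mc <- permanova(d, g, n_perm = 999, seed = 5)$p
  expect_lt(abs(mc - p_f_oracle), 3 * sqrt(p_f_oracle * (1 - p_f_oracle) / 999) + 0.01)
})

test_that("anosim is invariant to monotone transforms and separates groups", {
  set.seed(74)
  x <- matrix(rnorm(12 * 3), 12)
  d <- dist(x)
  g <- factor(rep(c("u", "v"), each = 6))
  r1 <- anosim(d, g, n_perm = 49, seed = 1)$statistic
  r2 <- anosim(d^2, g, n_perm = 49, seed = 1)$statistic  # monotone transform
  expect_equal(r1, r2, tolerance = 1e-12)
  # perfectly separated groups: all between > all within
  y <- rbind(matrix(rnorm(10, 0, 0.05), 5), matrix(rnorm(10, 10, 0.05), 5))
  expect_equal(anosim(dist(y), factor(rep(1:2, each = 5)),
                      n_perm = 49, seed = 1)$statistic, 1)
})

test_that("pcoa reconstructs Euclidean configurations and keeps trace identity", {
  pts <- cbind(c(0, 1, 3, 7), 0)
  d <- dist(pts)
  pc <- pcoa(d)
  rec <- dist(pc$points)
  expect_equal(as.numeric(rec), as.numeric(d), tolerance = 1e-9)
  expect_equal(ncol(pc$imaginary), 0)
  # identical rows coincide
  m <- rbind(c(1, 1, 0), c(1, 1, 0), c(0, 1, 1), c(1, 0, 1))
  pc2 <- pcoa(jaccard_matrix(m))
  expect_equal(pc2$points[1, ], pc2$points[2, ], tolerance = 1e-9)
  # eigenvalue sum = trace of the Gower matrix = total sum of squares
  dm <- as.matrix(jaccard_matrix(m))
  a <- -dm^2 / 2
  gower <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  expect_equal(sum(pc2$eigenvalues), sum(diag(gower)), tolerance = 1e-10)
})

test_that("dispersion distances match vegan::betadisper with centroids", {
  skip_if_not_installed("vegan")
  col <- small_collection(seed = 62, n_datasets = 8)
  occ <- suppressWarnings(build_occurrence_matrix(col))
  d <- jaccard_matrix(occ)
  g <- factor(occ$assignment_type)
  res <- dispersion_test(d, g, n_perm = 9, seed = 1)
  bd <- vegan::betadisper(d, g, type = "centroid")
  expect_equal(unname(res$distances), unname(bd$distances), tolerance = 1e-8)
  expect_true(all(res$distances >= 0))
  f_oracle <- unname(summary(aov(bd$distances ~ g))[[1]]$`F value`[1])
  expect_equal(res$statistic, f_oracle, tolerance = 1e-8)
})

test_that("dispersion test is calibrated for equal spread and powered for unequal", {
  set.seed(75)
  # mirror-copy groups: identical internal geometry
  base <- matrix(rnorm(8 * 2), 8)
  pts <- rbind(base, base + 100)
  g <- factor(rep(1:2, each = 8))
  res <- dispersion_test(dist(pts), g, n_perm = 199, seed = 3)
  expect_lt(res$statistic, 1e-10)
  expect_gt(res$p, 0.9)
  # one group scaled x3
  pts2 <- rbind(matrix(rnorm(40), 20), 3 * matrix(rnorm(40), 20))
  res2 <- dispersion_test(dist(pts2), factor(rep(1:2, each = 20)),
                          n_perm = 999, seed = 3)
  expect_lte(res2$p, 0.05)
})

test_that("dbrda equals classic RDA on Euclidean distances", {
  skip_if_not_installed("vegan")
  set.seed(76)
  x <- matrix(rnorm(18 * 4), 18)
  g <- factor(rep(1:3, each = 6))
  res <- dbrda(dist(x), g, n_perm = 199, seed = 2)
  rda_fit <- vegan::rda(x ~ g)
  f_oracle <- vegan::anova.cca(rda_fit, permutations = 19)$F[1]
  expect_equal(res$statistic, f_oracle, tolerance = 1e-8)
  # perfect one-dimensional separation explained by grouping
  y <- cbind(rep(c(0, 10, 20), each = 4) + rnorm(12, 0, 1e-4))
  r <- dbrda(dist(y), factor(rep(1:3, each = 4)), n_perm = 99, seed = 1)
  expect_gt(r$r2, 0.999)
})

test_that("permutation nulls are calibrated for permanova, anosim and dbrda", {
  set.seed(77)
  n_sim <- 300
  rej <- matrix(FALSE, n_sim, 3)
  for (s in seq_len(n_sim)) {
    x <- matrix(rnorm(12 * 3), 12)
    d <- dist(x)
    g <- factor(sample(rep(1:2, each = 6)))
    rej[s, 1] <- permanova(d, g, n_perm = 99, seed = s)$p <= 0.05
    rej[s, 2] <- anosim(d, g, n_perm = 99, seed = s)$p <= 0.05
    rej[s, 3] <- dbrda(d, g, n_perm = 99, seed = s)$p <= 0.05
  }
  rates <- colMeans(rej)
  # 99% Monte-Carlo band around 0.05 at 300 sims is about +/- 0.032
  expect_true(all(rates > 0.018 & rates < 0.082))
  # null anosim R averages near zero
  r_null <- replicate(500, {
    x <- matrix(rnorm(12 * 3), 12)
    anosim(dist(x), factor(sample(rep(1:2, each = 6))),
           n_perm = 1, seed = 1)$statistic
  })
  expect_lt(abs(mean(r_null)), 0.05)
})

test_that("nmds reaches near-zero stress on embeddable configurations", {
  set.seed(78)
  pts <- matrix(rnorm(15 * 2), 15)
  d <- dist(pts)
  m <- nmds(d, k = 2, seed = 1, n_restarts = 2)
  expect_lt(m$stress, 0.01)
  # stress trace is non-increasing
  expect_true(all(diff(m$trace) <= 1e-9))
  # duplicated observations land on coincident points
  ptsd <- rbind(pts, pts[1, ])
  m2 <- nmds(dist(ptsd), k = 2, seed = 1, n_restarts = 2)
  expect_lt(sqrt(sum((m2$points[16, ] - m2$points[1, ])^2)), 1e-3)
})

test_that("community_tests bundles tidy results over both groupings", {
  col <- small_collection(seed = 63, n_datasets = 6)
  ct <- suppressWarnings(community_tests(col, n_perm = 49, seed = 2))
  expect_equal(nrow(ct$tests), 8)
  expect_setequal(unique(ct$tests$grouping), c("continent", "assignment_type"))
  expect_true(all(ct$tests$p.value >= 1 / 50))
  expect_equal(nrow(ct$nmds), nrow(ct$occurrence))
})
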