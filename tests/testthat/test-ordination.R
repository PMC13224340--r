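test_that("pairwise distances satisfy closed forms and a brute-force oracle", {
  x <- rbind(c(1, 0), c(0, 1))
  d <- pairwise_distance(x, "bray_curtis")
  expect_equal(d$values[1, 2], 1)
  expect_equal(unname(diag(d$values)), c(0, 0))
  set.seed(1)
  y <- matrix(rexp(8 * 5), 8, 5)
  db <- pairwise_distance(y, "bray_curtis")
  expect_equal(db$values, bray_brute(y), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(max(abs(db$values - t(db$values))), 0)
  de <- pairwise_distance(y, "euclidean")
  expect_equal(de$values, as.matrix(dist(y)), ignore_attr = TRUE)
  z <- rbind(c(0, 0), c(0, 0))
  expect_error(pairwise_distance(z, "bray_curtis"), "all-zero")
})

test_that("PCoA recovers exact low-rank geometry", {
  pts <- c(0, 1, 3)                      # collinear
  d <- as.matrix(dist(pts))
  ord <- suppressWarnings(pcoa(d, n_axes = 2))
  expect_identical(sum(ord$eigenvalues > 1e-8), 1L)
  got <- ord$coordinates[, 1]
  expect_equal(as.matrix(dist(got)), d, ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("PCoA of Euclidean distances equals PCA scores up to axis sign", {
  set.seed(2)
  for (r in 1:5) {
    h <- rand_hellinger(30, 12)
    ord <- pcoa(pairwise_distance(h, "euclidean"), n_axes = 5)
    pc <- prcomp(h, center = TRUE, scale. = FALSE)$x[, 1:5]
    for (j in 1:5) {
      dd <- min(max(abs(ord$coordinates[, j] - pc[, j])),
                max(abs(ord$coordinates[, j] + pc[, j])))
      expect_lt(dd, 1e-8)
    }
    expect_true(all(diff(ord$eigenvalues) <= 1e-9))
    expect_true(all(ord$variance_explained >= 0 &
                      ord$variance_explained <= 1))
  }
})

test_that("NMDS reaches near-zero stress on embeddable data and is seeded", {
  set.seed(3)
  x <- matrix(rnorm(20), 10, 2)
  d <- pairwise_distance(x, "euclidean")
  ord <- nmds(d, n_starts = 5, seed = 1)
  expect_lt(ord$stress, 0.01)
  ord2 <- nmds(d, n_starts = 5, seed = 1)
  expect_identical(ord$stress, ord2$stress)
  # stress non-increasing across iterations within the winning start
  expect_true(all(diff(ord$stress_trace) <= 1e-8))
})

test_that("NMDS stress decreases with target dimensionality", {
  set.seed(4)
  h <- rand_hellinger(15, 8)
  d <- pairwise_distance(h, "bray_curtis")
  s2 <- nmds(d, d_target = 2, n_starts = 5, seed = 1)$stress
  s5 <- nmds(d, d_target = 5, n_starts = 5, seed = 1)$stress
  expect_lte(s5, s2 + 1e-8)
})

test_that("envfit recovers exact gradients and flags degenerate covariates", {
  set.seed(5)
  h <- rand_hellinger(25, 10)
  ord <- pcoa(pairwise_distance(h, "euclidean"), n_axes = 2)
  cov <- data.frame(ax = ord$coordinates[, 1],
                    flat = rep(1, 25),
                    noise = rnorm(25))
  ef <- envfit(ord, cov, n_permutations = 99, seed = 1)
  expect_equal(ef$r_squared[ef$variable == "ax"], 1, tolerance = 1e-12)
  expect_true(ef$constant[ef$variable == "flat"])
  expect_identical(ef$r_squared[ef$variable == "flat"], 0)
  expect_identical(ef$p_value[ef$variable == "flat"], 1)
  # r^2 invariant to affine rescaling of the covariate
  ef2 <- envfit(ord, data.frame(y = 3 * cov$noise - 7),
                n_permutations = 99, seed = 1)
  ef3 <- envfit(ord, data.frame(y = cov$noise),
                n_permutations = 99, seed = 1)
  expect_equal(ef2$r_squared, ef3$r_squared, tolerance = 1e-12)
  # direction vectors are unit length
  expect_equal(sqrt(ef$dir_axis1[1]^2 + ef$dir_axis2[1]^2), 1,
               tolerance = 1e-9)
})

test_that("NMDS + envfit agree with the vegan reference on structure", {
  set.seed(6)
  ds <- make_small_dataset()
  hel <- hellinger(drop_singletons(ds$counts))
  d <- pairwise_distance(hel, "bray_curtis")
  ord <- nmds(d, n_starts = 5, seed = 1)
  ref <- vegan::monoMDS(as.dist(d$values), k = 2)
  # same data, same model family: stress within a small absolute margin
  expect_lt(abs(ord$stress - ref$stress), 0.05)
})
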