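test_that("generated counts conserve sequencing depth and plant singletons", {
  ds <- make_small_dataset()
  expect_true(all(rowSums(ds$counts$values) == 5000))
  expect_identical(sum(colSums(ds$counts$values) == 1), 5L)
  expect_equal(dim(ds$counts$values), c(60L, 150L))
  # every non-background ASV maps to exactly one module
  expect_true(all(ds$truth$module_of_asv >= 0))
  # ecotype labels form contiguous runs except across the planted gaps
  tl <- cluster_timeline(ds$truth$ecotype_of_sample, ds$truth$dates,
                         break_gap_days = 40)
  expect_identical(as.integer(tl$label), sort(unique(as.integer(tl$label))))
})

test_that("generation is deterministic under a fixed seed", {
  a <- make_small_dataset(seed = 7)
  b <- make_small_dataset(seed = 7)
  expect_identical(a$counts$values, b$counts$values)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$traits, b$traits)
  c <- make_small_dataset(seed = 8)
  expect_false(identical(a$counts$values, c$counts$values))
})

test_that("config invariants are enforced", {
  expect_error(synth_config(depth = 500), "depth")
  expect_error(synth_config(background_fraction = 1), "background_fraction")
  expect_error(synth_config(n_samples = 0), "counts")
  expect_error(generate_dataset(synth_config(n_asvs = 3, n_modules = 10,
                                             background_fraction = 0,
                                             singleton_count = 0)),
               "n_modules")
})

test_that("within-module correlations approach 1 as noise vanishes", {
  ds <- generate_dataset(synth_config(n_samples = 60L, n_asvs = 120L,
                                      depth = 50000L, noise_sd = 0,
                                      background_fraction = 0,
                                      singleton_count = 0L,
                                      pulse_module = FALSE, seed = 3))
  rel <- ds$counts$values / rowSums(ds$counts$values)
  m1 <- rel[, ds$truth$module_of_asv == 1, drop = FALSE]
  cc <- stats::cor(m1[, 1:10])
  expect_gte(min(cc), 0.99)
})

test_that("COG rows are tpm-normalized and enrichment behaves", {
  ds <- make_small_dataset()
  cog <- generate_cog_table(ds$truth, effect = 5, seed = 1)
  m <- as.matrix(cog[, -1])
  expect_true(all(abs(rowSums(m) - 1e6) < 1e-6))
  expect_true(all(m >= 0))

  # effect = 5: the planted category is arg-max of its ecotype's mean z
  z <- scale(m)
  eco <- attr(cog, "ecotype")
  planted <- attr(cog, "planted_category")
  for (e in unique(eco)) {
    mean_z <- colMeans(z[eco == e, , drop = FALSE])
    expect_identical(names(which.max(mean_z)), unname(planted[as.character(e)]))
  }

  # effect = 1: no ecotype-mean z-score exceeds 1 in expectation —
  # average each (ecotype, category) mean z over 50 seeds
  acc <- 0
  for (s in 1:50) {
    cg <- generate_cog_table(ds$truth, effect = 1, seed = s)
    zz <- scale(as.matrix(cg[, -1]))
    ee <- attr(cg, "ecotype")
    acc <- acc + t(vapply(sort(unique(ee)), function(e)
      colMeans(zz[ee == e, , drop = FALSE]), numeric(ncol(zz))))
  }
  expect_lt(max(acc / 50), 1)

  # increasing effect monotonically increases the planted-category z-score
  mean_planted_z <- function(effect) {
    mean(vapply(1:20, function(s) {
      cg <- generate_cog_table(ds$truth, effect = effect, seed = s)
      zz <- scale(as.matrix(cg[, -1]))
      ee <- attr(cg, "ecotype")
      pl <- attr(cg, "planted_category")
      mean(vapply(unique(ee), function(e)
        mean(zz[ee == e, pl[as.character(e)]]), numeric(1)))
    }, numeric(1)))
  }
  ladder <- vapply(c(1, 2, 5), mean_planted_z, numeric(1))
  expect_true(all(diff(ladder) > 0))
})

test_that("fixtures round-trip bit-identically through the readers", {
  ds <- make_small_dataset()
  cog <- generate_cog_table(ds$truth, seed = 1)
  dir <- withr::local_tempdir()
  write_fixtures(ds, dir, cog = cog)
  back <- read_fixtures(dir)
  expect_equal(back$counts$values, ds$counts$values)
  expect_identical(back$counts$state, "raw")
  expect_equal(back$metadata, ds$metadata)
  expect_equal(back$traits, ds$traits, tolerance = 1e-12)
  expect_equal(back$truth_sample$ecotype,
               unname(ds$truth$ecotype_of_sample))
  expect_equal(back$truth_asv$module, unname(ds$truth$module_of_asv))
  expect_equal(as.matrix(back$cog[, -1]), as.matrix(cog[, -1]),
               ignore_attr = TRUE)
  expect_error(write_fixtures(ds, file.path(dir, "missing_subdir")),
               "missing_subdir")
})
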