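test_that("signed adjacency matches its closed forms and a brute-force loop", {
  x <- cbind(a = 1:6, b = 6:1, c = c(2, 4, 1, 5, 3, 6))
  net <- signed_adjacency(x, beta = 8)
  expect_equal(net$adjacency["a", "b"], 0)           # cor = -1
  expect_equal(net$adjacency["a", "a"], 1)
  expect_equal(((1 + 0) / 2)^8, 0.00390625)          # cor = 0 closed form
  set.seed(1)
  y <- matrix(rnorm(50), 5, 10)
  net2 <- signed_adjacency(y, beta = 6)
  brute <- matrix(0, 10, 10)
  cc <- cor(y)
  for (i in 1:10) for (j in 1:10) brute[i, j] <- ((1 + cc[i, j]) / 2)^6
  diag(brute) <- 1
  expect_equal(net2$adjacency, brute, ignore_attr = TRUE, tolerance = 1e-12)
  z <- y; z[, 3] <- 5
  colnames(z) <- paste0("v", 1:10)
  expect_error(signed_adjacency(z, 8), "v3")
  # raising beta strictly shrinks every off-diagonal with |cor| < 1
  net3 <- signed_adjacency(y, beta = 7)
  off <- upper.tri(net2$adjacency)
  expect_true(all(net3$adjacency[off] < net2$adjacency[off]))
})

test_that("scale-free fit flags power laws and degenerate graphs", {
  # nodes whose connectivities sit at 5 bin centers with frequencies on an
  # exact power law: the log-log regression over bins must be near-perfect
  k_centers <- c(10, 20, 30, 40, 50)
  freq <- round(100 * (k_centers / 10)^(-2))
  k <- rep(k_centers, freq)
  p <- length(k)
  a <- matrix(0, p, p)
  a[1, 2:p] <- k[2:p]
  a[2, 1] <- k[1]
  f <- scale_free_fit(a, n_bins = 5)
  expect_gte(f$fit_index, 0.99)
  expect_true(f$fit_index >= -1 && f$fit_index <= 1)
  expect_lt(f$slope, 0)
  eq <- matrix(0.5, 30, 30); diag(eq) <- 1
  expect_true(scale_free_fit(eq, n_bins = 10)$degenerate)
})

test_that("soft power selection follows the first-crossing contract", {
  ds <- make_small_dataset()
  hel <- hellinger(drop_singletons(ds$counts))
  qc <- network_qc(hel, n_keep = 60)
  cfg0 <- network_config(r2_target = 0.3, candidate_powers = c(2, 4, 6, 8))
  pick0 <- suppressWarnings(pick_soft_power(qc, cfg0))
  tab <- pick0$table
  expect_identical(nrow(tab), 4L)
  hit <- which(!is.na(tab$fit_index) & tab$fit_index >= 0.3)
  if (length(hit)) {
    expect_identical(pick0$beta, tab$power[hit[1]])
  } else {
    expect_identical(pick0$beta, tab$power[which.max(tab$fit_index)])
    expect_warning(pick_soft_power(qc, cfg0), "best-fitting")
  }
})

test_that("TOM matches the brute-force triple loop and special cases", {
  set.seed(3)
  cc <- cov2cor(crossprod(matrix(rnorm(15 * 12), 15, 12)))
  a <- ((1 + cc) / 2)^4
  diag(a) <- 1
  model <- structure(list(adjacency = a), class = "network_model")
  out <- tom(model)
  expect_lt(max(abs(out$tom - tom_brute(a))), 1e-12)
  expect_true(all(out$tom >= 0 & out$tom <= 1 + 1e-12))
  expect_equal(out$tom, t(out$tom))
  expect_equal(out$diss_tom, 1 - out$tom)
  # two nodes connected only to each other with a = 1 -> tom = 1
  a2 <- diag(3); a2[1, 2] <- a2[2, 1] <- 1
  t2 <- tom(structure(list(adjacency = a2), class = "network_model"))
  expect_equal(t2$tom[1, 2], 1)
  # empty graph -> zero overlap off-diagonal
  t3 <- tom(structure(list(adjacency = diag(4)), class = "network_model"))
  expect_true(all(t3$tom[upper.tri(t3$tom)] == 0))
})

test_that("module detection separates perfect blocks and is seeded", {
  set.seed(4)
  sig1 <- rnorm(30); sig2 <- rnorm(30)
  x <- cbind(sapply(1:8, function(i) sig1 + rnorm(30, 0, 0.01)),
             sapply(1:8, function(i) sig2 + rnorm(30, 0, 0.01)))
  colnames(x) <- paste0("a", 1:16)
  model <- tom(signed_adjacency(x, 8))
  lab <- detect_modules(model, k = 2, seed = 1)
  expect_equal(ari(lab, rep(1:2, each = 8)), 1)
  lab2 <- detect_modules(model, k = 2, seed = 1)
  expect_identical(lab, lab2)
  expect_error(detect_modules(model, k = 16), "k must be")
  # automatic k via the silhouette scan finds the two blocks
  lab3 <- detect_modules(model, seed = 1, k_range = 2:5)
  expect_identical(attr(lab3, "k"), 2L)
})

test_that("eigengenes summarize modules with unit variance and right sign", {
  set.seed(5)
  sig <- rnorm(40)
  x <- sapply(1:6, function(i) sig + rnorm(40, 0, 0.05))
  colnames(x) <- paste0("a", 1:6)
  me <- module_eigengenes(community_table(abs(x) + 1), rep(1L, 6))
  expect_equal(stats::sd(me[, 1]), 1, tolerance = 1e-9)
  expect_gt(mean(cor(me[, 1], abs(x) + 1)), 0.9)
  # identical profiles: eigengene equals the standardized profile
  xx <- matrix(rep(sig, 3), ncol = 3) + 5
  colnames(xx) <- paste0("b", 1:3)
  me2 <- module_eigengenes(community_table(abs(xx)), rep(1L, 3))
  expect_equal(abs(cor(me2[, 1], sig)), 1, tolerance = 1e-9)
  # singleton module flagged
  me3 <- module_eigengenes(community_table(abs(cbind(xx, z = rexp(40)))),
                           c(1L, 1L, 1L, 2L))
  expect_identical(attr(me3, "singleton_modules"), 2L)
})

test_that("kME and trait statistics respect bounds and planted signs", {
  ds <- make_small_dataset(noise_sd = 0.15)
  hel <- hellinger(drop_singletons(ds$counts))
  qc <- network_qc(hel, n_keep = 60)
  truemod <- ds$truth$module_of_asv[qc$asv_ids]
  me <- module_eigengenes(qc, truemod)
  kept <- match(qc$sample_ids, rownames(hel$values))
  stats_ <- kme_and_trait_stats(qc, me,
                                ds$traits[kept, c("copy_number",
                                                  "doubling_time",
                                                  "genome_size")])
  expect_true(all(stats_$kme >= -1 - 1e-9 & stats_$kme <= 1 + 1e-9))
  # the bloom module (fastest growth) eigengene is negatively correlated
  # with community doubling time
  bloom <- paste0("ME", 4)
  mt <- stats_$module_trait
  r <- mt$correlation[mt$module == bloom & mt$trait == "doubling_time"]
  expect_lt(r, 0)
  # kME of an ASV against its own singleton eigengene is 1
  one <- community_table(matrix(rexp(20), 20, 1,
                                dimnames = list(NULL, "a1")))
  me1 <- module_eigengenes(one, 1L)
  k1 <- kme_and_trait_stats(one, me1,
                            data.frame(t = rnorm(20)))$kme
  expect_equal(abs(k1[1, 1]), 1, tolerance = 1e-9)
})

test_that("module merging collapses duplicates and never splits", {
  set.seed(6)
  sig1 <- rnorm(40); sig2 <- sig1 + rnorm(40, 0, 0.3); sig3 <- rnorm(40)
  mk <- function(s, n) sapply(1:n, function(i) s + rnorm(40, 0, 0.05))
  x <- abs(cbind(mk(sig1, 5), mk(sig2, 5), mk(sig3, 5))) + 1
  colnames(x) <- paste0("a", 1:15)
  ct <- community_table(x)
  labels <- rep(1:3, each = 5)
  merged <- merge_modules(ct, labels, merge_threshold = 0.7)
  expect_identical(length(unique(merged)), 2L)
  expect_identical(length(unique(merged[1:10])), 1L)  # duplicates fused
  expect_lte(length(unique(merged)), length(unique(labels)))
  # all correlations below threshold: identity up to relabeling
  merged2 <- merge_modules(ct, labels, merge_threshold = 0.999)
  expect_equal(ari(merged2, labels), 1)
})
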