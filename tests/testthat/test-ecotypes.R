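test_that("cluster timelines split runs on label changes and date gaps", {
  dates <- as.Date("2020-01-01") + c(0:4, 20:24)
  labels <- c(1, 1, 1, 2, 2, 2, 2, 3, 3, 3)
  tl <- cluster_timeline(labels, dates)
  expect_identical(nrow(tl), 4L)                   # gap splits the label-2 run
  expect_identical(tl$n_samples, c(3L, 2L, 2L, 3L))
  one <- cluster_timeline(rep(1, 5), as.Date("2020-01-01") + 0:4)
  expect_identical(nrow(one), 1L)
  wide <- cluster_timeline(labels, dates, break_gap_days = 30)
  expect_identical(nrow(wide), 3L)
})

test_that("module dominance sums member abundances and stays bounded", {
  rel <- community_table(rbind(c(0.6, 0.1, 0.2, 0.1),
                               c(0.1, 0.2, 0.4, 0.3)),
                         state = "relative")
  labels <- c(1L, 1L, 2L, 2L)
  dom <- module_dominance(rel, labels)
  expect_equal(unname(dom), c(1L, 2L), ignore_attr = TRUE)
  ma <- attr(dom, "module_abundance")
  expect_true(all(rowSums(ma) <= 1 + 1e-12))
  expect_equal(ma[1, "1"], 0.7)
})

test_that("COG profiles scale to [0, 1] and recover planted enrichment", {
  ds <- make_small_dataset()
  cog <- generate_cog_table(ds$truth, effect = 5, seed = 1, every = 6)
  eco <- attr(cog, "ecotype")
  prof <- cog_profile(cog, eco)
  expect_true(all(prof$profile >= 0 & prof$profile <= 1))
  planted <- attr(cog, "planted_category")
  for (e in rownames(prof$profile))
    expect_identical(names(which.max(prof$profile[e, ])),
                     unname(planted[e]))
  # constant category: flagged, profile pinned to 0.5
  cog2 <- cog
  cog2[["C05"]] <- 1000
  prof2 <- cog_profile(cog2, eco)
  expect_identical(prof2$constant_categories, "C05")
  expect_true(all(prof2$profile[, "C05"] == 0.5))
  expect_error(cog_profile(cog, eco[-1]), "aligned")
})

test_that("qualification applies the four-part rule and small-n rejection", {
  set.seed(1)
  n <- 40
  dates <- as.Date("2020-01-01") + seq_len(n) - 1
  # two clean windows plus a 2-sample outlier wedge
  lab <- c(rep(1L, 19), rep(2L, 19), 3L, 3L)
  # disjoint community compositions per window
  rel_m <- matrix(0.001, n, 60,
                  dimnames = list(sprintf("S%03d", 1:n),
                                  sprintf("ASV%04d", 1:60)))
  rel_m[lab == 1, 1:25] <- 1
  rel_m[lab == 2, 26:50] <- 1
  rel_m[lab == 3, 51:60] <- 1
  rel_m <- rel_m / rowSums(rel_m)
  rel <- community_table(rel_m, "relative")
  traits <- data.frame(doubling_time = c(rnorm(19, 5, 0.1),
                                         rnorm(19, 40, 0.1), 20, 20.5),
                       genome_size = c(rnorm(19, 4e6, 1e4),
                                       rnorm(19, 2e6, 1e4), 3e6, 3.1e6),
                       chlorophyll_a = runif(n))
  module_trait <- data.frame(module = character(0), trait = character(0),
                             correlation = numeric(0), p_value = numeric(0))
  rep <- qualify_ecotypes(dates, list(som = lab),
                          module_labels = stats::setNames(integer(0),
                                                          character(0)),
                          rel = rel, traits = traits,
                          module_trait = module_trait, cog = NULL)
  cands <- rep$candidates
  expect_true(cands$SOM1$qualifies)
  expect_true(cands$SOM2$qualifies)
  expect_false(cands$SOM3$qualifies)
  expect_identical(cands$SOM3$reason, "insufficient support")
  expect_identical(length(rep$ecotypes), 2L)
  # monotone in evidence: widening the trait gap never un-qualifies
  traits2 <- traits
  traits2$doubling_time[lab == 2] <- traits2$doubling_time[lab == 2] + 100
  rep2 <- qualify_ecotypes(dates, list(som = lab),
                           module_labels = stats::setNames(integer(0),
                                                           character(0)),
                           rel = rel, traits = traits2,
                           module_trait = module_trait, cog = NULL)
  expect_true(rep2$candidates$SOM1$qualifies)
  expect_true(rep2$candidates$SOM2$qualifies)
})

test_that("rendered reports rank growth and handle the empty case", {
  empty <- structure(list(ecotypes = list(), candidates = list(),
                          rejected = list()), class = "ecotype_report")
  tab <- render_report(empty)
  expect_identical(nrow(tab), 0L)
  res <- suppressWarnings(
    run_all(config = synth_config(n_samples = 96L, n_asvs = 240L,
                                  depth = 20000L, singleton_count = 5L),
            seed = 1, k_range = 2:6, module_k_range = 2:8,
            run_nmds = FALSE))
  tab2 <- res$summary
  if (nrow(tab2)) {
    expect_setequal(tab2$growth_rate_rank, seq_len(nrow(tab2)))
    expect_true(all(tab2$genome_size_class %in% c("Large", "Streamlined")))
  }
  expect_s3_class(res$timings, "data.frame")
})
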