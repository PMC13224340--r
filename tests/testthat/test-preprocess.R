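test_that("copy-number normalization divides element-wise", {
  m <- matrix(c(10, 4, 0, 6), 2, 2,
              dimnames = list(c("a", "b"), c("x", "y")))
  ct <- community_table(m)
  out <- normalize_copy_number(ct, c(x = 2, y = 1))
  expect_equal(out$values[, "x"], c(a = 5, b = 2))
  expect_equal(out$values[, "y"], c(a = 0, b = 6))
  expect_identical(out$state, "copy_corrected")
  # all-ones copy numbers are the identity
  id <- normalize_copy_number(ct, c(x = 1, y = 1))
  expect_equal(id$values, ct$values)
  expect_error(normalize_copy_number(ct, c(x = 2)), "y")
  # brute-force quotient on a synthetic fixture
  ds <- make_small_dataset()
  cn <- ds$truth$asv_copy_number
  out <- normalize_copy_number(ds$counts, cn)
  expect_equal(out$values, sweep(ds$counts$values, 2, cn, "/"))
})

test_that("singleton removal uses study-wide total of exactly 1", {
  m <- cbind(a = c(1L, 0L), b = c(1L, 1L), c = c(0L, 3L))
  rownames(m) <- c("s1", "s2")
  out <- drop_singletons(community_table(m))
  expect_identical(colnames(out$values), c("b", "c"))   # total 2 retained
  expect_identical(attr(out, "removed"), "a")
  ds <- make_small_dataset()
  out <- drop_singletons(ds$counts)
  expect_identical(ncol(ds$counts$values) - ncol(out$values), 5L)
  # no singletons -> identity
  again <- drop_singletons(out)
  expect_equal(again$values, out$values)
})

test_that("relative abundance and Hellinger satisfy their contracts", {
  m <- rbind(c(2, 2), c(1, 3))
  rel <- relative_abundance(community_table(m))
  expect_equal(rel$values[1, ], c(ASV0001 = 0.5, ASV0002 = 0.5))
  expect_true(all(abs(rowSums(rel$values) - 1) < 1e-12))
  h <- hellinger(community_table(rbind(c(1, 0, 0), c(1, 1, 1))))
  expect_equal(unname(h$values[1, ]), c(1, 0, 0))
  expect_equal(unname(h$values[2, ]), rep(sqrt(1 / 3), 3))
  h4 <- hellinger(community_table(matrix(1, 1, 4)))
  expect_equal(unname(h4$values[1, ]), rep(0.5, 4))
  zero <- community_table(rbind(c(0, 0), c(1, 1)))
  expect_error(relative_abundance(zero), "S001")
  expect_error(hellinger(zero), "S001")
})

test_that("Euclidean distance of Hellinger rows equals the Hellinger distance", {
  set.seed(1)
  for (r in 1:5) {
    raw <- matrix(rexp(6 * 10), 6, 10)
    h <- hellinger(community_table(raw))
    d_pkg <- as.matrix(stats::dist(h$values))
    # direct formula: sqrt(sum((sqrt(p_i) - sqrt(q_i))^2))
    p <- raw / rowSums(raw)
    d_direct <- as.matrix(stats::dist(sqrt(p)))
    expect_equal(d_pkg, d_direct, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("network QC drops invariant ASVs, sparse samples, keeps top n", {
  m <- rbind(c(5, 5, 1, 0, 0, 0, 0, 0, 0, 2),
             c(5, 4, 0, 1, 0, 0, 0, 0, 0, 3),
             c(5, 6, 2, 2, 3, 1, 2, 1, 1, 4))
  colnames(m) <- paste0("a", 1:10)
  rownames(m) <- paste0("s", 1:3)
  m[, 1] <- 5   # constant column
  out <- network_qc(community_table(m), n_keep = 3)
  rep <- attr(out, "qc_report")
  expect_identical(rep$asvs_zero_variance, "a1")
  # rows s1 and s2 have > 50% zeros among the 9 surviving ASVs
  expect_identical(rep$samples_dropped, c("s1", "s2"))
  expect_identical(ncol(out$values), 3L)
  expect_error(network_qc(community_table(m), n_keep = 50), "exceeds")
})

test_that("the normalization chain preserves samples and state invariants", {
  ds <- make_small_dataset()
  t1 <- drop_singletons(ds$counts)
  t2 <- normalize_copy_number(t1, ds$truth$asv_copy_number[t1$asv_ids])
  t3 <- relative_abundance(t2)
  t4 <- hellinger(t2)
  for (t in list(t1, t2, t3, t4)) {
    expect_identical(nrow(t$values), nrow(ds$counts$values))
    expect_silent(validate_community_table(t))
  }
  expect_true(all(abs(rowSums(t4$values^2) - 1) < 1e-9))

  # drop_singletons then renormalization commutes with renormalized
  # restriction to the surviving ASVs
  r_all <- relative_abundance(ds$counts)
  restricted <- r_all$values[, t1$asv_ids, drop = FALSE]
  restricted <- restricted / rowSums(restricted)
  expect_equal(relative_abundance(t1)$values, restricted, tolerance = 1e-12)
})
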