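# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity.

# Bray-Curtis by explicit double loop over sample pairs
bray_brute <- function(x) {
  n <- nrow(x)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    m[i, j] <- sum(abs(x[i, ] - x[j, ])) / sum(x[i, ] + x[j, ])
  m
}

# topological overlap by explicit triple loop
tom_brute <- function(a) {
  p <- nrow(a)
  a0 <- a; diag(a0) <- 0
  out <- matrix(1, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(p)) if (u != i && u != j) l <- l + a0[i, u] * a0[u, j]
    ki <- sum(a0[i, -i]); kj <- sum(a0[j, -j])
    out[i, j] <- (l + a0[i, j]) / (min(ki, kj) + 1 - a0[i, j])
  }
  out
}

# global optimum WSS by enumerating every assignment of n points to k
# cluster ids (empty clusters allowed; they can only match, not beat, the
# non-empty optimum)
kmeans_enum_wss <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  A <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  xx <- sum(x^2)
  best <- Inf
  for (j in seq_len(k)) {
    mask_j <- A == j
    Sj <- mask_j %*% x
    nj <- rowSums(mask_j)
    contrib_j <- ifelse(nj > 0, rowSums(Sj^2) / pmax(nj, 1), 0)
    if (j == 1) tot <- contrib_j else tot <- tot + contrib_j
  }
  min(xx - tot)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# a random community table already in Hellinger state
rand_hellinger <- function(n, p) {
  raw <- matrix(stats::rexp(n * p), n, p)
  sqrt(raw / rowSums(raw))
}

# small low-noise synthetic dataset reused by several tests
make_small_dataset <- function(seed = 42, ...) {
  generate_dataset(synth_config(n_samples = 60L, n_asvs = 150L,
                                depth = 5000L, singleton_count = 5L,
                                seed = seed, ...))
}
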