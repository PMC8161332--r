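# In-code fixtures shared across the test files. Everything is generated at
# test time; no data files on disk.

# A tiny labelled count matrix (OTUs x samples).
toy_counts <- function(n_otu = 8, n_samp = 6, lambda = 5, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_otu * n_samp, lambda), n_otu, n_samp,
                dimnames = list(sprintf("OTU%02d", seq_len(n_otu)),
                                sprintf("s%02d", seq_len(n_samp))))
    m[, colSums(m) > 0, drop = FALSE]
  })
}

toy_meta <- function(counts) {
  tibble::tibble(
    sample_id = colnames(counts),
    station = paste0("st", seq_len(ncol(counts))),
    layer = "surface",
    lat = 16 + seq_len(ncol(counts)) / 10,
    lon = 116 + seq_len(ncol(counts)) / 10
  )
}

toy_otu_table <- function(...) {
  m <- toy_counts(...)
  kuromix::otu_table(m, toy_meta(m))
}

# Independent multinomial draws from a fixed lognormal regional pool
# (neutral assembly: no phylogeny-abundance association, no groups).
neutral_pool_counts <- function(n_samp = 12, n_otu = 100, depth = 500,
                                sdlog = 1.5, seed = 1) {
  withr::with_seed(seed, {
    pool <- rlnorm(n_otu, 0, sdlog)
    m <- vapply(seq_len(n_samp), function(j) {
      as.integer(rmultinom(1, depth, pool))
    }, integer(n_otu))
    dimnames(m) <- list(sprintf("OTU%04d", seq_len(n_otu)),
                        sprintf("s%02d", seq_len(n_samp)))
    m
  })
}

# A labelled distance matrix from random points in the plane.
toy_dist <- function(n = 6, seed = 1, labels = NULL) {
  withr::with_seed(seed, {
    pts <- matrix(runif(2 * n), n, 2)
    rownames(pts) <- labels %||% letters[seq_len(n)]
    dist(pts)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force one-sided Mantel p over all row/column permutations (oracle,
# independent of the package implementation).
oracle_mantel_p <- function(d1, d2) {
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  n <- nrow(m1)
  v2 <- m2[lower.tri(m2)]
  r_obs <- cor(m1[lower.tri(m1)], v2)
  perms <- kuromix_perms(n)
  stats <- apply(perms, 1, function(p) {
    mp <- m1[p, p]
    cor(mp[lower.tri(mp)], v2)
  })
  mean(stats >= r_obs - 1e-12)
}

# Recursive permutation generator local to the tests (kept separate from the
# package's own enumeration so the oracle is independent).
kuromix_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- kuromix_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub), n - 1))
  }))
}
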