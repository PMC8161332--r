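# Shared internal helpers: seeded RNG, permutation enumeration, distance-matrix
# plumbing used across the permutation tests and null models.

# Run `code` under a temporary RNG state seeded with `seed`; global RNG state is
# untouched. A NULL seed runs the code as-is (irreproducible, caller's RNG).
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# All n! permutations of 1:n as a matrix (one permutation per row). Guarded to
# small n; used only by the exact-enumeration modes of the permutation tests.
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 9)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    idx <- row:(row + nrow(sub) - 1L)
    out[idx, 1L] <- k
    out[idx, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    row <- row + nrow(sub)
  }
  out
}

# All distinct two-group label vectors for group sizes (n_a, n_b): one column
# per assignment, entries are the level indices 1/2.
two_group_assignments <- function(n_a, n_b) {
  n <- n_a + n_b
  picks <- combn(n, n_a)
  apply(picks, 2L, function(idx) {
    g <- rep(2L, n)
    g[idx] <- 1L
    g
  })
}

# Lower-triangle vector of a square matrix or dist.
lower_tri <- function(m) {
  if (inherits(m, "dist")) return(as.vector(m))
  m <- as.matrix(m)
  m[lower.tri(m)]
}

# Coerce a symmetric matrix (or dist) to dist, preserving labels, after
# checking alignment against `labels` when supplied.
as_dist_checked <- function(m, labels = NULL, arg = "distance matrix") {
  if (inherits(m, "dist")) {
    d <- m
  } else {
    m <- as.matrix(m)
    if (!isSymmetric(unname(m), tol = 1e-8)) {
      abort(sprintf("`%s` must be symmetric.", arg))
    }
    d <- as.dist(m)
  }
  if (!is.null(labels)) {
    lab <- attr(d, "Labels")
    if (is.null(lab)) {
      if (attr(d, "Size") != length(labels)) {
        abort(sprintf("`%s` has the wrong size.", arg))
      }
      attr(d, "Labels") <- labels
    } else if (!identical(lab, labels)) {
      if (!setequal(lab, labels)) {
        abort(sprintf("`%s` labels do not match the samples.", arg))
      }
      d <- as.dist(as.matrix(d)[labels, labels])
    }
  }
  d
}

# Apply a joint row/column permutation to a dist object.
permute_dist <- function(d, perm) {
  as.dist(as.matrix(d)[perm, perm])
}

# Permutation p-value with the add-one estimator (never exactly zero).
perm_pvalue <- function(n_ge, n_perm) (1 + n_ge) / (1 + n_perm)

# Pairwise Bray-Curtis between the columns of a count matrix, as a plain
# numeric for internal null-model loops (no transform).
bray_curtis_cols <- function(x, y) {
  s <- sum(x + y)
  if (s == 0) return(NA_real_)
  sum(abs(x - y)) / s
}

# Adjusted Rand index between two label vectors (used by module-recovery
# summaries; cross-checked against mclust in the tests).
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  denom <- (ai + bj) / 2 - expected
  if (denom == 0) return(1)
  (nij - expected) / denom
}

# Derive a stage-specific seed from a master seed (kept below 2^31).
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + as.integer(offset) * 1009L) %% 2147483587L
}
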