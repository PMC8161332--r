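test_that("rarefaction hits the target depth exactly and never invents reads", {
  tab <- toy_otu_table(n_otu = 30, n_samp = 8, lambda = 20, seed = 5)
  rar <- rarefy(tab, depth = 100, seed = 1)
  expect_true(all(colSums(rar$counts) == 100))
  expect_true(all(rar$counts <= tab$counts))
  # exhaustive draw leaves a sample unchanged
  rar2 <- rarefy(tab, depth = min(colSums(tab$counts)), seed = 1)
  j <- which.min(colSums(tab$counts))
  expect_equal(rar2$counts[, j], tab$counts[, j])
  # reproducible under seed
  expect_identical(rarefy(tab, depth = 100, seed = 7)$counts,
                   rarefy(tab, depth = 100, seed = 7)$counts)
  expect_false(identical(rarefy(tab, depth = 100, seed = 7)$counts,
                         rarefy(tab, depth = 100, seed = 8)$counts))
})

test_that("too-shallow samples are dropped with a warning or error on request", {
  m <- toy_counts(n_otu = 20, n_samp = 5, lambda = 10, seed = 2)
  shallow <- colnames(m)[which.min(colSums(m))]
  depth <- sort(colSums(m))[2]
  expect_warning(rar <- rarefy(m, depth = depth, seed = 1), shallow)
  expect_false(shallow %in% colnames(rar))
  expect_true(all(colSums(rar) == depth))
  expect_error(rarefy(m, depth = depth, seed = 1, shallow = "error"), shallow)
  expect_error(rarefy(m, depth = 0), "positive")
})

test_that("transforms follow their closed forms", {
  expect_equal(transform_table(matrix(0), "log1p")[1, 1], 0)
  expect_equal(transform_table(matrix(exp(1) - 1), "log1p")[1, 1], 1)
  m <- matrix(rnorm(40, 5), 10, 4, dimnames = list(NULL, letters[1:4]))
  z <- transform_table(m, "zscore")
  expect_equal(unname(colMeans(z)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 4), tolerance = 1e-12)
  m[, 2] <- 3
  expect_error(transform_table(m, "zscore"), "b")
  expect_error(transform_table(matrix(-1), "log1p"), "non-negative")
})

test_that("Bray-Curtis matches the formula and its bounds", {
  x <- matrix(c(1, 2, 3, 0), 2, 2,
              dimnames = list(c("o1", "o2"), c("a", "b")))
  expect_equal(as.vector(bray_curtis(x, transform = "raw")), 4 / 6)
  same <- cbind(a = c(1, 2), b = c(1, 2))
  rownames(same) <- c("o1", "o2")
  expect_equal(as.vector(bray_curtis(same, transform = "raw")), 0)
  disjoint <- cbind(a = c(5, 0), b = c(0, 7))
  rownames(disjoint) <- c("o1", "o2")
  expect_equal(as.vector(bray_curtis(disjoint, transform = "raw")), 1)
  m <- toy_counts(n_otu = 40, n_samp = 10, seed = 3)
  d <- bray_curtis(m)
  expect_true(all(as.vector(d) >= 0 & as.vector(d) <= 1))
})

test_that("PCoA recovers planar configurations and orders axes", {
  withr::with_seed(8, {
    pts <- matrix(rnorm(2 * 12), 12, 2)
    rownames(pts) <- sprintf("s%02d", 1:12)
  })
  ord <- pcoa_ord(dist(pts))
  expect_true(all(diff(ord$eig) <= 1e-9))
  expect_true(all(ord$eig > -1e-10)) # Euclidean input: non-negative spectrum
  rec <- as.matrix(ord$points[, c("axis1", "axis2")])
  proc <- vegan::procrustes(pts, rec, symmetric = FALSE)
  expect_lt(max(abs(residuals(proc))), 1e-8)
  # three mutually equidistant points: two equal positive eigenvalues
  tri <- matrix(1, 3, 3) - diag(3)
  dimnames(tri) <- list(c("a", "b", "c"), c("a", "b", "c"))
  eig <- pcoa_ord(as.dist(tri))$eig
  expect_equal(eig[1], eig[2], tolerance = 1e-10)
  expect_error(pcoa_ord(dist(pts[1:2, ])), "at least 3")
  expect_s3_class(tidy(ord), "tbl_df")
  expect_s3_class(autoplot(ord), "ggplot")
})

test_that("Lingoes correction removes negative eigenvalues", {
  m <- toy_counts(n_otu = 30, n_samp = 10, lambda = 0.5, seed = 4)
  d <- bray_curtis(m, transform = "raw")
  plain <- pcoa_ord(d)
  fixed <- pcoa_ord(d, correction = "lingoes")
  expect_lt(min(plain$eig), -1e-8)
  expect_gt(min(fixed$eig), -1e-6)
})

test_that("UPGMA joins at half the fusion dissimilarity with deterministic ties", {
  D <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(as.dist(D))
  cp <- cophenetic(tr)
  expect_equal(cp["A", "B"], 1)
  expect_equal(cp["A", "C"], 4)
  expect_equal(unname(ape::node.depth.edgelength(tr)[1:3]), rep(2, 3))
  # two samples: single join at D/2
  d2 <- as.dist(matrix(c(0, 3, 3, 0), 2, 2,
                       dimnames = list(c("x", "y"), c("x", "y"))))
  tr2 <- upgma(d2)
  expect_equal(unname(cophenetic(tr2)["x", "y"]), 3)
  # all equal distances: deterministic regardless of label order
  eq <- matrix(2, 4, 4) - 2 * diag(4)
  dimnames(eq) <- list(c("d", "b", "a", "c"), c("d", "b", "a", "c"))
  t1 <- upgma(as.dist(eq))
  t2 <- upgma(as.dist(eq[c(3, 2, 4, 1), c(3, 2, 4, 1)]))
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(all(cophenetic(t1)[upper.tri(matrix(0, 4, 4))] == 2))
})

test_that("ANOSIM equals 1 at maximal separation and matches vegan", {
  # two tight clusters far apart
  withr::with_seed(2, {
    pts <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2),
                 matrix(rnorm(10, 10, 0.1), 5, 2))
    rownames(pts) <- sprintf("s%d", 1:10)
  })
  d <- dist(pts)
  g <- rep(c("a", "b"), each = 5)
  res <- anosim_test(d, g, n_perm = 199, seed = 1)
  expect_equal(res$statistic, 1)
  expect_lt(res$p.value, 0.05)
  # statistic agrees with vegan on arbitrary data
  m <- toy_counts(n_otu = 30, n_samp = 10, seed = 6)
  d2 <- bray_curtis(m)
  g2 <- rep(c("x", "y"), 5)
  mine <- anosim_test(d2, g2, n_perm = 99, seed = 1)
  ref <- vegan::anosim(d2, g2, permutations = 99)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_error(anosim_test(d2, c(rep("x", 9), "y")), "Singleton")
})

test_that("ANOSIM is near zero for labels independent of structure", {
  m <- toy_counts(n_otu = 50, n_samp = 20, seed = 9)
  d <- bray_curtis(m)
  g <- rep(c("a", "b"), 10)
  res <- anosim_test(d, g, n_perm = 999, seed = 3)
  expect_lt(abs(res$statistic), 0.25)
  expect_gt(res$p.value, 0.05)
})

test_that("ANOSIM permutation p matches exhaustive enumeration on small designs", {
  # independent oracle: recompute R for every distinct assignment directly
  oracle <- function(d, g) {
    m <- as.matrix(d)
    n <- nrow(m)
    ranks <- rank(m[lower.tri(m)])
    denom <- n * (n - 1) / 4
    idx <- which(lower.tri(m), arr.ind = TRUE)
    stat <- function(gg) {
      within <- gg[idx[, 1]] == gg[idx[, 2]]
      (mean(ranks[!within]) - mean(ranks[within])) / denom
    }
    obs <- stat(g)
    n_a <- sum(g == unique(g)[1])
    picks <- combn(n, n_a)
    stats <- apply(picks, 2, function(ii) {
      gg <- rep("B", n); gg[ii] <- "A"
      stat(gg)
    })
    mean(stats >= obs - 1e-12)
  }
  for (sizes in list(c(2, 2), c(3, 3), c(3, 4))) {
    n <- sum(sizes)
    d <- toy_dist(n, seed = n)
    g <- rep(c("a", "b"), sizes)
    res <- anosim_test(d, g, exact = TRUE)
    expect_equal(res$p.value, oracle(d, g))
    expect_equal(res$n_perm, choose(n, sizes[1]))
  }
})
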