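test_that("indicator statistics hit their closed-form anchors", {
  counts <- rbind(
    perfect = c(4L, 4L, 4L, 0L, 0L, 0L),
    flat    = c(2L, 2L, 2L, 2L, 2L, 2L),
    other   = c(1L, 3L, 2L, 5L, 4L, 6L)
  )
  colnames(counts) <- paste0("s", 1:6)
  g <- rep(c("a", "b"), each = 3)
  iv <- indicator_stat(counts, g, index = "indval", n_perm = 99, seed = 1)
  expect_equal(iv$stat[iv$otu_id == "perfect"], 1)
  expect_equal(iv$group[iv$otu_id == "perfect"], "a")
  rg <- indicator_stat(counts, g, index = "r.g", n_perm = 99, seed = 1)
  expect_true(all(rg$stat >= -1 & rg$stat <= 1))
  # equal column totals make "flat" truly constant in relative abundance:
  # zero-variance OTUs get stat 0 and p 1 by convention
  eq <- rbind(flat = rep(3L, 6), varying = c(1L, 2L, 3L, 4L, 5L, 6L))
  eq <- rbind(eq, filler = 10L - colSums(eq))
  colnames(eq) <- paste0("s", 1:6)
  rg2 <- indicator_stat(eq, g, index = "r.g", n_perm = 99, seed = 1)
  expect_equal(rg2$stat[rg2$otu_id == "flat"], 0)
  expect_equal(rg2$p[rg2$otu_id == "flat"], 1)
})

test_that("group-equalized point-biserial reduces to plain correlation for equal groups", {
  m <- toy_counts(n_otu = 15, n_samp = 8, lambda = 10, seed = 7)
  g <- rep(c("a", "b"), each = 4)
  res <- indicator_stat(m, g, index = "r.g", n_perm = 99, seed = 1)
  rel <- t(sweep(m, 2, colSums(m), "/"))
  for (i in c(1, 5, 9)) {
    r_plain <- abs(cor(rel[, i], as.numeric(g == "a")))
    expect_equal(res$stat[i], r_plain, tolerance = 1e-12)
  }
})

test_that("indicator permutation p matches exhaustive enumeration", {
  counts <- rbind(
    o1 = c(9L, 7L, 8L, 1L, 2L, 1L),
    o2 = c(3L, 4L, 2L, 3L, 4L, 5L),
    o3 = c(0L, 5L, 1L, 4L, 0L, 6L)
  )
  colnames(counts) <- paste0("s", 1:6)
  g <- rep(c("a", "b"), each = 3)
  res <- indicator_stat(counts, g, index = "indval", exact = TRUE)
  # oracle: recompute max-group IndVal over every distinct assignment
  rel <- sweep(counts, 2, colSums(counts), "/")
  indval_max <- function(gg) {
    vapply(rownames(rel), function(o) {
      x <- rel[o, ]
      ms <- tapply(x, gg, mean)
      fs <- tapply(x > 0, gg, mean)
      max(sqrt(ms / sum(ms) * fs))
    }, numeric(1))
  }
  obs <- indval_max(g)
  picks <- combn(6, 3)
  ge <- matrix(FALSE, 3, ncol(picks))
  for (j in seq_len(ncol(picks))) {
    gg <- rep("b", 6); gg[picks[, j]] <- "a"
    ge[, j] <- indval_max(gg) >= obs - 1e-12
  }
  expect_equal(res$p, unname(rowMeans(ge)))
})

test_that("TMM factors track edgeR within tolerance", {
  skip_if_not_installed("edgeR")
  withr::with_seed(12, {
    m <- matrix(rnbinom(300 * 8, mu = 20, size = 2), 300, 8,
                dimnames = list(sprintf("o%03d", 1:300), paste0("s", 1:8)))
    m[1:20, 1:4] <- m[1:20, 1:4] * 5L # composition bias
  })
  mine <- tmm_factors(m)
  ref <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(unname(mine), unname(ref), tolerance = 0.02)
})

test_that("NB-LRT is null on identical groups and Poisson-limited correctly", {
  counts <- matrix(rep(c(5L, 9L, 14L, 3L, 20L), each = 8), 5, 8, byrow = TRUE,
                   dimnames = list(paste0("o", 1:5), paste0("s", 1:8)))
  g <- rep(c("a", "b"), each = 4)
  res <- nb_glm_lrt(counts, g)
  expect_true(all(res$lr < 1e-6))
  expect_true(all(res$p > 0.999))
  # Poisson-limit: LR equals the closed-form Poisson deviance difference
  withr::with_seed(3, {
    m <- matrix(rpois(40 * 20, 500), 40, 20,
                dimnames = list(sprintf("o%02d", 1:40), paste0("s", 1:20)))
  })
  g2 <- factor(rep(c("a", "b"), each = 10))
  out <- nb_glm_lrt(m, g2, dispersion = 0, normalize = "none")
  lib <- colSums(m)
  s <- lib / mean(lib)
  pois_dev <- function(y, mu) 2 * sum(ifelse(y == 0, 0, y * log(y / mu)) - (y - mu))
  for (i in c(1, 17, 40)) {
    y <- m[i, ]
    mu0 <- sum(y) / sum(s) * s
    cg <- tapply(y, g2, sum) / tapply(s, g2, sum)
    mu1 <- cg[g2] * s
    lr_oracle <- pois_dev(y, mu0) - pois_dev(y, mu1)
    expect_equal(out$lr[i], lr_oracle, tolerance = 1e-3)
  }
  # all-zero OTUs are excluded
  m0 <- rbind(m, zz = 0L)
  out0 <- nb_glm_lrt(m0, g2, dispersion = 0, normalize = "none")
  expect_false("zz" %in% out0$otu_id)
  expect_equal(attr(out0, "excluded"), "zz")
})

test_that("BH adjustment preserves the p-value ordering", {
  withr::with_seed(9, {
    m <- matrix(rnbinom(200 * 12, mu = 15, size = 1), 200, 12,
                dimnames = list(sprintf("o%03d", 1:200), paste0("s", 1:12)))
  })
  m <- m[rowSums(m) > 0, ]
  res <- nb_glm_lrt(m, rep(c("a", "b"), each = 6))
  expect_equal(order(res$p), order(res$q, res$p))
  expect_true(all(res$q >= res$p))
})

test_that("sensitivity is the strict intersection with correct abundance classes", {
  counts <- matrix(10L, 5, 4, dimnames = list(paste0("o", 1:5), paste0("s", 1:4)))
  counts[1, 1] <- 50L # o1 > 2% somewhere
  tab <- otu_table(counts, tibble::tibble(sample_id = paste0("s", 1:4)))
  ind <- tibble::tibble(otu_id = paste0("o", 1:5),
                        stat = c(0.9, 0.9, 0.9, 0.2, 0.9),
                        group = "more",
                        p = c(0.01, 0.01, 0.2, 0.01, 0.01))
  lrt <- tibble::tibble(otu_id = paste0("o", 1:5),
                        log2fc = c(1, -1, 1, 1, 1),
                        lr = 5, p = 0.01,
                        q = c(0.01, 0.01, 0.01, 0.01, 0.2))
  sens <- define_sensitive(ind, lrt, tab, enriched_level = "more")
  flag <- setNames(sens$otus$sensitive, sens$otus$otu_id)
  expect_equal(unname(flag[paste0("o", 1:5)]),
               c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_true(all(sens$otus$sensitive ==
                    (sens$otus$indicator_pass & sens$otus$lrt_pass)))
  cls <- setNames(sens$otus$abundance_class, sens$otus$otu_id)
  expect_equal(unname(cls["o1"]), "abundant") # 50/80 > 1% in sample 1
  # every count here is 10/80 = 12.5% so nothing is rare; build a rare one
  counts2 <- matrix(c(1000L, 5L, 995L, 5L), 2, 2,
                    dimnames = list(c("big", "small"), c("s1", "s2")))
  tab2 <- otu_table(counts2, tibble::tibble(sample_id = c("s1", "s2")))
  sens2 <- define_sensitive(ind[1:2, ] |> dplyr::mutate(otu_id = c("big", "small")),
                            lrt[1:2, ] |> dplyr::mutate(otu_id = c("big", "small")),
                            tab2, enriched_level = "more")
  cls2 <- setNames(sens2$otus$abundance_class, sens2$otus$otu_id)
  expect_equal(unname(cls2["small"]), "rare")
  expect_equal(unname(cls2["big"]), "abundant")
  # enrichment province follows the fold-change sign
  prov <- setNames(sens$otus$province_of_enrichment, sens$otus$otu_id)
  expect_equal(unname(prov["o1"]), "more")
  # summary read fraction
  expect_equal(sens$summary$n_sensitive, 2)
  expect_equal(sens$summary$read_fraction,
               sum(counts[1:2, ]) / sum(counts))
  expect_s3_class(tidy(sens), "tbl_df")
  expect_equal(glance(sens)$n_sensitive, 2)
})

test_that("intersection size never exceeds either method count", {
  sim <- simulate_dataset(n_stations = 8, n_otus = 150, n_winners = 10,
                          n_losers = 10, depth_mean = 1500, seed = 5)
  wm <- classify_stations(kuroshio_fraction(sim$hydro$samples,
                                            sim$hydro$endmembers))
  prov <- setNames(wm$per_station$province, wm$per_station$station)
  g <- prov[sim$table$meta$station]
  ind <- indicator_stat(sim$table, g, n_perm = 199, seed = 6)
  nb <- nb_glm_lrt(sim$table, factor(g, levels = c("less", "more")))
  sens <- define_sensitive(ind, nb, sim$table, enriched_level = "more")
  expect_lte(sens$summary$n_sensitive,
             min(sens$summary$n_indicator, sens$summary$n_lrt))
})
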