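# Identification of current-sensitive OTUs: a permutation indicator
# statistic and a negative-binomial likelihood-ratio test, intersected.

# Vectorized indicator statistics over all OTUs for one group labelling.
# `mat` is samples x OTUs (relative abundances); returns list(stat, group):
# the best (largest) statistic over groups and which group attains it.
indicator_kernel <- function(mat, groups, index) {
  groups <- as.factor(groups)
  lev <- levels(groups)
  n <- nrow(mat)
  k <- length(lev)
  sizes <- as.vector(table(groups))
  if (index == "indval") {
    gmeans <- vapply(lev, function(g) colMeans(mat[groups == g, , drop = FALSE]),
                     numeric(ncol(mat)))
    gfreq <- vapply(lev, function(g) colMeans(mat[groups == g, , drop = FALSE] > 0),
                    numeric(ncol(mat)))
    tot <- rowSums(gmeans)
    spec <- gmeans / ifelse(tot == 0, 1, tot)
    iv <- sqrt(spec * gfreq)
    iv[tot == 0, ] <- 0
    best <- max.col(iv, ties.method = "first")
    list(stat = iv[cbind(seq_len(nrow(iv)), best)], group = lev[best])
  } else {
    # Group-equalized point-biserial correlation: weight samples so every
    # group carries equal total weight, then correlate abundance with group
    # membership.
    w <- (n / k) / sizes[as.integer(groups)]
    sw <- sum(w)
    xm <- colSums(mat * w) / sw
    xc <- sweep(mat, 2, xm)
    vx <- colSums(w * xc^2)
    stat <- matrix(0, ncol(mat), k, dimnames = list(colnames(mat), lev))
    for (j in seq_len(k)) {
      t_j <- as.numeric(groups == lev[j])
      tm <- sum(w * t_j) / sw
      tc <- t_j - tm
      vt <- sum(w * tc^2)
      cov <- colSums(mat * (w * tc)) # == colSums(xc * w * tc) since sum(w*tc)=0
      r <- cov / sqrt(vx * vt)
      r[vx == 0] <- 0
      stat[, j] <- r
    }
    best <- max.col(stat, ties.method = "first")
    list(stat = stat[cbind(seq_len(nrow(stat)), best)], group = lev[best])
  }
}

#' Permutation indicator statistic per OTU
#'
#' Measures each OTU's association with the station provinces using either
#' the group-equalized point-biserial correlation between relative abundance
#' and group membership (`index = "r.g"`, the default, the
#' correlation-based indicator family) or the classic IndVal
#' \eqn{\sqrt{specificity \times fidelity}} (`index = "indval"`). For each
#' OTU the statistic is the best value over groups and the p-value comes
#' from group-label permutation (add-one estimator), or from exhaustive
#' enumeration of all distinct two-group assignments when `exact = TRUE`.
#' OTUs with zero variance get statistic 0 and p 1 by convention.
#'
#' @param x An [otu_table()] or count matrix; relative abundances are used.
#' @param groups Two-group labels aligned with samples (each group >= 2).
#' @param index `"r.g"` or `"indval"`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @param exact Exhaustive enumeration instead of sampling (small designs).
#' @return A tibble: `otu_id`, `stat`, `group` (group of maximal
#'   association), `p`.
#' @export
indicator_stat <- function(x, groups, index = c("r.g", "indval"),
                           n_perm = 999, seed = NULL, exact = FALSE) {
  index <- match.arg(index)
  counts <- get_counts(x)
  groups <- as.factor(groups)
  if (length(groups) != ncol(counts)) abort("`groups` must match the samples.")
  sizes <- table(groups)
  if (length(sizes) < 2 || any(sizes < 2)) {
    abort("Need >= 2 groups with >= 2 samples each.")
  }
  mat <- t(relative_abundance(counts))
  obs <- indicator_kernel(mat, groups, index)
  zero_var <- apply(mat, 2, function(v) all(v == v[1]))
  if (exact) {
    if (length(sizes) != 2) abort("Exact enumeration supports two groups only.")
    assigns <- two_group_assignments(sizes[[1]], sizes[[2]])
    ge <- matrix(0L, ncol(mat), ncol(assigns))
    for (j in seq_len(ncol(assigns))) {
      st <- indicator_kernel(mat, factor(assigns[, j]), index)$stat
      ge[, j] <- st >= obs$stat - 1e-12
    }
    p <- rowMeans(ge)
    n_used <- ncol(assigns)
  } else {
    n_ge <- integer(ncol(mat))
    with_seed_if(seed, {
      for (r in seq_len(n_perm)) {
        st <- indicator_kernel(mat, sample(groups), index)$stat
        n_ge <- n_ge + (st >= obs$stat - 1e-12)
      }
    })
    p <- perm_pvalue(n_ge, n_perm)
    n_used <- n_perm
  }
  out <- tibble(
    otu_id = colnames(mat),
    stat = obs$stat,
    group = obs$group,
    p = p
  )
  out$stat[zero_var] <- 0
  out$p[zero_var] <- 1
  attr(out, "index") <- index
  attr(out, "n_perm") <- n_used
  out
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Relative library scaling factors for count tables, computed from
#' log-ratio (M) and log-abundance (A) values against a reference sample
#' (the one whose upper quartile is closest to the mean upper quartile),
#' double-trimmed (30% on M, 5% on A) and precision-weighted. Factors are
#' rescaled to multiply to 1.
#'
#' @param counts OTUs x samples count matrix.
#' @param m_trim,a_trim Trim fractions for M and A (defaults 0.30, 0.05).
#' @return Named numeric vector of normalization factors.
#' @export
tmm_factors <- function(counts, m_trim = 0.30, a_trim = 0.05) {
  counts <- get_counts(counts)
  lib <- colSums(counts)
  uq <- apply(counts, 2, function(col) quantile(col[col > 0], 0.75)) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    y <- counts[, j]; r <- counts[, ref]
    keep <- y > 0 & r > 0
    y <- y[keep]; r <- r[keep]
    if (!length(y)) return(1)
    py <- y / lib[j]; pr <- r / lib[ref]
    m <- log2(py / pr)
    a <- 0.5 * log2(py * pr)
    w <- (lib[j] - y) / (lib[j] * y) + (lib[ref] - r) / (lib[ref] * r)
    if (max(abs(m)) < 1e-6) return(1)
    n_obs <- length(m)
    lo_m <- floor(n_obs * m_trim) + 1
    hi_m <- n_obs + 1 - lo_m
    lo_a <- floor(n_obs * a_trim) + 1
    hi_a <- n_obs + 1 - lo_a
    keep2 <- rank(m) >= lo_m & rank(m) <= hi_m & rank(a) >= lo_a & rank(a) <= hi_a
    if (!any(keep2)) return(1)
    2^(sum(m[keep2] / w[keep2]) / sum(1 / w[keep2]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

# Moderated method-of-moments NB dispersion per OTU, shrunk toward a lowess
# mean-dispersion trend. `z` is the matrix of normalized counts (y / s-tilde,
# s-tilde scaled to mean 1), `inv_s` the per-sample 1/s-tilde.
estimate_dispersion <- function(z, groups, inv_s, prior_df = 10) {
  groups <- as.factor(groups)
  lev <- levels(groups)
  n_tot <- length(groups)
  mu <- rowMeans(z)
  num <- numeric(nrow(z))
  den <- 0
  for (g in lev) {
    sel <- groups == g
    ng <- sum(sel)
    if (ng < 2) next
    mg <- rowMeans(z[, sel, drop = FALSE])
    vg <- apply(z[, sel, drop = FALSE], 1, var)
    cg <- mean(inv_s[sel])
    phi_g <- (vg - mg * cg) / pmax(mg, 1e-8)^2
    num <- num + (ng - 1) * phi_g
    den <- den + (ng - 1)
  }
  phi <- pmax(num / den, 0)
  ok <- mu > 0
  trend_fit <- lowess(log(mu[ok]), phi[ok], f = 0.5)
  trend <- approx(trend_fit$x, trend_fit$y, xout = log(pmax(mu, min(mu[ok]))),
                  rule = 2, ties = mean)$y
  trend <- pmax(trend, 0)
  df <- den
  pmax((prior_df * trend + df * phi) / (prior_df + df), 0)
}

#' Negative-binomial likelihood-ratio test per OTU
#'
#' Two-group differential abundance on raw counts: TMM-style normalization
#' factors give effective library sizes used as offsets; a per-OTU
#' negative-binomial dispersion is estimated by moderated method-of-moments
#' (shrunk toward the mean-dispersion trend); a log-link NB GLM with a group
#' term is compared against the intercept-only null by a likelihood-ratio
#' (deviance) statistic referred to \eqn{\chi^2_1}; p-values are BH-adjusted.
#'
#' @param x An [otu_table()] or count matrix (raw counts recommended).
#' @param groups Two-group factor aligned with samples. The log2 fold change
#'   is reported for the second level relative to the first.
#' @param dispersion Optional fixed dispersion (scalar or per-OTU). `0` gives
#'   the Poisson limit. Default `NULL` estimates it from the data.
#' @param normalize `"tmm"` (default) or `"none"` (library size only).
#' @return A tibble: `otu_id`, `base_mean`, `log2fc`, `lr`, `p`, `q`,
#'   `dispersion`. All-zero OTUs are excluded (ids in attribute
#'   `excluded`).
#' @export
nb_glm_lrt <- function(x, groups, dispersion = NULL,
                       normalize = c("tmm", "none")) {
  normalize <- match.arg(normalize)
  counts <- get_counts(x)
  groups <- as.factor(groups)
  if (length(groups) != ncol(counts)) abort("`groups` must match the samples.")
  if (nlevels(groups) != 2) abort("Exactly two groups are required.")
  excluded <- rownames(counts)[rowSums(counts) == 0]
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  lib <- colSums(counts)
  nf <- if (normalize == "tmm") tmm_factors(counts) else rep(1, ncol(counts))
  s <- lib * nf
  s <- s / mean(s)
  off <- log(s)
  z <- sweep(counts, 2, s, "/")
  if (is.null(dispersion)) {
    phi <- estimate_dispersion(z, groups, 1 / s)
  } else {
    phi <- rep_len(dispersion, nrow(counts))
  }
  x_null <- matrix(1, ncol(counts), 1)
  x_alt <- cbind(1, as.numeric(groups == levels(groups)[2]))
  fit_one <- function(y, xmat, fam) {
    fit <- suppressWarnings(
      glm.fit(xmat, y, family = fam, offset = off,
              control = list(maxit = 50))
    )
    list(dev = fit$deviance, coef = fit$coefficients)
  }
  res <- vapply(seq_len(nrow(counts)), function(i) {
    y <- counts[i, ]
    fam <- if (phi[i] < 1e-8) poisson() else
      MASS::negative.binomial(theta = 1 / phi[i])
    f0 <- fit_one(y, x_null, fam)
    f1 <- fit_one(y, x_alt, fam)
    lr <- max(0, f0$dev - f1$dev)
    c(lr = lr, log2fc = f1$coef[2] / log(2))
  }, numeric(2))
  p <- pchisq(res["lr", ], df = 1, lower.tail = FALSE)
  out <- tibble(
    otu_id = rownames(counts),
    base_mean = rowMeans(z),
    log2fc = res["log2fc", ],
    lr = res["lr", ],
    p = p,
    q = p.adjust(p, method = "BH"),
    dispersion = phi
  )
  attr(out, "excluded") <- excluded
  attr(out, "norm_factors") <- setNames(nf, colnames(counts))
  out
}

#' Define current-sensitive OTUs by method intersection
#'
#' An OTU is sensitive when it passes both the indicator screen
#' (`stat > iv_thresh` and `p < p_thresh`) and the negative-binomial LRT
#' (`q < q_thresh`). Each OTU is also classified by abundance: abundant when
#' its relative abundance exceeds 1% in at least one sample, rare when below
#' 1% in all samples, intermediate otherwise; and by province of enrichment
#' (the sign of the log2 fold change).
#'
#' @param indicator Output of [indicator_stat()].
#' @param lrt Output of [nb_glm_lrt()].
#' @param x The [otu_table()] the tests were run on (for abundance classes
#'   and read fractions).
#' @param iv_thresh,p_thresh,q_thresh Thresholds (defaults 0.5, 0.05, 0.05).
#' @param enriched_level Group label reported as the enriched province when
#'   `log2fc > 0` (defaults to the second factor level used in the LRT).
#' @return A `sensitive_otus` object: per-OTU tibble (`$otus`) plus a
#'   summary list (`$summary`) with method counts, intersection size and the
#'   fraction of total reads in sensitive OTUs.
#' @export
define_sensitive <- function(indicator, lrt, x, iv_thresh = 0.5,
                             p_thresh = 0.05, q_thresh = 0.05,
                             enriched_level = NULL) {
  counts <- get_counts(x)
  relab <- relative_abundance(counts)
  max_rel <- apply(relab, 1, max)
  abclass <- dplyr::case_when(
    max_rel > 0.01 ~ "abundant",
    max_rel < 0.01 ~ "rare",
    TRUE ~ "intermediate"
  )
  base <- tibble(otu_id = rownames(counts), abundance_class = abclass)
  ind <- rename(indicator, indicator_stat = "stat", indicator_group = "group",
                indicator_p = "p")
  nb <- select(lrt, "otu_id", nb_log2fc = "log2fc", nb_lr = "lr",
               nb_p = "p", nb_q = "q")
  otus <- base |>
    left_join(ind, by = "otu_id") |>
    left_join(nb, by = "otu_id") |>
    mutate(
      indicator_pass = !is.na(.data$indicator_stat) &
        .data$indicator_stat > iv_thresh & .data$indicator_p < p_thresh,
      lrt_pass = !is.na(.data$nb_q) & .data$nb_q < q_thresh,
      sensitive = .data$indicator_pass & .data$lrt_pass
    )
  if (is.null(enriched_level)) {
    enriched_level <- levels(as.factor(otus$indicator_group))[
      length(levels(as.factor(otus$indicator_group)))]
  }
  lev <- sort(unique(otus$indicator_group[!is.na(otus$indicator_group)]))
  other <- setdiff(lev, enriched_level)
  otus$province_of_enrichment <- ifelse(
    is.na(otus$nb_log2fc), NA_character_,
    ifelse(otus$nb_log2fc > 0, enriched_level,
           if (length(other)) other[1] else NA_character_)
  )
  sens_ids <- otus$otu_id[otus$sensitive]
  read_fraction <- sum(counts[sens_ids, , drop = FALSE]) / sum(counts)
  summary <- list(
    n_indicator = sum(otus$indicator_pass, na.rm = TRUE),
    n_indicator_by_group = table(otus$indicator_group[otus$indicator_pass]),
    n_lrt = sum(otus$lrt_pass, na.rm = TRUE),
    n_sensitive = length(sens_ids),
    read_fraction = read_fraction,
    abundant_fraction_of_sensitive =
      mean(otus$abundance_class[otus$sensitive] == "abundant"),
    thresholds = c(iv = iv_thresh, p = p_thresh, q = q_thresh)
  )
  structure(list(otus = otus, summary = summary), class = "sensitive_otus")
}

#' @export
print.sensitive_otus <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<sensitive_otus> %d indicator, %d LRT, %d sensitive (intersection); %.1f%% of reads\n",
    s$n_indicator, s$n_lrt, s$n_sensitive, 100 * s$read_fraction
  ))
  invisible(x)
}

#' @rdname define_sensitive
#' @param ... Unused.
#' @export
tidy.sensitive_otus <- function(x, ...) x$otus

#' @rdname define_sensitive
#' @export
glance.sensitive_otus <- function(x, ...) {
  s <- x$summary
  tibble(
    n_indicator = s$n_indicator, n_lrt = s$n_lrt,
    n_sensitive = s$n_sensitive, read_fraction = s$read_fraction,
    abundant_fraction_of_sensitive = s$abundant_fraction_of_sensitive
  )
}
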