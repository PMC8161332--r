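# Phylogenetic and compositional null models for community assembly:
# betaMNTD / betaNTI against a tip-shuffle null, abundance-based Raup-Crick
# on Bray-Curtis, and the process-fraction bookkeeping that classifies each
# sample pair into selection, dispersal, or drift.

# Core betaMNTD kernel. `dmat` is the patristic distance matrix over the OTUs
# (rows of `freq`), `freq` the per-sample weight matrix (columns sum to 1 for
# the abundance-weighted variant, or 1/richness for unweighted), `support`
# the list of OTU indices present in each sample.
bmntd_kernel <- function(dmat, freq, support) {
  n_samp <- ncol(freq)
  n_otu <- nrow(freq)
  dmin <- matrix(0, n_otu, n_samp)
  for (m in seq_len(n_samp)) {
    sub <- dmat[, support[[m]], drop = FALSE]
    mins <- sub[, 1]
    if (ncol(sub) > 1) {
      for (j in 2:ncol(sub)) mins <- pmin(mins, sub[, j])
    }
    dmin[, m] <- mins
  }
  a <- crossprod(freq, dmin) # a[k, m] = sum_i f_ik * min_j-in-m d(i, j)
  b <- (a + t(a)) / 2
  diag(b) <- 0
  b
}

# Shared validation/preparation for the phylogenetic null model.
prep_phylo <- function(x, tree, weighted) {
  counts <- get_counts(x)
  missing <- setdiff(rownames(counts), tree$tip.label)
  if (length(missing)) {
    abort(paste0("OTUs missing from the tree: ",
                 paste(head(missing, 10), collapse = ", "),
                 if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10)))
  }
  tree <- ape::keep.tip(tree, rownames(counts))
  dmat <- cophenetic(tree)[rownames(counts), rownames(counts)]
  freq <- if (weighted) {
    relative_abundance(counts)
  } else {
    pres <- counts > 0
    sweep(pres * 1, 2, colSums(pres), "/")
  }
  support <- apply(counts > 0, 2, which, simplify = FALSE)
  if (any(lengths(support) == 0)) abort("Samples with no OTUs present.")
  list(counts = counts, dmat = dmat, freq = freq, support = support)
}

#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' For each sample pair (k, m), averages the patristic distance from every
#' OTU in one sample to its nearest relative in the other:
#' \eqn{\beta MNTD_{km} = \frac12 [\sum_i f_{ik} \min_{j \in m} d_{ij} +
#' \sum_j f_{jm} \min_{i \in k} d_{ji}]}, with \eqn{f} the relative
#' abundances (abundance-weighted, the default) or \eqn{1/}richness
#' (unweighted).
#'
#' @param x An [otu_table()] or count matrix (OTUs x samples).
#' @param tree A rooted `phylo` whose tips cover the table's OTUs.
#' @param weighted Abundance-weighted (default) or presence-based.
#' @return A `dist` of betaMNTD values (phylogenetic distance units).
#' @export
beta_mntd <- function(x, tree, weighted = TRUE) {
  prep <- prep_phylo(x, tree, weighted)
  b <- bmntd_kernel(prep$dmat, prep$freq, prep$support)
  rownames(b) <- colnames(b) <- colnames(prep$counts)
  as.dist(b)
}

#' Beta nearest taxon index (betaNTI) against a tip-shuffle null
#'
#' Standardises observed betaMNTD against a null distribution obtained by
#' shuffling OTU labels across all tips in the regional pool (the union of
#' OTUs in the table), recomputing betaMNTD each time:
#' \eqn{\beta NTI = (obs - \overline{null}) / sd(null)}. Pairs with zero null
#' standard deviation are returned as `NA` (undefined). |betaNTI| > 2 is the
#' conventional signature of selection.
#'
#' @inheritParams beta_mntd
#' @param n_null Number of null randomizations (>= 99; the conventional
#'   production value is 999).
#' @param seed Integer seed.
#' @return An object of class `beta_nti_result` with `beta_mntd` (dist),
#'   `beta_nti` (dist, NA where undefined), `n_null`, `seed`.
#' @export
beta_nti <- function(x, tree, n_null = 999, seed = NULL, weighted = TRUE) {
  if (n_null < 99) abort("`n_null` must be at least 99.")
  prep <- prep_phylo(x, tree, weighted)
  obs <- bmntd_kernel(prep$dmat, prep$freq, prep$support)
  n_otu <- nrow(prep$freq)
  acc <- matrix(0, ncol(prep$freq), ncol(prep$freq))
  acc2 <- acc
  with_seed_if(seed, {
    for (r in seq_len(n_null)) {
      perm <- sample.int(n_otu)
      b <- bmntd_kernel(prep$dmat[perm, perm], prep$freq, prep$support)
      acc <- acc + b
      acc2 <- acc2 + b^2
    }
  })
  mu <- acc / n_null
  sdv <- sqrt(pmax(0, acc2 / n_null - mu^2) * n_null / (n_null - 1))
  bnti <- (obs - mu) / sdv
  bnti[sdv < 1e-12] <- NA_real_
  diag(bnti) <- 0
  labels <- colnames(prep$counts)
  rownames(obs) <- colnames(obs) <- labels
  rownames(bnti) <- colnames(bnti) <- labels
  structure(
    list(beta_mntd = as.dist(obs), beta_nti = as.dist(bnti),
         n_null = n_null, seed = seed, weighted = weighted),
    class = "beta_nti_result"
  )
}

#' @export
print.beta_nti_result <- function(x, ...) {
  v <- as.vector(x$beta_nti)
  cat(sprintf(
    "<beta_nti_result> %d sample pairs, %d nulls; |betaNTI| > 2 for %.1f%% of pairs (%d undefined)\n",
    length(v), x$n_null, 100 * mean(abs(v) > 2, na.rm = TRUE), sum(is.na(v))
  ))
  invisible(x)
}

#' Abundance-based Raup-Crick dissimilarity on Bray-Curtis
#'
#' For each sample pair, compares the observed Bray-Curtis dissimilarity
#' (raw counts) with a null distribution of Bray-Curtis values between
#' probabilistically assembled communities that preserve each sample's
#' observed richness and total reads: null OTUs are drawn without
#' replacement with probability proportional to occupancy (number of samples
#' occupied), seeded with one read each, and the remaining reads are
#' distributed multinomially with probability proportional to regional
#' relative abundance. The result is rescaled to \[-1, 1\]:
#' \eqn{RC = 2[(\#null < obs) + \frac12(\#null = obs)]/n_{null} - 1}.
#'
#' @param x An [otu_table()] or count matrix (typically rarefied counts).
#' @param n_null Number of null draws per pair (>= 99).
#' @param seed Integer seed.
#' @return A `dist` of RC values in \[-1, 1\].
#' @export
raup_crick_bray <- function(x, n_null = 999, seed = NULL) {
  if (n_null < 99) abort("`n_null` must be at least 99.")
  counts <- get_counts(x)
  n_samp <- ncol(counts)
  if (n_samp < 2) abort("Need at least 2 samples.")
  occupancy <- rowSums(counts > 0)
  regional <- rowSums(counts)
  n_otu <- nrow(counts)
  richness <- colSums(counts > 0)
  totals <- colSums(counts)
  draw_null <- function(rich, total) {
    chosen <- sample.int(n_otu, rich, replace = FALSE, prob = occupancy)
    com <- numeric(n_otu)
    com[chosen] <- 1
    extra <- total - rich
    if (extra > 0) {
      com[chosen] <- com[chosen] +
        as.vector(rmultinom(1, extra, prob = regional[chosen]))
    }
    com
  }
  rc <- matrix(0, n_samp, n_samp)
  with_seed_if(seed, {
    for (k in seq_len(n_samp - 1)) {
      for (m in (k + 1):n_samp) {
        obs <- bray_curtis_cols(counts[, k], counts[, m])
        nulls <- vapply(seq_len(n_null), function(r) {
          bray_curtis_cols(draw_null(richness[k], totals[k]),
                           draw_null(richness[m], totals[m]))
        }, numeric(1))
        n_less <- sum(nulls < obs - 1e-12)
        n_eq <- sum(abs(nulls - obs) <= 1e-12)
        rc[m, k] <- rc[k, m] <- 2 * (n_less + 0.5 * n_eq) / n_null - 1
      }
    }
  })
  rownames(rc) <- colnames(rc) <- colnames(counts)
  as.dist(rc)
}

#' Classify sample pairs into ecological processes
#'
#' Applies the conventional two-stage rule: pairs with betaNTI > +2 reflect
#' heterogeneous selection and betaNTI < -2 homogeneous selection; among the
#' remaining pairs (|betaNTI| <= 2), RC > +0.95 indicates dispersal
#' limitation, RC < -0.95 homogenizing dispersal, and intermediate values
#' drift. Fractions are reported over all pairs with a defined betaNTI.
#'
#' @param bnti A `beta_nti_result` or a `dist`/matrix of betaNTI values.
#' @param rc A `dist`/matrix of Raup-Crick values aligned with `bnti`.
#' @param bnti_thresh,rc_thresh Classification thresholds (defaults 2, 0.95).
#' @return An `assembly_processes` object: a tibble with one row per process
#'   (`process`, `n_pairs`, `fraction`), plus attributes recording excluded
#'   (undefined) pairs.
#' @export
process_fractions <- function(bnti, rc, bnti_thresh = 2, rc_thresh = 0.95) {
  if (inherits(bnti, "beta_nti_result")) bnti <- bnti$beta_nti
  b <- lower_tri(bnti)
  r <- lower_tri(rc)
  if (length(b) != length(r)) abort("`bnti` and `rc` are not aligned.")
  defined <- !is.na(b)
  n_excluded <- sum(!defined)
  b <- b[defined]
  r <- r[defined]
  cls <- dplyr::case_when(
    b > bnti_thresh ~ "heterogeneous_selection",
    b < -bnti_thresh ~ "homogeneous_selection",
    r > rc_thresh ~ "dispersal_limitation",
    r < -rc_thresh ~ "homogenizing_dispersal",
    TRUE ~ "drift"
  )
  levels <- c("heterogeneous_selection", "homogeneous_selection",
              "dispersal_limitation", "homogenizing_dispersal", "drift")
  tab <- table(factor(cls, levels = levels))
  out <- tibble(
    process = levels,
    n_pairs = as.integer(tab),
    fraction = as.numeric(tab) / length(b)
  )
  structure(out, class = c("assembly_processes", class(out)),
            n_pairs_total = length(b), n_excluded = n_excluded,
            bnti_thresh = bnti_thresh, rc_thresh = rc_thresh)
}

#' @rdname process_fractions
#' @param x An `assembly_processes` object.
#' @param ... Unused.
#' @export
glance.assembly_processes <- function(x, ...) {
  wide <- setNames(as.list(x$fraction), x$process)
  bind_cols(as_tibble(wide),
            tibble(n_pairs = attr(x, "n_pairs_total"),
                   n_excluded = attr(x, "n_excluded")))
}

#' Quantify assembly processes in one call
#'
#' Convenience wrapper running [beta_nti()], [raup_crick_bray()] and
#' [process_fractions()] on the same table.
#'
#' @inheritParams beta_nti
#' @param rc_seed Optional separate seed for the Raup-Crick null (defaults to
#'   a seed derived from `seed`).
#' @param bnti_thresh,rc_thresh Passed to [process_fractions()].
#' @return A list with `bnti` (`beta_nti_result`), `rc` (dist) and
#'   `processes` (`assembly_processes`).
#' @export
quantify_assembly <- function(x, tree, n_null = 999, seed = NULL,
                              weighted = TRUE, rc_seed = NULL,
                              bnti_thresh = 2, rc_thresh = 0.95) {
  bnti <- beta_nti(x, tree, n_null = n_null, seed = seed, weighted = weighted)
  rc <- raup_crick_bray(x, n_null = n_null,
                        seed = rc_seed %||% derive_seed(seed, 1L))
  list(bnti = bnti, rc = rc,
       processes = process_fractions(bnti, rc, bnti_thresh, rc_thresh))
}
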