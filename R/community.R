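#' Rarefy an OTU table to even sequencing depth
#'
#' Subsamples each sample's reads without replacement down to `depth`.
#' Samples with fewer reads than `depth` are either dropped with a warning
#' (default) or raise an error, depending on `shallow`.
#'
#' @param x An [otu_table()] (or a count matrix).
#' @param depth Target reads per sample. Defaults to the minimum sample depth
#'   (so nothing is dropped).
#' @param seed Integer seed for reproducible subsampling.
#' @param shallow `"drop"` (default) to drop too-shallow samples with a
#'   warning, `"error"` to fail.
#' @return An object of the same class as `x` with every retained sample
#'   summing exactly to `depth`. Attributes `rarefaction_depth` and
#'   `rarefaction_seed` record the draw.
#' @export
rarefy <- function(x, depth = NULL, seed = NULL, shallow = c("drop", "error")) {
  shallow <- match.arg(shallow)
  counts <- get_counts(x)
  totals <- colSums(counts)
  depth <- depth %||% min(totals)
  if (depth <= 0) abort("`depth` must be positive.")
  too_shallow <- totals < depth
  if (any(too_shallow)) {
    if (shallow == "error") {
      abort(paste0("Samples shallower than the rarefaction depth: ",
                   paste(colnames(counts)[too_shallow], collapse = ", ")))
    }
    warn(paste0("Dropping samples shallower than depth ", depth, ": ",
                paste(colnames(counts)[too_shallow], collapse = ", ")))
    counts <- counts[, !too_shallow, drop = FALSE]
  }
  # Draw without replacement from the read pool of each sample.
  rar <- with_seed_if(seed, {
    vapply(seq_len(ncol(counts)), function(j) {
      col <- counts[, j]
      if (sum(col) == depth) return(col)
      pool <- rep.int(seq_along(col), col)
      picked <- sample(pool, depth, replace = FALSE)
      tabulate(picked, nbins = length(col))
    }, numeric(nrow(counts)))
  })
  rar <- matrix(rar, nrow = nrow(counts),
                dimnames = list(rownames(counts), colnames(counts)))
  out <- if (inherits(x, "otu_table")) {
    otu_table(rar, x$meta[x$meta$sample_id %in% colnames(rar), , drop = FALSE])
  } else {
    rar
  }
  attr(out, "rarefaction_depth") <- depth
  attr(out, "rarefaction_seed") <- seed
  out
}

#' Transform a count matrix or environmental table
#'
#' `"log1p"` applies the natural-log transform `ln(x + 1)` elementwise (the
#' standard treatment of sequence counts before distance-based analyses);
#' `"zscore"` standardises each numeric column to mean 0 and sd 1 (the
#' standard treatment of environmental variables).
#'
#' @param x A numeric matrix, data frame, or [otu_table()] (counts are
#'   transformed, metadata untouched).
#' @param mode `"log1p"` or `"zscore"`.
#' @return The transformed object, same shape as the input.
#' @export
transform_table <- function(x, mode = c("log1p", "zscore")) {
  mode <- match.arg(mode)
  if (inherits(x, "otu_table")) {
    x$counts <- transform_table(x$counts, mode)
    return(x)
  }
  if (mode == "log1p") {
    m <- as.matrix(x)
    if (any(m < 0)) abort("log1p transform requires non-negative values.")
    return(log1p(m))
  }
  m <- as.matrix(x)
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("Cannot z-score constant column(s): ",
                 paste(colnames(m)[sds == 0], collapse = ", ")))
  }
  scale(m)[, , drop = FALSE]
}

#' Bray-Curtis dissimilarity between samples
#'
#' Computes \eqn{BC_{ij} = \sum_k |x_{ki} - x_{kj}| / \sum_k (x_{ki} +
#' x_{kj})} between sample columns, by default on `ln(x + 1)`-transformed
#' counts (pass `transform = "raw"` for untransformed counts).
#'
#' @param x An [otu_table()] or count matrix (OTUs x samples).
#' @param transform `"log1p"` (default) or `"raw"`.
#' @return A `dist` object labelled by sample id, entries in \[0, 1\].
#' @export
bray_curtis <- function(x, transform = c("log1p", "raw")) {
  transform <- match.arg(transform)
  counts <- get_counts(x)
  if (ncol(counts) < 2) abort("Need at least 2 samples.")
  zero_pairs <- sum(colSums(counts) == 0)
  if (zero_pairs >= 2) abort("Bray-Curtis is undefined between all-zero samples.")
  m <- if (transform == "log1p") log1p(counts) else counts
  vegan::vegdist(t(m), method = "bray")
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a dissimilarity matrix: Gower double-centring
#' of \eqn{-D^2/2} and eigendecomposition. Axes are ordered by descending
#' eigenvalue; negative eigenvalues (possible for semimetric dissimilarities
#' such as Bray-Curtis) are reported, not corrected, unless
#' `correction = "lingoes"`.
#'
#' @param d A `dist` (or symmetric matrix).
#' @param correction `"none"` (default) or `"lingoes"` (adds the smallest
#'   constant to squared off-diagonal dissimilarities that makes the
#'   configuration Euclidean).
#' @return An object of class `pcoa_ord` with elements `points` (tibble:
#'   `sample_id`, `axis1`, `axis2`, ...), `eig` (all eigenvalues) and
#'   `prop_explained` (positive-eigenvalue proportions).
#' @export
pcoa_ord <- function(d, correction = c("none", "lingoes")) {
  correction <- match.arg(correction)
  d <- as_dist_checked(d)
  n <- attr(d, "Size")
  if (n < 3) abort("PCoA needs at least 3 samples.")
  if (correction == "lingoes") {
    eig0 <- suppressWarnings(cmdscale(d, k = n - 1, eig = TRUE))$eig
    cmin <- min(eig0)
    if (cmin < 0) {
      m <- as.matrix(d)
      m2 <- sqrt(m^2 + 2 * abs(cmin))
      diag(m2) <- 0
      d <- as.dist(m2)
    }
  }
  # cmdscale warns when fewer than k axes have positive eigenvalues; that is
  # the expected situation here (we ask for all of them).
  fit <- suppressWarnings(cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig))
  pts <- fit$points[, seq_len(sum(pos)), drop = FALSE]
  colnames(pts) <- paste0("axis", seq_len(ncol(pts)))
  points <- bind_cols(tibble(sample_id = attr(d, "Labels") %||% rownames(pts) %||%
                               as.character(seq_len(n))),
                      as_tibble(pts))
  structure(
    list(points = points, eig = eig,
         prop_explained = pmax(eig, 0)[pos] / sum(pmax(eig, 0)),
         correction = correction),
    class = "pcoa_ord"
  )
}

#' @export
print.pcoa_ord <- function(x, ...) {
  cat(sprintf("<pcoa_ord> %d samples, %d positive axes; axis1 %.1f%%, axis2 %.1f%%\n",
              nrow(x$points), length(x$prop_explained),
              100 * x$prop_explained[1],
              100 * (x$prop_explained[2] %||% NA_real_)))
  invisible(x)
}

#' @rdname pcoa_ord
#' @param x A `pcoa_ord` object.
#' @param ... Unused.
#' @export
tidy.pcoa_ord <- function(x, ...) x$points

#' @export
autoplot.pcoa_ord <- function(object, colour = NULL, ...) {
  d <- object$points
  p <- ggplot(d, aes(x = .data$axis1, y = .data$axis2))
  if (!is.null(colour)) {
    d$colour <- colour
    p <- ggplot(d, aes(x = .data$axis1, y = .data$axis2, colour = .data$colour))
  }
  p + geom_point(size = 2) +
    labs(
      x = sprintf("PCoA 1 (%.1f%%)", 100 * object$prop_explained[1]),
      y = sprintf("PCoA 2 (%.1f%%)", 100 * object$prop_explained[2]),
      colour = NULL
    ) +
    theme_minimal()
}

#' UPGMA clustering of a dissimilarity matrix
#'
#' Average-linkage agglomeration returned as an ultrametric `phylo` tree
#' whose root-to-tip depths are half the fusion dissimilarities. Labels are
#' sorted lexicographically first so equal-distance ties resolve
#' deterministically.
#'
#' @param d A `dist` (or symmetric matrix) with labels.
#' @return An `ape::phylo` dendrogram.
#' @export
upgma <- function(d) {
  d <- as_dist_checked(d)
  labs <- attr(d, "Labels") %||% as.character(seq_len(attr(d, "Size")))
  ord <- order(labs)
  d <- as.dist(as.matrix(d)[ord, ord])
  if (attr(d, "Size") == 2) {
    h <- as.vector(d) / 2
    txt <- sprintf("(%s:%f,%s:%f);", attr(d, "Labels")[1], h,
                   attr(d, "Labels")[2], h)
    return(ape::read.tree(text = txt))
  }
  ape::as.phylo(hclust(d, method = "average"))
}

#' Analysis of similarities (ANOSIM)
#'
#' Tests whether between-group dissimilarities exceed within-group
#' dissimilarities on ranked distances:
#' \eqn{R = (\bar r_B - \bar r_W) / (n(n-1)/4)}. The p-value comes from label
#' permutation with the add-one estimator, or from exhaustive enumeration of
#' all distinct two-group assignments when `exact = TRUE`.
#'
#' @param d A `dist` (or symmetric matrix) between samples.
#' @param groups Group labels aligned with the rows of `d` (two or more
#'   groups, each with at least 2 members).
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @param exact If `TRUE`, enumerate all distinct assignments (two groups
#'   only); the p-value is then the exact proportion of assignments with
#'   `R >= R_obs` (the observed assignment included).
#' @return A `perm_test` object with `statistic`, `p.value`, `n_perm`,
#'   `method`, `seed`.
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = NULL, exact = FALSE) {
  d <- as_dist_checked(d)
  n <- attr(d, "Size")
  groups <- as.factor(groups)
  if (length(groups) != n) abort("`groups` must match the size of `d`.")
  sizes <- table(groups)
  if (length(sizes) < 2) abort("Need at least 2 groups.")
  if (any(sizes < 2)) {
    abort(paste0("Singleton group(s): ", paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  ranks <- rank(as.vector(d))
  denom <- n * (n - 1) / 4
  # dist stores the lower triangle column-major: (2,1),(3,1),...,(n,n-1)
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  stat_for <- function(g) {
    within <- g[idx[, 1]] == g[idx[, 2]]
    (mean(ranks[!within]) - mean(ranks[within])) / denom
  }
  r_obs <- stat_for(groups)
  if (exact) {
    if (length(sizes) != 2) abort("Exact enumeration supports two groups only.")
    assigns <- two_group_assignments(sizes[[1]], sizes[[2]])
    # map assignment slots back onto the observed positions of each group size
    stats <- apply(assigns, 2, function(a) {
      g <- factor(a)
      stat_for(g)
    })
    p <- mean(stats >= r_obs - 1e-12)
    n_used <- ncol(assigns)
  } else {
    stats <- with_seed_if(seed, {
      vapply(seq_len(n_perm), function(i) stat_for(sample(groups)), numeric(1))
    })
    p <- perm_pvalue(sum(stats >= r_obs - 1e-12), n_perm)
    n_used <- n_perm
  }
  structure(
    list(statistic = r_obs, p.value = p, n_perm = n_used, exact = exact,
         method = "ANOSIM", seed = seed),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4f, p = %.4g (%s, %d %s)\n",
              x$method, x$statistic, x$p.value,
              if (isTRUE(x$exact)) "exact" else "permutation",
              x$n_perm,
              if (isTRUE(x$exact)) "assignments" else "permutations"))
  invisible(x)
}

#' @rdname anosim_test
#' @param x A `perm_test` object.
#' @param ... Unused.
#' @export
glance.perm_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p.value, n_perm = x$n_perm,
         exact = isTRUE(x$exact), method = x$method)
}

#' @rdname anosim_test
#' @export
tidy.perm_test <- function(x, ...) glance.perm_test(x, ...)
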