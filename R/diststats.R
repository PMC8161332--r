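# Distance-matrix statistics: great-circle distances, Mantel and partial
# Mantel correlations, and multiple regression on distance matrices (MRM),
# all with joint row/column matrix permutation (triangle entries are never
# permuted independently).

#' Great-circle distance matrix between samples
#'
#' Haversine distances in kilometres (Earth radius 6371.0 km) from WGS84
#' decimal-degree coordinates.
#'
#' @param coords A tibble with `lat`, `lon`, and an id column (`sample_id`
#'   or `station`; the first one found labels the matrix).
#' @return A `dist` of distances in km.
#' @export
geo_distance <- function(coords) {
  coords <- as_tibble(coords)
  if (!all(c("lat", "lon") %in% names(coords))) {
    abort("`coords` needs `lat` and `lon` columns.")
  }
  if (any(abs(coords$lat) > 90) || any(abs(coords$lon) > 180)) {
    abort("Coordinates out of range: |lat| <= 90, |lon| <= 180.")
  }
  idcol <- intersect(c("sample_id", "station"), names(coords))[1]
  labels <- if (!is.na(idcol)) as.character(coords[[idcol]]) else
    as.character(seq_len(nrow(coords)))
  n <- nrow(coords)
  p <- cbind(coords$lon, coords$lat)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    d <- geosphere::distHaversine(p[i, , drop = FALSE], p[j, , drop = FALSE],
                                  r = 6371000) / 1000
    m[i, j] <- m[j, i] <- d
  }
  as.dist(m)
}

#' Mantel and partial Mantel tests
#'
#' Correlates the lower triangles of two distance matrices; the partial
#' variant (with `partial`) computes the first-order partial correlation,
#' equivalent to correlating the residuals of both matrices after
#' regressing each on the control matrix. Significance comes from jointly
#' permuting rows and columns of `d1` (one-sided, `r >= r_obs`, add-one
#' estimator), or from exhaustive enumeration of all `n!` permutations when
#' `exact = TRUE`.
#'
#' @param d1,d2 `dist` objects (or symmetric matrices) on the same samples;
#'   when both carry labels they are aligned by label.
#' @param partial Optional third `dist` to control for.
#' @param method `"pearson"` (default) or `"spearman"` (triangles are
#'   ranked before correlating).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @param exact Exhaustive enumeration over all permutations (n <= 8).
#' @return A `perm_test` object.
#' @export
mantel_test <- function(d1, d2, partial = NULL,
                        method = c("pearson", "spearman"),
                        n_perm = 999, seed = NULL, exact = FALSE) {
  method <- match.arg(method)
  d1 <- as_dist_checked(d1, arg = "d1")
  labels <- attr(d1, "Labels")
  d2 <- as_dist_checked(d2, labels = labels, arg = "d2")
  if (!is.null(partial)) partial <- as_dist_checked(partial, labels = labels,
                                                    arg = "partial")
  n <- attr(d1, "Size")
  if (n < 4) abort("Mantel tests need at least 4 samples.")
  v2 <- as.vector(d2)
  vz <- if (!is.null(partial)) as.vector(partial) else NULL
  if (method == "spearman") {
    v2 <- rank(v2)
    if (!is.null(vz)) vz <- rank(vz)
  }
  r23 <- if (!is.null(vz)) cor(v2, vz) else NULL
  # First-order partial correlation (equivalent to correlating the residuals
  # of both matrices on the control); degenerate controls (|r| = 1 with
  # either matrix) yield 0 by convention.
  stat_for <- function(d1p) {
    v1 <- as.vector(d1p)
    if (method == "spearman") v1 <- rank(v1)
    if (is.null(vz)) return(cor(v1, v2))
    r12 <- cor(v1, v2)
    r13 <- cor(v1, vz)
    den <- sqrt((1 - r13^2) * (1 - r23^2))
    if (!is.finite(den) || den < 1e-12) return(0)
    (r12 - r13 * r23) / den
  }
  r_obs <- stat_for(d1)
  if (exact) {
    perms <- all_permutations(n)
    stats <- apply(perms, 1, function(pp) stat_for(permute_dist(d1, pp)))
    p <- mean(stats >= r_obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    stats <- with_seed_if(seed, {
      vapply(seq_len(n_perm), function(i) {
        stat_for(permute_dist(d1, sample.int(n)))
      }, numeric(1))
    })
    p <- perm_pvalue(sum(stats >= r_obs - 1e-12), n_perm)
    n_used <- n_perm
  }
  structure(
    list(statistic = r_obs, p.value = p, n_perm = n_used, exact = exact,
         method = if (is.null(partial)) "Mantel" else "partial Mantel",
         seed = seed),
    class = "perm_test"
  )
}

#' Multiple regression on distance matrices (MRM)
#'
#' Ordinary least squares of the response matrix's lower triangle on the
#' lower triangles of the predictor matrices. Per-coefficient significance
#' comes from jointly permuting rows and columns of the response matrix and
#' comparing absolute coefficients; the R-squared p-value counts
#' permutations with `R^2 >= obs`.
#'
#' @param response A `dist` (or symmetric matrix).
#' @param predictors A named list of `dist` objects aligned with the
#'   response.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return An `mrm_fit` object: `$coefficients` tibble (`term`, `estimate`,
#'   `p`), `r_squared`, `p_r_squared`, `n_perm`.
#' @export
mrm <- function(response, predictors, n_perm = 999, seed = NULL) {
  response <- as_dist_checked(response, arg = "response")
  labels <- attr(response, "Labels")
  if (is.null(names(predictors)) || any(names(predictors) == "")) {
    abort("`predictors` must be a named list.")
  }
  xs <- map(predictors, as_dist_checked, labels = labels, arg = "predictor")
  xmat <- cbind(1, do.call(cbind, map(xs, as.vector)))
  colnames(xmat) <- c("(Intercept)", names(predictors))
  # collinearity check on standardized predictors so measurement units do
  # not masquerade as rank deficiency
  xstd <- scale(xmat[, -1, drop = FALSE])
  if (any(!is.finite(xstd)) || kappa(crossprod(cbind(1, xstd))) > 1e8) {
    abort("Predictor matrices are collinear on the lower triangle.")
  }
  fit_for <- function(y) {
    fit <- stats::lm.fit(xmat, y)
    b <- fit$coefficients
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    list(b = b, r2 = r2)
  }
  y_obs <- as.vector(response)
  obs <- fit_for(y_obs)
  n <- attr(response, "Size")
  n_ge_b <- numeric(length(obs$b))
  n_ge_r2 <- 0
  with_seed_if(seed, {
    for (i in seq_len(n_perm)) {
      yp <- as.vector(permute_dist(response, sample.int(n)))
      f <- fit_for(yp)
      n_ge_b <- n_ge_b + (abs(f$b) >= abs(obs$b) - 1e-12)
      n_ge_r2 <- n_ge_r2 + (f$r2 >= obs$r2 - 1e-12)
    }
  })
  coefs <- tibble(
    term = colnames(xmat),
    estimate = unname(obs$b),
    p = perm_pvalue(n_ge_b, n_perm)
  )
  structure(
    list(coefficients = coefs, r_squared = obs$r2,
         p_r_squared = perm_pvalue(n_ge_r2, n_perm),
         n_perm = n_perm, seed = seed),
    class = "mrm_fit"
  )
}

#' @export
print.mrm_fit <- function(x, ...) {
  cat(sprintf("<mrm_fit> R-squared = %.4f (p = %.4g, %d permutations)\n",
              x$r_squared, x$p_r_squared, x$n_perm))
  print(x$coefficients)
  invisible(x)
}

#' @rdname mrm
#' @param x An `mrm_fit` object.
#' @param ... Unused.
#' @export
tidy.mrm_fit <- function(x, ...) x$coefficients

#' @rdname mrm
#' @export
glance.mrm_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, p = x$p_r_squared, n_perm = x$n_perm)
}
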