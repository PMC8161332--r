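#' Read a CTD cast table
#'
#' Reads a CSV of CTD levels with columns `station`, `lat`, `lon`, `depth_m`,
#' `theta_c`, `salinity_psu`, and optionally `sigma_theta` and `dcm_m`
#' (depth of the deep chlorophyll maximum for the station).
#'
#' @param path Path to the CSV file.
#' @return A tibble, one row per station/depth level.
#' @export
read_ctd <- function(path) {
  ctd <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("station", "depth_m", "theta_c", "salinity_psu")
  missing <- setdiff(required, names(ctd))
  if (length(missing)) {
    abort(paste0("CTD table is missing columns: ", paste(missing, collapse = ", ")))
  }
  ctd
}

#' Build a monotone isopycnal lookup table for an end-member profile
#'
#' Converts one station's CTD cast into a strictly increasing
#' \eqn{\sigma_\theta \to (\theta, S)} table for isopycnal interpolation.
#' Levels are walked from the shallowest downward and any level whose density
#' does not exceed the last retained one (a density inversion) is dropped, so
#' the retained nodes are strictly increasing in \eqn{\sigma_\theta}. If the
#' cast lacks a `sigma_theta` column it is computed with
#' [compute_sigma_theta()].
#'
#' @param ctd A CTD tibble (see [read_ctd()]); if several stations are present
#'   use `station` to select one.
#' @param station Optional station id to filter on.
#' @return A tibble of class `endmember_lut` with columns `sigma_theta`,
#'   `theta_c`, `salinity_psu`, `depth_m`, strictly increasing in
#'   `sigma_theta`.
#' @export
build_endmember_lut <- function(ctd, station = NULL) {
  if (!is.null(station)) ctd <- ctd[ctd$station == station, , drop = FALSE]
  if (nrow(ctd) < 2) abort("End-member profile needs at least 2 levels.")
  if (is.unsorted(ctd$depth_m, strictly = TRUE)) {
    ctd <- ctd[order(ctd$depth_m), , drop = FALSE]
    if (anyDuplicated(ctd$depth_m)) abort("Depths must be strictly increasing.")
  }
  if (any(ctd$salinity_psu <= 0)) abort("Salinity must be positive.")
  if (!"sigma_theta" %in% names(ctd) || all(is.na(ctd[["sigma_theta"]]))) {
    ctd$sigma_theta <- compute_sigma_theta(ctd$theta_c, ctd$salinity_psu)
  }
  keep <- logical(nrow(ctd))
  running <- -Inf
  for (i in seq_len(nrow(ctd))) {
    if (ctd$sigma_theta[i] > running) {
      keep[i] <- TRUE
      running <- ctd$sigma_theta[i]
    }
  }
  lut <- tibble(
    sigma_theta = ctd$sigma_theta[keep],
    theta_c = ctd$theta_c[keep],
    salinity_psu = ctd$salinity_psu[keep],
    depth_m = ctd$depth_m[keep]
  )
  if (nrow(lut) < 2) {
    abort("Degenerate end-member profile: fewer than 2 monotone density levels.")
  }
  structure(lut, class = c("endmember_lut", class(lut)),
            station = if (is.null(station)) ctd$station[1] else station)
}

#' Pair the two end-member lookup tables
#'
#' @param kuroshio,scs `endmember_lut` objects (or CTD tibbles, which are
#'   passed through [build_endmember_lut()]) for the boundary-current and
#'   basin end-members.
#' @return An object of class `endmember_pair` with elements `lut_k`, `lut_s`
#'   and the common \eqn{\sigma_\theta} range `sigma_range`.
#' @export
endmember_pair <- function(kuroshio, scs) {
  if (!inherits(kuroshio, "endmember_lut")) kuroshio <- build_endmember_lut(kuroshio)
  if (!inherits(scs, "endmember_lut")) scs <- build_endmember_lut(scs)
  rng <- c(
    max(min(kuroshio$sigma_theta), min(scs$sigma_theta)),
    min(max(kuroshio$sigma_theta), max(scs$sigma_theta))
  )
  if (rng[1] >= rng[2]) {
    abort("End-member profiles share no common sigma-theta interval.")
  }
  structure(list(lut_k = kuroshio, lut_s = scs, sigma_range = rng),
            class = "endmember_pair")
}

#' @export
print.endmember_pair <- function(x, ...) {
  cat(sprintf(
    "<endmember_pair> common sigma-theta range [%.3f, %.3f] kg/m3 (K: %d nodes, S: %d nodes)\n",
    x$sigma_range[1], x$sigma_range[2], nrow(x$lut_k), nrow(x$lut_s)
  ))
  invisible(x)
}

# Linear interpolation of (theta, S) at sigma on one lut; no extrapolation.
interp_lut <- function(lut, sigma) {
  in_range <- sigma >= min(lut$sigma_theta) & sigma <= max(lut$sigma_theta)
  theta <- approx(lut$sigma_theta, lut$theta_c, xout = sigma, rule = 1)$y
  sal <- approx(lut$sigma_theta, lut$salinity_psu, xout = sigma, rule = 1)$y
  list(theta = theta, salinity = sal, in_range = in_range)
}

#' Kuroshio water fraction from the two-end-member isopycnal mixing model
#'
#' For each sample, interpolates both end-member tracers at the sample's
#' \eqn{\sigma_\theta} and solves the conservative mixing law
#' \eqn{R_K = (S - S_S) / (S_K - S_S)} (salinity tracer) or the analogous
#' expression in potential temperature. Salinity is the default tracer for
#' depths at or above `switch_depth_m` (100 m), because upper-ocean potential
#' temperature is perturbed by seasonal heat flux; potential temperature is
#' used below. Raw fractions outside \[0, 1\] (measurement noise) are clamped
#' and flagged.
#'
#' @param samples A tibble with columns `depth_m`, `theta_c`, `salinity_psu`
#'   and optionally `sigma_theta` (computed via EOS-80 when absent). Other
#'   columns (station ids, coordinates, ...) are carried through.
#' @param endmembers An [endmember_pair()].
#' @param switch_depth_m Depth (m) at and above which salinity is the tracer;
#'   potential temperature is used below. Default 100.
#' @param sep_tol Minimum end-member tracer separation on the isopycnal;
#'   smaller separations make the mixing fraction indeterminate and raise an
#'   error. Default 0.01.
#' @param clamp Clamp raw fractions into \[0, 1\] (flagged in `clamped`).
#' @return The input tibble with added columns `sigma_theta`, `tracer_used`,
#'   `r_k_raw`, `r_k`, `clamped`.
#' @export
kuroshio_fraction <- function(samples, endmembers, switch_depth_m = 100,
                              sep_tol = 0.01, clamp = TRUE) {
  stopifnot(inherits(endmembers, "endmember_pair"))
  samples <- as_tibble(samples)
  required <- c("depth_m", "theta_c", "salinity_psu")
  missing <- setdiff(required, names(samples))
  if (length(missing)) {
    abort(paste0("`samples` is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (!"sigma_theta" %in% names(samples) || all(is.na(samples[["sigma_theta"]]))) {
    samples$sigma_theta <- compute_sigma_theta(samples$theta_c, samples$salinity_psu)
  }
  k <- interp_lut(endmembers$lut_k, samples$sigma_theta)
  s <- interp_lut(endmembers$lut_s, samples$sigma_theta)
  out_of_range <- !(k$in_range & s$in_range)
  if (any(out_of_range)) {
    abort(sprintf(
      "%d sample(s) have sigma-theta outside the common end-member range [%.3f, %.3f]; the mixing model is undefined there.",
      sum(out_of_range), endmembers$sigma_range[1], endmembers$sigma_range[2]
    ))
  }
  use_s <- samples$depth_m <= switch_depth_m
  x <- ifelse(use_s, samples$salinity_psu, samples$theta_c)
  x_k <- ifelse(use_s, k$salinity, k$theta)
  x_s <- ifelse(use_s, s$salinity, s$theta)
  denom <- x_k - x_s
  if (any(abs(denom) < sep_tol)) {
    abort(sprintf(
      "End-member tracer separation below %g on %d isopycnal(s): fraction indeterminate.",
      sep_tol, sum(abs(denom) < sep_tol)
    ))
  }
  raw <- (x - x_s) / denom
  samples$tracer_used <- ifelse(use_s, "S", "theta")
  samples$r_k_raw <- raw
  if (clamp) {
    samples$r_k <- pmin(1, pmax(0, raw))
    samples$clamped <- raw < 0 | raw > 1
  } else {
    samples$r_k <- raw
    samples$clamped <- FALSE
  }
  samples
}

#' Classify stations into more and less current-influenced provinces
#'
#' Averages per-sample Kuroshio fractions over the levels at or above each
#' station's deep chlorophyll maximum and labels the station `"more"` when the
#' mean fraction strictly exceeds `threshold` (default 0.30), `"less"`
#' otherwise. Stations without any level at or above the DCM are dropped with
#' a warning.
#'
#' @param rk A tibble from [kuroshio_fraction()]; must contain `station`,
#'   `depth_m`, `r_k` and a DCM depth column `dcm_m` (per row).
#' @param threshold Province threshold on the station mean fraction; the
#'   comparison is strict (`> threshold` means "more influenced").
#' @param weighting `"mean"` (unweighted arithmetic mean over sampled levels,
#'   the default) or `"trapezoid"` (depth-weighted trapezoidal average).
#' @return An object of class `watermass` holding `per_sample` and
#'   `per_station` tibbles plus the threshold used.
#' @export
classify_stations <- function(rk, threshold = 0.30,
                              weighting = c("mean", "trapezoid")) {
  weighting <- match.arg(weighting)
  required <- c("station", "depth_m", "r_k", "dcm_m")
  missing <- setdiff(required, names(rk))
  if (length(missing)) {
    abort(paste0("`rk` is missing columns: ", paste(missing, collapse = ", ")))
  }
  stopifnot(threshold >= 0, threshold <= 1)
  above <- rk[rk$depth_m <= rk$dcm_m, , drop = FALSE]
  dropped <- setdiff(unique(rk$station), unique(above$station))
  if (length(dropped)) {
    warn(paste0("Stations without samples above the DCM were excluded: ",
                paste(dropped, collapse = ", ")))
  }
  station_mean <- function(depth, r_k) {
    if (weighting == "mean" || length(depth) < 2) return(mean(r_k))
    ord <- order(depth)
    depth <- depth[ord]; r_k <- r_k[ord]
    w <- diff(depth)
    sum(w * (head(r_k, -1) + r_k[-1]) / 2) / sum(w)
  }
  per_station <- above |>
    group_by(.data$station) |>
    summarise(
      mean_rk_above_dcm = station_mean(.data$depth_m, .data$r_k),
      n_levels = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(province = ifelse(.data$mean_rk_above_dcm > threshold, "more", "less"))
  structure(
    list(per_sample = as_tibble(rk), per_station = per_station,
         threshold = threshold, weighting = weighting),
    class = "watermass"
  )
}

#' @export
print.watermass <- function(x, ...) {
  n_more <- sum(x$per_station$province == "more")
  cat(sprintf(
    "<watermass> %d samples, %d stations (%d more / %d less influenced at R_K > %.2f)\n",
    nrow(x$per_sample), nrow(x$per_station), n_more,
    nrow(x$per_station) - n_more, x$threshold
  ))
  cat(sprintf("  station mean R_K above DCM: %.3f - %.3f\n",
              min(x$per_station$mean_rk_above_dcm),
              max(x$per_station$mean_rk_above_dcm)))
  invisible(x)
}

#' @rdname classify_stations
#' @param x A `watermass` object.
#' @param which `"stations"` (default) or `"samples"`.
#' @param ... Unused.
#' @export
tidy.watermass <- function(x, which = c("stations", "samples"), ...) {
  which <- match.arg(which)
  if (which == "stations") x$per_station else as_tibble(x$per_sample)
}

#' @rdname classify_stations
#' @export
glance.watermass <- function(x, ...) {
  tibble(
    n_samples = nrow(x$per_sample),
    n_stations = nrow(x$per_station),
    n_more = sum(x$per_station$province == "more"),
    n_less = sum(x$per_station$province == "less"),
    rk_min = min(x$per_station$mean_rk_above_dcm),
    rk_max = max(x$per_station$mean_rk_above_dcm),
    threshold = x$threshold
  )
}

#' @export
autoplot.watermass <- function(object, ...) {
  d <- object$per_station |> arrange(.data$mean_rk_above_dcm) |>
    mutate(station = factor(.data$station, levels = .data$station))
  ggplot(d, aes(x = .data$station, y = .data$mean_rk_above_dcm,
                fill = .data$province)) +
    geom_col() +
    geom_hline(yintercept = object$threshold, linetype = 2) +
    labs(x = NULL, y = expression("Mean " * R[K] * " above DCM"),
         fill = "Province") +
    theme_minimal()
}

#' Write per-sample and per-station water-mass results to CSV
#'
#' Writes a single CSV with a `block` column distinguishing per-sample rows
#' from per-station rows.
#'
#' @param x A `watermass` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_watermass <- function(x, path) {
  stopifnot(inherits(x, "watermass"))
  per_sample <- mutate(as_tibble(x$per_sample), block = "sample")
  per_station <- mutate(x$per_station, block = "station")
  out <- bind_rows(per_sample, per_station)
  readr::write_csv(out, path)
  invisible(path)
}
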