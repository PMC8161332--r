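# Synthetic-data generator: hydrography built from two analytic end-member
# profiles with exact isopycnal mixtures, a birth-death phylogeny with
# optionally clade-clustered responders, and an OTU count table whose
# planted winner/loser groups respond log-linearly to the mixing fraction.

#' Simulate hydrography as exact two-end-member isopycnal mixtures
#'
#' Builds two stratified end-member CTD profiles (a warm, salty
#' boundary-current end-member and a cooler, fresher basin end-member) and,
#' for each station, surface and DCM samples whose tracers are exact convex
#' combinations of the two end-members on the sample's isopycnal with a
#' station-specific mixing fraction f. Sample rows carry the nominal
#' `sigma_theta` used for the mixture so the mixing model can be inverted
#' exactly.
#'
#' @param n_stations Number of stations (default 16; surface + DCM per
#'   station gives 2x that many samples).
#' @param f_range Range of the station mixing-fraction gradient (default
#'   `c(0.05, 0.75)`); stations are evenly spaced across it.
#' @param geography `"gradient"` (coordinates track f, the realistic
#'   intrusion pattern) or `"random"` (coordinates independent of f).
#' @param dcm_range Range (m) of the per-station DCM depth.
#' @param seed Integer seed.
#' @return A list with `samples` (tibble of sample rows ready for
#'   [kuroshio_fraction()]), `endmembers` (an [endmember_pair()]),
#'   `endmember_ctd` (the two end-member casts as a CTD tibble) and `truth`
#'   (tibble: `station`, `f`).
#' @export
simulate_hydrography <- function(n_stations = 16, f_range = c(0.05, 0.75),
                                 geography = c("gradient", "random"),
                                 dcm_range = c(40, 70), seed = NULL) {
  geography <- match.arg(geography)
  if (n_stations < 2) abort("Need at least 2 stations.")
  if (any(f_range < 0) || any(f_range > 1)) abort("`f_range` must lie in [0, 1].")
  z <- seq(0, 300, by = 10)
  em_k <- tibble(
    station = "EM_K", lat = 22.243, lon = 123.211, depth_m = z,
    theta_c = 29.5 - 0.062 * z, salinity_psu = 34.55 - 0.0008 * z
  )
  em_s <- tibble(
    station = "EM_S", lat = 15.233, lon = 114.888, depth_m = z,
    theta_c = 30.0 - 0.070 * z, salinity_psu = 33.20 + 0.0030 * z
  )
  em_k$sigma_theta <- compute_sigma_theta(em_k$theta_c, em_k$salinity_psu)
  em_s$sigma_theta <- compute_sigma_theta(em_s$theta_c, em_s$salinity_psu)
  pair <- endmember_pair(build_endmember_lut(em_k), build_endmember_lut(em_s))
  f <- seq(f_range[1], f_range[2], length.out = n_stations)
  stations <- sprintf("S%02d", seq_len(n_stations))
  samples <- with_seed_if(seed, {
    dcm <- runif(n_stations, dcm_range[1], dcm_range[2])
    sig_surf <- runif(n_stations, pair$sigma_range[1] + 0.2,
                      pair$sigma_range[1] + 0.6)
    sig_dcm <- runif(n_stations, 23.5, 24.5)
    if (geography == "gradient") {
      lon <- 115 + 8 * f + rnorm(n_stations, 0, 0.3)
      lat <- 15.5 + 6.5 * f + rnorm(n_stations, 0, 0.3)
    } else {
      lon <- runif(n_stations, 115, 123)
      lat <- runif(n_stations, 15, 22)
    }
    rows <- map(seq_len(n_stations), function(i) {
      sig <- c(sig_surf[i], sig_dcm[i])
      k <- interp_lut(pair$lut_k, sig)
      s <- interp_lut(pair$lut_s, sig)
      tibble(
        station = stations[i],
        layer = c("surface", "DCM"),
        depth_m = c(5, dcm[i]),
        dcm_m = dcm[i],
        lat = lat[i], lon = lon[i],
        sigma_theta = sig,
        theta_c = f[i] * k$theta + (1 - f[i]) * s$theta,
        salinity_psu = f[i] * k$salinity + (1 - f[i]) * s$salinity
      )
    })
    bind_rows(rows)
  })
  samples <- samples |>
    mutate(sample_id = paste(.data$station, .data$layer, sep = "_"),
           .before = 1)
  list(
    samples = samples,
    endmembers = pair,
    endmember_ctd = bind_rows(em_k, em_s),
    truth = tibble(station = stations, f = f)
  )
}

#' Simulate a phylogeny with optionally clade-clustered responders
#'
#' Draws a pure-birth (Yule) tree and selects the planted winner and loser
#' OTU sets. With `clustered_responders = TRUE` each role is drawn from a
#' single clade (disjoint between roles), so habitat filtering along the
#' gradient carries a recoverable phylogenetic signal; otherwise roles are
#' random tips.
#'
#' @param n_otus Number of tips (default 800).
#' @param n_winners,n_losers Planted responder counts (defaults 20 each).
#' @param clustered_responders Draw responders as clades (default `TRUE`).
#' @param seed Integer seed.
#' @return A list with `tree` (a rooted `phylo` with tips `OTU0001`, ...),
#'   `winners`, `losers` (tip label vectors).
#' @export
simulate_tree <- function(n_otus = 800, n_winners = 20, n_losers = 20,
                          clustered_responders = TRUE, seed = NULL) {
  if (n_otus < 4) abort("Need at least 4 OTUs.")
  if (n_winners + n_losers >= n_otus) abort("Too many planted responders.")
  with_seed_if(seed, {
    tree <- ape::rphylo(n_otus, birth = 1, death = 0)
    tree$tip.label <- sprintf("OTU%04d", seq_len(n_otus))
    if (clustered_responders) {
      clades <- ape::prop.part(tree)
      labs <- attr(clades, "labels")
      sizes <- lengths(clades)
      pick_clade <- function(n_role, taken) {
        ok <- which(sizes >= n_role & sizes <= max(4 * n_role, n_role + 4) &
                      vapply(clades, function(cl) !any(labs[cl] %in% taken),
                             logical(1)))
        if (!length(ok)) return(NULL)
        best <- ok[which.min(sizes[ok])]
        labs[clades[[best]]][seq_len(n_role)]
      }
      winners <- pick_clade(n_winners, character(0))
      losers <- pick_clade(n_losers, winners)
      if (is.null(winners) || is.null(losers)) {
        warn("No suitable disjoint clades found; falling back to random tips.")
        picked <- sample(tree$tip.label, n_winners + n_losers)
        winners <- picked[seq_len(n_winners)]
        losers <- picked[n_winners + seq_len(n_losers)]
      }
    } else {
      picked <- sample(tree$tip.label, n_winners + n_losers)
      winners <- picked[seq_len(n_winners)]
      losers <- picked[n_winners + seq_len(n_losers)]
    }
    list(tree = tree, winners = winners, losers = losers)
  })
}

#' Simulate an OTU count table along the mixing-fraction gradient
#'
#' Expected relative abundances start from a lognormal baseline. Winner
#' OTUs are multiplied by \eqn{2^{e \cdot g(f_s)}} and losers by
#' \eqn{2^{-e \cdot g(f_s)}}, where \eqn{e} is `effect_log2fc` and
#' \eqn{g(f) = (f - \bar f) / (\bar f_{more} - \bar f_{less})} centres and
#' scales the station fraction so that the realized log2 fold change between
#' the more- and less-influenced provinces equals `effect_log2fc` while the
#' response stays linear in f (both the two-group tests and the
#' gradient regression see signal). Winners and losers form two latent
#' blocks sharing a per-sample lognormal factor (sd `block_sd`), which
#' induces the co-occurrence module structure; every OTU gets independent
#' lognormal noise (sd `noise_sd`). Counts are multinomial draws at a
#' Poisson-distributed depth around `depth_mean`.
#'
#' @param hydro Output of [simulate_hydrography()].
#' @param tree_roles Output of [simulate_tree()] (tree + winner/loser sets).
#' @param depth_mean Mean sequencing depth per sample (default 7493).
#' @param effect_log2fc Planted cross-province log2 fold change (default
#'   1.5). Zero plants no signal.
#' @param block_sd Sd of the shared per-sample block factor (log scale,
#'   default 0.40, commensurate with the gradient-driven covariance so
#'   module membership carries signal beyond the gradient itself). Zero
#'   removes module structure.
#' @param noise_sd Sd of per-OTU-per-sample lognormal noise (default 0.15).
#' @param planted_mean_reads Target expected reads per sample for each
#'   planted OTU (default 30; sets the planted baseline abundances).
#' @param base_sdlog Lognormal sd of the neutral baseline abundances
#'   (default 1.5).
#' @param seed Integer seed.
#' @return A list with `table` (an [otu_table()]) and `truth` (list:
#'   station fractions, per-OTU roles and blocks, effect, scaling, seed).
#' @export
simulate_community <- function(hydro, tree_roles, depth_mean = 7493,
                               effect_log2fc = 1.5, block_sd = 0.40,
                               noise_sd = 0.15, planted_mean_reads = 30,
                               base_sdlog = 1.5, seed = NULL) {
  if (depth_mean <= 0) abort("`depth_mean` must be positive.")
  tree <- tree_roles$tree
  winners <- tree_roles$winners
  losers <- tree_roles$losers
  otus <- tree$tip.label
  n_otu <- length(otus)
  samples <- hydro$samples
  f_station <- setNames(hydro$truth$f, hydro$truth$station)
  f_s <- f_station[samples$station]
  n_samp <- nrow(samples)
  role <- setNames(rep(0, n_otu), otus)
  role[winners] <- 1
  role[losers] <- -1
  block <- setNames(rep(NA_integer_, n_otu), otus)
  block[winners] <- 1L
  block[losers] <- 2L
  more <- f_station > 0.3
  scale_f <- if (any(more) && any(!more)) {
    1 / (mean(f_station[more]) - mean(f_station[!more]))
  } else {
    1 / diff(range(f_station))
  }
  g <- (f_s - mean(f_station)) * scale_f
  with_seed_if(seed, {
    base <- rlnorm(n_otu, meanlog = 0, sdlog = base_sdlog)
    names(base) <- otus
    planted <- c(winners, losers)
    q <- planted_mean_reads / depth_mean
    neutral_total <- sum(base[setdiff(otus, planted)])
    base[planted] <- q * neutral_total / (1 - length(planted) * q) *
      rlnorm(length(planted), 0, 0.2)
    u1 <- rnorm(n_samp, 0, block_sd)
    u2 <- rnorm(n_samp, 0, block_sd)
    eps <- matrix(rnorm(n_otu * n_samp, 0, noise_sd), n_otu, n_samp)
    counts <- matrix(0L, n_otu, n_samp,
                     dimnames = list(otus, samples$sample_id))
    for (j in seq_len(n_samp)) {
      logw <- log(base) + role * g[j] * effect_log2fc * log(2) + eps[, j]
      logw[!is.na(block) & block == 1L] <-
        logw[!is.na(block) & block == 1L] + u1[j]
      logw[!is.na(block) & block == 2L] <-
        logw[!is.na(block) & block == 2L] + u2[j]
      w <- exp(logw - max(logw))
      depth_j <- rpois(1, depth_mean)
      counts[, j] <- as.integer(rmultinom(1, depth_j, prob = w))
    }
    meta <- samples |>
      select("sample_id", "station", "layer", "lat", "lon")
    truth <- list(
      f_by_station = hydro$truth,
      otu_roles = tibble(otu_id = otus, role = unname(role),
                         block = unname(block)),
      winners = winners, losers = losers,
      effect_log2fc = effect_log2fc, f_scale = scale_f,
      block_sd = block_sd, noise_sd = noise_sd,
      depth_mean = depth_mean, seed = seed
    )
    list(table = otu_table(counts, meta), truth = truth)
  })
}

#' Simulate a complete synthetic study
#'
#' Orchestrates [simulate_hydrography()], [simulate_tree()] and
#' [simulate_community()] with seeds derived from one master seed.
#'
#' @inheritParams simulate_hydrography
#' @inheritParams simulate_tree
#' @inheritParams simulate_community
#' @param seed Master integer seed.
#' @return A list with `hydro`, `tree`, `winners`, `losers`, `table`,
#'   `truth`.
#' @export
simulate_dataset <- function(n_stations = 16, n_otus = 800, n_winners = 20,
                             n_losers = 20, depth_mean = 7493,
                             effect_log2fc = 1.5, f_range = c(0.05, 0.75),
                             geography = "gradient",
                             clustered_responders = TRUE, block_sd = 0.40,
                             noise_sd = 0.15, planted_mean_reads = 30,
                             seed = NULL) {
  hydro <- simulate_hydrography(n_stations = n_stations, f_range = f_range,
                                geography = geography,
                                seed = derive_seed(seed, 1L))
  tr <- simulate_tree(n_otus = n_otus, n_winners = n_winners,
                      n_losers = n_losers,
                      clustered_responders = clustered_responders,
                      seed = derive_seed(seed, 2L))
  com <- simulate_community(hydro, tr, depth_mean = depth_mean,
                            effect_log2fc = effect_log2fc,
                            block_sd = block_sd, noise_sd = noise_sd,
                            planted_mean_reads = planted_mean_reads,
                            seed = derive_seed(seed, 3L))
  list(hydro = hydro, tree = tr$tree, winners = tr$winners,
       losers = tr$losers, table = com$table, truth = com$truth)
}

#' Write the synthetic ground truth as JSON
#'
#' @param truth The `truth` element of [simulate_community()] /
#'   [simulate_dataset()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(
      f_by_station = truth$f_by_station,
      otu_roles = truth$otu_roles[truth$otu_roles$role != 0, ],
      effect_log2fc = truth$effect_log2fc,
      f_scale = truth$f_scale,
      depth_mean = truth$depth_mean,
      seed = truth$seed
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
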