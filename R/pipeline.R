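# End-to-end orchestration: configuration, stage sequencing, artifact I/O
# and the run manifest. Stages are the exported module functions; this file
# only wires them together.

#' Default run configuration
#'
#' All analysis thresholds default to the study's printed values: province
#' threshold 0.30 on the mean Kuroshio fraction above the DCM, rarefaction
#' to the minimum sample depth, null-model deviates 999, permutations 999,
#' network thresholds |rho| > 0.6 and q < 0.01 with prevalence filters (20%
#' of samples, 32 reads), indicator thresholds IV > 0.5 and p < 0.05, and
#' FDR threshold q < 0.05.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    # input paths (NULL = simulate a synthetic study instead)
    ctd_path = NULL, otu_path = NULL, meta_path = NULL, tree_path = NULL,
    endmember_stations = c("EM_K", "EM_S"),
    # synthetic-study design
    n_stations = 16, n_otus = 800, n_winners = 20, n_losers = 20,
    depth_mean = 7493, effect_log2fc = 1.5, f_range = c(0.05, 0.75),
    # analysis parameters
    rk_threshold = 0.30, switch_depth_m = 100,
    rarefy_depth = NULL, n_null = 999, n_perm = 999,
    rho_thresh = 0.6, network_q_thresh = 0.01,
    min_prevalence = 0.20, min_total_reads = 32,
    iv_thresh = 0.5, indicator_p_thresh = 0.05, fdr_thresh = 0.05,
    seed = 1L
  )
  modifyList(cfg, list(...))
}

#' Read a YAML run configuration
#'
#' Keys mirror [default_config()]; unspecified keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  do.call(default_config, user)
}

write_dist_csv <- function(d, path) {
  m <- as.matrix(d)
  out <- bind_cols(tibble(sample_id = rownames(m)), as_tibble(m))
  readr::write_csv(out, path)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: hydrography (water-mass fractions and provinces),
#' beta-diversity (rarefaction, Bray-Curtis, PCoA, UPGMA, ANOSIM between
#' provinces), assembly null models (betaNTI, Raup-Crick, process
#' fractions), sensitive-OTU identification (indicator + NB-LRT
#' intersection), the co-occurrence network with modules and module
#' regressions on R_K, and distance-matrix statistics (Mantel, partial
#' Mantel, MRM). Writes every artifact into `out_dir` together with a
#' manifest recording the configuration and seed. With no input paths in
#' the configuration a synthetic study with known truth is generated and a
#' recovery report (planted-responder precision/recall, module agreement)
#' is included.
#'
#' @param config A configuration list from [default_config()] /
#'   [read_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with every stage result (`watermass`, `beta`,
#'   `assembly`, `sensitive`, `network`, `diststats`, `recovery`, paths).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("kuromix_run_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage=%s error=%s", name, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      abort(sprintf("[%s] %s", name, conditionMessage(e)))
    })
  }

  # --- inputs -------------------------------------------------------------
  truth <- NULL
  sim <- NULL
  if (is.null(config$otu_path)) {
    sim <- stage("simulate", simulate_dataset(
      n_stations = config$n_stations, n_otus = config$n_otus,
      n_winners = config$n_winners, n_losers = config$n_losers,
      depth_mean = config$depth_mean, effect_log2fc = config$effect_log2fc,
      f_range = config$f_range, seed = seed
    ))
    samples <- sim$hydro$samples
    endmembers <- sim$hydro$endmembers
    tab <- sim$table
    tree <- sim$tree
    truth <- sim$truth
    write_truth(truth, file.path(out_dir, "truth.json"))
    write_otu_table(tab, file.path(out_dir, "otu_table.tsv"),
                    file.path(out_dir, "sample_meta.csv"))
    ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
    readr::write_csv(samples, file.path(out_dir, "ctd_samples.csv"))
  } else {
    ctd <- stage("inputs", read_ctd(config$ctd_path))
    endmembers <- stage("inputs", endmember_pair(
      build_endmember_lut(ctd, config$endmember_stations[1]),
      build_endmember_lut(ctd, config$endmember_stations[2])
    ))
    samples <- ctd[!ctd$station %in% config$endmember_stations, , drop = FALSE]
    tab <- stage("inputs", read_otu_table(config$otu_path, config$meta_path))
    tree <- if (!is.null(config$tree_path)) ape::read.tree(config$tree_path)
  }

  # --- hydrography --------------------------------------------------------
  wm <- stage("watermass", {
    rk <- kuroshio_fraction(samples, endmembers,
                            switch_depth_m = config$switch_depth_m)
    classify_stations(rk, threshold = config$rk_threshold)
  })
  write_watermass(wm, file.path(out_dir, "watermass.csv"))
  province <- setNames(wm$per_station$province, wm$per_station$station)
  rk_sample <- tibble(
    sample_id = wm$per_sample$sample_id %||% wm$per_sample$station,
    r_k = wm$per_sample$r_k
  )

  # --- beta-diversity -----------------------------------------------------
  beta <- stage("beta", {
    rar <- rarefy(tab, depth = config$rarefy_depth,
                  seed = derive_seed(seed, 10L))
    d <- bray_curtis(rar)
    groups <- province[rar$meta$station]
    ord <- pcoa_ord(d)
    dend <- upgma(d)
    an <- anosim_test(d, groups, n_perm = config$n_perm,
                      seed = derive_seed(seed, 11L))
    list(rarefied = rar, bray = d, groups = groups, pcoa = ord,
         upgma = dend, anosim = an)
  })
  write_dist_csv(beta$bray, file.path(out_dir, "bray_curtis.csv"))
  readr::write_csv(beta$pcoa$points, file.path(out_dir, "pcoa.csv"))
  ape::write.tree(beta$upgma, file.path(out_dir, "upgma.nwk"))
  jsonlite::write_json(
    list(R = beta$anosim$statistic, p = beta$anosim$p.value,
         n_perm = beta$anosim$n_perm, seed = seed),
    file.path(out_dir, "anosim.json"), auto_unbox = TRUE, digits = NA
  )

  # --- assembly null models ----------------------------------------------
  assembly <- if (!is.null(tree)) {
    stage("assembly", quantify_assembly(
      beta$rarefied, tree, n_null = config$n_null,
      seed = derive_seed(seed, 20L)
    ))
  }
  if (!is.null(assembly)) {
    write_dist_csv(assembly$bnti$beta_nti, file.path(out_dir, "beta_nti.csv"))
    write_dist_csv(assembly$rc, file.path(out_dir, "rc_bray.csv"))
    jsonlite::write_json(
      c(setNames(as.list(assembly$processes$fraction),
                 assembly$processes$process),
        list(n_pairs = attr(assembly$processes, "n_pairs_total"),
             n_null = config$n_null, seed = seed)),
      file.path(out_dir, "assembly.json"), auto_unbox = TRUE, digits = NA
    )
  }

  # --- sensitive OTUs -----------------------------------------------------
  sens <- stage("sensitive", {
    groups <- factor(province[tab$meta$station], levels = c("less", "more"))
    ind <- indicator_stat(beta$rarefied, province[beta$rarefied$meta$station],
                          n_perm = config$n_perm,
                          seed = derive_seed(seed, 30L))
    nb <- nb_glm_lrt(tab, groups)
    define_sensitive(ind, nb, tab, iv_thresh = config$iv_thresh,
                     p_thresh = config$indicator_p_thresh,
                     q_thresh = config$fdr_thresh, enriched_level = "more")
  })
  readr::write_csv(sens$otus, file.path(out_dir, "sensitive_otus.csv"))

  # --- co-occurrence network ---------------------------------------------
  net <- stage("network", {
    filt <- prevalence_filter(beta$rarefied,
                              min_prevalence = config$min_prevalence,
                              min_total_reads = config$min_total_reads)
    n <- build_network(filt, rho_thresh = config$rho_thresh,
                       q_thresh = config$network_q_thresh)
    detect_modules(n, seed = derive_seed(seed, 40L))
  })
  modsum <- stage("network", module_summary(net, beta$rarefied, rk_sample,
                                            sensitive = sens))
  write_network(net, file.path(out_dir, "network_edges.csv"),
                file.path(out_dir, "network_nodes.csv"),
                file.path(out_dir, "network.graphml"))
  readr::write_csv(modsum$modules, file.path(out_dir, "modules.csv"))

  # --- distance statistics ------------------------------------------------
  diststats <- stage("diststats", {
    meta <- beta$rarefied$meta
    geo <- geo_distance(meta)
    drk <- dist(matrix(rk_sample$r_k[match(meta$sample_id,
                                           rk_sample$sample_id)],
                       dimnames = list(meta$sample_id, NULL)))
    m_rk <- mantel_test(beta$bray, drk, n_perm = config$n_perm,
                        seed = derive_seed(seed, 50L))
    m_geo <- mantel_test(beta$bray, geo, n_perm = config$n_perm,
                         seed = derive_seed(seed, 51L))
    pm_rk <- mantel_test(beta$bray, drk, partial = geo,
                         n_perm = config$n_perm,
                         seed = derive_seed(seed, 52L))
    pm_geo <- mantel_test(beta$bray, geo, partial = drk,
                          n_perm = config$n_perm,
                          seed = derive_seed(seed, 53L))
    mr <- mrm(beta$bray, list(geo = geo, delta_rk = drk),
              n_perm = config$n_perm, seed = derive_seed(seed, 54L))
    list(geo = geo, delta_rk = drk, mantel_rk = m_rk, mantel_geo = m_geo,
         partial_rk = pm_rk, partial_geo = pm_geo, mrm = mr)
  })
  jsonlite::write_json(
    list(
      mantel_rk = glance(diststats$mantel_rk),
      mantel_geo = glance(diststats$mantel_geo),
      partial_rk_given_geo = glance(diststats$partial_rk),
      partial_geo_given_rk = glance(diststats$partial_geo),
      mrm = list(coefficients = diststats$mrm$coefficients,
                 r_squared = diststats$mrm$r_squared,
                 p = diststats$mrm$p_r_squared),
      n_perm = config$n_perm, seed = seed
    ),
    file.path(out_dir, "mantel_mrm.json"), auto_unbox = TRUE, digits = NA
  )

  # --- recovery against planted truth ------------------------------------
  recovery <- if (!is.null(truth)) {
    stage("recovery", recovery_report(sens, net, wm, truth))
  }
  if (!is.null(recovery)) {
    jsonlite::write_json(recovery, file.path(out_dir, "recovery.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package = "kuromix",
    package_version = as.character(utils::packageVersion("kuromix")),
    r_version = as.character(getRversion()),
    seed = seed,
    config = config[setdiff(names(config), "seed")],
    artifacts = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(
    watermass = wm, beta = beta, assembly = assembly, sensitive = sens,
    network = net, module_summary = modsum, diststats = diststats,
    recovery = recovery, truth = truth, table = tab, tree = tree,
    out_dir = out_dir
  ))
}

#' Compare pipeline results with the planted truth
#'
#' Precision and recall of the sensitive-OTU intersection against the
#' planted winners/losers, province classification accuracy against the
#' planted fractions, and the adjusted Rand index between detected network
#' modules and the planted winner/loser blocks (over planted OTUs present
#' in the network).
#'
#' @param sens A `sensitive_otus` object.
#' @param net A `co_network` with modules.
#' @param wm A `watermass` object.
#' @param truth The generator truth.
#' @return A list of recovery metrics.
#' @export
recovery_report <- function(sens, net, wm, truth) {
  planted <- c(truth$winners, truth$losers)
  detected <- sens$otus$otu_id[sens$otus$sensitive]
  tp <- length(intersect(detected, planted))
  precision <- if (length(detected)) tp / length(detected) else NA_real_
  recall <- tp / length(planted)
  prov_truth <- ifelse(truth$f_by_station$f > 0.3, "more", "less")
  prov_est <- wm$per_station$province[
    match(truth$f_by_station$station, wm$per_station$station)]
  province_match <- mean(prov_est == prov_truth)
  in_net <- intersect(planted, net$nodes$otu_id[!is.na(net$nodes$module)])
  ari <- if (length(in_net) >= 4 && !is.null(net$nodes$module)) {
    truth_lab <- ifelse(in_net %in% truth$winners, "winner", "loser")
    mod_lab <- net$nodes$module[match(in_net, net$nodes$otu_id)]
    adjusted_rand(truth_lab, mod_lab)
  } else {
    NA_real_
  }
  list(
    n_planted = length(planted), n_detected = length(detected),
    true_positives = tp, precision = precision, recall = recall,
    province_match = province_match, module_ari = ari,
    n_planted_in_network = length(in_net)
  )
}
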