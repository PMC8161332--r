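# Spearman co-occurrence network: prevalence filtering, edge construction
# with FDR control, Louvain modules, and module-level summaries against the
# water-mass gradient.

#' Prevalence/abundance filter before network construction
#'
#' Retains OTUs present (count > 0) in at least `ceiling(min_prevalence *
#' n_samples)` samples and with at least `min_total_reads` reads in total.
#'
#' @param x An [otu_table()] or count matrix.
#' @param min_prevalence Minimum occurrence fraction (default 0.20).
#' @param min_total_reads Minimum total reads across samples (default 32).
#' @return The filtered object (same class as the input).
#' @export
prevalence_filter <- function(x, min_prevalence = 0.20, min_total_reads = 32) {
  counts <- get_counts(x)
  need <- ceiling(min_prevalence * ncol(counts))
  keep <- rowSums(counts > 0) >= need & rowSums(counts) >= min_total_reads
  if (!any(keep)) abort("No OTUs pass the prevalence/abundance filter.")
  if (inherits(x, "otu_table")) {
    otu_table(x$counts[keep, , drop = FALSE], x$meta)
  } else {
    counts[keep, , drop = FALSE]
  }
}

# Exact two-sided Spearman permutation p-value for one pair (small n).
spearman_exact_p <- function(xr, yr) {
  n <- length(xr)
  perms <- all_permutations(n)
  obs <- suppressWarnings(cor(xr, yr))
  stats <- apply(perms, 1, function(pp) suppressWarnings(cor(xr[pp], yr)))
  mean(abs(stats) >= abs(obs) - 1e-12)
}

#' Build a Spearman co-occurrence network
#'
#' Computes Spearman's rank correlation (mid-ranks for ties) between all OTU
#' pairs of a (pre-filtered) table, two-sided p-values by the
#' t-approximation for `n >= 10` samples (exact permutation below that),
#' BH adjustment over all tested pairs, and keeps edges with
#' `|rho| > rho_thresh` and `q < q_thresh`. OTUs with constant counts are
#' kept as nodes but form no edges (their correlations are undefined).
#'
#' @param x A filtered [otu_table()] or count matrix.
#' @param rho_thresh Correlation magnitude threshold (default 0.6).
#' @param q_thresh BH-adjusted p-value threshold (default 0.01).
#' @return An object of class `co_network` with `nodes` (tibble: `otu_id`,
#'   `degree`), `edges` (tibble: `otu_a`, `otu_b`, `rho`, `p`, `q`, `sign`)
#'   and the thresholds used.
#' @export
build_network <- function(x, rho_thresh = 0.6, q_thresh = 0.01) {
  counts <- get_counts(x)
  n_samp <- ncol(counts)
  if (n_samp < 3) abort("Need at least 3 samples.")
  mat <- t(counts)
  constant <- apply(mat, 2, function(v) all(v == v[1]))
  rho <- suppressWarnings(cor(mat, method = "spearman"))
  ids <- colnames(mat)
  idx <- which(lower.tri(rho), arr.ind = TRUE)
  edges <- tibble(
    otu_a = ids[idx[, 2]],
    otu_b = ids[idx[, 1]],
    rho = rho[idx]
  )
  tested <- !(constant[idx[, 1]] | constant[idx[, 2]]) & is.finite(edges$rho)
  edges <- edges[tested, , drop = FALSE]
  if (n_samp >= 10) {
    r <- pmin(pmax(edges$rho, -1), 1)
    tstat <- r * sqrt((n_samp - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n_samp - 2)
    p[abs(r) >= 1 - 1e-12] <- 0
  } else {
    ranks <- apply(mat, 2, rank)
    p <- vapply(seq_len(nrow(edges)), function(e) {
      spearman_exact_p(ranks[, edges$otu_a[e]], ranks[, edges$otu_b[e]])
    }, numeric(1))
  }
  edges$p <- p
  edges$q <- p.adjust(p, method = "BH")
  edges <- edges |>
    filter(abs(.data$rho) > rho_thresh, .data$q < q_thresh) |>
    mutate(sign = ifelse(.data$rho > 0, "positive", "negative"))
  degree <- table(factor(c(edges$otu_a, edges$otu_b), levels = ids))
  nodes <- tibble(otu_id = ids, degree = as.integer(degree))
  structure(
    list(nodes = nodes, edges = edges, n_samples = n_samp,
         rho_thresh = rho_thresh, q_thresh = q_thresh),
    class = "co_network"
  )
}

#' @export
print.co_network <- function(x, ...) {
  cat(sprintf(
    "<co_network> %d nodes, %d edges (%d positive / %d negative), |rho| > %.2f & q < %.2g\n",
    nrow(x$nodes), nrow(x$edges),
    sum(x$edges$sign == "positive"), sum(x$edges$sign == "negative"),
    x$rho_thresh, x$q_thresh
  ))
  if (!is.null(x$nodes$module)) {
    cat(sprintf("  %d modules (modularity %.3f)\n",
                length(unique(x$nodes$module)), attr(x, "modularity")))
  }
  invisible(x)
}

#' Convert a co-occurrence network to igraph
#'
#' Edge weights are |rho|; the signed correlation is kept as an edge
#' attribute.
#'
#' @param net A `co_network`.
#' @return An `igraph` graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "co_network"))
  g <- igraph::graph_from_data_frame(
    d = net$edges |> mutate(weight = abs(.data$rho)),
    directed = FALSE,
    vertices = net$nodes
  )
  g
}

#' Detect network modules by Louvain modularity maximization
#'
#' Greedy multilevel modularity optimization on the unsigned graph (|rho|
#' edge weights). Isolated nodes become singleton modules. Modules are
#' relabelled `M1`, `M2`, ... in decreasing size order.
#'
#' @param net A `co_network` with at least one edge.
#' @param seed Integer seed (the algorithm breaks ties stochastically).
#' @return The network with a `module` column added to `$nodes` and the
#'   achieved modularity in `attr(, "modularity")`.
#' @export
detect_modules <- function(net, seed = NULL) {
  stopifnot(inherits(net, "co_network"))
  if (nrow(net$edges) == 0) abort("Cannot detect modules in an edgeless network.")
  g <- as_igraph(net)
  comm <- with_seed_if(seed, igraph::cluster_louvain(g, weights = igraph::E(g)$weight))
  membership <- igraph::membership(comm)
  ord <- order(-as.vector(table(membership)[as.character(sort(unique(membership)))]))
  relabel <- setNames(seq_along(ord), sort(unique(membership))[ord])
  mod_id <- paste0("M", relabel[as.character(membership)])
  net$nodes$module <- mod_id[match(net$nodes$otu_id, names(membership))]
  attr(net, "modularity") <- igraph::modularity(comm)
  net
}

#' Summarise network modules against the water-mass gradient
#'
#' Per module: node counts, sensitive-OTU membership, within-module edge
#' counts by sign, and an ordinary least-squares regression of the module's
#' cumulative relative abundance per sample on the sample's Kuroshio
#' fraction R_K (slope, R-squared, p). Between-module edge counts by sign
#' are reported separately. When a [define_sensitive()] result is supplied,
#' cumulative abundance sums the module's sensitive OTUs (the module's
#' current-responsive core); otherwise all module members are summed.
#'
#' @param net A `co_network` with modules (see [detect_modules()]).
#' @param x The [otu_table()] the network was built from (or a superset).
#' @param r_k A tibble with `sample_id` and `r_k` per sample.
#' @param sensitive Optional `sensitive_otus` object.
#' @return A `module_summary` object with `modules`, `between_edges` and
#'   `abundance` tibbles.
#' @export
module_summary <- function(net, x, r_k, sensitive = NULL) {
  stopifnot(inherits(net, "co_network"))
  if (is.null(net$nodes$module)) abort("Run detect_modules() first.")
  counts <- get_counts(x)
  relab <- relative_abundance(counts)
  if (!all(c("sample_id", "r_k") %in% names(r_k))) {
    abort("`r_k` needs columns sample_id and r_k.")
  }
  r_k <- r_k[match(colnames(counts), r_k$sample_id), , drop = FALSE]
  if (anyNA(r_k$r_k)) abort("`r_k` does not cover every sample.")
  sens_ids <- if (!is.null(sensitive)) {
    sensitive$otus$otu_id[sensitive$otus$sensitive]
  } else {
    character(0)
  }
  nodes <- net$nodes |>
    mutate(sensitive = .data$otu_id %in% sens_ids)
  mod_of <- setNames(nodes$module, nodes$otu_id)
  e <- net$edges |>
    mutate(module_a = mod_of[.data$otu_a], module_b = mod_of[.data$otu_b],
           within = .data$module_a == .data$module_b)
  between_edges <- e |>
    filter(!.data$within) |>
    mutate(pair = paste(pmin(.data$module_a, .data$module_b),
                        pmax(.data$module_a, .data$module_b), sep = "-")) |>
    count(.data$pair, .data$sign, name = "n_edges")
  abundance <- NULL
  fits <- list()
  modules <- nodes |>
    group_by(.data$module) |>
    summarise(n_otus = dplyr::n(), n_sensitive = sum(.data$sensitive),
              .groups = "drop")
  mod_stats <- map(modules$module, function(m) {
    members <- nodes$otu_id[nodes$module == m]
    core <- if (length(sens_ids)) intersect(members, sens_ids) else members
    ew <- e |> filter(.data$within, .data$module_a == m)
    cum <- if (length(core)) {
      colSums(relab[core, , drop = FALSE])
    } else {
      rep(NA_real_, ncol(relab))
    }
    ab <- tibble(module = m, sample_id = colnames(counts),
                 cum_relab = cum, r_k = r_k$r_k)
    constant <- !anyNA(cum) && sd(cum) == 0
    fit <- if (!anyNA(cum) && !constant && sd(r_k$r_k) > 0) {
      lm(cum_relab ~ r_k, data = ab)
    } else {
      NULL
    }
    list(
      row = tibble(
        module = m,
        within_positive = sum(ew$sign == "positive"),
        within_negative = sum(ew$sign == "negative"),
        n_core_otus = length(core),
        slope = if (!is.null(fit)) coef(fit)[["r_k"]] else
          if (constant) 0 else NA_real_,
        r_squared = if (!is.null(fit)) summary(fit)$r.squared else NA_real_,
        slope_p = if (!is.null(fit)) summary(fit)$coefficients["r_k", 4] else NA_real_
      ),
      abundance = ab
    )
  })
  modules <- modules |>
    left_join(bind_rows(map(mod_stats, "row")), by = "module") |>
    arrange(dplyr::desc(.data$n_sensitive), dplyr::desc(.data$n_otus))
  abundance <- bind_rows(map(mod_stats, "abundance"))
  structure(
    list(modules = modules, between_edges = between_edges,
         abundance = abundance),
    class = "module_summary"
  )
}

#' @export
print.module_summary <- function(x, ...) {
  cat(sprintf("<module_summary> %d modules\n", nrow(x$modules)))
  print(x$modules)
  invisible(x)
}

#' @rdname module_summary
#' @param ... Unused.
#' @export
tidy.module_summary <- function(x, ...) x$modules

#' @export
autoplot.module_summary <- function(object, modules = NULL, ...) {
  ab <- object$abundance
  if (!is.null(modules)) ab <- ab |> filter(.data$module %in% modules)
  ggplot(ab, aes(x = .data$r_k, y = .data$cum_relab, colour = .data$module)) +
    geom_point() +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    labs(x = expression(R[K]), y = "Cumulative relative abundance",
         colour = "Module") +
    theme_minimal()
}

#' Write network artifacts to disk
#'
#' Writes the edge list (with module assignments) and module membership as
#' CSV, and optionally the graph as GraphML.
#'
#' @param net A `co_network` (ideally after [detect_modules()]).
#' @param edges_path,nodes_path CSV output paths.
#' @param graphml_path Optional GraphML output path.
#' @return `edges_path`, invisibly.
#' @export
write_network <- function(net, edges_path, nodes_path, graphml_path = NULL) {
  stopifnot(inherits(net, "co_network"))
  e <- net$edges
  if (!is.null(net$nodes$module)) {
    mod_of <- setNames(net$nodes$module, net$nodes$otu_id)
    e <- e |> mutate(module_a = mod_of[.data$otu_a],
                     module_b = mod_of[.data$otu_b])
  }
  readr::write_csv(e, edges_path)
  readr::write_csv(net$nodes, nodes_path)
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph(net), graphml_path, format = "graphml")
  }
  invisible(edges_path)
}
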