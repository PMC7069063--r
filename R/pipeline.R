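# Ensemble pipeline: sweep network families, aggregate one summary row
# per network, and run one-way ANOVA group comparisons.

#' Full structural summary of one network
#'
#' Computes every summary the sweep reports for a single graph: mean/sd
#' path length and clustering, mean/sd participation coefficient and
#' within-module z-score, and small-world propensity.
#'
#' @param graph an igraph object (or wrapper).
#' @param family label for the network family (e.g. "ASN", "WS").
#' @param params named list recorded as provenance.
#' @param n_null random-null draws for small-world propensity.
#' @param seed integer seed (nulls + community detection).
#' @return One-row data frame (a summary record).
#' @export
summarize_network <- function(graph, family = "network", params = list(),
                              n_null = 10, seed = 1L) {
  g <- as_igraph(graph)
  ps <- mean_path_length(g)
  cs <- clustering_stats(g)
  swp <- small_world_propensity(g, n_null = n_null, seed = seed)
  carto <- cartographic_profile(g, seed = seed)
  data.frame(
    family = family,
    size = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    params = paste(names(params), unlist(params), sep = "=", collapse = ";"),
    mean_pl = ps$mean_pl, sd_pl = ps$sd_pl,
    mean_cc = cs$mean_cc, sd_cc = stats::sd(cs$per_node),
    mean_pcoeff = carto$summary$mean_pcoeff,
    sd_pcoeff = carto$summary$sd_pcoeff,
    mean_mz = carto$summary$mean_mz,
    sd_mz = carto$summary$sd_mz,
    modularity_q = carto$summary$modularity_q,
    swp_phi = swp$phi,
    fraction_excluded = ps$fraction_excluded,
    stringsAsFactors = FALSE
  )
}

#' Default sweep configuration
#'
#' The study conditions: nanowire ensembles over a grid of sizes, mean
#' lengths 6-9 um and dispersions 0-50% on a 30 x 30 um plane; a
#' Watts-Strogatz beta sweep from 0 to 1 in steps of 0.05 (21 values)
#' degree-matched per size to the nanowire networks; and the 5-layer
#' 10-160-160-160-10 fully-connected ANN. Override any element to
#' subset or rescale.
#'
#' @param sizes nanowire counts to simulate.
#' @return A config list for [run_sweep()].
#' @export
default_sweep_config <- function(sizes = c(100, 500)) {
  list(
    asn = list(
      sizes = sizes,
      mean_lengths = c(6, 7, 8, 9),
      dispersions = c(0, 0.1, 0.2, 0.5),
      replicates = 1,
      plane_width = 30, plane_height = 30
    ),
    ws = list(betas = seq(0, 1, by = 0.05)),
    ann = list(layers = c(10, 160, 160, 160, 10)),
    connectome = NULL,
    n_null = 10
  )
}

#' Run a structural sweep over network families
#'
#' Generates or loads every configured network, computes the full metric
#' battery per network, and aggregates one summary record each.
#' Watts-Strogatz networks are degree-matched per size to the mean
#' degree of the nanowire networks of that size. A failure in one
#' network logs a diagnostic and the sweep continues.
#'
#' @param config a list as produced by [default_sweep_config()];
#'   elements `asn`, `ws`, `ann` and `connectome` (path or `connectome`
#'   object) may each be `NULL` to skip the family.
#' @param out_dir optional directory: writes `summary.csv`,
#'   `ws_plane.csv`, `swp.csv`, per-network node tables under
#'   `cartography/`, and `manifest.json`.
#' @param seed master seed; all per-network seeds derive from it.
#' @return Data frame of summary records (one row per network).
#' @export
run_sweep <- function(config = default_sweep_config(), out_dir = NULL,
                      seed = 1L) {
  n_null <- config$n_null %||% 10
  records <- list()
  carto_tables <- list()
  counter <- 0L
  add_record <- function(graph, family, params, label) {
    counter <<- counter + 1L
    s <- derive_seed(seed, counter)
    rec <- tryCatch(
      summarize_network(graph, family = family, params = params,
                        n_null = n_null, seed = s),
      error = function(e) {
        message(sprintf("[sweep] %s failed: %s", label, conditionMessage(e)))
        NULL
      }
    )
    if (!is.null(rec)) {
      records[[length(records) + 1L]] <<- rec
      carto_tables[[label]] <<- tryCatch(
        cartographic_profile(graph, seed = s)$nodes,
        error = function(e) NULL
      )
    }
    invisible(rec)
  }

  asn_degrees <- list() # mean degree per size, for WS matching
  if (!is.null(config$asn)) {
    a <- config$asn
    for (size in a$sizes) {
      nets <- generate_ensemble(
        n_wires = size, mean_lengths = a$mean_lengths,
        dispersions = a$dispersions, replicates = a$replicates %||% 1,
        plane_width = a$plane_width %||% 30,
        plane_height = a$plane_height %||% 30,
        seed = derive_seed(seed, 1000L + size)
      )
      degs <- numeric(0)
      for (i in seq_along(nets)) {
        net <- nets[[i]]
        p <- net$params
        label <- sprintf("ASN_n%d_l%g_d%g_r%d", p$n_wires, p$mean_length,
                         p$dispersion, i)
        add_record(net, "ASN",
                   list(n = p$n_wires, length = p$mean_length,
                        dispersion = p$dispersion, seed = p$seed),
                   label)
        degs <- c(degs, mean(igraph::degree(largest_component(net)$graph)))
      }
      asn_degrees[[as.character(size)]] <- mean(degs)
    }
  }

  if (!is.null(config$ws)) {
    w <- config$ws
    sizes <- w$sizes %||% (if (length(asn_degrees)) {
      as.numeric(names(asn_degrees))
    } else {
      stop_param("WS sweep needs `sizes` (or an ASN family to match)")
    })
    for (size in sizes) {
      k <- w$k %||% {
        md <- asn_degrees[[as.character(size)]]
        if (is.null(md)) stop_param("no ASN of size %d to degree-match", size)
        max(1L, as.integer(round(md / 2)))
      }
      for (beta in w$betas) {
        counter <- counter + 1L
        g <- watts_strogatz(size, k, beta, seed = derive_seed(seed, counter))
        add_record(g, "WS", list(n = size, k = k, beta = beta),
                   sprintf("WS_n%d_k%d_b%g", size, k, beta))
      }
    }
  }

  if (!is.null(config$ann)) {
    g <- layered_ann(config$ann$layers)
    add_record(g, "ANN",
               list(layers = paste(config$ann$layers, collapse = "-")),
               "ANN")
  }

  if (!is.null(config$connectome)) {
    cn <- config$connectome
    conn <- if (inherits(cn, "connectome")) cn else load_connectome(cn)
    add_record(conn, "connectome",
               list(n = igraph::vcount(conn$graph)), "connectome")
  }

  out <- do.call(rbind, records)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(
      out[, c("family", "size", "params", "mean_cc", "mean_pl")],
      file.path(out_dir, "ws_plane.csv"), row.names = FALSE
    )
    utils::write.csv(
      out[, c("family", "size", "params", "swp_phi")],
      file.path(out_dir, "swp.csv"), row.names = FALSE
    )
    cdir <- file.path(out_dir, "cartography")
    dir.create(cdir, showWarnings = FALSE)
    for (label in names(carto_tables)) {
      if (!is.null(carto_tables[[label]])) {
        utils::write.csv(carto_tables[[label]],
                         file.path(cdir, paste0(label, ".csv")),
                         row.names = FALSE)
      }
    }
    cfg_manifest <- config
    if (inherits(cfg_manifest$connectome, "connectome")) {
      cfg_manifest$connectome <- list(
        source = "in-memory connectome object",
        n_nodes = igraph::vcount(config$connectome$graph),
        n_edges = igraph::ecount(config$connectome$graph)
      )
    }
    manifest <- list(
      package = "asntopo",
      version = as.character(utils::packageVersion("asntopo")),
      seed = seed,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config = cfg_manifest
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  out
}

#' Per-node path-length profile from a source node
#'
#' Breadth-first distances of every node from a chosen source, plus the
#' all-pairs hop-count histogram of the largest connected component with
#' its mean and median.
#'
#' @param graph an igraph object (or wrapper).
#' @param source vertex name or index.
#' @return List with `distances` (data frame node, hops), `histogram`
#'   (table hop count -> pair count), `mean_pl`, `median_pl`.
#' @export
path_profile <- function(graph, source) {
  ps <- mean_path_length(graph, source = source)
  hops <- ps$per_node_from_source
  counts <- ps$length_counts
  all_lengths <- rep(as.numeric(names(counts)), as.integer(counts))
  list(
    distances = if (is.null(hops)) NULL else
      data.frame(node = names(hops), hops = as.numeric(hops),
                 stringsAsFactors = FALSE),
    histogram = counts,
    mean_pl = ps$mean_pl,
    median_pl = stats::median(all_lengths)
  )
}

#' One-way ANOVA with Bonferroni post-hoc comparisons
#'
#' Standard fixed-effects one-way analysis of variance across labelled
#' groups, followed by pairwise t tests with Bonferroni-adjusted
#' p-values (pooled SD).
#'
#' @param groups named list of numeric vectors (>= 2 groups).
#' @return Object of class `group_comparison`: `groups`, `f_stat`,
#'   `df_between`, `df_within`, `p_value`, `posthoc` (matrix of adjusted
#'   p-values).
#' @examples
#' cmp <- one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4),
#'                           c = c(10, 11, 12)))
#' cmp$f_stat
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop_param("`groups` must be a list of >= 2 numeric vectors")
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  sizes <- lengths(groups)
  if (any(sizes < 1)) stop_param("every group needs >= 1 value")
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), sizes))
  if (stats::var(values) < 1e-24 || length(values) <= length(groups)) {
    stop_metric("ANOVA undefined: no residual variance between or within groups")
  }
  fit <- stats::aov(values ~ labels)
  tab <- summary(fit)[[1]]
  if (is.na(tab[["F value"]][1]) || tab[["Mean Sq"]][2] < 1e-24) {
    stop_metric("ANOVA undefined: zero within-group variance")
  }
  posthoc <- stats::pairwise.t.test(values, labels,
                                    p.adjust.method = "bonferroni")
  structure(
    list(
      groups = groups,
      f_stat = tab[["F value"]][1],
      df_between = tab[["Df"]][1],
      df_within = tab[["Df"]][2],
      p_value = tab[["Pr(>F)"]][1],
      posthoc = posthoc$p.value
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d,%d) = %.2f, p = %.3g\n",
              x$df_between, x$df_within, x$f_stat, x$p_value))
  cat("Bonferroni-adjusted pairwise p-values:\n")
  print(signif(x$posthoc, 3))
  invisible(x)
}
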