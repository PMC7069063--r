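# Functional cartography: modularity partition, participation
# coefficient, within-module degree z-score, and the seven-region node
# classification of the (PCoeff, MZ) plane.

#' Detect communities by modularity maximisation
#'
#' Louvain-style greedy modularity maximisation (resolution 1) via
#' [igraph::cluster_louvain()], made deterministic by an explicit seed.
#' Module ids are relabelled to be contiguous integers starting at 1.
#'
#' @param graph an igraph object (or wrapper) with >= 1 edge.
#' @param seed integer seed.
#' @return Object of class `graph_partition`: `membership` (named
#'   integer vector, node -> module), `modularity_q`, `n_modules`.
#' @examples
#' g <- igraph::make_full_graph(5) + igraph::make_full_graph(5)
#' g <- igraph::add_edges(g, c(1, 6))
#' detect_communities(g, seed = 1)$n_modules # 2
#' @export
detect_communities <- function(graph, seed = 1L) {
  g <- as_igraph(graph)
  if (igraph::ecount(g) == 0) {
    stop_metric("community detection is undefined for an edgeless graph")
  }
  cl <- local_seed_eval(seed, igraph::cluster_louvain(g))
  memb <- igraph::membership(cl)
  memb <- match(memb, sort(unique(memb)))
  names(memb) <- igraph::V(g)$name %||% as.character(seq_along(memb))
  structure(
    list(
      membership = memb,
      modularity_q = igraph::modularity(g, memb),
      n_modules = length(unique(memb))
    ),
    class = "graph_partition"
  )
}

#' @export
print.graph_partition <- function(x, ...) {
  cat(sprintf("Partition: %d modules, modularity Q = %.3f\n",
              x$n_modules, x$modularity_q))
  invisible(x)
}

membership_of <- function(partition, g) {
  memb <- if (inherits(partition, "graph_partition")) {
    partition$membership
  } else {
    partition
  }
  if (length(memb) != igraph::vcount(g)) {
    stop_param("partition must assign every node of the graph")
  }
  as.integer(memb)
}

#' Participation coefficient
#'
#' For node i with degree k_i and k_is edges into module s:
#' \deqn{P_i = 1 - \sum_s (k_{is} / k_i)^2.}
#' 0 means all edges stay within the node's own module; values near 1
#' mean edges spread evenly across modules. Degree-0 nodes score 0.
#'
#' @param graph an igraph object (or wrapper).
#' @param partition a `graph_partition` or a module-membership vector
#'   covering all nodes.
#' @return Named numeric vector of coefficients in `[0, 1]`.
#' @export
participation_coefficient <- function(graph, partition) {
  g <- as_igraph(graph)
  memb <- membership_of(partition, g)
  adj <- igraph::as_adj_list(g)
  p <- vapply(seq_along(adj), function(i) {
    nb <- as.integer(adj[[i]])
    if (!length(nb)) return(0)
    kis <- tabulate(memb[nb], nbins = max(memb))
    1 - sum((kis / length(nb))^2)
  }, numeric(1))
  names(p) <- igraph::V(g)$name %||% as.character(seq_along(p))
  p
}

#' Within-module degree z-score
#'
#' z_i = (kappa_i - mean(kappa, module)) / sd(kappa, module), where
#' kappa is the number of edges a node has to members of its own module
#' and mean/sd are taken over that module (population standard
#' deviation). Modules with zero spread give z = 0 for all members, so
#' the z-scores of every module -- and hence the whole network --
#' average to 0.
#'
#' @inheritParams participation_coefficient
#' @return Named numeric vector of z-scores.
#' @export
within_module_z <- function(graph, partition) {
  g <- as_igraph(graph)
  memb <- membership_of(partition, g)
  adj <- igraph::as_adj_list(g)
  kappa <- vapply(seq_along(adj), function(i) {
    nb <- as.integer(adj[[i]])
    sum(memb[nb] == memb[i])
  }, numeric(1))
  z <- numeric(length(kappa))
  for (s in unique(memb)) {
    ix <- which(memb == s)
    mu <- mean(kappa[ix])
    sg <- sqrt(mean((kappa[ix] - mu)^2)) # population sd
    z[ix] <- if (sg < 1e-12) 0 else (kappa[ix] - mu) / sg
  }
  names(z) <- igraph::V(g)$name %||% as.character(seq_along(z))
  z
}

cartography_regions <- c(
  "ultra-peripheral", "peripheral", "non-hub connector", "non-hub kinless",
  "provincial hub", "connector hub", "kinless hub"
)

#' Classify a node on the cartographic plane
#'
#' Deterministic seven-region classification of (participation
#' coefficient, within-module z-score) pairs. Nodes with z >= 2.5 are
#' hubs; participation thresholds split non-hubs at 0 / 0.62 / 0.80 and
#' hubs at 0.30 / 0.75. Boundary values belong to the upper region
#' (half-open intervals), so every point of the plane receives exactly
#' one label.
#'
#' @param pcoeff participation coefficient(s) in `[0, 1]`.
#' @param mz within-module degree z-score(s).
#' @return Factor with levels ultra-peripheral, peripheral, non-hub
#'   connector, non-hub kinless, provincial hub, connector hub, kinless
#'   hub.
#' @examples
#' classify_node(c(0, 0.7, 0.2), c(1, 1, 3))
#' @export
classify_node <- function(pcoeff, mz) {
  if (length(pcoeff) != length(mz)) {
    stop_param("`pcoeff` and `mz` must have equal length")
  }
  if (any(!is.finite(pcoeff)) || any(pcoeff < 0 | pcoeff > 1)) {
    stop_param("`pcoeff` must lie in [0, 1]")
  }
  hub <- mz >= 2.5
  lab <- ifelse(
    hub,
    ifelse(pcoeff < 0.30, "provincial hub",
           ifelse(pcoeff < 0.75, "connector hub", "kinless hub")),
    ifelse(pcoeff < 1e-12, "ultra-peripheral",
           ifelse(pcoeff < 0.62, "peripheral",
                  ifelse(pcoeff < 0.80, "non-hub connector",
                         "non-hub kinless")))
  )
  factor(lab, levels = cartography_regions)
}

#' Cartographic profile of a network
#'
#' End-to-end node cartography on the largest connected component:
#' modularity partition, then per-node participation coefficient,
#' within-module degree z-score and region label, with network-level
#' summaries.
#'
#' @param graph an igraph object (or wrapper) with >= 1 edge.
#' @param seed integer seed (community detection).
#' @return Object of class `node_cartography`: `nodes` (data frame with
#'   columns node, degree, module, pcoeff, mz, region), `summary` (list
#'   with mean/sd of pcoeff and mz, region counts, modularity_q,
#'   n_modules, fraction_excluded).
#' @examples
#' prof <- cartographic_profile(watts_strogatz(60, 3, beta = 0.2, seed = 1))
#' prof$summary$mean_pcoeff
#' @export
cartographic_profile <- function(graph, seed = 1L) {
  g <- as_igraph(graph)
  lcc <- largest_component(g)
  part <- detect_communities(lcc$graph, seed = seed)
  pc <- participation_coefficient(lcc$graph, part)
  mz <- within_module_z(lcc$graph, part)
  region <- classify_node(pc, mz)
  nodes <- data.frame(
    node = names(pc),
    degree = as.integer(igraph::degree(lcc$graph)),
    module = as.integer(part$membership),
    pcoeff = unname(pc),
    mz = unname(mz),
    region = region,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      nodes = nodes,
      summary = list(
        mean_pcoeff = mean(pc), sd_pcoeff = stats::sd(pc),
        mean_mz = mean(mz), sd_mz = stats::sd(mz),
        region_counts = table(region),
        modularity_q = part$modularity_q,
        n_modules = part$n_modules,
        fraction_excluded = lcc$fraction_excluded
      )
    ),
    class = "node_cartography"
  )
}

#' @export
print.node_cartography <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Node cartography: %d nodes, %d modules (Q = %.3f)\n  PCoeff %.3f +/- %.3f, MZ %.3f +/- %.3f\n",
    nrow(x$nodes), s$n_modules, s$modularity_q,
    s$mean_pcoeff, s$sd_pcoeff, s$mean_mz, s$sd_mz
  ))
  print(s$region_counts)
  invisible(x)
}
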