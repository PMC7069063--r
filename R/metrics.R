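# Global structural measures. All global metrics operate on the largest
# connected component (LCC); the excluded-node fraction is reported so
# nothing is silently dropped.

as_igraph <- function(x) {
  if (inherits(x, "nanowire_network")) return(x$graph)
  if (inherits(x, "connectome")) return(x$graph)
  if (igraph::is_igraph(x)) return(x)
  stop_param("expected an igraph, nanowire_network or connectome object")
}

#' Largest connected component of a graph
#'
#' @param graph an igraph object (or `nanowire_network` / `connectome`).
#' @return List with `graph` (the induced subgraph of the largest
#'   component) and `fraction_excluded` (share of nodes outside it).
#' @export
largest_component <- function(graph) {
  g <- as_igraph(graph)
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  list(
    graph = igraph::induced_subgraph(g, keep),
    fraction_excluded = 1 - length(keep) / igraph::vcount(g)
  )
}

#' Mean shortest-path length (hop count)
#'
#' Breadth-first shortest paths over all unordered node pairs of the
#' largest connected component: the mean and standard deviation of the
#' minimal edge counts between node pairs. Optionally also returns the
#' distance of every node from a chosen source, for per-node path-length
#' profiles.
#'
#' @param graph an igraph object (or wrapper); needs >= 2 nodes and
#'   >= 1 edge.
#' @param source optional vertex name (or index) for a per-node distance
#'   profile.
#' @return Object of class `path_stats`: `mean_pl`, `sd_pl`, `n_pairs`,
#'   `length_counts` (table of hop count -> number of pairs),
#'   `per_node_from_source` (or `NULL`), `fraction_excluded`.
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c)
#' mean_path_length(g)$mean_pl # 4/3
#' @export
mean_path_length <- function(graph, source = NULL) {
  g <- as_igraph(graph)
  if (igraph::vcount(g) < 2 || igraph::ecount(g) == 0) {
    stop_metric("mean path length is undefined for an edgeless graph")
  }
  lcc <- largest_component(g)
  d <- igraph::distances(lcc$graph)
  vals <- d[upper.tri(d)]
  per_source <- NULL
  if (!is.null(source)) {
    nm <- igraph::V(lcc$graph)$name
    idx <- if (is.character(source)) match(source, nm) else as.integer(source)
    if (is.na(idx) || idx < 1 || idx > nrow(d)) {
      warning("source node is not in the largest connected component; no profile")
    } else {
      per_source <- d[idx, ]
      names(per_source) <- nm %||% as.character(seq_len(nrow(d)))
    }
  }
  structure(
    list(
      mean_pl = mean(vals), sd_pl = stats::sd(vals),
      n_pairs = length(vals),
      length_counts = table(vals),
      per_node_from_source = per_source,
      fraction_excluded = lcc$fraction_excluded
    ),
    class = "path_stats"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Local clustering coefficients
#'
#' Per-node local clustering (fraction of a node's neighbour pairs that
#' are themselves connected), with the convention that nodes of degree
#' < 2 score 0, averaged over the nodes of the largest connected
#' component. This is the node-wise mean, not the global transitivity
#' ratio.
#'
#' @param graph an igraph object (or wrapper).
#' @return Object of class `clustering_stats`: `per_node` (named vector),
#'   `degree` (named vector), `mean_cc`, `fraction_excluded`.
#' @examples
#' clustering_stats(igraph::make_full_graph(4))$mean_cc # 1
#' @export
clustering_stats <- function(graph) {
  g <- as_igraph(graph)
  lcc <- largest_component(g)
  cc <- igraph::transitivity(lcc$graph, type = "localundirected",
                             isolates = "zero")
  cc[is.nan(cc)] <- 0
  deg <- igraph::degree(lcc$graph)
  cc[deg < 2] <- 0
  nm <- igraph::V(lcc$graph)$name %||% as.character(seq_along(cc))
  names(cc) <- nm
  names(deg) <- nm
  structure(
    list(per_node = cc, degree = deg, mean_cc = mean(cc),
         fraction_excluded = lcc$fraction_excluded),
    class = "clustering_stats"
  )
}

#' Small-world propensity
#'
#' Quantifies how far a network's clustering falls below a degree-matched
#' ring lattice and how far its path length exceeds a density-matched
#' random graph:
#' \deqn{\phi = 1 - \sqrt{(\Delta_C^2 + \Delta_L^2) / 2}}
#' with \eqn{\Delta_C = (C_{latt} - C_{obs}) / (C_{latt} - C_{rand})}
#' and \eqn{\Delta_L = (L_{obs} - L_{rand}) / (L_{latt} - L_{rand})},
#' each clamped to `[0, 1]`. A ring lattice scores
#' \eqn{1 - 1/\sqrt{2} \approx 0.293} (all its deficit is in path
#' length), a random graph the same (all in clustering), and a
#' small-world network approaches 1.
#'
#' Nulls are matched on the largest connected component: the lattice null
#' is a ring lattice with the same node count and `k = matched_k()`
#' (half the mean degree, rounded); the random null is the average of
#' `n_null` Erdos-Renyi G(N, M) draws with the same node and edge count.
#' If a null degenerates (lattice and random clustering or path length
#' coincide) the corresponding delta is set to 0 with a warning.
#'
#' @param graph an igraph object (or wrapper) with mean degree >= 2 on
#'   its largest component.
#' @param n_null number of random-null draws to average.
#' @param seed integer seed for the random nulls.
#' @return Object of class `swp_result` with fields `c_obs, c_latt,
#'   c_rand, l_obs, l_latt, l_rand, delta_c, delta_l, phi, k, n,
#'   fraction_excluded`.
#' @examples
#' swp <- small_world_propensity(ring_lattice(60, 3), seed = 1)
#' swp$phi # 1 - 1/sqrt(2)
#' @export
small_world_propensity <- function(graph, n_null = 10, seed = 1L) {
  g <- as_igraph(graph)
  lcc <- largest_component(g)$graph
  n <- igraph::vcount(lcc)
  m <- igraph::ecount(lcc)
  if (n < 4 || m == 0) stop_metric("graph too small for small-world propensity")
  if (2 * m / n < 2) {
    stop_metric("mean degree %.2f < 2: nulls are degenerate", 2 * m / n)
  }
  k <- min(matched_k(lcc), as.integer((n - 1) %/% 2))
  latt <- ring_lattice(n, k)
  c_obs <- clustering_stats(lcc)$mean_cc
  l_obs <- mean_path_length(lcc)$mean_pl
  c_latt <- clustering_stats(latt)$mean_cc
  l_latt <- mean_path_length(latt)$mean_pl
  nulls <- local_seed_eval(seed, {
    vapply(seq_len(n_null), function(b) {
      r <- igraph::sample_gnm(n, m)
      c(clustering_stats(r)$mean_cc, mean_path_length(r)$mean_pl)
    }, numeric(2))
  })
  c_rand <- mean(nulls[1, ])
  l_rand <- mean(nulls[2, ])
  # Deficits are non-negative by definition: a network more clustered than
  # its lattice null has no clustering deficit (and one faster than its
  # random null no path-length excess), so numerators are floored at zero
  # before the ratio. This also covers the degenerate sparse regime where
  # the matched lattice is a bare cycle with zero clustering.
  if (abs(c_latt - c_rand) < 1e-12) {
    warning("degenerate clustering nulls (C_latt = C_rand); delta_C set to 0")
    delta_c <- 0
  } else {
    delta_c <- clamp01(max(0, c_latt - c_obs) / (c_latt - c_rand))
  }
  if (abs(l_latt - l_rand) < 1e-12) {
    warning("degenerate path-length nulls (L_latt = L_rand); delta_L set to 0")
    delta_l <- 0
  } else {
    delta_l <- clamp01(max(0, l_obs - l_rand) / (l_latt - l_rand))
  }
  structure(
    list(
      c_obs = c_obs, c_latt = c_latt, c_rand = c_rand,
      l_obs = l_obs, l_latt = l_latt, l_rand = l_rand,
      delta_c = delta_c, delta_l = delta_l,
      phi = 1 - sqrt((delta_c^2 + delta_l^2) / 2),
      k = k, n = n,
      fraction_excluded = largest_component(g)$fraction_excluded
    ),
    class = "swp_result"
  )
}

#' @export
print.swp_result <- function(x, ...) {
  cat(sprintf(
    paste0("Small-world propensity: phi = %.3f (deltaC = %.3f, deltaL = %.3f)\n",
           "  C: obs %.3f, lattice %.3f, random %.3f\n",
           "  L: obs %.3f, lattice %.3f, random %.3f  (N = %d, k = %d)\n"),
    x$phi, x$delta_c, x$delta_l, x$c_obs, x$c_latt, x$c_rand,
    x$l_obs, x$l_latt, x$l_rand, x$n, x$k
  ))
  invisible(x)
}

#' Coordinates on the clustering / path-length plane
#'
#' The (mean clustering, mean path length) pair used to place a network
#' on the Watts-Strogatz plane.
#'
#' @param graph an igraph object (or wrapper).
#' @return Named numeric `c(mean_cc, mean_pl)`.
#' @export
ws_plane_point <- function(graph) {
  c(mean_cc = clustering_stats(graph)$mean_cc,
    mean_pl = mean_path_length(graph)$mean_pl)
}
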