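# Reference network families: Watts-Strogatz sweep, layered feed-forward
# ANN topology, and connectome loading (plus a synthetic stand-in fixture).

#' Watts-Strogatz small-world graph
#'
#' Builds a ring lattice with `n` nodes each connected to its `k` nearest
#' neighbours on either side (mean degree `2k`), then rewires each lattice
#' edge independently with probability `beta`: the far endpoint is
#' replaced by a node chosen uniformly at random, rejecting self-loops
#' and duplicate edges. `beta = 0` returns the deterministic ring lattice
#' ("grid-like"); `beta = 1` rewires every edge ("random"). The edge count
#' `n * k` is invariant under rewiring.
#'
#' This is hand-rolled rather than delegated to
#' [igraph::sample_smallworld()] because that generator may emit loops
#' and multiple edges, which would break the fixed-edge-count contract
#' after simplification.
#'
#' @param n number of nodes; must satisfy `2 * k < n`.
#' @param k neighbours per side in the initial lattice (>= 1).
#' @param beta per-edge rewiring probability in `[0, 1]`.
#' @param seed integer seed (ignored at `beta = 0`, which is
#'   deterministic).
#' @return An undirected simple igraph with `n * k` edges.
#' @examples
#' g <- watts_strogatz(100, k = 3, beta = 0.2, seed = 1)
#' igraph::ecount(g) # always n * k
#' @export
watts_strogatz <- function(n, k, beta, seed = 1L) {
  assert_scalar_num(n, "n"); assert_scalar_num(k, "k")
  assert_scalar_num(beta, "beta")
  if (k < 1 || k != round(k)) stop_param("`k` must be a positive integer")
  if (2 * k >= n) stop_param("need 2k < n, got k = %s, n = %s", k, n)
  if (beta < 0 || beta > 1) stop_param("`beta` must lie in [0, 1]")
  n <- as.integer(n); k <- as.integer(k)
  adj <- matrix(FALSE, n, n)
  for (s in seq_len(k)) {
    j <- (seq_len(n) + s - 1L) %% n + 1L
    adj[cbind(seq_len(n), j)] <- TRUE
    adj[cbind(j, seq_len(n))] <- TRUE
  }
  if (beta > 0) {
    local_seed_eval(seed, {
      for (s in seq_len(k)) {
        for (i in seq_len(n)) {
          if (stats::runif(1) < beta) {
            j <- (i + s - 1L) %% n + 1L
            if (!adj[i, j]) next # already rewired away by an earlier pass
            cand <- sample.int(n, 1L)
            tries <- 0L
            while (cand == i || adj[i, cand]) {
              cand <- sample.int(n, 1L)
              tries <- tries + 1L
              if (tries > 100L * n) break # node saturated; keep lattice edge
            }
            if (cand != i && !adj[i, cand]) {
              adj[i, j] <- adj[j, i] <- FALSE
              adj[i, cand] <- adj[cand, i] <- TRUE
            }
          }
        }
      }
      NULL
    })
  }
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

#' Ring lattice (grid-like Watts-Strogatz endpoint)
#'
#' @inheritParams watts_strogatz
#' @return The deterministic `beta = 0` lattice.
#' @export
ring_lattice <- function(n, k) watts_strogatz(n, k, beta = 0)

#' Lattice parameter k matched to a target graph
#'
#' Half the target's mean degree, rounded to the nearest integer (ties to
#' even), floored at 1. Used to degree-match lattice and Watts-Strogatz
#' nulls to an observed network.
#'
#' @param graph an igraph object.
#' @return Integer `k >= 1`.
#' @export
matched_k <- function(graph) {
  max(1L, as.integer(round(mean(igraph::degree(graph)) / 2)))
}

#' Watts-Strogatz graph degree-matched to a target network
#'
#' Constructs a WS graph with as many nodes as `target_graph` and
#' `k = matched_k(target_graph)`, so the lattice mean degree `2k` matches
#' the target's mean degree.
#'
#' @param target_graph igraph object to match (>= 3 nodes).
#' @param beta rewiring probability.
#' @param seed integer seed.
#' @return An igraph object.
#' @export
matched_ws <- function(target_graph, beta, seed = 1L) {
  n <- igraph::vcount(target_graph)
  if (n < 3) stop_param("target graph needs >= 3 nodes")
  k <- min(matched_k(target_graph), as.integer((n - 1) %/% 2))
  watts_strogatz(n, k, beta, seed)
}

#' Fully-connected layered ANN topology
#'
#' The undirected graph of a feed-forward artificial neural network:
#' every node in a layer connects to every node of the adjacent layers
#' and to nothing within its own layer (complete bipartite between
#' consecutive layers). A topology object only; no weights, no training.
#'
#' @param layer_sizes integer vector of layer widths (>= 2 layers).
#' @return An igraph object with `sum(layer_sizes)` nodes. Triangle-free
#'   by construction, so every clustering coefficient is 0.
#' @examples
#' g <- layered_ann(c(10, 160, 160, 160, 10))
#' igraph::vcount(g); igraph::ecount(g)
#' @export
layered_ann <- function(layer_sizes) {
  if (length(layer_sizes) < 2 || any(layer_sizes < 1) ||
      any(layer_sizes != round(layer_sizes))) {
    stop_param("`layer_sizes` must be >= 2 positive integers")
  }
  offsets <- cumsum(c(0, layer_sizes))
  edges <- lapply(seq_len(length(layer_sizes) - 1), function(l) {
    a <- offsets[l] + seq_len(layer_sizes[l])
    b <- offsets[l + 1] + seq_len(layer_sizes[l + 1])
    cbind(rep(a, each = length(b)), rep(b, times = length(a)))
  })
  em <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = sum(layer_sizes), directed = FALSE)
  g <- igraph::add_edges(g, t(em))
  igraph::V(g)$layer <- rep(seq_along(layer_sizes), layer_sizes)
  g
}

#' Load a connectome as an undirected simple graph
#'
#' Reads either a two-column edge list (tab- or comma-separated, optional
#' header) or a square adjacency matrix CSV (node labels as header row /
#' first column). Directed or weighted input is symmetrised and
#' binarised; self-loops are dropped and parallel entries merged, so the
#' result always passes the simple-graph validator.
#'
#' @param path file path.
#' @param format `"auto"` (default; chosen from the column count),
#'   `"edgelist"` or `"matrix"`.
#' @return An object of class `connectome`: list with `node_labels`
#'   (character) and `graph` (igraph, vertex names = labels).
#' @export
load_connectome <- function(path, format = c("auto", "edgelist", "matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_format("file not found: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- tryCatch(
    utils::read.table(path, sep = sep, header = FALSE,
                      stringsAsFactors = FALSE, comment.char = "#"),
    error = function(e) stop_format("cannot parse %s: %s", path,
                                    conditionMessage(e))
  )
  if (format == "auto") {
    format <- if (ncol(raw) <= 3) "edgelist" else "matrix"
  }
  if (format == "edgelist") {
    # drop a header row if the first line is non-numeric labels over
    # otherwise numeric columns
    if (nrow(raw) > 1 &&
        suppressWarnings(all(is.na(as.numeric(raw[1, 1:2])))) &&
        suppressWarnings(!any(is.na(as.numeric(raw[-1, 1]))))) {
      raw <- raw[-1, , drop = FALSE]
    }
    if (nrow(raw) == 0) stop_format("empty edge list: %s", path)
    el <- cbind(as.character(raw[[1]]), as.character(raw[[2]]))
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
  } else {
    m <- tryCatch(
      as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE)),
      error = function(e) stop_format("cannot parse matrix %s: %s", path,
                                      conditionMessage(e))
    )
    if (nrow(m) != ncol(m)) stop_format("adjacency matrix is not square")
    mode(m) <- "numeric"
    g <- igraph::graph_from_adjacency_matrix(
      (m + t(m)) > 0, mode = "undirected", diag = FALSE
    )
  }
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (igraph::ecount(g) == 0) stop_format("graph in %s has no edges", path)
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  structure(
    list(node_labels = igraph::V(g)$name, graph = g),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("Connectome: %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Synthetic connectome-like fixture graph
#'
#' Constructs a connected, modular, simple graph of exactly the requested
#' size with a configurable minority of high-degree hub nodes, emulating
#' the gross statistics of a small neuronal connectome (modular with a
#' few hubs). Purely synthetic: a test fixture, not biological data.
#'
#' The construction places nodes in modules, wires a random spanning tree
#' (guaranteeing connectivity), then adds edges preferring within-module
#' pairs and, when `hub_fraction > 0`, pairs touching designated hub
#' nodes.
#'
#' @param n_nodes number of nodes.
#' @param n_edges number of edges; must satisfy
#'   `n_nodes - 1 <= n_edges <= n_nodes (n_nodes - 1) / 2`.
#' @param n_modules number of planted modules.
#' @param hub_fraction fraction of nodes given hub preference, in
#'   `[0, 1]`.
#' @param seed integer seed.
#' @return A `connectome` object.
#' @examples
#' syn <- synthetic_connectome(277, 2105, seed = 1)
#' syn
#' @export
synthetic_connectome <- function(n_nodes, n_edges, n_modules = 6,
                                 hub_fraction = 0.05, seed = 1L) {
  assert_scalar_num(n_nodes, "n_nodes"); assert_scalar_num(n_edges, "n_edges")
  if (n_nodes < 2) stop_param("need >= 2 nodes")
  max_edges <- n_nodes * (n_nodes - 1) / 2
  if (n_edges < n_nodes - 1 || n_edges > max_edges) {
    stop_param("n_edges must lie in [%d, %d] for a connected simple graph",
               n_nodes - 1, max_edges)
  }
  local_seed_eval(seed, {
    module <- sort(rep_len(seq_len(n_modules), n_nodes))
    hubs <- if (hub_fraction > 0) {
      sample.int(n_nodes, max(1L, round(hub_fraction * n_nodes)))
    } else integer()
    # random spanning tree: attach each node to a random earlier node
    ord <- sample.int(n_nodes)
    parent <- vapply(2:n_nodes, function(i) ord[sample.int(i - 1, 1)],
                     integer(1))
    el <- cbind(pmin(ord[-1], parent), pmax(ord[-1], parent))
    seen <- new.env(hash = TRUE)
    for (r in seq_len(nrow(el))) {
      assign(paste(el[r, 1], el[r, 2]), TRUE, envir = seen)
    }
    need <- n_edges - nrow(el)
    extra <- matrix(0L, need, 2)
    got <- 0L
    while (got < need) {
      m <- min(4L * (need - got) + 32L, 1e6)
      a <- sample.int(n_nodes, m, replace = TRUE)
      # bias endpoint choice: same module 80%; hubs get 5x weight
      w <- rep(1, n_nodes)
      if (length(hubs)) w[hubs] <- 5
      b <- integer(m)
      same <- stats::runif(m) < 0.8
      for (t in seq_len(m)) {
        pool <- if (same[t]) which(module == module[a[t]]) else seq_len(n_nodes)
        b[t] <- pool[sample.int(length(pool), 1, prob = w[pool])]
      }
      lo <- pmin(a, b); hi <- pmax(a, b)
      for (t in seq_len(m)) {
        if (got >= need) break
        if (lo[t] == hi[t]) next
        key <- paste(lo[t], hi[t])
        if (!exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)
          got <- got + 1L
          extra[got, ] <- c(lo[t], hi[t])
        }
      }
    }
    el <- rbind(el, extra)
    g <- igraph::make_empty_graph(n = n_nodes, directed = FALSE)
    igraph::V(g)$name <- sprintf("n%03d", seq_len(n_nodes))
    g <- igraph::add_edges(g, t(el))
    structure(list(node_labels = igraph::V(g)$name, graph = g),
              class = "connectome")
  })
}

#' Write a graph as a two-column edge list
#'
#' Tab-separated, one edge per line, vertex names (or 1-based indices)
#' as ids. Round-trips through [load_connectome()].
#'
#' @param graph an igraph object.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_edgelist <- function(graph, path) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Validate that a graph is undirected and simple
#'
#' @param graph an igraph object.
#' @return `TRUE` (invisibly) or an error describing the violation.
#' @export
validate_simple_graph <- function(graph) {
  if (igraph::is_directed(graph)) stop_format("graph is directed")
  if (igraph::any_loop(graph)) stop_format("graph has self-loops")
  if (igraph::any_multiple(graph)) stop_format("graph has parallel edges")
  invisible(TRUE)
}
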