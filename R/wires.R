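# Nanowire deposition simulator: random 1D segments on a 2D plane and the
# junction graph they induce (nodes = wires, edges = wire-wire intersections).

#' Parameters for a simulated nanowire deposition
#'
#' Bundles and validates the parameters of one random nanowire network:
#' how many wires are dropped, the wire-length distribution (normal with
#' mean `mean_length` and standard deviation `dispersion * mean_length`,
#' resampled to be strictly positive), and the deposition plane. Wire
#' midpoints are uniform on the plane; orientations are uniform on
#' `[0, 2*pi)`. Wires may extend beyond the plane edge: only midpoints are
#' constrained.
#'
#' @param n_wires number of nanowires (>= 1).
#' @param mean_length mean wire length in micrometres.
#' @param dispersion ratio of the length standard deviation to the mean,
#'   in `[0, 1]`. 0 makes every wire exactly `mean_length` long.
#' @param plane_width,plane_height plane dimensions in micrometres.
#' @param seed integer seed making the deposition reproducible.
#' @return An object of class `wire_params`.
#' @examples
#' wire_params(100, mean_length = 7, dispersion = 0.2, seed = 1)
#' @export
wire_params <- function(n_wires, mean_length = 7, dispersion = 0,
                        plane_width = 30, plane_height = 30, seed = 1L) {
  assert_scalar_num(n_wires, "n_wires")
  assert_scalar_num(mean_length, "mean_length")
  assert_scalar_num(dispersion, "dispersion")
  assert_scalar_num(plane_width, "plane_width")
  assert_scalar_num(plane_height, "plane_height")
  assert_scalar_num(seed, "seed")
  if (n_wires < 1 || n_wires != round(n_wires)) {
    stop_param("`n_wires` must be a positive integer, got %s", n_wires)
  }
  if (mean_length <= 0) stop_param("`mean_length` must be > 0")
  if (dispersion < 0 || dispersion > 1) {
    stop_param("`dispersion` must lie in [0, 1], got %s", dispersion)
  }
  if (plane_width <= 0 || plane_height <= 0) {
    stop_param("plane dimensions must be > 0")
  }
  structure(
    list(
      n_wires = as.integer(n_wires), mean_length = mean_length,
      dispersion = dispersion, plane_width = plane_width,
      plane_height = plane_height, seed = as.integer(seed)
    ),
    class = "wire_params"
  )
}

#' @export
print.wire_params <- function(x, ...) {
  cat(sprintf(
    "Nanowire deposition parameters: %d wires, length %.3g um (dispersion %.0f%%), plane %.3g x %.3g um, seed %d\n",
    x$n_wires, x$mean_length, 100 * x$dispersion,
    x$plane_width, x$plane_height, x$seed
  ))
  invisible(x)
}

#' Sample a random nanowire deposition
#'
#' Draws `n_wires` wires: lengths from a normal distribution with the
#' configured mean and standard deviation (non-positive draws are rejected
#' and redrawn), midpoints uniform on the plane rectangle, and angles
#' uniform on `[0, 2*pi)`. Fully reproducible from the seed in `params`.
#'
#' @param params a [wire_params()] object.
#' @return A data frame with one row per wire and columns `id`, `cx`, `cy`
#'   (midpoint, micrometres), `angle` (radians) and `length` (micrometres).
#' @examples
#' wires <- sample_wires(wire_params(50, seed = 7))
#' head(wires)
#' @export
sample_wires <- function(params) {
  if (!inherits(params, "wire_params")) {
    stop_param("`params` must be created by wire_params()")
  }
  n <- params$n_wires
  local_seed_eval(params$seed, {
    len <- stats::rnorm(n, params$mean_length,
                        params$dispersion * params$mean_length)
    while (any(bad <- len <= 0)) {
      len[bad] <- stats::rnorm(sum(bad), params$mean_length,
                               params$dispersion * params$mean_length)
    }
    cx <- stats::runif(n, 0, params$plane_width)
    cy <- stats::runif(n, 0, params$plane_height)
    angle <- stats::runif(n, 0, 2 * pi)
    data.frame(id = seq_len(n), cx = cx, cy = cy, angle = angle, length = len)
  })
}

#' Endpoint coordinates of wires
#'
#' @param wires a wire table as returned by [sample_wires()].
#' @return A data frame with columns `x1, y1, x2, y2`; endpoints are
#'   midpoint +/- (length/2) (cos angle, sin angle).
#' @export
wire_endpoints <- function(wires) {
  hx <- wires$length / 2 * cos(wires$angle)
  hy <- wires$length / 2 * sin(wires$angle)
  data.frame(
    x1 = wires$cx - hx, y1 = wires$cy - hy,
    x2 = wires$cx + hx, y2 = wires$cy + hy
  )
}

#' Intersection point of two wires
#'
#' Solves the 2x2 linear system for the crossing of two 1D segments.
#' Returns the crossing point when the segments properly intersect
#' (endpoint touches within `tol` micrometres count), and `NULL` for
#' disjoint or parallel segments. Collinear overlapping segments are a
#' measure-zero event for continuously sampled wires; they yield no
#' junction and a warning, since a contact line has no unique
#' intersection point.
#'
#' @param a,b one-row wire data frames (columns `cx, cy, angle, length`).
#' @param tol endpoint tolerance in micrometres.
#' @return Named numeric `c(x, y)` or `NULL`.
#' @examples
#' w <- data.frame(id = 1:2, cx = c(1, 1), cy = c(0, 0),
#'                 angle = c(0, pi / 2), length = c(2, 2))
#' segment_intersection(w[1, ], w[2, ])
#' @export
segment_intersection <- function(a, b, tol = 1e-9) {
  ea <- wire_endpoints(a)
  eb <- wire_endpoints(b)
  dax <- ea$x2 - ea$x1; day <- ea$y2 - ea$y1
  dbx <- eb$x2 - eb$x1; dby <- eb$y2 - eb$y1
  rx <- eb$x1 - ea$x1; ry <- eb$y1 - ea$y1
  denom <- dax * dby - day * dbx
  la <- a$length; lb <- b$length
  if (abs(denom) <= 1e-12 * la * lb) {
    # parallel; check collinear overlap to warn
    if (abs(rx * day - ry * dax) <= 1e-12 * la * lb) {
      t1 <- (rx * dax + ry * day) / (la^2)
      t2 <- t1 + (dbx * dax + dby * day) / (la^2)
      if (min(t1, t2) < 1 + tol / la && max(t1, t2) > -tol / la) {
        warning("collinear overlapping wires: contact line produces no junction")
      }
    }
    return(NULL)
  }
  t <- (rx * dby - ry * dbx) / denom
  u <- (rx * day - ry * dax) / denom
  if (t < -tol / la || t > 1 + tol / la) return(NULL)
  if (u < -tol / lb || u > 1 + tol / lb) return(NULL)
  c(x = ea$x1 + t * dax, y = ea$y1 + t * day)
}

# All-pairs junction finder, vectorised and chunked. A bounding-circle
# prefilter (centre distance <= half-length sum) discards most pairs before
# the exact solve.
find_junctions <- function(wires, tol = 1e-9) {
  n <- nrow(wires)
  ep <- wire_endpoints(wires)
  out <- list()
  if (n >= 2) {
    pairs_total <- n * (n - 1) / 2
    chunk <- 2e6
    # enumerate unordered pairs (i < j) lazily by linear index
    start <- 1
    idx_i <- rep.int(seq_len(n - 1), times = (n - 1):1)
    idx_j <- sequence((n - 1):1) + idx_i
    while (start <= pairs_total) {
      stop_at <- min(start + chunk - 1, pairs_total)
      i <- idx_i[start:stop_at]; j <- idx_j[start:stop_at]
      dx <- wires$cx[i] - wires$cx[j]
      dy <- wires$cy[i] - wires$cy[j]
      reach <- (wires$length[i] + wires$length[j]) / 2 + tol
      keep <- dx * dx + dy * dy <= reach * reach
      i <- i[keep]; j <- j[keep]
      if (length(i)) {
        dax <- ep$x2[i] - ep$x1[i]; day <- ep$y2[i] - ep$y1[i]
        dbx <- ep$x2[j] - ep$x1[j]; dby <- ep$y2[j] - ep$y1[j]
        rx <- ep$x1[j] - ep$x1[i]; ry <- ep$y1[j] - ep$y1[i]
        denom <- dax * dby - day * dbx
        la <- wires$length[i]; lb <- wires$length[j]
        ok <- abs(denom) > 1e-12 * la * lb
        t <- ifelse(ok, (rx * dby - ry * dbx) / denom, NA_real_)
        u <- ifelse(ok, (rx * day - ry * dax) / denom, NA_real_)
        hit <- ok & t >= -tol / la & t <= 1 + tol / la &
          u >= -tol / lb & u <= 1 + tol / lb
        hit[is.na(hit)] <- FALSE
        if (any(hit)) {
          out[[length(out) + 1L]] <- data.frame(
            wire_a = wires$id[i[hit]], wire_b = wires$id[j[hit]],
            x = ep$x1[i[hit]] + t[hit] * dax[hit],
            y = ep$y1[i[hit]] + t[hit] * day[hit]
          )
        }
      }
      start <- stop_at + 1
    }
  }
  if (!length(out)) {
    return(data.frame(wire_a = integer(), wire_b = integer(),
                      x = numeric(), y = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$wire_a, res$wire_b), , drop = FALSE]
}

#' Build the junction graph of a nanowire deposition
#'
#' Maps a wire table to an undirected simple graph with one node per wire
#' and one edge per intersecting wire pair, under the simplifying
#' assumption that every wire-wire intersection forms a junction. Junction
#' coordinates are retained.
#'
#' @param wires a wire table as returned by [sample_wires()].
#' @param params the [wire_params()] that generated `wires` (optional,
#'   stored as provenance).
#' @param tol endpoint tolerance in micrometres.
#' @return An object of class `nanowire_network`: a list with elements
#'   `params`, `wires`, `junctions` (data frame `wire_a, wire_b, x, y`)
#'   and `graph` (an [igraph][igraph::make_empty_graph] object whose
#'   vertex names are wire ids).
#' @examples
#' net <- build_network(sample_wires(wire_params(100, seed = 3)))
#' net
#' @export
build_network <- function(wires, params = NULL, tol = 1e-9) {
  if (!is.data.frame(wires) || nrow(wires) < 1) {
    stop_param("`wires` must be a non-empty wire table")
  }
  junctions <- find_junctions(wires, tol = tol)
  g <- igraph::make_empty_graph(n = nrow(wires), directed = FALSE)
  igraph::V(g)$name <- as.character(wires$id)
  if (nrow(junctions)) {
    ids <- match(c(rbind(junctions$wire_a, junctions$wire_b)), wires$id)
    g <- igraph::add_edges(g, ids)
  }
  structure(
    list(params = params, wires = wires, junctions = junctions, graph = g),
    class = "nanowire_network"
  )
}

#' @export
print.nanowire_network <- function(x, ...) {
  cat(sprintf(
    "Nanowire network: %d wires, %d junctions, mean degree %.2f\n",
    nrow(x$wires), nrow(x$junctions),
    mean(igraph::degree(x$graph))
  ))
  invisible(x)
}

#' Simulate a nanowire deposition end to end
#'
#' Convenience wrapper: [wire_params()] -> [sample_wires()] ->
#' [build_network()].
#'
#' @inheritParams wire_params
#' @return A `nanowire_network`.
#' @export
simulate_network <- function(n_wires, mean_length = 7, dispersion = 0,
                             plane_width = 30, plane_height = 30, seed = 1L) {
  p <- wire_params(n_wires, mean_length, dispersion,
                   plane_width, plane_height, seed)
  build_network(sample_wires(p), params = p)
}

#' Generate an ensemble of nanowire networks over a parameter grid
#'
#' Crosses wire counts, mean lengths and dispersions, generating
#' `replicates` networks per combination. Per-network seeds are derived
#' from the master seed by a deterministic counter so the ensemble is
#' reproducible as a whole and each member individually re-creatable.
#'
#' @param n_wires vector of wire counts.
#' @param mean_lengths vector of mean wire lengths (micrometres).
#' @param dispersions vector of length dispersions in `[0, 1]`.
#' @param replicates networks per parameter combination.
#' @param plane_width,plane_height plane dimensions in micrometres.
#' @param seed master seed.
#' @return A list of `nanowire_network` objects; each carries its
#'   `params` (including its derived seed) as provenance.
#' @examples
#' ens <- generate_ensemble(n_wires = 100, mean_lengths = c(6, 9),
#'                          dispersions = 0, seed = 42)
#' length(ens)
#' @export
generate_ensemble <- function(n_wires, mean_lengths, dispersions,
                              replicates = 1, plane_width = 30,
                              plane_height = 30, seed = 1L) {
  grid <- expand.grid(
    n = n_wires, len = mean_lengths, disp = dispersions,
    rep = seq_len(replicates), KEEP.OUT.ATTRS = FALSE
  )
  if (!nrow(grid)) stop_param("empty parameter grid")
  lapply(seq_len(nrow(grid)), function(i) {
    simulate_network(
      n_wires = grid$n[i], mean_length = grid$len[i],
      dispersion = grid$disp[i], plane_width = plane_width,
      plane_height = plane_height, seed = derive_seed(seed, i - 1)
    )
  })
}

#' Expected junction count for a random deposition
#'
#' Buffon-type estimate of the expected number of pairwise crossings of
#' `n` randomly oriented segments of mean length `l` whose midpoints are
#' uniform on a plane of area `A`: `n (n - 1) l^2 / (pi A)`. Useful as an
#' analytic sanity check on simulated densities (boundary effects make
#' real counts deviate slightly).
#'
#' @param n_wires number of wires.
#' @param mean_length mean wire length (micrometres).
#' @param plane_width,plane_height plane dimensions (micrometres).
#' @return Expected junction count.
#' @export
expected_junctions <- function(n_wires, mean_length,
                               plane_width = 30, plane_height = 30) {
  n_wires * (n_wires - 1) * mean_length^2 /
    (pi * plane_width * plane_height)
}

#' Export a nanowire network as plain-text tables
#'
#' Writes three files into `dir`: `edges.tsv` (tab-separated node-id
#' pairs), `wires.csv` (`id,cx,cy,angle,length`) and `junctions.csv`
#' (`wire_a,wire_b,x,y`).
#'
#' @param net a `nanowire_network`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
export_network <- function(net, dir) {
  if (!inherits(net, "nanowire_network")) {
    stop_param("`net` must be a nanowire_network")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    edges = file.path(dir, "edges.tsv"),
    wires = file.path(dir, "wires.csv"),
    junctions = file.path(dir, "junctions.csv")
  )
  write_edgelist(net$graph, paths[["edges"]])
  utils::write.csv(net$wires, paths[["wires"]], row.names = FALSE)
  utils::write.csv(net$junctions, paths[["junctions"]], row.names = FALSE)
  invisible(paths)
}
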