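# Nanowire deposition simulator and junction graph extraction.

test_that("wire_params validates its arguments", {
  expect_s3_class(wire_params(10), "wire_params")
  expect_error(wire_params(0), class = "asntopo_parameter_error")
  expect_error(wire_params(10, mean_length = -1),
               class = "asntopo_parameter_error")
  expect_error(wire_params(10, dispersion = 1.2),
               class = "asntopo_parameter_error")
  expect_error(wire_params(10, plane_width = 0),
               class = "asntopo_parameter_error")
})

test_that("zero dispersion makes every wire exactly mean_length long", {
  w <- sample_wires(wire_params(3, mean_length = 8, dispersion = 0, seed = 5))
  expect_equal(nrow(w), 3)
  expect_equal(w$length, rep(8, 3))
})

test_that("sampled wires respect the plane, angle range and positivity", {
  w <- sample_wires(wire_params(500, mean_length = 7, dispersion = 0.5,
                                seed = 1))
  expect_equal(nrow(w), 500)
  expect_true(all(w$cx >= 0 & w$cx <= 30))
  expect_true(all(w$cy >= 0 & w$cy <= 30))
  expect_true(all(w$angle >= 0 & w$angle < 2 * pi))
  expect_true(all(w$length > 0))
})

test_that("sampling is reproducible from the seed", {
  p <- wire_params(200, mean_length = 7, dispersion = 0.3, seed = 42)
  expect_identical(sample_wires(p), sample_wires(p))
  p2 <- wire_params(200, mean_length = 7, dispersion = 0.3, seed = 43)
  expect_false(identical(sample_wires(p), sample_wires(p2)))
})

test_that("endpoints are midpoint +/- half-length along the angle", {
  w <- sample_wires(wire_params(50, dispersion = 0.2, seed = 9))
  ep <- wire_endpoints(w)
  len <- sqrt((ep$x2 - ep$x1)^2 + (ep$y2 - ep$y1)^2)
  expect_equal(len, w$length, tolerance = 1e-12)
  expect_equal((ep$x1 + ep$x2) / 2, w$cx, tolerance = 1e-12)
  expect_equal((ep$y1 + ep$y2) / 2, w$cy, tolerance = 1e-12)
})

as_wire <- function(x1, y1, x2, y2) {
  data.frame(
    id = 1L, cx = (x1 + x2) / 2, cy = (y1 + y2) / 2,
    angle = atan2(y2 - y1, x2 - x1) %% (2 * pi),
    length = sqrt((x2 - x1)^2 + (y2 - y1)^2)
  )
}

test_that("segment_intersection handles crossing, parallel and touching cases", {
  expect_equal(
    segment_intersection(as_wire(0, 0, 2, 0), as_wire(1, -1, 1, 1)),
    c(x = 1, y = 0), tolerance = 1e-12
  )
  expect_null(segment_intersection(as_wire(0, 0, 1, 0), as_wire(0, 1, 1, 1)))
  # disjoint on the same line through both
  expect_null(segment_intersection(as_wire(0, 0, 1, 0), as_wire(3, -1, 3, 1)))
  # exactly touching endpoints count as an intersection
  tp <- segment_intersection(as_wire(0, 0, 1, 1), as_wire(1, 1, 2, 0))
  expect_equal(tp, c(x = 1, y = 1), tolerance = 1e-9)
  # collinear overlap yields no junction, with a warning
  expect_warning(
    res <- segment_intersection(as_wire(0, 0, 2, 0), as_wire(1, 0, 3, 0)),
    "collinear"
  )
  expect_null(res)
})

test_that("segment_intersection agrees with independent crossing oracles", {
  wires <- sample_wires(wire_params(60, mean_length = 8, dispersion = 0.4,
                                    seed = 31))
  ep <- wire_endpoints(wires)
  pairs <- t(utils::combn(60, 2))
  withr::with_seed(7, pairs <- pairs[sample(nrow(pairs), 300), ])
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    pt <- segment_intersection(wires[i, ], wires[j, ])
    expect_identical(!is.null(pt), segments_cross_oracle(ep[i, ], ep[j, ]),
                     info = sprintf("pair (%d, %d)", i, j))
    gap <- point_sampling_cross_oracle(ep[i, ], ep[j, ])
    if (!is.null(pt)) {
      expect_lt(gap, 1e-2) # dense sampling approaches the crossing
      # the returned point lies on both segments
      for (e in list(ep[i, ], ep[j, ])) {
        d <- point_sampling_cross_oracle(
          data.frame(x1 = pt[["x"]], y1 = pt[["y"]],
                     x2 = pt[["x"]], y2 = pt[["y"]]), e, n_points = 2
        )
        expect_lt(d, 1e-9)
      }
    } else {
      expect_gt(gap, 1e-9)
    }
  }
})

test_that("build_network matches the brute-force pairwise oracle", {
  for (seed in 1:5) {
    wires <- sample_wires(wire_params(80, mean_length = 7,
                                      dispersion = 0.3, seed = seed))
    net <- build_network(wires)
    expect_equal(igraph::ecount(net$graph), junction_count_oracle(wires))
    expect_equal(igraph::vcount(net$graph), 80)
    validate_simple_graph(net$graph)
    # junction coordinates lie on both parent segments
    ep <- wire_endpoints(wires)
    for (r in seq_len(min(nrow(net$junctions), 50))) {
      jr <- net$junctions[r, ]
      pt <- data.frame(x1 = jr$x, y1 = jr$y, x2 = jr$x, y2 = jr$y)
      expect_lt(point_sampling_cross_oracle(pt, ep[jr$wire_a, ],
                                            n_points = 2), 1e-8)
      expect_lt(point_sampling_cross_oracle(pt, ep[jr$wire_b, ],
                                            n_points = 2), 1e-8)
    }
    expect_true(all(net$junctions$wire_a < net$junctions$wire_b))
    expect_false(any(duplicated(net$junctions[, c("wire_a", "wire_b")])))
  }
})

test_that("two crossing wires give 2 nodes and 1 edge; empty input errors", {
  w <- rbind(as_wire(0, 0, 2, 0), as_wire(1, -1, 1, 1))
  w$id <- 1:2
  net <- build_network(w)
  expect_equal(igraph::vcount(net$graph), 2)
  expect_equal(igraph::ecount(net$graph), 1)
  expect_error(build_network(data.frame()), class = "asntopo_parameter_error")
})

test_that("ensemble junction counts track the Buffon-type estimate", {
  # wires extending past the plane edge depress crossing counts ~10-13%
  # below the unbounded-plane estimate, so the mean needs enough seeds to
  # resolve that the deficit stays inside the 15% band
  seeds <- list(`100` = 1:200, `500` = 1:40)
  for (n in c(100, 500)) {
    counts <- vapply(seeds[[as.character(n)]], function(s) {
      nrow(simulate_network(n, 8, 0, seed = s)$junctions)
    }, numeric(1))
    expect_lt(abs(mean(counts) / expected_junctions(n, 8) - 1), 0.15)
  }
})

test_that("mean junction count increases strictly with mean wire length", {
  mean_count <- function(l) {
    mean(vapply(1:10, function(s) {
      nrow(simulate_network(150, l, 0, seed = s)$junctions)
    }, numeric(1)))
  }
  counts <- vapply(c(6, 7, 8, 9), mean_count, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("generate_ensemble crosses the grid and is seed-reproducible", {
  ens <- generate_ensemble(n_wires = c(20, 50), mean_lengths = c(6, 9),
                           dispersions = c(0, 0.5), seed = 3)
  expect_length(ens, 8)
  prov <- vapply(ens, function(x) {
    paste(x$params$n_wires, x$params$mean_length, x$params$dispersion)
  }, character(1))
  expect_equal(length(unique(prov)), 8)
  ens2 <- generate_ensemble(n_wires = c(20, 50), mean_lengths = c(6, 9),
                            dispersions = c(0, 0.5), seed = 3)
  expect_identical(
    lapply(ens, function(x) x$junctions),
    lapply(ens2, function(x) x$junctions)
  )
  expect_error(generate_ensemble(integer(), 7, 0),
               class = "asntopo_parameter_error")
})

test_that("export_network round-trips through the edge-list loader", {
  net <- simulate_network(60, 8, 0.2, seed = 8)
  dir <- withr::local_tempdir()
  paths <- export_network(net, dir)
  expect_true(all(file.exists(paths)))
  conn <- load_connectome(paths[["edges"]])
  expect_equal(igraph::ecount(conn$graph), igraph::ecount(net$graph))
  # same edges as sets of id pairs
  canon <- function(g) {
    el <- igraph::as_edgelist(g)
    el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    el[order(as.numeric(el[, 1]), as.numeric(el[, 2])), ]
  }
  expect_equal(canon(conn$graph), canon(net$graph))
})
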