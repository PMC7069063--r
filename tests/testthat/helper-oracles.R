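# Independent oracles used across the suite. Deliberately different
# algorithms from the package implementation so agreement is evidence,
# not tautology.

# Orientation-predicate segment-crossing test (ccw sign changes), used to
# cross-check the linear-solve junction finder on generic (non-degenerate)
# inputs.
ccw <- function(ax, ay, bx, by, cx, cy) {
  sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
}

segments_cross_oracle <- function(e1, e2) {
  d1 <- ccw(e2$x1, e2$y1, e2$x2, e2$y2, e1$x1, e1$y1)
  d2 <- ccw(e2$x1, e2$y1, e2$x2, e2$y2, e1$x2, e1$y2)
  d3 <- ccw(e1$x1, e1$y1, e1$x2, e1$y2, e2$x1, e2$y1)
  d4 <- ccw(e1$x1, e1$y1, e1$x2, e1$y2, e2$x2, e2$y2)
  d1 != d2 && d3 != d4
}

# Brute-force O(n^2) junction count via the orientation oracle.
junction_count_oracle <- function(wires) {
  ep <- wire_endpoints(wires)
  n <- nrow(wires)
  cnt <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (segments_cross_oracle(ep[i, ], ep[j, ])) cnt <- cnt + 1L
    }
  }
  cnt
}

# Dense point-sampling crossing oracle: sample points along segment a and
# test distance to segment b.
point_sampling_cross_oracle <- function(e1, e2, n_points = 4001, tol = 1e-6) {
  t <- seq(0, 1, length.out = n_points)
  px <- e1$x1 + t * (e1$x2 - e1$x1)
  py <- e1$y1 + t * (e1$y2 - e1$y1)
  dx <- e2$x2 - e2$x1
  dy <- e2$y2 - e2$y1
  len2 <- dx^2 + dy^2
  u <- pmin(1, pmax(0, ((px - e2$x1) * dx + (py - e2$y1) * dy) / len2))
  qx <- e2$x1 + u * dx
  qy <- e2$y1 + u * dy
  min(sqrt((px - qx)^2 + (py - qy)^2))
}

# All-pairs shortest paths by Floyd-Warshall on the adjacency matrix.
floyd_warshall_oracle <- function(g) {
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(a)
  d <- ifelse(a > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  }
  d
}

# Hand-rolled modularity Q = sum_s (e_ss/m - (d_s/2m)^2).
modularity_oracle <- function(g, memb) {
  m <- igraph::ecount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  deg <- igraph::degree(g)
  q <- 0
  for (s in unique(memb)) {
    within <- sum(memb[el[, 1]] == s & memb[el[, 2]] == s)
    ds <- sum(deg[memb == s])
    q <- q + within / m - (ds / (2 * m))^2
  }
  q
}

# Exhaustive modularity maximisation over all set partitions (restricted
# growth strings); only feasible for tiny graphs.
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxid) {
    i <- length(prefix) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (v in seq_len(maxid + 1L)) {
      rec(c(prefix, v), max(maxid, v))
    }
  }
  rec(integer(), 0L)
  out
}

best_partition_oracle <- function(g) {
  n <- igraph::vcount(g)
  stopifnot(n <= 9)
  best_q <- -Inf
  best <- NULL
  for (p in all_partitions(n)) {
    q <- modularity_oracle(g, p)
    if (q > best_q) {
      best_q <- q
      best <- p
    }
  }
  list(membership = best, q = best_q)
}

# One-way ANOVA F from raw sums of squares.
anova_f_oracle <- function(groups) {
  values <- unlist(groups)
  grand <- mean(values)
  ss_between <- sum(vapply(groups, function(g) {
    length(g) * (mean(g) - grand)^2
  }, numeric(1)))
  ss_within <- sum(vapply(groups, function(g) {
    sum((g - mean(g))^2)
  }, numeric(1)))
  df_b <- length(groups) - 1
  df_w <- length(values) - length(groups)
  (ss_between / df_b) / (ss_within / df_w)
}

# Small random connected-ish graph fixture.
random_test_graph <- function(n, p = 0.15, seed = 1) {
  withr::with_seed(seed, igraph::sample_gnp(n, p))
}
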