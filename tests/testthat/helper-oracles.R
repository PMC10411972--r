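# Independent brute-force oracles used across tests. These re-derive the
# quantities from the raw node table, without calling the package's
# implementation paths.

# segment endpoints for dendritic edges, straight from the node table
raw_dend_segments <- function(m) {
  non_root <- m$parent_id != -1L
  child <- m[non_root & m$node_kind == "dendrite", ]
  pidx <- match(child$parent_id, m$id)
  list(a = cbind(m$x[pidx], m$y[pidx], m$z[pidx]),
       b = cbind(child$x, child$y, child$z))
}

raw_soma_center <- function(m) {
  s <- m[m$node_kind == "soma", ]
  c(mean(s$x), mean(s$y), mean(s$z))
}

# Sholl counts by dense sampling of the distance profile along each segment:
# a crossing of radius r is a sign change of d(t) - r along t in [0, 1].
oracle_sholl <- function(m, step, npts = 4001) {
  seg <- raw_dend_segments(m)
  ctr <- raw_soma_center(m)
  tgrid <- seq(0, 1, length.out = npts)
  dmax <- 0
  dists <- vector("list", nrow(seg$a))
  for (i in seq_len(nrow(seg$a))) {
    p <- outer(1 - tgrid, seg$a[i, ]) + outer(tgrid, seg$b[i, ])
    d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
    dists[[i]] <- d
    dmax <- max(dmax, d[1], d[npts])
  }
  radii <- seq(step, by = step, length.out = max(1, ceiling(dmax / step)))
  counts <- vapply(radii, function(r) {
    tot <- 0L
    for (d in dists) {
      below <- d < r
      tot <- tot + sum(below[-length(below)] != below[-1])
    }
    tot
  }, integer(1))
  list(radii = radii, counts = counts)
}

# convex hull area via gift wrapping (independent of grDevices::chull)
oracle_hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  if (n < 3) return(0)
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    q <- if (p == n) 1L else p + 1L
    for (r in seq_len(n)) {
      cr <- (pts[q, 1] - pts[p, 1]) * (pts[r, 2] - pts[p, 2]) -
            (pts[q, 2] - pts[p, 2]) * (pts[r, 1] - pts[p, 1])
      if (cr < 0) q <- r
    }
    if (q == start) break
    hull <- c(hull, q)
    if (length(hull) > n) break
  }
  xs <- pts[hull, 1]; ys <- pts[hull, 2]
  abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
}

# total dendritic cable length straight from the node table
oracle_dend_length <- function(m) {
  seg <- raw_dend_segments(m)
  sum(sqrt(rowSums((seg$b - seg$a)^2)))
}

# bilinear interpolation on a grid (for contour residual checks)
bilinear_at <- function(ex, ih, z, x, y) {
  i <- findInterval(x, ex, all.inside = TRUE)
  j <- findInterval(y, ih, all.inside = TRUE)
  fx <- (x - ex[i]) / (ex[i + 1] - ex[i])
  fy <- (y - ih[j]) / (ih[j + 1] - ih[j])
  z[cbind(i, j)] * (1 - fx) * (1 - fy) + z[cbind(i + 1, j)] * fx * (1 - fy) +
    z[cbind(i, j + 1)] * (1 - fx) * fy + z[cbind(i + 1, j + 1)] * fx * fy
}

# column-wise equality of two morphologies (ignoring label/provenance)
expect_same_nodes <- function(a, b) {
  for (cl in c("id", "parent_id", "node_kind", "x", "y", "z", "radius")) {
    testthat::expect_identical(a[[cl]], b[[cl]])
  }
}

# small random test trees (valid, soma-rooted, branching)
random_test_tree <- function(seed) {
  synthesize_morphology(
    morph_params(n_primary = (seed %% 3) + 2, branch_length_mean = 35,
                 branch_length_sd = 10, p_branch = 0.6, max_depth = 4,
                 target_length = 500, tolerance = 0.4, node_spacing = 8),
    seed = seed)
}

# a small passive model: sphere soma, no channels
passive_sphere_model <- function(g_leak = 5e-5, e_leak = -80, radius = 7) {
  m <- morphology(tibble::tibble(id = 1L, parent_id = -1L, node_kind = "soma",
                                 x = 0, y = 0, z = 0, radius = radius))
  spec <- default_model_spec()
  spec$channels <- list()
  spec$passive <- passive_spec(leak_conductance = g_leak, leak_reversal = e_leak)
  discretize(m, spec)
}

# soma + one dendritic cylinder compartment, passive (for the 2-comp oracle)
passive_two_comp_model <- function(g_leak = 5e-5, e_leak = -80) {
  m <- morphology(tibble::tibble(
    id = 1:2, parent_id = c(-1L, 1L), node_kind = c("soma", "dendrite"),
    x = c(0, 50), y = 0, z = 0, radius = c(7, 1)))
  spec <- default_model_spec()
  spec$channels <- list()
  spec$passive <- passive_spec(leak_conductance = g_leak, leak_reversal = e_leak)
  discretize(m, spec, max_seg_length_um = 50)
}

# default-spec spiking test cell (morphology fixed across tests)
spiking_test_model <- function() {
  m <- synthesize_morphology(morph_preset("wt"), seed = 42)
  suppressMessages(discretize(m, default_model_spec(), 20))
}
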