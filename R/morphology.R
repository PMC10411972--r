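#' Construct a morphology from a node table
#'
#' A morphology is a rooted tree of 3D points with radii, the standard SWC
#' representation of a reconstructed neuron. Each row is one node; every node
#' except the root points at an earlier row through `parent_id`. All
#' coordinates and radii are in micrometres.
#'
#' @param nodes A data frame with columns `id`, `parent_id`, `node_kind`
#'   (one of `"soma"`, `"dendrite"`, `"axon"`), `x`, `y`, `z`, `radius`.
#' @param label Free-text label (e.g. a genotype tag).
#' @param provenance Either `"reconstructed"` or `"synthetic"`.
#' @return A tibble of class `msn_morphology`.
#' @export
morphology <- function(nodes, label = "", provenance = c("synthetic", "reconstructed")) {
  provenance <- match.arg(provenance)
  req <- c("id", "parent_id", "node_kind", "x", "y", "z", "radius")
  missing_cols <- setdiff(req, names(nodes))
  if (length(missing_cols) > 0) {
    abort(paste0("morphology nodes lack columns: ", paste(missing_cols, collapse = ", ")))
  }
  nodes <- as_tibble(nodes)[req]
  nodes$id <- as.integer(nodes$id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  out <- new_tibble(nodes, label = label, provenance = provenance,
                    class = "msn_morphology")
  validate_morphology(out)
  out
}

#' @export
print.msn_morphology <- function(x, ...) {
  cat(sprintf("<morphology> %d nodes (%d soma, %d dendrite, %d axon), label '%s', %s\n",
              nrow(x), sum(x$node_kind == "soma"), sum(x$node_kind == "dendrite"),
              sum(x$node_kind == "axon"), attr(x, "label") %||% "",
              attr(x, "provenance") %||% "unknown"))
  cat(sprintf("  total dendritic length: %.1f um\n", total_dendritic_length(x)))
  NextMethod()
}

#' Validate morphology invariants
#'
#' Checks id uniqueness, single root, topological ordering of parents,
#' positive radii, presence of a soma, and non-zero cable length.
#'
#' @param m A morphology.
#' @return `m`, invisibly. Errors on violation.
#' @export
validate_morphology <- function(m) {
  if (anyDuplicated(m$id)) abort("morphology ids are not unique")
  roots <- which(m$parent_id == -1L)
  if (length(roots) != 1L) {
    abort(sprintf("morphology must have exactly one root, found %d", length(roots)))
  }
  kinds <- unique(m$node_kind)
  bad <- setdiff(kinds, c("soma", "dendrite", "axon"))
  if (length(bad) > 0) abort(paste0("unknown node_kind: ", paste(bad, collapse = ", ")))
  if (any(m$radius <= 0)) abort("all radii must be > 0")
  # every parent must reference an earlier-listed id (guarantees a connected tree)
  pos <- match(m$parent_id, m$id)
  non_root <- m$parent_id != -1L
  if (any(non_root & is.na(pos))) {
    first <- which(non_root & is.na(pos))[1]
    abort(sprintf("node %d references undefined parent %d", m$id[first], m$parent_id[first]))
  }
  rows <- seq_len(nrow(m))
  if (any(pos[non_root] >= rows[non_root])) {
    abort("every parent_id must reference an earlier-listed node")
  }
  if (!any(m$node_kind == "soma")) abort("morphology contains no soma node")
  if (nrow(m) > 1 && total_cable_length(m) <= 0) abort("total cable length must be > 0")
  invisible(m)
}

#' Read an SWC morphology file
#'
#' Parses the standard 7-column SWC dialect (`id type x y z radius parent`,
#' `#` comments). Type codes are mapped 1 = soma, 2 = axon, 3 = dendrite;
#' any other code is treated as dendrite with a warning.
#'
#' @param path Path to an SWC file.
#' @param label Optional label; defaults to the file name.
#' @return A morphology tibble.
#' @export
read_swc <- function(path, label = basename(path)) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) abort("SWC file contains no data lines")
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  n_fields <- lengths(fields)
  if (any(n_fields != 7L)) {
    bad <- keep[which(n_fields != 7L)[1]]
    abort(sprintf("malformed SWC line %d: expected 7 columns, got %d",
                  bad, n_fields[which(n_fields != 7L)[1]]))
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 7, byrow = TRUE)
  if (anyNA(mat)) {
    bad_row <- which(apply(mat, 1, anyNA))[1]
    abort(sprintf("malformed SWC line %d: non-numeric field", keep[bad_row]))
  }
  type_code <- as.integer(mat[, 2])
  kind <- rep("dendrite", nrow(mat))
  kind[type_code == 1L] <- "soma"
  kind[type_code == 2L] <- "axon"
  unknown <- !(type_code %in% c(1L, 2L, 3L))
  if (any(unknown)) {
    warn(sprintf("%d node(s) with unknown SWC type code mapped to dendrite", sum(unknown)))
  }
  morphology(
    tibble(id = as.integer(mat[, 1]), parent_id = as.integer(mat[, 7]),
           node_kind = kind, x = mat[, 3], y = mat[, 4], z = mat[, 5],
           radius = mat[, 6]),
    label = label, provenance = "reconstructed"
  )
}

#' Write a morphology to an SWC file
#'
#' Numeric fields are written with full double precision so that
#' `read_swc(write_swc(m))` reproduces `m` exactly.
#'
#' @param m A morphology.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(m, path) {
  validate_morphology(m)
  code <- c(soma = 1L, axon = 2L, dendrite = 3L)[m$node_kind]
  body <- sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                  m$id, code, m$x, m$y, m$z, m$radius, m$parent_id)
  ok <- tryCatch({
    writeLines(c("# SWC morphology (id type x y z radius parent)", body), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort(paste0("cannot write SWC file: ", path))
  invisible(path)
}

## ---- internal geometry helpers ----

soma_center <- function(m) {
  s <- m[m$node_kind == "soma", ]
  c(x = mean(s$x), y = mean(s$y), z = mean(s$z))
}

# one row per (non-root) node/parent edge with endpoint coordinates and length
morph_segments <- function(m, kinds = NULL) {
  non_root <- m$parent_id != -1L
  child <- m[non_root, ]
  pidx <- match(child$parent_id, m$id)
  seg <- tibble(
    child_id = child$id, kind = child$node_kind,
    x0 = m$x[pidx], y0 = m$y[pidx], z0 = m$z[pidx],
    x1 = child$x, y1 = child$y, z1 = child$z,
    r0 = m$radius[pidx], r1 = child$radius
  )
  seg$length <- sqrt((seg$x1 - seg$x0)^2 + (seg$y1 - seg$y0)^2 + (seg$z1 - seg$z0)^2)
  if (!is.null(kinds)) seg <- seg[seg$kind %in% kinds, ]
  seg
}

total_cable_length <- function(m) sum(morph_segments(m)$length)

#' Total dendritic cable length
#'
#' Sum of inter-node distances over all segments whose child node is a
#' dendrite, in micrometres.
#'
#' @param m A morphology.
#' @return Length in micrometres.
#' @export
total_dendritic_length <- function(m) sum(morph_segments(m, "dendrite")$length)

## ---- Sholl analysis ----

# Number of times each segment's centre-distance profile crosses radius r.
# The distance from a fixed point along a straight segment is unimodal, so a
# segment crosses a sphere 0, 1 or 2 times: once if exactly one endpoint lies
# inside (strictly < r; the far endpoint at >= r counts), twice if both
# endpoints are at >= r but the interior dips below r. Tangency is not counted.
segment_crossings <- function(d0, d1, dmin, r) {
  one <- (d0 < r & d1 >= r) | (d1 < r & d0 >= r)
  two <- d0 >= r & d1 >= r & dmin < r
  as.integer(one) + 2L * as.integer(two)
}

seg_distances <- function(seg, center, projection = "3d") {
  if (projection == "2d") {
    p0 <- cbind(seg$x0, seg$y0); p1 <- cbind(seg$x1, seg$y1)
    ctr <- center[c("x", "y")]
  } else {
    p0 <- cbind(seg$x0, seg$y0, seg$z0); p1 <- cbind(seg$x1, seg$y1, seg$z1)
    ctr <- center
  }
  a <- sweep(p0, 2, ctr); b <- sweep(p1, 2, ctr)
  d0 <- sqrt(rowSums(a^2)); d1 <- sqrt(rowSums(b^2))
  ab <- b - a
  len2 <- rowSums(ab^2)
  tstar <- ifelse(len2 > 0, pmin(pmax(-rowSums(a * ab) / len2, 0), 1), 0)
  pm <- a + ab * tstar
  dmin <- sqrt(rowSums(pm^2))
  list(d0 = d0, d1 = d1, dmin = pmin(dmin, d0, d1))
}

#' Sholl profile of a morphology
#'
#' Counts dendritic segment crossings of concentric spheres (or circles, for
#' the 2D projected variant) centred at the soma centroid, at radii
#' `step_um, 2 step_um, ...` out to the dendritic extent. A segment that
#' enters and leaves a shell is counted once per crossing.
#'
#' @param m A morphology.
#' @param step_um Shell spacing in micrometres (> 0).
#' @param projection `"3d"` (Euclidean distance, default) or `"2d"`
#'   (xy-projected distance).
#' @return A tibble of class `msn_sholl` with columns `radius` and `count`,
#'   plus attributes `step` and `center`.
#' @export
sholl <- function(m, step_um = 10, projection = c("3d", "2d")) {
  projection <- match.arg(projection)
  if (!is.numeric(step_um) || step_um <= 0) abort("step_um must be > 0")
  if (!any(m$node_kind == "soma")) abort("morphology has no soma node")
  seg <- morph_segments(m, "dendrite")
  ctr <- soma_center(m)
  if (nrow(seg) == 0) {
    out <- tibble(radius = step_um, count = 0L)
  } else {
    d <- seg_distances(seg, ctr, projection)
    rmax <- max(d$d0, d$d1)
    radii <- seq(step_um, by = step_um, length.out = max(1L, ceiling(rmax / step_um)))
    counts <- vapply(radii, function(r) sum(segment_crossings(d$d0, d$d1, d$dmin, r)),
                     integer(1))
    out <- tibble(radius = radii, count = counts)
  }
  new_tibble(out, step = step_um, center = ctr, projection = projection,
             class = "msn_sholl")
}

#' Count-weighted centroid of a Sholl profile
#'
#' The "centre of mass" of the Sholl plot: the intersection-count-weighted
#' mean shell radius, in micrometres.
#'
#' @param profile An `msn_sholl` tibble (or any data frame with `radius` and
#'   `count` columns).
#' @return Centroid radius in micrometres.
#' @export
sholl_centroid <- function(profile) {
  if (sum(profile$count) <= 0) abort("Sholl profile has no intersections; centroid undefined")
  sum(profile$radius * profile$count) / sum(profile$count)
}

#' Maximum dendritic Sholl radius
#'
#' Largest shell radius with at least one intersection.
#'
#' @inheritParams sholl_centroid
#' @return Radius in micrometres.
#' @export
sholl_max_radius <- function(profile) {
  if (sum(profile$count) <= 0) abort("Sholl profile has no intersections; max radius undefined")
  max(profile$radius[profile$count > 0])
}

#' Neuropil coverage area
#'
#' Area of the 2D convex hull of the dendritic nodes projected onto the
#' xy-plane, in square micrometres. This is a reproducible surrogate for the
#' shaded "mean coverage area" of overlaid polar reconstruction plots.
#' Degenerate (collinear) morphologies return 0 with a warning.
#'
#' @param m A morphology.
#' @return Area in square micrometres.
#' @export
coverage_area <- function(m) {
  d <- m[m$node_kind == "dendrite", ]
  if (nrow(d) < 3) abort("coverage_area needs at least 3 dendritic nodes")
  h <- grDevices::chull(d$x, d$y)
  if (length(h) < 3) {
    warn("dendritic nodes are collinear in the xy-plane; coverage area is 0")
    return(0)
  }
  xs <- d$x[h]; ys <- d$y[h]
  a <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  if (a == 0) warn("dendritic nodes are collinear in the xy-plane; coverage area is 0")
  a
}

## ---- branch decomposition ----

# maximal unbranched dendritic paths: a branch starts at a dendritic node
# whose parent is non-dendritic (soma) or a dendritic branching point, and
# runs to the next branching point or tip.
dendritic_branches <- function(m) {
  seg <- morph_segments(m, "dendrite")
  if (nrow(seg) == 0) {
    return(list(n_branches = 0L, n_branching_points = 0L, lengths = numeric(0)))
  }
  idx <- match(m$id, m$id)
  is_dend <- m$node_kind == "dendrite"
  parent_pos <- match(m$parent_id, m$id)
  # number of dendritic children per node position
  n_dend_children <- tabulate(parent_pos[is_dend & m$parent_id != -1L], nbins = nrow(m))
  branching <- is_dend & n_dend_children >= 2L
  seg_len <- setNames(seg$length, seg$child_id)
  starts <- which(is_dend & m$parent_id != -1L &
                    (!is_dend[parent_pos] | branching[parent_pos]))
  # root dendrite (a dendritic root would be unusual but legal)
  child_of <- split(which(is_dend & m$parent_id != -1L), parent_pos[is_dend & m$parent_id != -1L])
  lengths <- vapply(starts, function(s) {
    total <- seg_len[[as.character(m$id[s])]]
    cur <- s
    while (!branching[cur]) {
      kids <- child_of[[as.character(cur)]]
      if (is.null(kids) || length(kids) == 0L) break
      cur <- kids[1]
      total <- total + seg_len[[as.character(m$id[cur])]]
    }
    total
  }, numeric(1))
  list(n_branches = length(starts), n_branching_points = sum(branching),
       lengths = lengths)
}

#' Branch and arbor metrics of a morphology
#'
#' Decomposes the dendritic arbor into maximal unbranched paths (between the
#' soma, branching points with two or more dendritic children, and tips) and
#' returns a one-row summary: total dendritic length, number of branches and
#' branching points, mean branch length, maximum Sholl radius, Sholl
#' centroid, and xy convex-hull coverage area.
#'
#' @param m A morphology.
#' @param sholl_step_um Shell spacing used for the radius/centroid columns.
#' @return A one-row tibble.
#' @export
branch_metrics <- function(m, sholl_step_um = 10) {
  validate_morphology(m)
  br <- dendritic_branches(m)
  total_len <- total_dendritic_length(m)
  prof <- sholl(m, sholl_step_um)
  has_int <- sum(prof$count) > 0
  n_dend <- sum(m$node_kind == "dendrite")
  tibble(
    label = attr(m, "label") %||% "",
    total_dendritic_length = total_len,
    n_branches = br$n_branches,
    n_branching_points = br$n_branching_points,
    mean_branch_length = if (br$n_branches > 0) total_len / br$n_branches else 0,
    max_radius = if (has_int) sholl_max_radius(prof) else 0,
    centroid = if (has_int) sholl_centroid(prof) else 0,
    coverage_area = if (n_dend >= 3) tryCatch(suppressWarnings(coverage_area(m)),
                                              error = function(e) 0) else 0
  )
}

#' Estimate total spine number
#'
#' Spine number is the product of linear spine density and total dendritic
#' length; returned unrounded.
#'
#' @param spine_density_per_um Spines per micrometre (>= 0).
#' @param total_dendritic_length_um Dendritic length in micrometres (>= 0).
#' @return Estimated spine count (real-valued).
#' @export
estimate_spine_number <- function(spine_density_per_um, total_dendritic_length_um) {
  if (spine_density_per_um < 0 || total_dendritic_length_um < 0) {
    abort("spine density and dendritic length must be non-negative")
  }
  spine_density_per_um * total_dendritic_length_um
}

## ---- synthetic morphologies ----

#' Parameters for the synthetic morphology generator
#'
#' @param n_primary Number of primary dendrites leaving the soma.
#' @param branch_length_mean,branch_length_sd Branch length distribution (um).
#' @param p_branch Probability that a completed branch bifurcates.
#' @param max_depth Maximum branch order.
#' @param target_length Target total dendritic length (um).
#' @param tolerance Relative tolerance on the realized total length.
#' @param soma_radius Soma radius (um).
#' @param node_spacing Approximate spacing of nodes along a branch (um).
#' @param dendrite_radius Dendritic shaft radius (um).
#' @param max_attempts Number of regrowth attempts before failing.
#' @return A list of class `morph_params`.
#' @export
morph_params <- function(n_primary = 4, branch_length_mean = 45,
                         branch_length_sd = 12, p_branch = 0.55, max_depth = 5,
                         target_length = 2000, tolerance = 0.1,
                         soma_radius = 7, node_spacing = 10,
                         dendrite_radius = 0.6, max_attempts = 50) {
  structure(as.list(environment()), class = "morph_params")
}

#' Genotype presets for the synthetic morphology generator
#'
#' The `"ko"` preset (glutamate-transporter knockout) encodes the reported
#' direction of the genotype effect on D1-MSN dendrites: roughly twofold
#' larger total dendritic length, more primary dendrites and branching, and
#' a larger radial extent than `"wt"`.
#'
#' @param genotype `"wt"` or `"ko"`.
#' @return A `morph_params` list.
#' @export
morph_preset <- function(genotype = c("wt", "ko")) {
  genotype <- match.arg(genotype)
  switch(genotype,
    wt = morph_params(n_primary = 4, p_branch = 0.55, max_depth = 5,
                      target_length = 2000),
    ko = morph_params(n_primary = 5, p_branch = 0.70, max_depth = 6,
                      target_length = 4000)
  )
}

# rotate unit vector v by angle theta about a random perpendicular axis
jitter_direction <- function(v, theta) {
  # random unit vector not parallel to v
  repeat {
    u <- rnorm(3)
    u <- u - sum(u * v) * v
    nu <- sqrt(sum(u^2))
    if (nu > 1e-8) { u <- u / nu; break }
  }
  cos(theta) * v + sin(theta) * u
}

#' Generate a synthetic dendritic morphology
#'
#' Grows a stochastic binary-branching dendritic tree from a spherical soma.
#' Branch lengths are drawn from a truncated normal; each completed branch
#' bifurcates with probability `p_branch` up to `max_depth`. Growth stops
#' once the target total dendritic length is reached; trees whose realized
#' length falls outside the stated tolerance are regrown (up to
#' `max_attempts`, then an error is raised). The same seed always produces
#' the identical node list.
#'
#' @param params A `morph_params` list (see [morph_params()], [morph_preset()]).
#' @param seed Integer seed.
#' @param label Label stored on the result.
#' @return A morphology tibble with provenance `"synthetic"`.
#' @export
synthesize_morphology <- function(params = morph_params(), seed = 1,
                                  label = "synthetic") {
  stopifnot(inherits(params, "morph_params"))
  with_preserved_seed({
    for (attempt in seq_len(params$max_attempts)) {
      set.seed(as.integer(seed) + (attempt - 1L) * 7919L)
      m <- grow_tree(params)
      tot <- sum(m$seg_length[m$node_kind == "dendrite"], na.rm = TRUE)
      lo <- params$target_length * (1 - params$tolerance)
      hi <- params$target_length * (1 + params$tolerance)
      if (tot >= lo && tot <= hi) {
        m$seg_length <- NULL
        return(morphology(m, label = label, provenance = "synthetic"))
      }
    }
    abort(sprintf(
      "could not grow a tree with total length %.0f um within %.0f%% in %d attempts",
      params$target_length, 100 * params$tolerance, params$max_attempts))
  })
}

grow_tree <- function(p) {
  nodes <- list(tibble(id = 1L, parent_id = -1L, node_kind = "soma",
                       x = 0, y = 0, z = 0, radius = p$soma_radius,
                       seg_length = 0))
  next_id <- 2L
  total_len <- 0
  # primary directions: evenly spread azimuths with jitter
  az <- seq(0, 2 * pi, length.out = p$n_primary + 1)[-(p$n_primary + 1)]
  queue <- lapply(seq_len(p$n_primary), function(i) {
    elev <- runif(1, -pi / 6, pi / 6)
    a <- az[i] + runif(1, -0.3, 0.3)
    list(parent = 1L,
         origin = c(0, 0, 0),
         dir = c(cos(elev) * cos(a), cos(elev) * sin(a), sin(elev)),
         depth = 1L)
  })
  while (length(queue) > 0 && total_len < p$target_length) {
    item <- queue[[1]]; queue <- queue[-1]
    blen <- max(p$node_spacing,
                rnorm(1, p$branch_length_mean, p$branch_length_sd))
    n_seg <- max(1L, round(blen / p$node_spacing))
    seg_len <- blen / n_seg
    pos <- item$origin
    parent <- item$parent
    dir <- item$dir
    for (s in seq_len(n_seg)) {
      dir <- jitter_direction(dir / sqrt(sum(dir^2)), runif(1, 0, 0.15))
      pos <- pos + dir * seg_len
      nodes[[length(nodes) + 1]] <- tibble(
        id = next_id, parent_id = parent, node_kind = "dendrite",
        x = pos[1], y = pos[2], z = pos[3],
        radius = max(0.3, p$dendrite_radius * (1 - 0.08 * item$depth)),
        seg_length = seg_len)
      parent <- next_id
      next_id <- next_id + 1L
      total_len <- total_len + seg_len
      if (total_len >= p$target_length) break
    }
    if (total_len >= p$target_length) break
    if (item$depth < p$max_depth && runif(1) < p$p_branch) {
      for (k in 1:2) {
        theta <- runif(1, 0.35, 0.8)
        queue[[length(queue) + 1]] <- list(parent = parent, origin = pos,
                                           dir = jitter_direction(dir, theta),
                                           depth = item$depth + 1L)
      }
    }
  }
  dplyr::bind_rows(nodes)
}

# run code with the global RNG state saved and restored
with_preserved_seed <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Plot a Sholl profile
#'
#' @param object An `msn_sholl` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot msn_sholl
#' @export
autoplot.msn_sholl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$radius, y = .data$count)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "distance from soma (µm)", y = "intersections") +
    ggplot2::theme_minimal()
}
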