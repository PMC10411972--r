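test_that("SWC parsing handles the 3-node straight dendrite and errors", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# comment",
               "1 1 0 0 0 7 -1",
               "2 3 10 0 0 0.5 1",
               "3 3 25 0 0 0.5 2"), f)
  m <- read_swc(f)
  expect_s3_class(m, "msn_morphology")
  expect_equal(nrow(m), 3)
  expect_equal(total_dendritic_length(m), 10 + 15)

  writeLines(c("1 1 0 0 0 7 -1", "2 3 10 0 0 0.5 99"), f)
  expect_error(read_swc(f), "undefined parent")
  writeLines(c("1 1 0 0 0 7 -1", "2 3 10 0 0 0.5"), f)
  expect_error(read_swc(f), "7 columns")
  writeLines(c("1 1 0 0 0 7 -1", "2 3 10 0 0 0.5 1", "3 1 0 0 0 7 -1"), f)
  expect_error(read_swc(f), "exactly one root")
})

test_that("SWC round trip preserves every field on random trees", {
  f <- withr::local_tempfile(fileext = ".swc")
  for (seed in 1:5) {
    m <- random_test_tree(seed)
    write_swc(m, f)
    m2 <- read_swc(f)
    expect_same_nodes(m2, m)
    expect_equal(nrow(m) , length(grep("^[^#]", readLines(f))))
  }
  # single-soma morphology writes one data line
  fx <- fixture_morphologies(seed = 42)
  write_swc(fx$sphere, f)
  expect_length(grep("^[^#]", readLines(f)), 1)
})

test_that("unknown SWC type codes map to dendrite with a warning", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 7 -1", "2 5 10 0 0 0.5 1"), f)
  expect_warning(m <- read_swc(f), "unknown SWC type")
  expect_equal(m$node_kind[2], "dendrite")
})

test_that("Sholl counts match geometry on canonical shapes", {
  fx <- fixture_morphologies(seed = 42)
  # single straight dendrite of 100 um: one crossing at each shell 10..100
  p <- sholl(fx$stick100, 10)
  expect_equal(p$radius, seq(10, 100, 10))
  expect_equal(p$count, rep(1L, 10))
  # 4-armed star of arm length 80: 4 crossings inside, 0 beyond
  p4 <- sholl(fx$star4, 10)
  expect_equal(p4$count[p4$radius <= 80], rep(4L, 8))
  expect_error(sholl(fx$stick100, -1), "step_um")
  no_soma <- tibble::tibble(id = 1:2, parent_id = c(-1L, 1L),
                            node_kind = "dendrite", x = c(0, 10), y = 0, z = 0,
                            radius = 1)
  expect_error(morphology(no_soma), "no soma")
})

test_that("Sholl counts equal the brute-force segment-sphere oracle", {
  for (seed in 1:8) {
    m <- random_test_tree(seed)
    for (step in c(5, 10)) {
      got <- sholl(m, step)
      exp <- oracle_sholl(m, step)
      expect_equal(got$count, exp$counts, info = sprintf("seed %d step %g", seed, step))
      expect_equal(got$radius, exp$radii)
    }
  }
})

test_that("Sholl centroid and max radius agree with direct recomputation", {
  p <- tibble::tibble(radius = c(10, 20), count = c(1L, 3L))
  expect_equal(sholl_centroid(p), 17.5)
  expect_equal(sholl_max_radius(p), 20)
  # symmetric profile about 50
  ps <- tibble::tibble(radius = c(30, 50, 70), count = c(2L, 5L, 2L))
  expect_equal(sholl_centroid(ps), 50)
  for (seed in 1:5) {
    m <- random_test_tree(seed)
    pr <- sholl(m, 10)
    expect_equal(sholl_centroid(pr),
                 sum(pr$radius * pr$count) / sum(pr$count))
    expect_equal(sholl_max_radius(pr), max(pr$radius[pr$count > 0]))
  }
  zero <- tibble::tibble(radius = c(10, 20), count = c(0L, 0L))
  expect_error(sholl_centroid(zero), "undefined")
  expect_error(sholl_max_radius(zero), "undefined")
})

test_that("coverage area is the xy convex hull area", {
  sq <- morphology(tibble::tibble(
    id = 1:5, parent_id = c(-1L, 1L, 1L, 1L, 1L),
    node_kind = c("soma", rep("dendrite", 4)),
    x = c(0, 50, 50, -50, -50), y = c(0, 50, -50, 50, -50), z = 0,
    radius = c(7, rep(0.5, 4))))
  expect_equal(coverage_area(sq), 10000)
  line <- morphology(tibble::tibble(
    id = 1:4, parent_id = c(-1L, 1L, 2L, 3L),
    node_kind = c("soma", rep("dendrite", 3)),
    x = c(0, 10, 20, 30), y = 0, z = c(0, 5, 9, 2), radius = c(7, rep(0.5, 3))))
  expect_warning(a <- coverage_area(line), "collinear")
  expect_equal(a, 0)
  for (seed in 1:5) {
    m <- random_test_tree(seed)
    d <- m[m$node_kind == "dendrite", ]
    expect_equal(coverage_area(m), oracle_hull_area(d$x, d$y), tolerance = 1e-9)
  }
})

test_that("branch metrics decompose the arbor and conserve cable length", {
  fx <- fixture_morphologies(seed = 42)
  bm <- branch_metrics(fx$stick100)
  expect_equal(bm$n_branches, 1)
  expect_equal(bm$n_branching_points, 0)
  expect_equal(bm$total_dendritic_length, 100)
  ybm <- branch_metrics(fx$y_tree)
  expect_equal(ybm$n_branches, 3)
  expect_equal(ybm$n_branching_points, 1)
  expect_equal(ybm$total_dendritic_length, 150, tolerance = 1e-9)
  expect_equal(ybm$mean_branch_length, 50, tolerance = 1e-9)
  for (seed in 1:6) {
    m <- random_test_tree(seed)
    b <- branch_metrics(m)
    expect_equal(b$total_dendritic_length, oracle_dend_length(m),
                 tolerance = 1e-9)
    expect_equal(b$n_branches * b$mean_branch_length, b$total_dendritic_length,
                 tolerance = 1e-9)
  }
})

test_that("spine number estimate is the density-length product", {
  expect_equal(estimate_spine_number(0, 1000), 0)
  expect_equal(estimate_spine_number(1.2, 1000), 1200)
  expect_equal(estimate_spine_number(2.4, 500), estimate_spine_number(1.2, 1000))
  expect_error(estimate_spine_number(-1, 10), "non-negative")
})

test_that("synthetic morphologies are seed-deterministic and hit length targets", {
  m1 <- synthesize_morphology(morph_preset("wt"), seed = 1)
  m2 <- synthesize_morphology(morph_preset("wt"), seed = 1)
  expect_identical(as.data.frame(m1), as.data.frame(m2))
  p <- morph_params(target_length = 2000, tolerance = 0.1)
  for (seed in c(2, 9, 23)) {
    len <- total_dendritic_length(synthesize_morphology(p, seed = seed))
    expect_gte(len, 1800)
    expect_lte(len, 2200)
  }
  tight <- morph_params(target_length = 2000, tolerance = 1e-6, max_attempts = 3)
  expect_error(synthesize_morphology(tight, seed = 1), "could not grow")
})

test_that("knockout preset grows larger, busier arbors than wild type", {
  seeds <- 1:20
  wt <- purrr::map_dfr(seeds, function(s)
    branch_metrics(synthesize_morphology(morph_preset("wt"), seed = s)))
  ko <- purrr::map_dfr(seeds, function(s)
    branch_metrics(synthesize_morphology(morph_preset("ko"), seed = s)))
  expect_gt(mean(ko$total_dendritic_length), mean(wt$total_dendritic_length))
  expect_gt(mean(ko$n_branches), mean(wt$n_branches))
  expect_gt(mean(ko$n_branching_points), mean(wt$n_branching_points))
  expect_gt(mean(ko$max_radius), mean(wt$max_radius))
})

test_that("larger branching probability yields stochastically more branch points", {
  seeds <- 1:15
  lo <- purrr::map_int(seeds, function(s) as.integer(
    branch_metrics(synthesize_morphology(
      morph_params(p_branch = 0.3, target_length = 1200, tolerance = 0.3),
      seed = s))$n_branching_points))
  hi <- purrr::map_int(seeds, function(s) as.integer(
    branch_metrics(synthesize_morphology(
      morph_params(p_branch = 0.9, target_length = 1200, tolerance = 0.3),
      seed = s))$n_branching_points))
  expect_gt(mean(hi), mean(lo))
})
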