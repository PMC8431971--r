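test_that("pair distances are exact for constructed geometries", {
  nf <- 20L
  frames <- array(0, c(2, 3, nf))
  frames[2, 1, ] <- 5  # constant 5 A separation along x
  traj <- manual_trajectory(frames)
  s <- pair_distance_series(traj, "A1", "A2")
  expect_equal(s$values, rep(5, nf))
  expect_equal(s$times, (0:(nf - 1)) * 0.1)
  # an atom against itself is identically zero
  expect_equal(pair_distance_series(traj, "A1", "A1")$values, rep(0, nf))
  expect_error(pair_distance_series(traj, "A1", "ZZ"), "not found")
})

test_that("bound-ion series mean matches the generator ground truth", {
  sigma <- 0.4
  traj <- make_synthetic_trajectory(4000, bound_sigma = sigma,
                                    site_center = c(1, 2, 3), seed = 21)
  s <- point_distance_series(traj, "NA1", c(1, 2, 3))
  mu <- sigma * sqrt(8 / pi)          # mean radius of an isotropic Gaussian
  se <- sigma * sqrt(3 - 8 / pi) / sqrt(length(s$values))
  expect_lt(abs(mean(s$values) - mu), 3 * se)
})

test_that("nearest-distance series reduces to the pair series and matches brute force", {
  traj <- make_synthetic_trajectory(100, n_waters = 1, seed = 2)
  one <- nearest_distance_series(traj, "NA1", "W1")
  pair <- pair_distance_series(traj, "NA1", "W1")
  expect_equal(one$values, pair$values)
  expect_error(nearest_distance_series(traj, "NA1", character(0)), "empty")

  set.seed(9)
  nf <- 40L; nsel <- 100L
  frames <- array(stats::rnorm((nsel + 1) * 3 * nf, sd = 5),
                  c(nsel + 1, 3, nf))
  traj2 <- manual_trajectory(frames)
  s <- nearest_distance_series(traj2, 1L, 2:(nsel + 1L))
  brute <- vapply(seq_len(nf), function(k) {
    min(vapply(2:(nsel + 1L), function(j)
      sqrt(sum((frames[1, , k] - frames[j, , k])^2)), numeric(1)))
  }, numeric(1))
  expect_equal(s$values, brute, tolerance = 1e-9)
})

test_that("histograms are density-normalized with half-open bins", {
  h <- histogram(rep(3.14, 500), bin_width = 0.1)
  expect_equal(sum(h$densities * diff(h$bin_edges)), 1, tolerance = 1e-9)
  expect_equal(max(h$densities), 1 / 0.1, tolerance = 1e-9)
  expect_equal(sum(h$densities > 0), 1L)

  set.seed(4)
  u <- stats::runif(20000, 0, 10)
  hu <- histogram(u, range = c(0, 10), n_bins = 10)
  expect_equal(hu$densities, rep(0.1, 10), tolerance = 4 / sqrt(20000) / 0.1)

  for (rep in 1:5) {
    v <- stats::rnorm(500, sd = stats::runif(1, 0.5, 5))
    hr <- histogram(v, bin_width = 0.25)
    expect_equal(sum(hr$densities * diff(hr$bin_edges)), 1, tolerance = 1e-9)
  }
  expect_error(histogram(u, range = c(2, 2)), "zero width")
  expect_error(histogram(numeric(0)), "empty")
})

test_that("dissociation detection honours the dwell contract", {
  v <- rep(1, 500)
  none <- detect_dissociation(v, threshold = 8, dwell_frames = 10)
  expect_null(none$event_frame)

  spike <- v; spike[200] <- 20
  expect_null(detect_dissociation(spike, 8, 10)$event_frame)
  # the same spike is an event when dwell is 1
  expect_equal(detect_dissociation(spike, 8, 1)$event_frame, 200L)
  expect_false(detect_dissociation(spike, 8, 1)$irreversible)

  sustained <- c(rep(1, 100), rep(12, 400))
  ev <- detect_dissociation(sustained, 8, 100)
  expect_equal(ev$event_frame, 101L)
  expect_true(ev$irreversible)
  expect_error(detect_dissociation(v, 8, 0), "dwell")
})

test_that("raising the threshold never yields an earlier event", {
  traj <- make_synthetic_trajectory(800, t_off_frame = 150, seed = 17)
  s <- point_distance_series(traj, "NA1", c(0, 0, 0))
  thresholds <- c(2, 4, 6, 8, 12)
  fr <- vapply(thresholds, function(th) {
    ev <- detect_dissociation(s, th, 25)
    if (is.null(ev$event_frame)) Inf else as.numeric(ev$event_frame)
  }, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("dissociation detection recovers the generator's switch-off frame", {
  for (seed in c(3, 14, 15)) {
    traj <- make_synthetic_trajectory(600, t_off_frame = 100,
                                      bound_sigma = 0.5, seed = seed)
    s <- point_distance_series(traj, "NA1", c(0, 0, 0))
    ev <- detect_dissociation(s, threshold = 0.5 * 5, dwell_frames = 50)
    expect_gte(ev$event_frame, 100)
    expect_lte(ev$event_frame, 160)
    expect_true(ev$irreversible)
  }
})

test_that("occupancy grids conserve counts and localize stationary atoms", {
  nf <- 30L
  frames <- array(0, c(3, 3, nf))
  frames[2, 1, ] <- 4.2; frames[3, 2, ] <- -3.7
  traj <- manual_trajectory(frames)
  g <- occupancy_grid(traj, 1:3, spacing = 1)
  expect_equal(sum(g$counts), 3L * nf)
  expect_equal(sum(g$counts > 0), 3L)          # one voxel per atom
  expect_equal(max(g$density), nf / nf)        # each atom in its voxel every frame
  expect_error(occupancy_grid(traj, integer(0)), "empty")
})

test_that("per-frame rotations are undone by alignment", {
  set.seed(31)
  traj <- make_synthetic_trajectory(40, n_waters = 7, seed = 8)
  spec <- list(origin = c(-10, -10, -10), dims = c(20L, 20L, 20L))
  aln <- list(frame = 1, selection = paste0("W", 4:7))
  g0 <- occupancy_grid(traj, paste0("W", 1:3), spacing = 1, grid_spec = spec,
                       align_to = aln)
  rotated <- traj
  for (k in 2:40) {
    R <- random_rotation()
    rotated$frames[, , k] <- traj$frames[, , k] %*% t(R)
  }
  g1 <- occupancy_grid(rotated, paste0("W", 1:3), spacing = 1,
                       grid_spec = spec, align_to = aln)
  # voxel quantization allows single-voxel shifts; bulk mass must agree
  expect_equal(sum(g1$counts), sum(g0$counts))
  expect_gte(sum(pmin(g0$counts, g1$counts)) / sum(g0$counts), 0.9)

  collinear <- manual_trajectory(array(rep(c(0, 1, 2), each = 3),
                                       c(3, 3, 2)))
  expect_error(occupancy_grid(collinear, 1L, align_to =
                                list(frame = 1, selection = 1:3)),
               "collinear|3 atoms")
})

test_that("trajectory XYZ round trip preserves coordinates and metadata", {
  traj <- make_synthetic_trajectory(25, n_waters = 2, dt = 0.25, seed = 6)
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz_trajectory(traj, f)
  back <- read_xyz_trajectory(f)
  expect_equal(back$frames, traj$frames, tolerance = 1e-6)
  expect_identical(back$labels, traj$labels)
  expect_equal(back$dt, 0.25)
})

test_that("occupancy grids serialize to OpenDX text", {
  traj <- make_synthetic_trajectory(10, n_waters = 2, seed = 5)
  g <- occupancy_grid(traj, c("W1", "W2"), spacing = 1)
  f <- withr::local_tempfile(fileext = ".dx")
  write_dx(g, f)
  ln <- readLines(f)
  expect_true(any(grepl("gridpositions", ln)))
  nums <- as.numeric(unlist(strsplit(paste(
    ln[grep("data follows", ln) + seq_len(ceiling(prod(g$dims) / 3))],
    collapse = " "), "\\s+")))
  expect_equal(sum(nums, na.rm = TRUE), sum(g$density), tolerance = 1e-6)
})
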