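test_that("occupancy counts fractions of frames per voxel", {
  # one static atom: occupancy 1.0 in exactly one voxel
  top <- point_topology(1)
  coords <- array(rep(c(10.4, 11.2, 12.7), 100), c(1, 3, 100))
  tr <- trajectory(top, coords, seq_len(100) - 1, c(40, 40, 40))
  g <- occupancy_grid(tr, "all", voxel = 1)
  expect_equal(sum(g$occupancy == 1), 1)
  expect_equal(sum(g$occupancy > 0), 1)
  # atom in a second voxel 27 of 100 frames: occupancy 0.27
  coords[1, 1, 1:27] <- 20.4
  tr <- trajectory(top, coords, seq_len(100) - 1, c(40, 40, 40))
  g <- occupancy_grid(tr, "all", voxel = 1)
  expect_setequal(g$occupancy[g$occupancy > 0], c(0.27, 0.73))
  expect_error(occupancy_grid(tr, "all", voxel = 0), "voxel")
})

test_that("occupancy equals the brute-force binning oracle on a random walk", {
  set.seed(19)
  n <- 6
  top <- point_topology(n)
  nf <- 40
  coords <- array(0, c(n, 3, nf))
  pos <- matrix(runif(3 * n, 10, 30), ncol = 3)
  for (t in seq_len(nf)) {
    pos <- pos + matrix(rnorm(3 * n, sd = 1.5), ncol = 3)
    coords[, , t] <- pos
  }
  tr <- trajectory(top, coords, seq_len(nf) - 1, c(200, 200, 200))
  g <- occupancy_grid(tr, "all", voxel = 2, margin = 1)
  frames <- lapply(seq_len(nf), function(t) coords[, , t, drop = FALSE][, , 1])
  ref <- bf_occupancy(frames, g$origin, g$voxel, g$dim)
  expect_equal(g$occupancy, ref, ignore_attr = TRUE)
})

test_that("occupancy is invariant under frame duplication", {
  set.seed(20)
  top <- point_topology(4)
  coords <- array(runif(4 * 3 * 10, 5, 25), c(4, 3, 10))
  tr1 <- trajectory(top, coords, 0:9, c(50, 50, 50))
  dup <- array(c(coords, coords), c(4, 3, 20))
  tr2 <- trajectory(top, dup, 0:19, c(50, 50, 50))
  g1 <- occupancy_grid(tr1, "all", voxel = 1.5)
  g2 <- occupancy_grid(tr2, "all", voxel = 1.5)
  expect_equal(g1$occupancy, g2$occupancy)
})

test_that("iso-surface thresholding is monotone and handles edge cases", {
  set.seed(21)
  top <- point_topology(5)
  coords <- array(runif(5 * 3 * 30, 5, 20), c(5, 3, 30))
  tr <- trajectory(top, coords, 0:29, c(40, 40, 40))
  g <- occupancy_grid(tr, "all", voxel = 2)
  counts <- vapply(seq(0.05, 0.95, by = 0.1), function(th)
    suppressWarnings(iso_surface_export(g, th)$n_voxels), 0)
  expect_true(all(diff(counts) <= 0))
  # a threshold above the maximum yields an empty surface with a warning
  expect_warning(iso0 <- iso_surface_export(g, 0.99), "empty")
  expect_equal(iso0$n_voxels, 0)
  expect_null(iso0$vertices)
  # a uniform grid of 0.5 at threshold 0.27: every voxel is above
  gu <- g
  gu$occupancy[] <- 0.5
  isou <- iso_surface_export(gu, 0.27)
  expect_equal(isou$n_voxels, prod(gu$dim))
  expect_error(iso_surface_export(g, 1.2), "between 0 and 1")
})

test_that("DX and OBJ exports are written and structurally sound", {
  top <- point_topology(1)
  coords <- array(rep(c(5, 5, 5), 4), c(1, 3, 4))
  tr <- trajectory(top, coords, 0:3, c(20, 20, 20))
  g <- occupancy_grid(tr, "all", voxel = 1)
  dx <- tempfile(fileext = ".dx")
  obj <- tempfile(fileext = ".obj")
  iso <- iso_surface_export(g, 0.5, dx_path = dx, obj_path = obj)
  expect_true(file.exists(dx))
  expect_true(file.exists(obj))
  dxl <- readLines(dx)
  expect_match(dxl[1], "gridpositions counts")
  nitems <- as.integer(sub(".*items ([0-9]+) .*", "\\1",
                           grep("items", dxl, value = TRUE)[1]))
  expect_equal(nitems, prod(g$dim))
  objl <- readLines(obj)
  # a single occupied voxel exposes 6 faces (24 vertices)
  expect_equal(sum(grepl("^f ", objl)), 6)
  expect_equal(sum(grepl("^v ", objl)), 24)
  expect_equal(iso$n_voxels, 1)
})

test_that("unwrapping removes box jumps and rewraps to the original", {
  set.seed(22)
  box <- c(30, 25)
  steps <- matrix(rnorm(2 * 200, sd = 2), ncol = 2)
  true_track <- apply(rbind(c(15, 12), steps), 2, cumsum)
  wrapped <- true_track %% matrix(box, 201, 2, byrow = TRUE)
  un <- unwrap_track(wrapped, box)
  # unwrapped differs from the true track only by the starting image
  expect_equal(diff(un), diff(true_track), tolerance = 1e-9)
  expect_true(all(abs(diff(un)) < matrix(box, 200, 2, byrow = TRUE) / 2))
  rewrapped <- un %% matrix(box, 201, 2, byrow = TRUE)
  expect_equal(rewrapped, wrapped, tolerance = 1e-9)
})

test_that("a stationary molecule has MSD 0 and D 0", {
  top <- point_topology(1)
  coords <- array(rep(c(10, 10, 10), 50), c(1, 3, 50))
  tr <- trajectory(top, coords, 0:49, c(40, 40, 40))
  ld <- lateral_diffusion(tr, "all")
  # zero up to FFT round-off on ~1e4-magnitude intermediates
  expect_lt(max(abs(ld$msd$msd)), 1e-6)
  expect_lt(abs(ld$D_cm2_s), 1e-15)
})

test_that("deterministic drift is flagged as non-linear (MSD = v^2 t^2)", {
  top <- point_topology(1)
  nf <- 200
  coords <- array(0, c(1, 3, nf))
  coords[1, 1, ] <- 0.3 * (0:(nf - 1))  # x = v t, unwrapped within box?
  coords[1, 1, ] <- coords[1, 1, ] %% 500
  coords[1, 2, ] <- 10
  coords[1, 3, ] <- 10
  tr <- trajectory(top, coords, 0:(nf - 1), c(500, 500, 500))
  ld <- lateral_diffusion(tr, "all", fit_window = c(0.05, 0.4))
  lag <- ld$msd$lag_ns
  expect_equal(ld$msd$msd, (0.3 * lag)^2, tolerance = 1e-8)
  expect_true(ld$nonlinear)
})

test_that("halving dt at fixed physical length changes fitted D by < 5%", {
  # one Brownian path sampled at dt = 0.5 and its every-2nd-frame
  # subsample: the shared path makes the comparison sharp
  set.seed(23)
  nf <- 8000
  D <- 0.04  # A^2/ns
  dt <- 0.5
  steps <- matrix(rnorm(2 * (nf - 1), sd = sqrt(2 * D * dt)), ncol = 2)
  track <- apply(rbind(c(100, 100), steps), 2, cumsum)
  top <- point_topology(1)
  box <- c(400, 400, 50)
  mk <- function(tr2, times) {
    coords <- array(0, c(1, 3, nrow(tr2)))
    coords[1, 1, ] <- tr2[, 1] %% box[1]
    coords[1, 2, ] <- tr2[, 2] %% box[2]
    coords[1, 3, ] <- 25
    trajectory(top, coords, times, box)
  }
  fine <- lateral_diffusion(mk(track, (0:(nf - 1)) * dt), "all")
  idx <- seq(1, nf, by = 2)
  coarse <- lateral_diffusion(mk(track[idx, ], (seq_along(idx) - 1) * 1),
                              "all")
  expect_lt(abs(fine$D_A2_ns - coarse$D_A2_ns) / coarse$D_A2_ns, 0.05)
})

test_that("planted D is recovered on a small synthetic ensemble", {
  sys <- generate_system(generator_config(
    n_subunits = 0, n_lipids = 0, n_ligands = 8, n_frames = 4000,
    flexibility = 0, box = c(200, 200, 80), seed = 97))
  ld <- lateral_diffusion(sys$trajectory)
  expect_lt(abs(ld$D_cm2_s - 4e-9) / 4e-9, 0.2)
  expect_equal(ld$n_molecules, 8)
  expect_false(ld$nonlinear)
  # fewer than 3 lags in the window errors
  short <- generate_system(generator_config(
    n_subunits = 0, n_lipids = 0, n_ligands = 1, n_frames = 12,
    flexibility = 0, box = c(100, 100, 80), seed = 3))
  expect_error(lateral_diffusion(short$trajectory,
                                 fit_window = c(0.01, 0.05)),
               "fewer than 3 lags")
})
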