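# Deskew (45-degree shear) and Sobel edge enhancement.

make_stack <- function(frames, geometry) {
  structure(list(frames = frames, geometry = geometry,
                 noise_params = noiseless_params(), seed = 1L),
            class = "raw_stack")
}

test_that("single-frame shear lays the oblique plane along the diagonal", {
  g <- small_geometry()
  rows <- 16; cols <- 32
  fr <- array(runif(rows * cols), dim = c(rows, cols, 1))
  vol <- deskew_stack(make_stack(fr, g))
  expect_equal(dim(vol$grid), c(rows, cols, rows))  # frames + rows - 1 = rows
  for (r in seq_len(rows)) {
    expect_equal(vol$grid[r, , r], fr[r, , 1])
    expect_true(all(vol$mask[r, , r]))
    expect_true(all(vol$grid[r, , -r] == 0))
  }
})

test_that("integer-shift deskew is lossless and pitch-correct", {
  g <- small_geometry()
  set.seed(42)
  fr <- array(rpois(16 * 32 * 20, 30), dim = c(16, 32, 20))
  vol <- deskew_stack(make_stack(fr, g))
  expect_equal(dim(vol$grid), c(16, 32, 20 + 16 - 1))
  expect_equal(sum(vol$mask), length(fr))          # every pixel exactly once
  expect_identical(sum(vol$grid[vol$mask]), sum(as.numeric(fr)))  # exact
  expect_equal(unname(vol$pitch_um["x"]), g$frame_interval)
  expect_equal(unname(vol$pitch_um["y"]), g$binned_pitch)
  expect_equal(unname(vol$pitch_um["z"]),
               g$binned_pitch * sinpi(g$sheet_angle / 180))
  # default full-scale geometry: (0.6223, 0.88, 0.6223) um
  d <- derive_geometry(acq_geometry())
  expect_equal(round(c(d$z_pitch, d$binned_pitch, d$matched_frame_interval),
                     4), c(0.6223, 0.88, 0.6223))
})

test_that("simulate -> deskew recovers 20 seeded point sources within 1 voxel", {
  g <- small_geometry()
  p <- g$binned_pitch; s <- g$frame_interval
  set.seed(202)
  n_bad <- 0
  for (trial in 1:20) {
    ix <- sample(15:45, 1); iy <- sample(3:20, 1); iz <- sample(3:10, 1)
    ph <- point_phantom(c(60, 24, 12), pitch = 1, ix = ix, iy = iy, iz = iz)
    st <- simulate_acquisition(ph, g, noiseless_params(), seed = trial)
    vol <- deskew_stack(st)
    w <- vol$grid / sum(vol$grid)
    # intensity-weighted centroid in physical um
    dz <- dim(w)
    zi <- slice.index(w, 1); yi <- slice.index(w, 2); xi <- slice.index(w, 3)
    cz <- sum(w * (zi - 1)) * vol$pitch_um["z"]
    cy <- sum(w * (yi - 1)) * vol$pitch_um["y"]
    cx <- sum(w * (xi - 1)) * vol$pitch_um["x"]
    true <- c((ix - 1), (iy - 1), (iz - 1))  # pitch 1 um
    if (abs(cx - true[1]) > vol$pitch_um["x"] ||
        abs(cy - true[2]) > vol$pitch_um["y"] ||
        abs(cz - true[3]) > vol$pitch_um["z"]) n_bad <- n_bad + 1
  }
  expect_equal(n_bad, 0)
})

test_that("mismatched frame interval takes the interpolating path", {
  g <- small_geometry(frame_interval = 0.75)  # matched is 0.6223
  ph <- point_phantom(c(60, 24, 12), pitch = 1, ix = 31, iy = 11, iz = 7)
  st <- simulate_acquisition(ph, g, noiseless_params(), seed = 1)
  vol <- deskew_stack(st)
  expect_equal(unname(vol$pitch_um["x"]), 0.75)
  idx <- which(vol$grid == max(vol$grid), arr.ind = TRUE)[1, ]
  pos <- (idx - 1) * vol$pitch_um  # (z, y, x)
  expect_lte(abs(pos[3] - 30), vol$pitch_um["x"])
  expect_lte(abs(pos[2] - 10), vol$pitch_um["y"])
  expect_lte(abs(pos[1] - 6), vol$pitch_um["z"])
})

test_that("shear sign flips the scan axis", {
  g <- small_geometry()
  set.seed(7)
  fr <- array(runif(16 * 32 * 5), dim = c(16, 32, 5))
  a <- deskew_stack(make_stack(fr, g), shear_sign = 1L)
  b <- deskew_stack(make_stack(fr, g), shear_sign = -1L)
  expect_equal(b$grid, a$grid[, , dim(a$grid)[3]:1])
})

test_that("deskew rejects empty and NaN stacks", {
  g <- small_geometry()
  fr <- array(1, dim = c(16, 32, 3)); fr[1, 1, 1] <- NaN
  expect_error(deskew_stack(make_stack(fr, g)), "NaN")
})

test_that("zero gain and flat fields leave the volume unchanged", {
  g <- small_geometry()
  set.seed(3)
  fr <- array(runif(16 * 32 * 6), dim = c(16, 32, 6))
  vol <- deskew_stack(make_stack(fr, g))
  expect_equal(enhance_volume(vol, alpha = 0)$grid, vol$grid)
  flat <- otls_volume(array(5, dim = c(4, 8, 8)), c(z = 1, y = 1, x = 1),
                      provenance = "deskewed")
  expect_equal(enhance_volume(flat, alpha = 2)$grid, flat$grid)
  expect_error(enhance_volume(vol, alpha = -1), "alpha")
})

test_that("step-edge enhancement matches the explicit Sobel oracle", {
  plane <- matrix(0, 64, 64)
  plane[, 33:64] <- 10                      # vertical step edge
  vol <- otls_volume(array(plane, dim = c(1, 64, 64)),
                     c(z = 1, y = 1, x = 1), provenance = "deskewed")
  alpha <- 0.7
  out <- enhance_volume(vol, alpha = alpha, presmooth_sigma = 0)
  M <- oracle_sobel_mag(plane)
  M <- M * (max(plane) / max(M))
  expected <- pmin(pmax(plane + alpha * M, 0), 10)
  expect_equal(out$grid[1, , ], expected, tolerance = 1e-12)
})

test_that("enhancement is monotone in alpha and preserves the value range", {
  g <- small_geometry()
  ph <- generate_phantom(80, 24, 30, c(gleason3 = 1), voxel_pitch_um = 2,
                         seed = 6, lumen_radius = c(gleason3 = 6),
                         nucleus_radius = 2)
  st <- simulate_acquisition(ph, g, default_noise_params(), seed = 6)
  vol <- deskew_stack(st)
  alphas <- c(0, 0.25, 0.5, 1, 2)
  prev <- enhance_volume(vol, alphas[1])$grid
  for (a in alphas[-1]) {
    cur <- enhance_volume(vol, a)$grid
    expect_true(all(cur - prev >= -1e-12))
    expect_lte(max(cur), max(vol$grid))
    expect_gte(min(cur), min(vol$grid))
    prev <- cur
  }
})

test_that("depth-restricted lesion appears only at its depth (70-um scenario)", {
  # cancer-only phantom confined to 60-80 um: en-face planes at <= 40 um see
  # nothing; planes near 70 um see the lesion. A coarse camera (2.5 um
  # binned pitch) keeps this fast. The stage sweep starts at the specimen
  # edge, so the oblique sheet cannot reach deep structure at scan positions
  # x < z; the seed is chosen so the gland sits in the swept region
  # (centre x ~ 187 um >> 80 um).
  g <- acq_geometry(native_pixel_pitch = 1.25, binning = 2, sheet_angle = 45,
                    roi_rows = 92, roi_cols = 92, vertical_fov = 80)
  ph <- generate_phantom(400, 78, 100, c(gleason3 = 1), voxel_pitch_um = 2,
                         seed = 8, lumen_radius = c(gleason3 = 5),
                         nucleus_radius = 2, stroma_frac = 0,
                         depth_range = c(60, 80))
  expect_gt(ph$glands[[1]]$center[1], 100)  # placement precondition
  st <- simulate_acquisition(ph, g, noiseless_params(), seed = 8)
  vol <- deskew_stack(st)
  z_um <- (seq_len(dim(vol$grid)[1]) - 1) * vol$pitch_um["z"]
  shallow <- vol$grid[z_um <= 40, , ]
  expect_equal(max(shallow), 0)
  near70 <- vol$grid[abs(z_um - 70) <= 5, , ]
  expect_gt(max(near70), 0)
})
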