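#' Simulate oblique stage-scan acquisition of a phantom
#'
#' Forward model of open-top light-sheet imaging: the specimen translates
#' along the scan (x) axis while 2D frames are captured on a light sheet
#' inclined at `sheet_angle` to the surface. Frame `k` (0-based), camera row
#' `r`, column `c` samples the phantom, by trilinear interpolation, at
#' \deqn{x = k s + r p \cos\theta,\quad y = c p,\quad z = r p \sin\theta}
#' with `s` the frame interval, `p` the binned pixel pitch and `theta` the
#' sheet angle. Signal is attenuated by `exp(-z / attenuation_length_um)`
#' (optical clearing in this assay supports imaging only to ~100 um), then
#' corrupted by Poisson shot noise at `photon_scale` photons per intensity
#' unit and additive Gaussian read noise, and clipped at zero.
#'
#' The number of frames is `ceil(length / s) + ceil((rows-1) p cos(theta) / s)`
#' so the stage travels far enough that the deepest camera row has swept past
#' the end of the specimen (the oblique overhang).
#'
#' @param phantom A [generate_phantom()] result.
#' @param geometry An [acq_geometry()]; the phantom must fit the lateral strip
#'   width.
#' @param noise_params List with `photon_scale` (photons per intensity unit;
#'   `Inf` disables shot noise), `read_noise_sd` (same units as intensity; 0
#'   disables) and `attenuation_length_um` (1/e depth; `Inf` disables).
#' @param seed Integer seed for the noise draws.
#' @return An object of class `raw_stack`: list with `frames` (numeric array,
#'   dims rows x cols x n_frames, binned pixels), `geometry`, `noise_params`,
#'   `seed`.
#' @examples
#' ph <- generate_phantom(60, 60, 30, c(benign = 0), voxel_pitch_um = 2,
#'                        seed = 1)
#' g <- acq_geometry(roi_rows = 16, roi_cols = 32, vertical_fov = 10)
#' st <- simulate_acquisition(ph, g, noiseless_params())
#' dim(st$frames)
#' @export
simulate_acquisition <- function(phantom, geometry,
                                 noise_params = default_noise_params(),
                                 seed = 1L) {
  stopifnot(inherits(phantom, "biopsy_phantom"),
            inherits(geometry, "otls_geometry"))
  np <- noise_params
  for (f in c("photon_scale", "read_noise_sd", "attenuation_length_um"))
    if (is.null(np[[f]])) stop("noise_params missing field: ", f)
  if (np$attenuation_length_um <= 0)
    stop("attenuation_length_um must be positive (use Inf for none)")
  dg <- derive_geometry(geometry)
  if (phantom$extent_um[2] > dg$strip_width_mm * 1000 + 1e-9)
    stop("phantom wider than the imaging strip")

  p <- geometry$binned_pitch
  s <- geometry$frame_interval
  theta <- geometry$sheet_angle / 180
  rows <- geometry$roi_rows %/% geometry$binning
  cols <- geometry$roi_cols %/% geometry$binning
  n_frames <- ceiling(phantom$extent_um[1] / s) +
    ceiling((rows - 1) * p * cospi(theta) / s)

  # per-pixel specimen coordinates independent of frame index
  r_idx <- 0:(rows - 1)
  c_idx <- 0:(cols - 1)
  x_off <- r_idx * p * cospi(theta)          # by row
  z <- r_idx * p * sinpi(theta)              # by row
  y <- c_idx * p                             # by column
  atten <- exp(-z / np$attenuation_length_um)

  frames <- array(0, dim = c(rows, cols, n_frames))
  ygrid <- rep(y, each = rows)
  for (k in seq_len(n_frames) - 1L) {
    xg <- rep(k * s + x_off, times = cols)
    sig <- .trilinear(phantom$volume, phantom$voxel_pitch_um,
                      xg, ygrid, rep(z, times = cols))
    frames[, , k + 1L] <- sig * atten
  }

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  if (is.finite(np$photon_scale)) {
    frames[] <- stats::rpois(length(frames),
                             np$photon_scale * frames) / np$photon_scale
  }
  if (np$read_noise_sd > 0) {
    frames[] <- frames + stats::rnorm(length(frames), 0, np$read_noise_sd)
  }
  frames[frames < 0] <- 0

  structure(list(frames = frames, geometry = geometry, noise_params = np,
                 seed = as.integer(seed)),
            class = "raw_stack")
}

#' Default and noiseless noise parameter sets
#'
#' `default_noise_params()` gives a realistic sCMOS-like model: 50 detected
#' photons per intensity unit of shot noise, read noise of 1 intensity unit,
#' and a 100 um attenuation length (the assay's stated attainable imaging
#' depth). `noiseless_params()` disables noise and attenuation, for oracle
#' tests.
#' @return A list with `photon_scale`, `read_noise_sd`,
#'   `attenuation_length_um`.
#' @export
default_noise_params <- function() {
  list(photon_scale = 50, read_noise_sd = 1, attenuation_length_um = 100)
}

#' @rdname default_noise_params
#' @export
noiseless_params <- function() {
  list(photon_scale = Inf, read_noise_sd = 0, attenuation_length_um = Inf)
}

#' @export
print.raw_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Raw oblique stack: %d frames of %d x %d px (%.3g um step)\n",
              d[3], d[1], d[2], x$geometry$frame_interval))
  invisible(x)
}

# Trilinear interpolation of vol (0-based grid, voxel i at (i-1)*pitch) at
# physical coordinates (x, y, z) in um. Out-of-grid samples return 0.
.trilinear <- function(vol, pitch, x, y, z) {
  d <- dim(vol)
  gx <- x / pitch; gy <- y / pitch; gz <- z / pitch
  x0 <- floor(gx); y0 <- floor(gy); z0 <- floor(gz)
  fx <- gx - x0; fy <- gy - y0; fz <- gz - z0
  out <- numeric(length(x))
  # gather the 8 corners; clamp index lookups but zero-weight outside samples
  val <- function(ix, iy, iz) {
    ok <- ix >= 0 & ix <= d[1] - 1 & iy >= 0 & iy <= d[2] - 1 &
      iz >= 0 & iz <= d[3] - 1
    v <- numeric(length(ix))
    if (any(ok)) {
      idx <- cbind(ix[ok] + 1, iy[ok] + 1, iz[ok] + 1)
      v[ok] <- vol[idx]
    }
    v
  }
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    nz <- w > 0
    if (any(nz)) {
      v <- val(x0[nz] + dx, y0[nz] + dy, z0[nz] + dz)
      out[nz] <- out[nz] + w[nz] * v
    }
  }
  out
}
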