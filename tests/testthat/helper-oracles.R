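# Independent oracles and small fixtures used across the suite.
# Every oracle here is deliberately written as plain loops / first-principles
# code, separate from the package's vectorised implementations.

# small camera for fast acquisition tests: 16 x 32 binned pixels
small_geometry <- function(frame_interval = NULL) {
  acq_geometry(native_pixel_pitch = 0.44, binning = 2, sheet_angle = 45,
               frame_interval = frame_interval,
               roi_rows = 32, roi_cols = 64, vertical_fov = 10)
}

# an empty (background-free) phantom with one bright voxel at grid index
# (ix, iy, iz), 1-based; physical position (ix-1, iy-1, iz-1) * pitch
point_phantom <- function(dims_um, pitch, ix, iy, iz, intensity = 100) {
  ph <- generate_phantom(dims_um[1], dims_um[2], dims_um[3],
                         gland_mix = c(benign = 0), voxel_pitch_um = pitch,
                         seed = 1, stroma_frac = 0)
  ph$volume[ix, iy, iz] <- intensity
  ph
}

# brute-force forward model: evaluate the oblique sampling map and trilinear
# weights for every frame pixel with explicit loops
oracle_forward <- function(phantom, geometry, n_frames) {
  p <- geometry$binned_pitch
  s <- geometry$frame_interval
  th <- geometry$sheet_angle * pi / 180
  rows <- geometry$roi_rows / geometry$binning
  cols <- geometry$roi_cols / geometry$binning
  vol <- phantom$volume
  a <- phantom$voxel_pitch_um
  d <- dim(vol)
  tri <- function(x, y, z) {
    gx <- x / a; gy <- y / a; gz <- z / a
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      ix <- floor(gx) + dx; iy <- floor(gy) + dy; iz <- floor(gz) + dz
      w <- (1 - abs(gx - ix)) * (1 - abs(gy - iy)) * (1 - abs(gz - iz))
      if (w > 0 && ix >= 0 && ix < d[1] && iy >= 0 && iy < d[2] &&
          iz >= 0 && iz < d[3])
        acc <- acc + w * vol[ix + 1, iy + 1, iz + 1]
    }
    acc
  }
  fr <- array(0, dim = c(rows, cols, n_frames))
  for (k in 0:(n_frames - 1)) for (r in 0:(rows - 1)) for (c in 0:(cols - 1))
    fr[r + 1, c + 1, k + 1] <- tri(k * s + r * p * cos(th), c * p,
                                   r * p * sin(th))
  fr
}

# explicit loop-based block-mean downsampling
oracle_block_mean <- function(a, fac_zyx) {
  d <- dim(a)
  nd <- ceiling(d / fac_zyx)
  out <- array(NA_real_, dim = nd)
  for (i in seq_len(nd[1])) for (j in seq_len(nd[2])) for (k in seq_len(nd[3])) {
    zi <- ((i - 1) * fac_zyx[1] + 1):min(i * fac_zyx[1], d[1])
    yi <- ((j - 1) * fac_zyx[2] + 1):min(j * fac_zyx[2], d[2])
    xi <- ((k - 1) * fac_zyx[3] + 1):min(k * fac_zyx[3], d[3])
    out[i, j, k] <- mean(a[zi, yi, xi])
  }
  out
}

# pairwise agreement: fraction of agreeing rater pairs over all cases
oracle_pairwise_agreement <- function(calls) {
  n <- nrow(calls); r <- ncol(calls)
  agree <- 0
  for (i in seq_len(n)) for (a in 1:(r - 1)) for (b in (a + 1):r)
    agree <- agree + (calls[i, a] == calls[i, b])
  agree / (n * choose(r, 2))
}

# time-stepped discrete-event simulation of the pipelined workflow,
# structurally unlike the analytic recursion in build_schedule
oracle_des_schedule <- function(n, timing, dt = 0.005) {
  offset <- timing$stain_min + timing$rinse_min + timing$load_min
  ti <- timing$image_min_per_biopsy
  tp <- timing$process_min_per_biopsy
  td <- timing$diagnose_sec_per_biopsy / 60
  w <- timing$process_workers
  state <- rep("waiting", n)   # waiting -> imaging -> queued -> processing
                               # -> ready -> diagnosing -> done
  rem <- rep(NA_real_, n)
  done_t <- rep(NA_real_, n)
  ready_order <- integer(0)
  t <- offset
  imaging <- NA_integer_
  reader_busy_until <- -Inf
  reader_on <- NA_integer_
  eps <- 1e-9
  while (any(state != "done")) {
    # start imaging next biopsy if scope free
    if (is.na(imaging)) {
      nxt <- which(state == "waiting")[1]
      if (!is.na(nxt)) { imaging <- nxt; state[nxt] <- "imaging"; rem[nxt] <- ti }
    }
    # start processing for queued biopsies while workers free
    busy <- sum(state == "processing")
    for (i in which(state == "queued")) {
      if (busy < w) { state[i] <- "processing"; rem[i] <- tp; busy <- busy + 1 }
    }
    # start diagnosis if reader free and a dataset is ready (FIFO)
    if (is.na(reader_on) && length(ready_order) > 0 &&
        t >= reader_busy_until - eps) {
      reader_on <- ready_order[1]; ready_order <- ready_order[-1]
      state[reader_on] <- "diagnosing"; rem[reader_on] <- td
    }
    # advance time
    active <- which(state %in% c("imaging", "processing", "diagnosing"))
    if (length(active) == 0) { t <- t + dt; next }
    step <- max(min(dt, min(rem[active])), eps)
    t <- t + step
    rem[active] <- rem[active] - step
    for (i in active[rem[active] <= eps]) {
      if (state[i] == "imaging") { state[i] <- "queued"; imaging <- NA_integer_ }
      else if (state[i] == "processing") {
        state[i] <- "ready"; ready_order <- c(ready_order, i)
      } else {
        state[i] <- "done"; done_t[i] <- t
        reader_busy_until <- t; reader_on <- NA_integer_
      }
    }
  }
  list(total = max(done_t), done = done_t)
}

# direct 3x3 convolution with replicate padding, explicit loops
oracle_conv3 <- function(img, kern) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    acc <- 0
    for (di in -1:1) for (dj in -1:1) {
      ii <- min(max(i + di, 1), nr)
      jj <- min(max(j + dj, 1), nc)
      acc <- acc + kern[di + 2, dj + 2] * img[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

oracle_sobel_mag <- function(img) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  sqrt(oracle_conv3(img, kx)^2 + oracle_conv3(img, t(kx))^2)
}

random_rating_table <- function(n, r) {
  rating_table(matrix(sample(c("cancer", "benign"), n * r, replace = TRUE),
                      nrow = n, ncol = r))
}

fixture_calls_named <- function(fx, col) {
  stats::setNames(fx$table$calls[, col], fx$table$case_ids)
}
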