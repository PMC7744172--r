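#' @title Minimal multi-page TIFF I/O
#' @description The pipeline's raw frame stacks and reconstructed volumes are
#'   exchanged as multi-page grayscale TIFF. No TIFF package is available in
#'   the supported runtime, so the package carries a deliberately minimal
#'   codec: uncompressed, little-endian, single-sample (grayscale), one strip
#'   per page, 16-bit unsigned or 32-bit float. This covers everything the
#'   pipeline writes; it is not a general TIFF reader.
#' @name tiffio
NULL

#' Write a stack of 2D images as a multi-page TIFF
#'
#' @param pages Numeric 3D array (rows x cols x pages) or a single matrix.
#' @param path Output path.
#' @param dtype `"float32"` (default; values stored at single precision) or
#'   `"uint16"` (values rounded and clamped to `[0, 65535]`).
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(pages, path, dtype = c("float32", "uint16")) {
  dtype <- match.arg(dtype)
  if (is.matrix(pages)) pages <- array(pages, dim = c(dim(pages), 1L))
  stopifnot(is.array(pages), length(dim(pages)) == 3L)
  nr <- dim(pages)[1]; nc <- dim(pages)[2]; np <- dim(pages)[3]
  bps <- if (dtype == "uint16") 2L else 4L
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")

  writeChar("II", con, nchars = 2, eos = NULL)
  w2(42L)
  data_bytes <- nr * nc * bps
  ifd_bytes <- 2L + 10L * 12L + 4L
  # page k layout: [pixel data][IFD]; first IFD pointer -> after page 1 data
  first_ifd <- 8L + data_bytes
  w4(first_ifd)

  for (k in seq_len(np)) {
    page_start <- 8L + (k - 1L) * (data_bytes + ifd_bytes)
    v <- as.vector(t(pages[, , k]))          # row-major pixel order
    if (dtype == "uint16") {
      v <- round(v); v[v < 0] <- 0; v[v > 65535] <- 65535
      v <- as.integer(v)
      v[v > 32767L] <- v[v > 32767L] - 65536L  # low-16-bit two's complement
      writeBin(v, con, size = 2, endian = "little")
    } else {
      writeBin(as.double(v), con, size = 4, endian = "little")
    }
    entry <- function(tag, type, count, value) {
      w2(tag); w2(type); w4(count)
      if (type == 3L) { w2(value); w2(0L) } else w4(value)
    }
    w2(10L)                                   # entry count
    entry(256L, 4L, 1L, nc)                   # ImageWidth
    entry(257L, 4L, 1L, nr)                   # ImageLength
    entry(258L, 3L, 1L, 8L * bps)             # BitsPerSample
    entry(259L, 3L, 1L, 1L)                   # Compression: none
    entry(262L, 3L, 1L, 1L)                   # Photometric: BlackIsZero
    entry(273L, 4L, 1L, page_start)           # StripOffsets
    entry(277L, 3L, 1L, 1L)                   # SamplesPerPixel
    entry(278L, 4L, 1L, nr)                   # RowsPerStrip
    entry(279L, 4L, 1L, data_bytes)           # StripByteCounts
    entry(339L, 3L, 1L, if (dtype == "uint16") 1L else 3L)  # SampleFormat
    next_ifd <- if (k < np)
      8L + k * (data_bytes + ifd_bytes) + data_bytes else 0L
    w4(next_ifd)
  }
  invisible(path)
}

#' Read a multi-page TIFF written by [write_tiff_stack()]
#'
#' Accepts any uncompressed little-endian grayscale TIFF with 16-bit unsigned
#' or 32-bit float samples and contiguous strips.
#'
#' @param path TIFF file path.
#' @return Numeric 3D array (rows x cols x pages).
#' @export
read_tiff_stack <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.numeric(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  if (rawToChar(raw[1:2]) != "II" || u16(2) != 42L)
    stop("not a little-endian TIFF")
  ifd <- u32(4)
  pages <- list()
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifd + 2 + (i - 1) * 12
      tag <- u16(e); type <- u16(e + 2)
      val <- if (type == 3L) u16(e + 8) else u32(e + 8)
      tags[[as.character(tag)]] <- val
    }
    g <- function(t, default = NULL) tags[[as.character(t)]] %||% default
    if (g(259, 1) != 1) stop("compressed TIFF not supported")
    nc <- g(256); nr <- g(257); bits <- g(258); sfmt <- g(339, 1)
    off <- g(273); nbytes <- g(279)
    if (is.null(off) || is.null(nc) || is.null(nr))
      stop("malformed TIFF page")
    bytes <- raw[off + seq_len(nbytes)]
    v <- if (bits == 16 && sfmt == 1) {
      as.double(readBin(bytes, "integer", n = nr * nc, size = 2,
                        signed = FALSE, endian = "little"))
    } else if (bits == 32 && sfmt == 3) {
      readBin(bytes, "double", n = nr * nc, size = 4, endian = "little")
    } else stop("unsupported sample layout: ", bits, "-bit format ", sfmt)
    pages[[length(pages) + 1L]] <- matrix(v, nrow = nr, ncol = nc,
                                          byrow = TRUE)
    ifd <- u32(ifd + 2 + n * 12)
  }
  array(unlist(pages), dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                               length(pages)))
}

#' Save / load a raw oblique stack as TIFF + YAML sidecar
#'
#' The frames go to a float32 multi-page TIFF (one page per frame); the
#' acquisition geometry, noise parameters and seed go to a YAML sidecar at
#' `<stem>.yaml`.
#' @param stack A `raw_stack`.
#' @param path TIFF output path.
#' @return The reader returns a `raw_stack`; the writer returns `path`
#'   invisibly.
#' @export
write_raw_stack <- function(stack, path) {
  stopifnot(inherits(stack, "raw_stack"))
  write_tiff_stack(stack$frames, path, dtype = "float32")
  g <- stack$geometry
  meta <- list(geometry = g[c("native_pixel_pitch", "binning", "sheet_angle",
                              "frame_interval", "roi_rows", "roi_cols",
                              "vertical_fov")],
               noise_params = lapply(stack$noise_params, .yaml_num),
               seed = stack$seed)
  yaml::write_yaml(meta, .sidecar(path), precision = 15)
  invisible(path)
}

#' @rdname write_raw_stack
#' @export
read_raw_stack <- function(path) {
  meta <- yaml::read_yaml(.sidecar(path))
  gm <- meta$geometry
  geometry <- acq_geometry(native_pixel_pitch = gm$native_pixel_pitch,
                           binning = gm$binning,
                           sheet_angle = gm$sheet_angle,
                           frame_interval = gm$frame_interval,
                           roi_rows = gm$roi_rows, roi_cols = gm$roi_cols,
                           vertical_fov = gm$vertical_fov)
  structure(list(frames = read_tiff_stack(path), geometry = geometry,
                 noise_params = lapply(meta$noise_params, .from_yaml_num),
                 seed = meta$seed),
            class = "raw_stack")
}

#' Save / load a calibrated volume as TIFF + YAML sidecar
#'
#' Pages are z-planes (depth); the per-axis pitches and provenance go to the
#' YAML sidecar. The validity mask is not persisted (unobserved voxels are
#' stored as 0).
#' @param volume An [otls_volume()].
#' @param path TIFF output path.
#' @return The reader returns an [otls_volume()]; the writer returns `path`
#'   invisibly.
#' @export
write_volume_tiff <- function(volume, path) {
  stopifnot(inherits(volume, "otls_volume"))
  # store as (y, x) pages stacked along z
  pages <- aperm(volume$grid, c(2L, 3L, 1L))
  write_tiff_stack(pages, path, dtype = "float32")
  yaml::write_yaml(list(pitch_um = as.list(volume$pitch_um),
                        provenance = volume$provenance,
                        axes = "pages=z, rows=y, cols=x"),
                   .sidecar(path), precision = 15)
  invisible(path)
}

#' @rdname write_volume_tiff
#' @export
read_volume_tiff <- function(path) {
  meta <- yaml::read_yaml(.sidecar(path))
  pages <- read_tiff_stack(path)
  grid <- aperm(pages, c(3L, 1L, 2L))
  otls_volume(grid, pitch_um = unlist(meta$pitch_um),
              provenance = meta$provenance)
}

.sidecar <- function(path) paste0(tools::file_path_sans_ext(path), ".yaml")
.yaml_num <- function(x) if (is.infinite(x)) ".inf" else x
.from_yaml_num <- function(x) if (identical(x, ".inf")) Inf else x
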