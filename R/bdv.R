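#' Multiresolution pyramid specification
#'
#' Describes the level-of-detail pyramid written to the XML/HDF5 container:
#' per-level integer downsampling factors (per axis, `(x, y, z)` order as in
#' the container convention) and the chunk (block) size used for storage.
#'
#' @param levels List of length-3 integer vectors, one per level; level 1
#'   must be `c(1, 1, 1)` and factors must be non-decreasing per axis.
#' @param chunk_shape Length-3 integer block size (x, y, z). Default 64^3.
#' @return A list of class `pyramid_spec`.
#' @examples
#' default_pyramid()  # (1,1,1), (2,2,2), (4,4,4)
#' @export
pyramid_spec <- function(levels = list(c(1L, 1L, 1L), c(2L, 2L, 2L),
                                       c(4L, 4L, 4L)),
                         chunk_shape = c(64L, 64L, 64L)) {
  stopifnot(is.list(levels), length(levels) >= 1L)
  levels <- lapply(levels, function(l) {
    l <- as.integer(l)
    if (length(l) != 3L || any(l < 1L)) stop("each level needs 3 factors >= 1")
    l
  })
  if (!identical(levels[[1]], c(1L, 1L, 1L)))
    stop("level 1 must be (1,1,1)")
  fac <- do.call(rbind, levels)
  if (any(apply(fac, 2, function(col) any(diff(col) < 0))))
    stop("downsample factors must be non-decreasing per axis across levels")
  chunk_shape <- as.integer(chunk_shape)
  stopifnot(length(chunk_shape) == 3L, all(chunk_shape > 0L))
  structure(list(levels = levels, chunk_shape = chunk_shape),
            class = "pyramid_spec")
}

#' @rdname pyramid_spec
#' @export
default_pyramid <- function() pyramid_spec()

#' Block-mean multiresolution pyramid
#'
#' Level `L` is obtained from level 1 by averaging non-overlapping blocks of
#' the level's per-axis factors; edge blocks that extend past the grid are
#' averaged over the voxels actually available (graceful truncation).
#'
#' @param volume An [otls_volume()].
#' @param spec A [pyramid_spec()].
#' @return A list of [otls_volume()]s, one per level, with pitches scaled by
#'   the factors.
#' @export
build_pyramid <- function(volume, spec = default_pyramid()) {
  stopifnot(inherits(volume, "otls_volume"), inherits(spec, "pyramid_spec"))
  lapply(spec$levels, function(fac) {
    # fac is (x, y, z); grid dims are (z, y, x)
    fzyx <- rev(fac)
    g <- .block_mean(volume$grid, fzyx)
    otls_volume(g, pitch_um = volume$pitch_um * fzyx,
                provenance = volume$provenance, geometry = volume$geometry)
  })
}

# block-mean downsample a 3D array by integer factors (per-dim), truncating
# edge blocks to the available voxels; blocks are separable, so sum each
# dimension in turn and divide by the outer product of block sizes
.block_mean <- function(a, fac) {
  d <- dim(a)
  bins <- lapply(1:3, function(i)
    rep(seq_len(ceiling(d[i] / fac[i])), each = fac[i])[seq_len(d[i])])
  res <- a
  for (i in 1:3) {
    dd <- dim(res)
    perm <- c(i, setdiff(1:3, i))
    m <- matrix(aperm(res, perm), nrow = dd[i])
    s <- rowsum(m, bins[[i]], reorder = TRUE)
    res <- aperm(array(s, dim = c(nrow(s), dd[setdiff(1:3, i)])), order(perm))
  }
  sizes <- lapply(bins, tabulate)
  res / outer(outer(sizes[[1]], sizes[[2]]), sizes[[3]])
}

#' Write a volume as a BigDataViewer-style XML + HDF5 dataset
#'
#' Re-saves a reconstructed volume into the multiresolution XML/HDF5 layout
#' used by the BigDataViewer/BigStitcher ecosystem, so biopsies can be opened
#' zoomed-out at low resolution and inspected at depth at full resolution.
#' One setup, one timepoint, unsigned 16-bit storage. Datasets live at
#' `s00/resolutions`, `s00/subdivisions` and `t00000/s00/<L>/cells`; the
#' sibling XML registers the setup with a pure scaling affine
#' `diag(x-pitch, y-pitch, z-pitch)` — the shear has already been applied by
#' [deskew_stack()], so no shear terms appear.
#'
#' Intensities are rounded to the nearest integer and clamped to
#' `[0, 65535]`; pass integer-valued data for a bit-exact round trip.
#'
#' @param volume An [otls_volume()].
#' @param spec A [pyramid_spec()].
#' @param path Output path for the HDF5 file (`.h5`); the XML is written next
#'   to it with the same stem.
#' @param compression Gzip level 0-9; 0 (default) stores uncompressed.
#' @return Invisibly, a list with the `h5` and `xml` paths.
#' @export
write_bdv <- function(volume, spec = default_pyramid(), path,
                      compression = 0L) {
  stopifnot(inherits(volume, "otls_volume"))
  if (!grepl("\\.h5$", path)) path <- paste0(path, ".h5")
  xml_path <- sub("\\.h5$", ".xml", path)
  pyr <- build_pyramid(volume, spec)
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)

  n_lev <- length(spec$levels)
  res <- t(vapply(spec$levels, as.numeric, numeric(3)))       # levels x 3 (xyz)
  sub <- matrix(rep(as.numeric(spec$chunk_shape), n_lev), ncol = 3,
                byrow = TRUE)
  rhdf5::h5createGroup(path, "s00")
  # store as (3 x levels) R matrices so the HDF5 file holds (levels x 3)
  rhdf5::h5write(t(res), path, "s00/resolutions")
  rhdf5::h5write(t(sub), path, "s00/subdivisions")
  rhdf5::h5createGroup(path, "t00000")
  rhdf5::h5createGroup(path, "t00000/s00")
  for (L in seq_len(n_lev)) {
    grp <- sprintf("t00000/s00/%d", L - 1L)
    rhdf5::h5createGroup(path, grp)
    g <- pyr[[L]]$grid
    g <- round(g); g[g < 0] <- 0; g[g > 65535] <- 65535
    storage.mode(g) <- "integer"
    # write as (x, y, z) R array -> HDF5 dims (z, y, x), the viewer convention
    gx <- aperm(g, c(3L, 2L, 1L))
    dname <- paste0(grp, "/cells")
    rhdf5::h5createDataset(path, dname, dims = dim(gx),
                           H5type = "H5T_STD_U16LE",
                           chunk = pmin(spec$chunk_shape, dim(gx)),
                           level = as.integer(compression))
    rhdf5::h5write(gx, path, dname)
  }
  rhdf5::h5closeAll()

  .write_bdv_xml(xml_path, basename(path), dim(volume$grid),
                 volume$pitch_um)
  invisible(list(h5 = path, xml = xml_path))
}

.write_bdv_xml <- function(xml_path, h5_name, dim_zyx, pitch) {
  nx <- dim_zyx[3]; ny <- dim_zyx[2]; nz <- dim_zyx[1]
  px <- pitch[["x"]]; py <- pitch[["y"]]; pz <- pitch[["z"]]
  doc <- xml2::xml_new_root("SpimData", version = "0.2")
  xml2::xml_add_child(doc, "BasePath", ".", type = "relative")
  sd <- xml2::xml_add_child(doc, "SequenceDescription")
  il <- xml2::xml_add_child(sd, "ImageLoader", format = "bdv.hdf5")
  xml2::xml_add_child(il, "hdf5", h5_name, type = "relative")
  vs <- xml2::xml_add_child(sd, "ViewSetups")
  v <- xml2::xml_add_child(vs, "ViewSetup")
  xml2::xml_add_child(v, "id", "0")
  xml2::xml_add_child(v, "name", "biopsy")
  xml2::xml_add_child(v, "size", paste(nx, ny, nz))
  vx <- xml2::xml_add_child(v, "voxelSize")
  xml2::xml_add_child(vx, "unit", "micrometer")
  xml2::xml_add_child(vx, "size", paste(px, py, pz))
  tp <- xml2::xml_add_child(sd, "Timepoints", type = "pattern")
  xml2::xml_add_child(tp, "integerpattern", "0")
  vr <- xml2::xml_add_child(doc, "ViewRegistrations")
  reg <- xml2::xml_add_child(vr, "ViewRegistration", timepoint = "0",
                             setup = "0")
  vt <- xml2::xml_add_child(reg, "ViewTransform", type = "affine")
  xml2::xml_add_child(vt, "Name", "calibration")
  xml2::xml_add_child(vt, "affine",
                      paste(c(px, 0, 0, 0, 0, py, 0, 0, 0, 0, pz, 0),
                            collapse = " "))
  xml2::write_xml(doc, xml_path)
}

#' Read one level of a BigDataViewer-style dataset
#'
#' @param path Path to the `.h5` file (or its `.xml` sibling).
#' @param level 1-based pyramid level.
#' @return An [otls_volume()] whose pitches are the level-1 pitches times the
#'   level's downsampling factors.
#' @export
read_bdv <- function(path, level = 1L) {
  if (grepl("\\.xml$", path)) path <- sub("\\.xml$", ".h5", path)
  if (!file.exists(path)) stop("no such file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  res <- t(rhdf5::h5read(path, "s00/resolutions"))   # levels x 3 (xyz)
  n_lev <- nrow(res)
  level <- as.integer(level)
  if (level < 1L || level > n_lev)
    stop(sprintf("level %d not present; available levels: %s",
                 level, paste(seq_len(n_lev), collapse = ", ")))
  gx <- rhdf5::h5read(path, sprintf("t00000/s00/%d/cells", level - 1L))
  grid <- aperm(gx, c(3L, 2L, 1L))                    # back to (z, y, x)
  storage.mode(grid) <- "double"

  xml_path <- sub("\\.h5$", ".xml", path)
  pitch0 <- c(z = 1, y = 1, x = 1)
  if (file.exists(xml_path)) {
    doc <- xml2::read_xml(xml_path)
    sz <- xml2::xml_text(xml2::xml_find_first(doc, "//voxelSize/size"))
    v <- as.numeric(strsplit(trimws(sz), "\\s+")[[1]])  # (x, y, z)
    pitch0 <- c(z = v[3], y = v[2], x = v[1])
  }
  fac_xyz <- res[level, ]
  otls_volume(grid,
              pitch_um = pitch0 * c(z = fac_xyz[3], y = fac_xyz[2],
                                    x = fac_xyz[1]),
              provenance = "deskewed")
}
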