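#' @title Synthetic needle-core biopsy phantoms
#' @description Seeded generators for ground-truthed 3D nuclear-fluorescence
#'   phantoms that emulate prostate needle-core biopsies: benign glands with a
#'   two-cell epithelial layer, well-formed single-layer cancer glands
#'   (Gleason pattern 3) and fused cancer glands (Gleason pattern 4), on a dim
#'   stromal background. Only a nuclear channel is modelled (the imaging assay
#'   uses a single nucleic-acid-binding fluorophore), so glands appear as
#'   rings of bright nuclei around an unstained lumen.
#' @name phantom
NULL

.GLAND_KINDS <- c("benign", "gleason3", "gleason4")

#' Specify one gland
#'
#' A gland is modelled as a spherical acinar cross-section: an unstained lumen
#' of radius `lumen_radius` surrounded by `n_layers` concentric shells of
#' nuclei of radius `nucleus_radius`. Benign glands carry two layers
#' (secretory + basal); cancer glands (Gleason 3/4) have lost the basal layer
#' and carry one. Gleason-4 glands list the indices of the glands their lumens
#' fuse with.
#'
#' @param center Numeric length-3 gland centre, um, in (x = scan, y = lateral,
#'   z = depth-from-surface) order.
#' @param kind One of `"benign"`, `"gleason3"`, `"gleason4"`.
#' @param lumen_radius,nucleus_radius Radii in um; `lumen_radius` must exceed
#'   `nucleus_radius`, both positive.
#' @param fused_partners Integer indices of fusion partners (Gleason 4 only).
#' @param depth_range Length-2 interval, um, the gland must occupy in z.
#' @return A list of class `gland_spec`.
#' @export
gland_spec <- function(center, kind, lumen_radius, nucleus_radius,
                       fused_partners = integer(), depth_range = NULL) {
  kind <- match.arg(kind, .GLAND_KINDS)
  stopifnot(length(center) == 3L, is.numeric(center),
            lumen_radius > nucleus_radius, nucleus_radius > 0)
  n_layers <- if (kind == "benign") 2L else 1L
  if (kind != "gleason4" && length(fused_partners) > 0L)
    stop("only gleason4 glands may have fused partners")
  if (is.null(depth_range)) {
    half <- lumen_radius + (2 * n_layers - 1 + 1.25) * nucleus_radius
    depth_range <- c(center[3] - half, center[3] + half)
  }
  stopifnot(length(depth_range) == 2L, depth_range[1] <= depth_range[2])
  structure(list(center = as.numeric(center), kind = kind,
                 lumen_radius = lumen_radius, n_layers = n_layers,
                 nucleus_radius = nucleus_radius,
                 fused_partners = as.integer(fused_partners),
                 depth_range = as.numeric(depth_range)),
            class = "gland_spec")
}

# outer radius of the rendered gland: outermost shell plus the largest
# nuclear semi-axis (anisotropy ratio <= 1.2), with a little slack
.gland_outer_radius <- function(lumen, n_layers, nuc) {
  lumen + (2 * n_layers - 1) * nuc + 1.25 * nuc
}

# place ~uniform points on a sphere of radius r about ctr (local RNG state)
.sphere_points <- function(n, ctr, r) {
  u <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - u^2)
  cbind(ctr[1] + r * s * cos(phi),
        ctr[2] + r * s * sin(phi),
        ctr[3] + r * u)
}

# render one solid ellipsoidal nucleus into vol/lab by reference-free update;
# returns modified list(vol, lab). pitch um/voxel; axes (x, y, z) as dims 1:3.
.paint_nucleus <- function(vol, lab, ctr, radius, axis_ratio, peak, cancer,
                           pitch) {
  dims <- dim(vol)
  semi <- radius * axis_ratio           # per-axis semi-axes, um
  lo <- pmax(1L, floor(ctr / pitch - semi / pitch) + 1L)
  hi <- pmin(dims, ceiling(ctr / pitch + semi / pitch) + 1L)
  if (any(lo > hi)) return(list(vol = vol, lab = lab))
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  # voxel-centre coordinates (0-based grid: voxel i sits at (i-1)*pitch)
  dx <- ((ix - 1L) * pitch - ctr[1]) / semi[1]
  dy <- ((iy - 1L) * pitch - ctr[2]) / semi[2]
  dz <- ((iz - 1L) * pitch - ctr[3]) / semi[3]
  inside <- outer(outer(dx^2, dy^2, "+"), dz^2, "+") <= 1
  sub <- vol[ix, iy, iz, drop = FALSE]
  sub[inside] <- pmax(sub[inside], peak)
  vol[ix, iy, iz] <- sub
  if (cancer) {
    lsub <- lab[ix, iy, iz, drop = FALSE]
    lsub[inside] <- 1L
    lab[ix, iy, iz] <- lsub
  }
  list(vol = vol, lab = lab)
}

#' Generate a seeded synthetic biopsy phantom
#'
#' Builds a 3D nuclear-intensity volume the size of a (possibly truncated)
#' needle-core biopsy, populates it with glands drawn from `gland_mix`, and
#' records per-voxel cancer labels so every downstream stage can be checked
#' against ground truth. The full holder slot is 0.9 mm wide x 0.6 mm deep x
#' 25 mm long; defaults here use a short segment so volumes stay small.
#'
#' Nuclei are solid ellipsoids (radius `nucleus_radius`, mild random
#' anisotropy) of intensity `nuclear_peak` placed on concentric spherical
#' shells around each lumen; stroma sits at `stroma_frac * nuclear_peak`.
#' Gleason-4 glands are laid down in fused groups whose centres are closer
#' than the sum of their lumen radii, producing merged lumens; their
#' `fused_partners` fields are symmetric. The phantom's `truth_label` is
#' `"cancer"` iff any gland is Gleason 3 or 4.
#'
#' @param length_um,width_um,thickness_um Phantom extent, um (x = scan,
#'   y = lateral, z = depth). Must not exceed the 25 mm x 0.9 mm x 0.6 mm
#'   holder slot.
#' @param gland_mix Named counts per gland kind, e.g.
#'   `c(benign = 4, gleason3 = 2, gleason4 = 2)`. Missing names count 0.
#' @param voxel_pitch_um Isotropic voxel pitch, um; must not exceed
#'   `nucleus_radius` so nuclei stay resolvable.
#' @param seed Integer seed; all randomness is local to the call.
#' @param lumen_radius Named per-kind lumen radii, um. Benign acini are
#'   larger than the small, crowded glands of Gleason 3/4.
#' @param nucleus_radius Nuclear radius, um. Default 3 (epithelial nuclei run
#'   5 to 7 um across).
#' @param nuclear_peak Peak nuclear intensity, arbitrary fluorescence units.
#' @param stroma_frac Stromal background as a fraction of `nuclear_peak`.
#' @param depth_range Optional length-2 interval, um: confine *cancer* gland
#'   centres so the whole gland lies inside this depth band (used to emulate
#'   a lesion visible only at a specific image depth).
#' @return A list of class `biopsy_phantom`: `volume` (numeric array,
#'   dims x/y/z), `labels` (integer array, 1 = cancer voxel), `glands`
#'   (list of [gland_spec()]), `truth_label`, `voxel_pitch_um`, `extent_um`,
#'   `seed`.
#' @examples
#' ph <- generate_phantom(200, 200, 100, c(benign = 2), voxel_pitch_um = 2,
#'                        seed = 1)
#' ph$truth_label  # "benign"
#' @export
generate_phantom <- function(length_um, width_um, thickness_um,
                             gland_mix = c(benign = 0),
                             voxel_pitch_um = 2,
                             seed = 1L,
                             lumen_radius = c(benign = 22, gleason3 = 12,
                                              gleason4 = 12),
                             nucleus_radius = 3,
                             nuclear_peak = 100,
                             stroma_frac = 0.05,
                             depth_range = NULL) {
  stopifnot(length_um > 0, width_um > 0, thickness_um > 0,
            voxel_pitch_um > 0)
  if (length_um > 25000 || width_um > 900 || thickness_um > 600)
    stop("phantom exceeds the 25 mm x 0.9 mm x 0.6 mm holder slot")
  if (voxel_pitch_um > nucleus_radius)
    stop("voxel_pitch_um must not exceed nucleus_radius (nuclei unresolvable)")
  lr_default <- c(benign = 22, gleason3 = 12, gleason4 = 12)
  lr_default[names(lumen_radius)] <- lumen_radius
  lumen_radius <- lr_default
  counts <- vapply(.GLAND_KINDS, function(k) {
    v <- if (k %in% names(gland_mix)) gland_mix[[k]] else NULL
    if (is.null(v) || is.na(v)) 0L else as.integer(v)
  }, integer(1))
  if (any(counts < 0)) stop("gland counts must be >= 0")

  dims <- pmax(1L, as.integer(round(c(length_um, width_um, thickness_um) /
                                      voxel_pitch_um)))
  if (prod(dims) == 0) stop("zero-size volume")

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))

  vol <- array(stroma_frac * nuclear_peak, dim = dims)
  lab <- array(0L, dim = dims)
  extent <- c(length_um, width_um, thickness_um)

  glands <- list()
  place_center <- function(outer_r, zr) {
    # margin so every rendered voxel stays inside the extent
    lo <- rep(outer_r, 3); hi <- extent - outer_r
    if (!is.null(zr)) {
      lo[3] <- max(lo[3], zr[1] + outer_r)
      hi[3] <- min(hi[3], zr[2] - outer_r)
    }
    if (any(hi < lo)) return(NULL)
    stats::runif(3, lo, hi)
  }

  add_gland <- function(kind, center, zr) {
    g <- gland_spec(center, kind, lumen_radius[[kind]], nucleus_radius,
                    depth_range = zr)
    glands[[length(glands) + 1L]] <<- g
    g
  }

  # benign and gleason3: independent glands
  for (kind in c("benign", "gleason3")) {
    zr <- if (kind == "gleason3") depth_range else NULL
    for (i in seq_len(counts[[kind]])) {
      n_layers <- if (kind == "benign") 2L else 1L
      outer_r <- .gland_outer_radius(lumen_radius[[kind]], n_layers,
                                     nucleus_radius)
      ctr <- place_center(outer_r, zr)
      if (is.null(ctr))
        stop(sprintf("gland %s #%d cannot fit inside the phantom extent",
                     kind, i))
      add_gland(kind, ctr, zr)
    }
  }
  # gleason4: fused groups of 2 (last group of 3 when the count is odd)
  n4 <- counts[["gleason4"]]
  if (n4 > 0L) {
    sizes <- if (n4 == 1L) 1L
             else if (n4 %% 2L == 0L) rep(2L, n4 %/% 2L)
             else c(rep(2L, (n4 - 3L) %/% 2L), 3L)
    for (gs in sizes) {
      r <- lumen_radius[["gleason4"]]
      # room for offset centres plus each member's rendered extent
      outer_r <- (if (gs > 1L) 0.6 * r else 0) +
        .gland_outer_radius(r, 1L, nucleus_radius)
      ctr <- place_center(outer_r, depth_range)
      if (is.null(ctr))
        stop("gleason4 gland group cannot fit inside the phantom extent")
      first <- length(glands) + 1L
      for (j in seq_len(gs)) {
        # centres ~1.2 * lumen_radius apart -> lumens overlap (fuse)
        off <- if (gs == 1L) c(0, 0, 0) else
          0.6 * r * c(cos(2 * pi * j / gs), sin(2 * pi * j / gs), 0)
        add_gland("gleason4", ctr + off, depth_range)
      }
      idx <- first:(first + gs - 1L)
      for (j in idx) glands[[j]]$fused_partners <- setdiff(idx, j)
    }
  }

  # render: nuclei on concentric shells; shell circumference sets nucleus count
  for (g in glands) {
    for (layer in seq_len(g$n_layers)) {
      r_shell <- g$lumen_radius + (2 * layer - 1) * g$nucleus_radius
      n_nuc <- max(8L, ceiling(4 * pi * r_shell^2 /
                                 (pi * (2 * g$nucleus_radius)^2) * 0.7))
      pts <- .sphere_points(n_nuc, g$center, r_shell)
      ratios <- matrix(stats::runif(3L * n_nuc, 0.8, 1.2), ncol = 3L)
      cancer <- g$kind != "benign"
      for (i in seq_len(n_nuc)) {
        res <- .paint_nucleus(vol, lab, pts[i, ], g$nucleus_radius,
                              ratios[i, ], nuclear_peak, cancer,
                              voxel_pitch_um)
        vol <- res$vol; lab <- res$lab
      }
    }
  }

  truth <- if (any(vapply(glands, function(g) g$kind != "benign", logical(1))))
    "cancer" else "benign"

  structure(list(volume = vol, labels = lab, glands = glands,
                 truth_label = truth, voxel_pitch_um = voxel_pitch_um,
                 extent_um = extent, seed = as.integer(seed)),
            class = "biopsy_phantom")
}

#' @export
print.biopsy_phantom <- function(x, ...) {
  kinds <- vapply(x$glands, `[[`, character(1), "kind")
  cat(sprintf("Biopsy phantom: %s, %s voxels @ %g um, %d glands (%s)\n",
              x$truth_label, paste(dim(x$volume), collapse = "x"),
              x$voxel_pitch_um, length(x$glands),
              if (length(kinds)) paste(names(table(kinds)), table(kinds),
                                       sep = ":", collapse = ", ") else "none"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
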