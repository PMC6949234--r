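#' Phantom specification
#'
#' A parametric digital breast phantom: a uniform adipose-like background
#' slab with embedded test objects -- beads (small spheres emulating
#' microcalcifications), masses (larger spheres) and fibers (cylinders).
#'
#' @param grid a [VolumeGrid-class].
#' @param backgroundMu background attenuation (1/mm).
#' @param objects list of objects, each a list with fields `kind`
#'   (`"bead"`, `"mass"` or `"fiber"`), `center` (3D point, mm), `mu`
#'   (attenuation, 1/mm), `diameter` (mm), and for fibers `length` (mm) and
#'   `orientation` (3D axis vector).
#' @return a classed list (`PhantomSpec`).
#' @export
phantomSpec <- function(grid, backgroundMu, objects = list()) {
  stopifnot(is(grid, "VolumeGrid"), backgroundMu >= 0)
  lo <- grid@origin
  hi <- grid@origin + grid@dims * grid@spacing
  for (ob in objects) {
    stopifnot(ob$kind %in% c("bead", "mass", "fiber"),
              length(ob$center) == 3L, ob$mu >= 0, ob$diameter > 0)
    ext <- objectExtent(ob)
    if (any(ob$center - ext < lo) || any(ob$center + ext > hi))
      stop("object outside grid bounds: ", ob$kind, " at (",
           paste(ob$center, collapse = ", "), ")")
  }
  structure(list(grid = grid, backgroundMu = backgroundMu,
                 objects = objects), class = "PhantomSpec")
}

# per-axis half-extent of an object's bounding box
objectExtent <- function(ob) {
  r <- ob$diameter / 2
  if (ob$kind == "fiber") {
    a <- ob$orientation / sqrt(sum(ob$orientation^2))
    abs(a) * ob$length / 2 + r * sqrt(pmax(0, 1 - a^2))
  } else {
    rep(r, 3L)
  }
}

#' Noise specification
#'
#' White Gaussian noise calibrated so that the measured signal-to-noise
#' ratio, defined as `20 * log10(||b + eps|| / ||eps||)` with the noisy
#' projections in the numerator, equals the requested value.
#'
#' @param snrDb target SNR in dB.
#' @param seed RNG seed (fixed for reproducibility).
#' @param convention `"noisy"` (numerator `||b + eps||`, the default) or
#'   `"clean"` (numerator `||b||`, the conventional alternative).
#' @return a classed list (`NoiseSpec`).
#' @export
noiseSpec <- function(snrDb = 50, seed = 1L,
                      convention = c("noisy", "clean")) {
  stopifnot(is.finite(snrDb))
  structure(list(snrDb = as.numeric(snrDb), seed = as.integer(seed),
                 convention = match.arg(convention)), class = "NoiseSpec")
}

#' Rasterize a phantom onto its voxel grid
#'
#' Spheres and cylinders are rasterized with partial-volume weighting: each
#' voxel is sampled at a fixed stratified `subsamples^3` grid of interior
#' points and the voxel attenuation is the background plus the inside
#' fraction times the object's excess attenuation. Deterministic: no
#' randomness is involved.
#'
#' @param spec a [phantomSpec()].
#' @param subsamples sub-voxel sampling points per axis (default 3).
#' @return a [Volume-class].
#' @export
makePhantom <- function(spec, subsamples = 3L) {
  stopifnot(inherits(spec, "PhantomSpec"), subsamples >= 1L)
  grid <- spec$grid
  dm <- grid@dims; sp <- grid@spacing; or <- grid@origin
  vol <- array(spec$backgroundMu, dim = dm)
  off <- (seq_len(subsamples) - 0.5) / subsamples
  offsets <- as.matrix(expand.grid(ox = off * sp[1], oy = off * sp[2],
                                   oz = off * sp[3]))
  for (ob in spec$objects) {
    r <- ob$diameter / 2
    ext <- objectExtent(ob)
    i0 <- pmax(1L, floor((ob$center - ext - or) / sp) + 1L)
    i1 <- pmin(dm, ceiling((ob$center + ext - or) / sp))
    if (any(i0 > i1)) next
    ix <- i0[1]:i1[1]; iy <- i0[2]:i1[2]; iz <- i0[3]:i1[3]
    corners <- as.matrix(expand.grid(
      x = or[1] + (ix - 1L) * sp[1],
      y = or[2] + (iy - 1L) * sp[2],
      z = or[3] + (iz - 1L) * sp[3]))
    inside <- numeric(nrow(corners))
    if (ob$kind == "fiber") {
      ax <- ob$orientation / sqrt(sum(ob$orientation^2))
      for (m in seq_len(nrow(offsets))) {
        p <- sweep(corners, 2L, -offsets[m, ])  # corner + offset
        d <- sweep(p, 2L, ob$center)
        along <- as.numeric(d %*% ax)
        rad2 <- rowSums(d^2) - along^2
        inside <- inside + (abs(along) <= ob$length / 2 & rad2 <= r^2)
      }
    } else {
      for (m in seq_len(nrow(offsets))) {
        p <- sweep(corners, 2L, -offsets[m, ])
        d <- sweep(p, 2L, ob$center)
        inside <- inside + (rowSums(d^2) <= r^2)
      }
    }
    frac <- array(inside / nrow(offsets),
                  dim = c(length(ix), length(iy), length(iz)))
    vol[ix, iy, iz] <- vol[ix, iy, iz, drop = FALSE] +
      frac * (ob$mu - spec$backgroundMu)
  }
  volume(vol, grid)
}

#' Simulate noiseless projections of a phantom
#'
#' Forward projection of the phantom volume under the scan geometry; the
#' noiseless data vector b.
#'
#' @param phantom a [Volume-class].
#' @param geometry a [ScanGeometry-class].
#' @param ... passed to [forwardProject()].
#' @return a [ProjectionStack-class].
#' @export
simulateProjections <- function(phantom, geometry, ...) {
  forwardProject(phantom, geometry, ...)
}

#' Add SNR-calibrated Gaussian noise
#'
#' Draws white Gaussian noise with the fixed seed and scales it
#' analytically so the measured SNR matches `snrDb` exactly. Under the
#' `"noisy"` convention the scale c solves
#' `20 log10(||b + c e|| / ||c e||) = snrDb`, a quadratic in c with the
#' positive root taken; under `"clean"` it is `||b|| / (10^(snr/20) ||e||)`.
#' The caller's RNG state is left untouched.
#'
#' @param b a [ProjectionStack-class]; must not be identically zero.
#' @param noise a [noiseSpec()].
#' @return a [ProjectionStack-class] of `b + eps`.
#' @export
addNoise <- function(b, noise) {
  stopifnot(inherits(noise, "NoiseSpec"))
  bv <- b@values
  nb2 <- sum(bv^2)
  if (nb2 == 0) stop("b: SNR is undefined for identically zero projections")
  state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(noise$seed)
  e <- array(rnorm(length(bv)), dim = dim(bv))
  ne2 <- sum(e^2)
  r <- 10^(noise$snrDb / 20)
  if (noise$convention == "clean") {
    cc <- sqrt(nb2) / (r * sqrt(ne2))
  } else {
    # ||b + c e||^2 = r^2 c^2 ||e||^2  =>
    # c^2 ne2 (r^2 - 1) - 2 c <b,e> - nb2 = 0, positive root
    be <- sum(bv * e)
    aq <- ne2 * (r^2 - 1)
    if (aq <= 0) stop("snrDb: must be positive under the 'noisy' convention")
    cc <- (2 * be + sqrt(4 * be^2 + 4 * aq * nb2)) / (2 * aq)
  }
  projectionStack(bv + cc * e, b@geometry)
}

#' Desk-scale digital phantom preset
#'
#' A proportionally scaled version of the packaged simulation study: at full
#' scale, a 3000 x 1000 x 50 volume with 0.100 mm in-plane voxels and
#' 1.000 mm slices, projected onto a 3200 x 1100 pixel detector with
#' 0.100 mm pitch from 11 views spanning -15 to +15 degrees (690 mm source
#' height), with Gaussian noise at SNR 50 dB. The phantom holds a cluster of
#' five 0.300 mm beads (3 voxels wide in-plane) at the central slice, plus a
#' mass and a fiber, in a uniform adipose-like background
#' (0.05 /mm; bead 10x, mass 1.5x, fiber 2x background -- surrogate values,
#' configurable via the returned spec).
#'
#' In-plane counts scale by `scale`; the in-depth count scales by
#' `min(1, 2 * scale)` so desk-scale presets keep several slices
#' (`scale = 0.05` gives a 150 x 50 x 5 volume and a 160 x 55 detector).
#'
#' @param scale in (0, 1]; 1 reproduces the full-size configuration.
#' @param snrDb noise level (default 50).
#' @param seed noise seed (default 1).
#' @return list with `phantom` (a [phantomSpec()]), `grid`, `geometry`
#'   (a [ScanGeometry-class]) and `noise` (a [noiseSpec()]).
#' @export
d3Preset <- function(scale = 1, snrDb = 50, seed = 1L) {
  stopifnot(scale > 0, scale <= 1)
  Nx <- max(9L, round(3000 * scale))
  Ny <- max(9L, round(1000 * scale))
  Nz <- max(3L, round(50 * min(1, 2 * scale)))
  nxDet <- max(12L, round(3200 * scale))
  nyDet <- max(12L, round(1100 * scale))
  grid <- volumeGrid(c(Nx, Ny, Nz), c(0.1, 0.1, 1.0),
                     origin = c(-Nx * 0.1 / 2, -Ny * 0.1 / 2, 1))
  geometry <- scanGeometry(
    sourceDetectorDistance = 690,
    angles = seq(-15, 15, length.out = 11),
    detectorRows = nyDet, detectorCols = nxDet,
    pitchX = 0.1, pitchY = 0.1)
  bg <- 0.05
  zc <- grid@origin[3] + Nz * 1.0 / 2     # central-slice mid height
  beadMu <- 10 * bg; massMu <- 1.5 * bg; fiberMu <- 2 * bg
  beadD <- 0.300
  spread <- min(1.0, Ny * 0.1 / 8)        # cluster spacing, mm
  # bead centers sit at voxel centers (half-pitch offset) so a 0.300 mm
  # bead occupies a clean 3-voxel-wide in-plane footprint
  beads <- lapply(list(c(0, 0), c(spread, spread), c(-spread, spread),
                       c(spread, -spread), c(-spread, -spread)),
                  function(o) list(kind = "bead",
                                   center = c(o[1] + 0.05, o[2] + 0.05, zc),
                                   mu = beadMu, diameter = beadD))
  xOff <- Nx * 0.1 / 4
  massD <- min(2.0, Nz * 1.0 / 3, Ny * 0.1 / 3)
  objects <- c(beads, list(
    list(kind = "mass", center = c(-xOff, 0, zc), mu = massMu,
         diameter = massD),
    list(kind = "fiber", center = c(xOff, 0, zc), mu = fiberMu,
         diameter = 0.3, length = min(3.0, Nx * 0.1 / 4),
         orientation = c(1, 0, 0))))
  list(phantom = phantomSpec(grid, bg, objects),
       grid = grid, geometry = geometry,
       noise = noiseSpec(snrDb = snrDb, seed = seed))
}
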