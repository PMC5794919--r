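# Digital hand/wrist phantom: elongated "bone" regions split by a dark
# growth-plate slab whose width shrinks linearly with age until fusion.
# Geometry, not MR physics, carries the age signal: the analysis downstream
# only needs gap widths that are recoverable from image intensity profiles.

#' Phantom specification
#'
#' Bundles every parameter of the synthetic hand/wrist volume. The default
#' grid is a desk-scale 64 x 64 x 16 volume with six ossification sites;
#' the full-size acquisition geometry (matrix 129 x 230, 72 slices, voxels
#' 0.45 x 0.45 x 0.90 mm) can be requested through `grid_shape` /
#' `voxel_size`.
#'
#' @param true_age Chronological age in years driving the growth-plate gaps.
#' @param grid_shape Integer triple (readout, pe1, pe2) of voxel counts.
#' @param voxel_size Numeric triple, mm per voxel along each axis.
#' @param n_bones Number of modeled ossification sites (1..6 on the default
#'   layout).
#' @param gap_widths Optional numeric vector of per-site growth-plate widths
#'   in mm. When `NULL` they are derived from `true_age` via [age_to_gap()]
#'   plus i.i.d. Gaussian site jitter of SD `gap_jitter_sd` (clipped at 0).
#' @param tissue_levels Named intensities in `[0, 1]` for
#'   `bone`, `cartilage`, `muscle`, `background`.
#' @param noise_sigma Standard deviation of the complex k-space noise on the
#'   unit intensity scale (the phantom peak is `tissue_levels["bone"]`).
#'   Each real/imaginary component receives `noise_sigma / sqrt(2)`.
#' @param fusion_age Age in years at which all gaps reach 0 (default 18).
#' @param gap_jitter_sd SD in mm of per-site gap jitter (default 0.05).
#' @param seed Integer seed; identical spec + seed gives bit-identical
#'   phantom and k-space.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(true_age,
                         grid_shape = c(64L, 64L, 16L),
                         voxel_size = c(0.45, 0.45, 0.90),
                         n_bones = 6L,
                         gap_widths = NULL,
                         tissue_levels = c(bone = 0.9, cartilage = 0.25,
                                           muscle = 0.4, background = 0),
                         noise_sigma = 0.02,
                         fusion_age = 18,
                         gap_jitter_sd = 0.05,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape <= 0L))
    stop("grid_shape must be 3 positive integers")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive values (mm)")
  if (n_bones < 1L) stop("n_bones must be >= 1")
  req <- c("bone", "cartilage", "muscle", "background")
  if (!all(req %in% names(tissue_levels)))
    stop("tissue_levels must name bone, cartilage, muscle, background")
  if (any(tissue_levels < 0 | tissue_levels > 1))
    stop("tissue intensities must lie in [0, 1]")
  if (is.null(gap_widths)) {
    base <- age_to_gap(true_age, fusion_age = fusion_age)
    gap_widths <- with_seed(seed + 211L, {
      if (base > 0) pmax(0, base + stats::rnorm(n_bones, 0, gap_jitter_sd))
      else rep(0, n_bones)
    })
  }
  if (length(gap_widths) != n_bones)
    stop("gap_widths must have one entry per bone")
  if (any(gap_widths < 0)) stop("gap_widths must be >= 0")
  structure(list(true_age = true_age, grid_shape = grid_shape,
                 voxel_size = voxel_size, n_bones = as.integer(n_bones),
                 gap_widths = gap_widths, tissue_levels = tissue_levels,
                 noise_sigma = noise_sigma, fusion_age = fusion_age,
                 gap_jitter_sd = gap_jitter_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("phantom_spec:", paste(x$grid_shape, collapse = " x "),
      "grid,", x$n_bones, "sites, age", format(x$true_age, digits = 4),
      "y, gaps [mm]", paste(format(x$gap_widths, digits = 2), collapse = " "),
      "\n")
  invisible(x)
}

#' Age to growth-plate gap width
#'
#' Linear maturation model: the epiphyseal gap narrows from 3 mm at age 10
#' to 0 mm at `fusion_age`, and stays 0 (fused) afterwards. Strictly
#' decreasing below `fusion_age`, identically zero above.
#'
#' @param age Age(s) in years.
#' @param fusion_age Fusion age in years (default 18).
#' @param gap_at_10 Gap width in mm at age 10 (default 3).
#' @return Gap width(s) in mm.
#' @export
age_to_gap <- function(age, fusion_age = 18, gap_at_10 = 3.0) {
  pmax(gap_at_10 * (fusion_age - age) / (fusion_age - 10), 0)
}

#' Gap width to age (inverse maturation model)
#'
#' Inverts [age_to_gap()] on its decreasing segment. A width of 0 maps to
#' `fusion_age` exactly; widths above the curve maximum (`gap_at_10`) are
#' clipped to the curve domain with a warning.
#'
#' @inheritParams age_to_gap
#' @param width Gap width(s) in mm.
#' @return Age(s) in years.
#' @export
gap_to_age <- function(width, fusion_age = 18, gap_at_10 = 3.0) {
  if (any(width < 0)) stop("gap widths must be >= 0")
  if (any(width > gap_at_10)) {
    warning("gap width above curve maximum; clipped to curve domain")
    width <- pmin(width, gap_at_10)
  }
  fusion_age - width * (fusion_age - 10) / gap_at_10
}

# mm coordinate vectors, centered on the grid (voxel centers).
grid_coords <- function(grid_shape, voxel_size) {
  lapply(1:3, function(k) {
    n <- grid_shape[k]
    (seq_len(n) - (n + 1) / 2) * voxel_size[k]
  })
}

# Linear edge ramp of full width `e`: 0 below -e/2, 1 above e/2.
soft_step <- function(t, e) pmin(pmax(t / e + 0.5, 0), 1)

#' Generate the ground-truth hand/wrist volume
#'
#' Renders `n_bones` elongated bone regions (bright marrow) inside a muscle
#' envelope, each split at its mid-shaft by a dark growth-plate slab of the
#' requested width. Edges are rendered with a linear one-voxel partial-volume
#' ramp so that the full width at half contrast of the slab profile equals
#' the requested width exactly (for widths of at least one voxel), which
#' makes sub-voxel width measurement well-posed.
#'
#' Bones run along the first phase-encode axis, so undersampling blur along
#' that axis broadens the measured gap directly.
#'
#' @param spec A [phantom_spec()].
#' @return Object of class `image_volume` with `provenance = "ground-truth"`
#'   and attribute `sites`: a data.frame of per-site slab center coordinates
#'   (mm), requested widths (mm), bone half-lengths and radii.
#' @export
make_hand_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape; vs <- spec$voxel_size
  lv <- spec$tissue_levels
  co <- grid_coords(gs, vs)
  x <- co[[1]]; y <- co[[2]]; z <- co[[3]]
  ex <- vs[1]; ey <- vs[2]; ez <- vs[3]      # partial-volume edge widths

  fov <- gs * vs
  bone_len <- 0.70 * fov[2]
  if (any(spec$gap_widths > bone_len))
    stop("gap width exceeds bone length: geometry error")

  # site layout: up to 3 columns across the readout axis x 2 slabs in z
  ncol_x <- min(3L, spec$n_bones)
  cx_pos <- (seq_len(ncol_x) - (ncol_x + 1) / 2) * fov[1] / (ncol_x + 0.5)
  cz_pos <- c(-0.22, 0.22) * fov[3]
  centers <- with_seed(spec$seed + 97L, {
    t(vapply(seq_len(spec$n_bones), function(b) {
      cx <- cx_pos[(b - 1L) %% ncol_x + 1L]
      cz <- cz_pos[(b - 1L) %/% ncol_x + 1L]
      cy <- stats::rnorm(1, 0, 0.04 * fov[2])   # mild anatomical jitter
      c(cx, cy, cz)
    }, numeric(3)))
  })
  radius <- 0.30 * fov[1] / (ncol_x + 0.5)

  # muscle envelope: soft ellipsoid enclosing all bones
  X <- array(rep(x, times = gs[2] * gs[3]), gs)
  Y <- array(rep(rep(y, each = gs[1]), times = gs[3]), gs)
  Z <- array(rep(z, each = gs[1] * gs[2]), gs)
  rx <- 0.44 * fov[1]; ry <- 0.46 * fov[2]; rz <- 0.40 * fov[3]
  renv <- sqrt((X / rx)^2 + (Y / ry)^2 + (Z / rz)^2)
  w_env <- soft_step(1 - renv, 2 * ex / rx)
  img <- lv["background"] + (lv["muscle"] - lv["background"]) * w_env

  for (b in seq_len(spec$n_bones)) {
    cb <- centers[b, ]
    w <- spec$gap_widths[b]
    rho <- sqrt((X - cb[1])^2 + (Z - cb[3])^2)
    w_cyl <- soft_step(radius - rho, ex) *
      soft_step(bone_len / 2 - abs(Y - cb[2]), ey)
    # trapezoid dip along the bone axis: FWHM = w for w >= one voxel
    dip <- if (w > 0) {
      pmin(pmax((w / 2 + ey / 2 - abs(Y - cb[2])) / ey, 0), 1)
    } else 0
    lvl <- lv["bone"] + (lv["cartilage"] - lv["bone"]) * dip
    img <- img + (lvl - img) * w_cyl
  }
  dimnames(img) <- NULL

  sites <- data.frame(site = seq_len(spec$n_bones),
                      center_x = centers[, 1], center_y = centers[, 2],
                      center_z = centers[, 3],
                      width_mm = spec$gap_widths,
                      bone_half_length = bone_len / 2,
                      radius = radius)
  out <- image_volume(img, voxel_size = vs, provenance = "ground-truth")
  attr(out, "sites") <- sites
  out
}

#' Construct an image volume
#'
#' Lightweight container for a real or complex 3D array with voxel size and
#' a provenance label.
#'
#' @param values 3D array.
#' @param voxel_size mm triple.
#' @param provenance One of `"ground-truth"`, `"zero-filled"`, `"tgv"`,
#'   `"acquired-sim"`.
#' @return Object of class `image_volume`.
#' @export
image_volume <- function(values, voxel_size,
                         provenance = c("ground-truth", "zero-filled",
                                        "tgv", "acquired-sim")) {
  provenance <- match.arg(provenance)
  stopifnot(length(dim(values)) == 3L, length(voxel_size) == 3L)
  if (any(!is.finite(Mod(values)))) stop("image magnitude must be finite")
  structure(list(values = values, voxel_size = voxel_size,
                 provenance = provenance),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("image_volume [", x$provenance, "]: ",
      paste(dim(x$values), collapse = " x "), " voxels, ",
      paste(format(x$voxel_size, digits = 3), collapse = " x "), " mm\n",
      sep = "")
  invisible(x)
}

#' Smooth complex coil sensitivity maps
#'
#' Each coil is a low-order complex polynomial in the normalized coordinates
#' multiplied by a Gaussian falloff from the coil center. Coils sit on a
#' ring around the readout axis, so their sensitivities vary across both
#' phase-encode dimensions — the variation parallel imaging relies on to
#' separate aliased voxels. Maps are normalized
#' so that the sum over coils of squared magnitudes is 1 at every voxel
#' ("sos" convention); with a single coil the normalized magnitude is
#' therefore identically 1.
#'
#' @param n_coils Number of receive coils (>= 1).
#' @param grid_shape Integer triple of voxel counts.
#' @param voxel_size mm triple.
#' @param smoothness Gaussian falloff length scale in mm (default 60).
#'   Together with the coil-ring radius this sets the spatial bandwidth of
#'   the maps; the default keeps them representable at the resolution of a
#'   small central calibration region, as autocalibrated sensitivity
#'   estimation assumes.
#' @param seed Integer seed for the polynomial coefficients.
#' @return Object of class `sensitivity_maps`: `values` is a complex
#'   (nx, ny, nz, n_coils) array, `normalization = "sos"`. The analytic
#'   generating parameters are kept in `$params` so the continuous map can
#'   be evaluated off-grid with [eval_coil_maps()].
#' @export
make_coil_maps <- function(n_coils, grid_shape = c(64L, 64L, 16L),
                           voxel_size = c(0.45, 0.45, 0.90),
                           smoothness = 60, seed = 1L) {
  n_coils <- as.integer(n_coils)
  if (length(n_coils) != 1L || is.na(n_coils) || n_coils < 1L)
    stop("n_coils must be >= 1")
  fov <- grid_shape * voxel_size
  ring_r <- 1.2 * max(fov[2], fov[3])
  params <- with_seed(seed, {
    lapply(seq_len(n_coils), function(cc) {
      ang <- 2 * pi * (cc - 1) / n_coils
      list(center = c(0, ring_r * cos(ang), ring_r * sin(ang)),
           re = c(1 + 0.3 * stats::rnorm(1), 0.15 * stats::rnorm(3)),
           im = c(0.3 * stats::rnorm(1), 0.15 * stats::rnorm(3)))
    })
  })
  pars <- list(coils = params, smoothness = smoothness, fov = fov)
  co <- grid_coords(grid_shape, voxel_size)
  pts <- cbind(rep(co[[1]], times = grid_shape[2] * grid_shape[3]),
               rep(rep(co[[2]], each = grid_shape[1]), times = grid_shape[3]),
               rep(co[[3]], each = grid_shape[1] * grid_shape[2]))
  raw <- eval_coil_maps_raw(pars, pts)           # (nvox x n_coils) complex
  if (!is.matrix(raw)) raw <- matrix(raw, nrow = nrow(pts))
  sos <- sqrt(rowSums(Mod(raw)^2))
  vals <- array(raw / sos, c(grid_shape, n_coils))
  structure(list(values = vals, normalization = "sos",
                 voxel_size = voxel_size, params = pars),
            class = "sensitivity_maps")
}

# Unnormalized analytic coil map at arbitrary mm points (nvox x 3 matrix).
eval_coil_maps_raw <- function(pars, pts) {
  s <- pars$smoothness; fov <- pars$fov
  xn <- pts[, 1] / fov[1]; yn <- pts[, 2] / fov[2]; zn <- pts[, 3] / fov[3]
  vapply(pars$coils, function(p) {
    d2 <- (pts[, 1] - p$center[1])^2 + (pts[, 2] - p$center[2])^2 +
      (pts[, 3] - p$center[3])^2
    env <- exp(-d2 / (2 * s^2))
    poly <- complex(real = p$re[1] + p$re[2] * xn + p$re[3] * yn + p$re[4] * zn,
                    imaginary = p$im[1] + p$im[2] * xn + p$im[3] * yn +
                      p$im[4] * zn)
    poly * env
  }, complex(nrow(pts)))
}

#' Evaluate the normalized analytic coil maps off-grid
#'
#' Evaluates the continuous expression behind [make_coil_maps()] (polynomial
#' times Gaussian envelope, then sos normalization across coils) at
#' arbitrary points; used to bound map smoothness independently of the
#' gridded values.
#'
#' @param maps A `sensitivity_maps` object from [make_coil_maps()].
#' @param pts Numeric matrix (n x 3) of mm coordinates.
#' @return Complex matrix (n x n_coils), sos-normalized per row.
#' @export
eval_coil_maps <- function(maps, pts) {
  raw <- eval_coil_maps_raw(maps$params, pts)
  if (!is.matrix(raw)) raw <- matrix(raw, nrow = nrow(pts))
  raw / sqrt(rowSums(Mod(raw)^2))
}

#' @export
print.sensitivity_maps <- function(x, ...) {
  d <- dim(x$values)
  cat("sensitivity_maps:", d[4], "coils on",
      paste(d[1:3], collapse = " x "), "grid,", x$normalization,
      "normalized\n")
  invisible(x)
}

#' Simulate noisy multi-coil k-space
#'
#' Per coil, the centered unitary forward transform of the coil-weighted
#' image plus i.i.d. complex Gaussian noise. `noise_sigma` is the standard
#' deviation of the complex sample; each real and imaginary component
#' receives `noise_sigma / sqrt(2)`.
#'
#' @param image An `image_volume`.
#' @param maps A `sensitivity_maps` on the same grid.
#' @param noise_sigma Complex noise SD (unit intensity scale).
#' @param seed Integer seed.
#' @return Object of class `kspace_volume`: complex (nx, ny, nz, n_coils)
#'   array in the centered layout, plus voxel size.
#' @export
simulate_kspace <- function(image, maps, noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(image, "image_volume"),
            inherits(maps, "sensitivity_maps"))
  gs <- dim(image$values)
  if (!all(gs == dim(maps$values)[1:3]))
    stop("image and maps do not share a grid")
  nc <- dim(maps$values)[4]
  kv <- array(complex(real = 0), c(gs, nc))
  for (cc in seq_len(nc))
    kv[, , , cc] <- fft3c(coil_slab(maps$values, cc) * image$values)
  if (noise_sigma > 0) {
    kv <- kv + with_seed(seed, {
      n <- length(kv)
      array(complex(real = stats::rnorm(n, 0, noise_sigma / sqrt(2)),
                    imaginary = stats::rnorm(n, 0, noise_sigma / sqrt(2))),
            c(gs, nc))
    })
  }
  kspace_volume(kv, voxel_size = image$voxel_size)
}

#' Construct a k-space volume
#'
#' @param values Complex (nx, ny, nz, n_coils) array, centered layout
#'   (DC at `floor(N/2) + 1` on each axis).
#' @param voxel_size mm triple of the underlying image grid.
#' @return Object of class `kspace_volume`.
#' @export
kspace_volume <- function(values, voxel_size) {
  stopifnot(length(dim(values)) == 4L)
  structure(list(values = values, voxel_size = voxel_size),
            class = "kspace_volume")
}

#' @export
print.kspace_volume <- function(x, ...) {
  d <- dim(x$values)
  cat("kspace_volume:", paste(d[1:3], collapse = " x "), "grid,",
      d[4], "coils\n")
  invisible(x)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
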