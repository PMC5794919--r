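# Automated stand-ins for the two rating pathways: a continuous skeletal
# score from measured growth-plate widths, and a Greulich-Pyle-style
# estimate quantized to the 0.5-year atlas grid and capped at 19 years.

#' Measure growth-plate gap widths from an image
#'
#' For each ossification site, takes the intensity profile along the bone
#' axis through the slab center and measures the full width at half the
#' local bone/gap contrast (linear interpolation between samples, hence
#' sub-voxel). Site geometry comes from the phantom ground truth:
#' localization is deliberately not under test, only reconstruction
#' fidelity.
#'
#' @param image An `image_volume` (magnitude used).
#' @param sites data.frame of site geometry as produced by
#'   [make_hand_phantom()] (`attr(phantom, "sites")`).
#' @param min_contrast Minimum dip depth (intensity units) below the local
#'   bone level for a gap to count; shallower profiles return width 0
#'   (fused). Default 0.08.
#' @return Numeric vector of gap widths in mm, one per site.
#' @export
measure_gap_widths <- function(image, sites, min_contrast = 0.08) {
  vals <- Mod(image$values)
  gs <- dim(vals); vs <- image$voxel_size
  co <- grid_coords(gs, vs)
  vapply(seq_len(nrow(sites)), function(b) {
    s <- sites[b, ]
    ix <- which.min(abs(co[[1]] - s$center_x))
    iz <- which.min(abs(co[[3]] - s$center_z))
    if (ix < 1 || ix > gs[1] || iz < 1 || iz > gs[3])
      stop("profile entirely outside image")
    half_len <- s$bone_half_length * 0.85      # stay inside the bone ends
    sel <- which(abs(co[[2]] - s$center_y) <= half_len)
    if (length(sel) < 5) stop("profile entirely outside image")
    prof <- vals[ix, sel, iz]
    yy <- co[[2]][sel]
    profile_fwhm(yy, prof, s$center_y, min_contrast)
  }, numeric(1))
}

# Full width at half the local bone/gap contrast of a dip near y0.
# Returns 0 when no dip deeper than min_contrast exists.
profile_fwhm <- function(yy, prof, y0, min_contrast) {
  n <- length(prof)
  ic <- which.min(abs(yy - y0))
  # local minimum near the slab center (within a third of the profile)
  win <- max(1L, ic - n %/% 3):min(n, ic + n %/% 3)
  imin <- win[which.min(prof[win])]
  gap_lvl <- prof[imin]
  bone_lvl <- min(max(prof[1:imin]), max(prof[imin:n]))
  if (bone_lvl - gap_lvl < min_contrast) return(0)
  half <- (bone_lvl + gap_lvl) / 2
  # walk outwards to the half-contrast crossings, linear interpolation
  il <- imin
  while (il > 1 && prof[il] < half) il <- il - 1L
  ir <- imin
  while (ir < n && prof[ir] < half) ir <- ir + 1L
  if (prof[il] < half || prof[ir] < half) return(0)  # dip runs off the bone
  yl <- yy[il] + (yy[il + 1] - yy[il]) *
    (prof[il] - half) / (prof[il] - prof[il + 1])
  yr <- yy[ir] - (yy[ir] - yy[ir - 1]) *
    (prof[ir] - half) / (prof[ir] - prof[ir - 1])
  max(0, yr - yl)
}

#' Continuous skeletal age from gap widths
#'
#' Inverts the maturation curve per site and averages: sites measuring 0
#' contribute the fusion age. Widths above the curve maximum are clipped
#' to the curve domain with a warning (see [gap_to_age()]).
#'
#' @param widths Numeric vector of gap widths in mm.
#' @param fusion_age,gap_at_10 Curve parameters, matching the generator.
#' @return Continuous age estimate in years.
#' @export
gaps_to_age <- function(widths, fusion_age = 18, gap_at_10 = 3.0) {
  mean(gap_to_age(widths, fusion_age = fusion_age, gap_at_10 = gap_at_10))
}

#' Greulich-Pyle-style quantization of an age estimate
#'
#' Nearest multiple of 0.5 years (ties rounding up), capped at 19.0 — the
#' maximum age assignable from the atlas.
#'
#' @param age Continuous age estimate(s) in years.
#' @param cap Maximum assignable age (default 19).
#' @return Quantized age(s) on the 0.5-year grid.
#' @export
gp_quantize <- function(age, cap = 19.0) {
  if (any(!is.finite(age))) stop("age must be finite")
  pmin(floor(age * 2 + 0.5) / 2, cap)
}
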