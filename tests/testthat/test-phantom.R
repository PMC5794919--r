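# Synthetic phantom generator: geometry ground truth, coil maps, k-space
# noise statistics.

test_that("fused spec produces no dark slab inside any bone", {
  sp <- phantom_spec(20, seed = 3)          # above fusion age
  expect_true(all(sp$gap_widths == 0))
  ph <- make_hand_phantom(sp)
  w <- measure_gap_widths(ph, attr(ph, "sites"))
  expect_true(all(w == 0))
})

test_that("identical spec + seed gives bit-identical phantom and k-space", {
  sp1 <- phantom_spec(14, seed = 7)
  sp2 <- phantom_spec(14, seed = 7)
  expect_identical(sp1$gap_widths, sp2$gap_widths)
  p1 <- make_hand_phantom(sp1); p2 <- make_hand_phantom(sp2)
  expect_identical(p1$values, p2$values)
  m <- make_coil_maps(3, seed = 2)
  k1 <- simulate_kspace(p1, m, 0.05, seed = 9)
  k2 <- simulate_kspace(p2, m, 0.05, seed = 9)
  expect_identical(k1$values, k2$values)
})

test_that("slab widths re-measured by voxel counting match the request", {
  # brute-force oracle: count sub-threshold voxels along the bone axis at
  # the slab center and convert to mm (accurate to one voxel)
  sp <- fx_spec()
  ph <- fx_phantom()
  sites <- attr(ph, "sites")
  vs <- ph$voxel_size
  co <- agesim:::grid_coords(dim(ph$values), vs)
  lv <- sp$tissue_levels
  half <- (lv[["bone"]] + lv[["cartilage"]]) / 2
  for (b in seq_len(nrow(sites))) {
    s <- sites[b, ]
    ix <- which.min(abs(co[[1]] - s$center_x))
    iz <- which.min(abs(co[[3]] - s$center_z))
    sel <- abs(co[[2]] - s$center_y) <= s$bone_half_length * 0.8
    prof <- ph$values[ix, sel, iz]
    counted <- sum(prof < half) * vs[2]
    expect_lt(abs(counted - s$width_mm), vs[2])
  }
})

test_that("gap width exceeding bone length is rejected", {
  sp <- phantom_spec(14, gap_widths = rep(25, 6), seed = 1)
  expect_error(make_hand_phantom(sp), "geometry")
})

test_that("age-gap curve is strictly decreasing then identically zero", {
  ages <- seq(10, 22, by = 0.25)
  g <- age_to_gap(ages)
  below <- ages < 18
  expect_true(all(diff(g[below]) < 0))
  expect_true(all(g[ages >= 18] == 0))
  # inverse on the decreasing segment
  expect_equal(gap_to_age(age_to_gap(c(11, 14.5, 17.9))),
               c(11, 14.5, 17.9), tolerance = 1e-12)
  expect_equal(gap_to_age(0), 18)
  expect_warning(w <- gap_to_age(5), "clipped")
  expect_equal(w, 10)
})

test_that("single coil map normalizes to magnitude 1; sos holds in general", {
  m1 <- make_coil_maps(1, grid_shape = c(16, 16, 4), seed = 5)
  expect_lt(max(abs(Mod(m1$values) - 1)), 1e-12)
  m4 <- fx_maps4()
  sos <- apply(Mod(m4$values)^2, 1:3, sum)
  expect_lt(max(abs(sos - 1)), 1e-6)
})

test_that("coil maps are n_coils = 0 rejected and smoothness bounded", {
  expect_error(make_coil_maps(0), "n_coils")
  # analytic oracle: the maximum gridded adjacent-voxel difference cannot
  # exceed the maximum fine-grid (quarter-voxel) variation of the closed
  # form, summed over the four sub-steps
  gs <- c(16L, 16L, 16L); vsz <- c(4, 4, 4)   # 64 mm cube
  maps <- make_coil_maps(3, grid_shape = gs, voxel_size = vsz,
                         smoothness = 30, seed = 8)
  co <- agesim:::grid_coords(gs, vsz)
  # adjacent-voxel differences along z for each coil
  vals <- maps$values
  dz <- Mod(vals[, , 2:16, ] - vals[, , 1:15, ])
  # oracle: evaluate the analytic map on a 4x finer z-grid along a line
  # through the volume and take 4x the max quarter-step difference
  zs <- seq(co[[3]][1], co[[3]][16], by = vsz[3] / 4)
  for (cc in 1:3) {
    pts <- cbind(rep(co[[1]][8], length(zs)), rep(co[[2]][8], length(zs)), zs)
    fine <- eval_coil_maps(maps, pts)[, cc]
    bound <- 4 * max(Mod(diff(fine)))
    expect_lt(max(dz[8, 8, , cc]), bound * 1.05 + 1e-12)
  }
})

test_that("k-space is the unitary transform of the coil-weighted image", {
  ph <- fx_phantom()
  m1 <- make_coil_maps(1, seed = 5)
  ks <- simulate_kspace(ph, m1, 0, seed = 1)
  # single coil, |map| = 1: inverse transform returns map*image exactly
  back <- ifft3c(ks$values[, , , 1])
  expect_lt(max(Mod(back - m1$values[, , , 1] * ph$values)) /
              max(ph$values), 1e-10)
  # Parseval per coil
  ks4 <- fx_kspace()
  for (cc in 1:4) {
    ei <- sum(Mod(fx_maps4()$values[, , , cc] * ph$values)^2)
    ek <- sum(Mod(ks4$values[, , , cc])^2)
    expect_equal(ek, ei, tolerance = 1e-10)
  }
})

test_that("complex noise convention: each component gets sigma/sqrt(2)", {
  # Monte-Carlo oracle on a 1-voxel image
  img <- image_volume(array(0, c(1, 1, 1)), c(1, 1, 1), "ground-truth")
  maps <- make_coil_maps(1, grid_shape = c(1, 1, 1), voxel_size = c(1, 1, 1),
                         seed = 1)
  draws <- vapply(1:10000, function(i)
    simulate_kspace(img, maps, 0.05, seed = i)$values[1, 1, 1, 1],
    complex(1))
  expect_lt(abs(sd(Re(draws)) - 0.05 / sqrt(2)) / (0.05 / sqrt(2)), 0.03)
  expect_lt(abs(sd(Im(draws)) - 0.05 / sqrt(2)) / (0.05 / sqrt(2)), 0.03)
})

test_that("noiseless round trip through true maps reproduces the phantom", {
  ph <- fx_phantom()
  maps <- fx_maps4()
  ks <- fx_kspace()
  acc <- array(0i, dim(ph$values))
  for (cc in 1:4)
    acc <- acc + Conj(maps$values[, , , cc]) * ifft3c(ks$values[, , , cc])
  expect_lt(max(abs(Mod(acc) - ph$values)), 1e-10)
})

test_that("shape mismatches are rejected", {
  ph <- fx_phantom()
  m_small <- make_coil_maps(2, grid_shape = c(16, 16, 4), seed = 1)
  expect_error(simulate_kspace(ph, m_small, 0), "grid")
})
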