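# SENSE operators, proximal maps, TGV solver behavior, baselines, metrics.

test_that("adjoint identity holds for random image/k-space pairs", {
  maps <- make_coil_maps(3, grid_shape = c(16, 12, 4),
                         voxel_size = c(1, 1, 1), seed = 2)
  pat <- caipirinha_pattern(c(12, 4), 2, 2, 1, 2, AF_nominal = 4)
  for (i in 1:20) {
    x <- rand_cx_array(c(16, 12, 4), seed = 100 + i)
    y <- rand_cx_array(c(16, 12, 4, 3), seed = 200 + i)
    xi <- image_volume(x, c(1, 1, 1), "ground-truth")
    Ax <- sense_forward(xi, maps, pat)$values
    Aty <- sense_adjoint(kspace_volume(y, c(1, 1, 1)), maps, pat)$values
    lhs <- sum(Conj(Ax) * y)
    rhs <- sum(Conj(x) * Aty)
    expect_lt(Mod(lhs - rhs) / (sqrt(sum(Mod(x)^2)) * sqrt(sum(Mod(y)^2))),
              1e-8)
  }
})

test_that("forward output vanishes on unsampled lines; full mask is unitary", {
  maps <- make_coil_maps(1, grid_shape = c(16, 12, 4),
                         voxel_size = c(1, 1, 1), seed = 2)
  x <- rand_cx_array(c(16, 12, 4), seed = 1)
  xi <- image_volume(x, c(1, 1, 1), "ground-truth")
  pat <- caipirinha_pattern(c(12, 4), 3, 2, 1, 0, AF_nominal = 6)
  k <- sense_forward(xi, maps, pat)$values
  off <- which(pat$mask == 0, arr.ind = TRUE)
  for (r in seq_len(min(5, nrow(off))))
    expect_true(all(k[, off[r, 1], off[r, 2], ] == 0))
  full <- caipirinha_pattern(c(12, 4), 1, 1, 0, 0, AF_nominal = 1)
  kf <- sense_forward(xi, maps, full)
  back <- sense_adjoint(kf, maps, full)$values
  expect_lt(max(Mod(back - x)), 1e-10)
})

test_that("dual-ball projection matches its closed form", {
  set.seed(42)
  dims <- c(5, 4, 3)
  comps <- lapply(1:3, function(i) rand_cx_array(dims, seed = 300 + i))
  alpha <- 0.7
  out <- agesim:::cpp_project_l2ball(comps, c(1, 1, 1), alpha)
  nrm <- sqrt(Reduce(`+`, lapply(comps, function(x) Mod(x)^2)))
  scale <- pmin(1, alpha / nrm)       # closed form
  for (i in 1:3)
    expect_lt(max(Mod(out[[i]] - comps[[i]] * scale)), 1e-12)
  # weighted (symmetric tensor) variant
  comps6 <- lapply(1:6, function(i) rand_cx_array(dims, seed = 400 + i))
  w <- c(1, 1, 1, 2, 2, 2)
  out6 <- agesim:::cpp_project_l2ball(comps6, w, alpha)
  nrm6 <- sqrt(Reduce(`+`, Map(function(x, wi) wi * Mod(x)^2, comps6, w)))
  scale6 <- pmin(1, alpha / nrm6)
  for (i in 1:6)
    expect_lt(max(Mod(out6[[i]] - comps6[[i]] * scale6)), 1e-12)
})

test_that("data-term dual resolvent matches its closed form", {
  dims <- c(4, 4, 2)
  r <- rand_cx_array(dims, seed = 1)
  Au <- rand_cx_array(dims, seed = 2)
  f <- rand_cx_array(dims, seed = 3)
  sigma <- 0.37; lambda <- 1.4
  out <- agesim:::cpp_prox_data_dual(r, Au, f, sigma, lambda)
  expect_lt(max(Mod(out - (r + sigma * (Au - f)) / (1 + sigma / lambda))),
            1e-12)
})

test_that("gradient and symmetrized-gradient adjoints are exact", {
  dims <- c(8, 7, 5)
  for (d in 0:2) {
    x <- rand_cx_array(dims, seed = 10 + d)
    y <- rand_cx_array(dims, seed = 20 + d)
    lhs <- sum(Conj(agesim:::cpp_grad(x, d)) * y)
    rhs <- sum(Conj(x) * agesim:::cpp_grad_adj(y, d))
    expect_lt(Mod(lhs - rhs), 1e-10)
  }
})

test_that("vanishing regularization reproduces the zero-filled combination", {
  sl <- fx_slice()   # 64 x 64 x 1, noiseless
  full <- caipirinha_pattern(c(64, 1), 1, 1, 0, 1, AF_nominal = 1)
  zf <- zero_filled_recon(sl$kspace, sl$maps, full)
  cfg <- recon_config(alpha1 = 1e-8, alpha0 = 2e-8, n_iter = 80,
                      check_every = 20)
  rec <- tgv2_reconstruct(sl$kspace, sl$maps, full, cfg)
  expect_lt(sqrt(sum((rec$values - zf$values)^2)) /
              sqrt(sum(zf$values^2)), 1e-3)
})

test_that("TGV beats zero-filling on an undersampled 2D slice", {
  sl <- fx_slice()
  pat <- caipirinha_pattern(c(64, 1), 2, 1, 0, 1, AF_nominal = 2)
  ku <- apply_pattern(sl$kspace, pat)
  zf <- zero_filled_recon(ku, sl$maps, pat)
  rec <- tgv2_reconstruct(ku, sl$maps, pat,
                          recon_config(n_iter = 100, check_every = 20))
  n_zf <- image_quality(zf, sl$phantom)$nrmse
  n_tgv <- image_quality(rec, sl$phantom)$nrmse
  expect_gt(n_zf, 0)
  expect_lt(n_tgv, n_zf)
})

test_that("energy trace is non-increasing after burn-in", {
  ks <- fx_kspace_noisy()
  pat <- caipirinha_pattern(c(64, 16), 4, 2, 1, 12, AF_nominal = 7.49)
  ku <- apply_pattern(ks, pat)
  rec <- tgv2_reconstruct(ku, fx_maps4(), pat,
                          recon_config(n_iter = 200, check_every = 10))
  en <- attr(rec, "trace")$energy
  burn <- en[-(1:10)]
  expect_true(all(diff(burn) <= 1e-6 * abs(burn[-length(burn)])))
  expect_false(attr(rec, "diverged"))
})

test_that("solution is 1-homogeneous in (data, regularization) scale", {
  sl <- fx_slice()
  pat <- caipirinha_pattern(c(64, 1), 2, 1, 0, 1, AF_nominal = 2)
  ku <- apply_pattern(sl$kspace, pat)
  a1 <- 1e-3
  cfg1 <- recon_config(alpha1 = a1, alpha0 = 2 * a1, n_iter = 100,
                       check_every = 50)
  r1 <- tgv2_reconstruct(ku, sl$maps, pat, cfg1)
  c <- 10
  ku_scaled <- kspace_volume(ku$values * c, ku$voxel_size)
  cfg2 <- recon_config(alpha1 = c * a1, alpha0 = 2 * c * a1, n_iter = 100,
                       check_every = 50)
  r2 <- tgv2_reconstruct(ku_scaled, sl$maps, pat, cfg2)
  expect_lt(max(abs(r2$values / c - r1$values)) / max(r1$values), 1e-4)
})

test_that("zero-filled baselines: exact full recovery and RSS identity", {
  ph <- fx_phantom()
  maps <- fx_maps4()
  ks <- fx_kspace()
  full <- fx_full_pattern()
  zf <- zero_filled_recon(ks, maps, full)
  expect_lt(max(abs(zf$values - ph$values)), 1e-10)
  # undersampled without calibration: aliasing present
  p <- caipirinha_pattern(c(64, 16), 2, 2, 1, 0, AF_nominal = 4)
  zfu <- zero_filled_recon(apply_pattern(ks, p), maps, p)
  expect_gt(image_quality(zfu, ph)$nrmse, 0)
  # RSS agrees with map combination when maps are sos-normalized and the
  # combined image is phase-free
  rss <- zero_filled_recon(ks, NULL, full)
  expect_lt(max(abs(rss$values - zf$values)), 1e-6)
})

test_that("quality metrics: identity, constant offset, profile line", {
  ph <- fx_phantom()
  q0 <- image_quality(ph, ph)
  expect_equal(q0$nrmse, 0)
  expect_equal(q0$max_abs_diff, 0)
  shifted <- image_volume(ph$values + 0.1 * (ph$values > 0),
                          ph$voxel_size, "tgv")
  q1 <- image_quality(shifted, ph)
  expect_equal(q1$max_abs_diff, 0.1, tolerance = 1e-12)
  line <- cbind(1:10, 32, 8)
  q2 <- image_quality(shifted, ph, profile_line = line)
  expect_equal(length(q2$profile_diff), 10)
  expect_error(image_quality(ph, ph, profile_line = cbind(99, 99, 99)),
               "outside")
  small <- image_volume(array(0.5, c(4, 4, 4)), c(1, 1, 1), "tgv")
  expect_error(image_quality(small, ph), "mismatch")
})
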