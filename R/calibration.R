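# Autocalibration: SVD coil compression to virtual coils and ESPIRiT
# sensitivity estimation from the fully sampled central k-space block.

#' Compress physical coils to virtual coils
#'
#' The compression operator is built from the calibration block only
#' (mirroring what an accelerated scan provides): the coil-by-sample
#' calibration matrix is decomposed by SVD and the leading left singular
#' vectors define an orthonormal projection onto `n_virtual` virtual coils,
#' which is then applied to the full k-space coil-wise.
#'
#' @param kspace A `kspace_volume`.
#' @param n_virtual Number of virtual coils, `1 <= n_virtual <= n_coils`.
#' @param pattern A `sampling_pattern` with a calibration block, used to
#'   locate the calibration data.
#' @return List with `kspace` (compressed `kspace_volume`) and `operator`
#'   (class `compression_operator`: complex `matrix` of dimension
#'   n_virtual x n_coils with orthonormal rows, and `energy_retained`,
#'   the calibration-energy fraction kept).
#' @export
compress_coils <- function(kspace, n_virtual, pattern) {
  stopifnot(inherits(kspace, "kspace_volume"))
  nc <- dim(kspace$values)[4]
  n_virtual <- as.integer(n_virtual)
  if (n_virtual < 1L || n_virtual > nc)
    stop("n_virtual must lie in [1, n_coils]")
  calib <- extract_calibration(kspace, pattern)
  X <- t(matrix(calib, ncol = nc))               # coils x samples
  sv <- svd(X, nu = nc, nv = 0)
  op <- Conj(t(sv$u[, seq_len(n_virtual), drop = FALSE]))
  energy <- sum(sv$d[seq_len(n_virtual)]^2) / sum(sv$d^2)
  d <- dim(kspace$values)
  kmat <- matrix(kspace$values, ncol = nc)
  comp <- array(kmat %*% t(op), c(d[1:3], n_virtual))
  operator <- structure(list(matrix = op, energy_retained = energy),
                        class = "compression_operator")
  list(kspace = kspace_volume(comp, kspace$voxel_size), operator = operator)
}

#' @export
print.compression_operator <- function(x, ...) {
  cat(sprintf("compression_operator: %d virtual <- %d physical coils, %.4f energy retained\n",
              nrow(x$matrix), ncol(x$matrix), x$energy_retained))
  invisible(x)
}

#' ESPIRiT sensitivity estimation from calibration data
#'
#' Builds the block-Hankel calibration matrix from sliding kernels over the
#' calibration block, keeps the row-space basis at a relative
#' singular-value threshold, transforms the kernels to the image domain and
#' extracts, per voxel, the leading eigenvector of the resulting
#' reconstruction operator. The eigenvector is kept (scaled to unit
#' magnitude across coils, i.e. sos normalization) where the leading
#' eigenvalue reaches `eig_threshold` and set to 0 elsewhere; the phase is
#' fixed by rotating the first-coil component to be real non-negative.
#'
#' With an orthonormal row-space basis the operator's eigenvalues lie in
#' `[0, 1]`, reaching 1 exactly where the local coil vector lies in the
#' calibration row space.
#'
#' @param calib Complex calibration array (nx, ncal1, ncal2, n_coils) as
#'   returned by [extract_calibration()].
#' @param grid_shape Integer triple: output map grid.
#' @param kernel_size Integer triple of kernel extents (default 6 x 6 x 6,
#'   clipped nowhere — the calibration block must be strictly larger in
#'   every dimension).
#' @param sv_threshold Relative singular-value cutoff for the row space
#'   (default 0.01).
#' @param eig_threshold Leading-eigenvalue cutoff for the support mask
#'   (default 0.9).
#' @param voxel_size mm triple carried into the returned maps.
#' @param n_power Power-iteration count for the voxelwise eigenvector
#'   (default 60).
#' @return A `sensitivity_maps` object (values complex
#'   (grid_shape, n_coils), `normalization = "sos"`), with attribute
#'   `eigenvalues`: the per-voxel leading eigenvalue array.
#' @export
estimate_sensitivities <- function(calib, grid_shape,
                                   kernel_size = c(6L, 6L, 6L),
                                   sv_threshold = 0.01,
                                   eig_threshold = 0.9,
                                   voxel_size = c(0.45, 0.45, 0.90),
                                   n_power = 60L) {
  dcal <- dim(calib)
  nc <- dcal[4]
  kernel_size <- as.integer(kernel_size)
  if (any(kernel_size >= dcal[1:3]))
    stop("calibration block must be strictly larger than the kernel in every dimension")
  nk <- prod(kernel_size)

  # block-Hankel matrix: rows = sliding windows, cols = kernel x coil
  nwin <- dcal[1:3] - kernel_size + 1L
  off <- as.matrix(expand.grid(0:(kernel_size[1] - 1L),
                               0:(kernel_size[2] - 1L),
                               0:(kernel_size[3] - 1L)))
  st <- as.matrix(expand.grid(seq_len(nwin[1]), seq_len(nwin[2]),
                              seq_len(nwin[3])))
  lin <- function(ijk) ijk[, 1] + (ijk[, 2] - 1L) * dcal[1] +
    (ijk[, 3] - 1L) * dcal[1] * dcal[2]
  rel <- off[, 1] + off[, 2] * dcal[1] + off[, 3] * dcal[1] * dcal[2]
  win_idx <- outer(lin(st), rel, "+")
  ncs <- dcal[1] * dcal[2] * dcal[3]
  A <- matrix(0i, nrow(win_idx), nk * nc)
  for (cc in seq_len(nc))
    A[, (cc - 1L) * nk + seq_len(nk)] <- calib[win_idx + (cc - 1L) * ncs]

  AHA <- crossprod(Conj(A), A)
  eg <- eigen(AHA, symmetric = TRUE)
  sv <- sqrt(pmax(eg$values, 0))
  keep <- which(sv >= sv_threshold * sv[1])
  if (length(keep) == 0L) stop("empty calibration row space")
  V <- eg$vectors[, keep, drop = FALSE]

  # image-domain kernels, voxelwise operator, leading eigenvector (C++)
  res <- cpp_espirit_maps(V, kernel_size, as.integer(grid_shape), nc,
                          as.integer(n_power))
  m <- res$m
  lam <- res$lambda

  phase <- m[, 1]
  mag1 <- Mod(phase)
  rot <- ifelse(mag1 > 0, Conj(phase) / mag1, 1 + 0i)
  m <- m * rot
  m[lam < eig_threshold, ] <- 0i

  maps <- structure(list(values = array(m, c(grid_shape, nc)),
                         normalization = "sos",
                         voxel_size = voxel_size, params = NULL),
                    class = "sensitivity_maps")
  attr(maps, "eigenvalues") <- array(lam, grid_shape)
  maps
}
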