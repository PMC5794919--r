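# Centered unitary Fourier transforms. The k-space DC sample sits at index
# floor(N/2) + 1 (1-based) on every axis; transforms are scaled by 1/sqrt(N)
# so that forward and inverse are exact adjoints (Parseval holds).

#' Centered unitary FFT of a 3D array
#'
#' Forward transform from image space to k-space with the DC component at
#' `floor(N/2) + 1` along every axis (1-based) and unitary `1/sqrt(N)`
#' scaling, so `ifft3c(fft3c(x))` recovers `x` to machine precision and
#' energy is preserved.
#'
#' @param x Real or complex 3D array.
#' @return Complex array of the same shape.
#' @export
fft3c <- function(x) {
  fftshift3(fft_raw(ifftshift3(x))) / sqrt(length(x))
}

#' Centered unitary inverse FFT of a 3D array
#'
#' @param x Complex 3D array in the centered k-space layout of [fft3c()].
#' @return Complex array of the same shape.
#' @export
ifft3c <- function(x) {
  fftshift3(fft_raw(ifftshift3(x), inverse = TRUE)) / sqrt(length(x))
}

# Raw (unnormalized, DC-at-origin) 3D DFT via the compiled backend.
fft_raw <- function(x, inverse = FALSE) {
  if (!is.complex(x)) storage.mode(x) <- "complex"
  cpp_fft3(x, inverse)
}

# Circular shift moving index 1 to floor(N/2)+1 per axis (and its inverse).
fftshift3 <- function(x) shift3(x, vapply(dim(x), function(n) n %/% 2L, 1L))
ifftshift3 <- function(x) shift3(x, vapply(dim(x), function(n) -(n %/% 2L), 1L))

shift3 <- function(x, by) {
  d <- dim(x)
  stopifnot(length(d) == 3L)
  idx <- lapply(seq_along(d), function(k) {
    n <- d[k]
    1L + (seq_len(n) - 1L - by[k]) %% n
  })
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# Extract coil cc from a (nx, ny, nz, ncoil) array without dropping
# singleton spatial dimensions.
coil_slab <- function(a, cc) {
  d <- dim(a)
  array(a[, , , cc, drop = FALSE], d[1:3])
}
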