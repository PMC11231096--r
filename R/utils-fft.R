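# Centered Fourier conventions used throughout:
#   image coordinates x, y in FOV units on [-0.5, 0.5), sample i -> (i-1-N/2)/N
#   k-space in grid units (delta-k = 1/FOV), sample j -> (j-1-N/2)
#   DC sits at index N/2 + 1; all grid sizes are even.
# fft2c / ifft2c are unitary, so white noise keeps its variance across domains.

#' @keywords internal
shift_idx <- function(n) c((n %/% 2L + 1L):n, 1L:(n %/% 2L))

# For even n the forward and inverse shifts coincide, which is all we support.
fftshift <- function(x, dims = c(1L, 2L)) {
  d <- dim(x)
  if (is.null(d)) return(x[shift_idx(length(x))])
  ii <- lapply(d, seq_len)
  for (k in dims) ii[[k]] <- shift_idx(d[k])
  do.call(`[`, c(list(x), ii, list(drop = FALSE)))
}

# FFT along one dimension of an array (R's fft() is full n-dimensional).
fft_dim <- function(x, dim, inverse = FALSE) {
  d <- dim(x)
  if (is.null(d)) {
    return(stats::fft(x, inverse = inverse))
  }
  perm <- c(dim, setdiff(seq_along(d), dim))
  m <- matrix(aperm(x, perm), nrow = d[dim])
  m <- stats::mvfft(m, inverse = inverse)
  aperm(array(m, d[perm]), order(perm))
}

#' Centered unitary 2-D DFT over the first two array dimensions
#' @keywords internal
fft2c <- function(x) {
  d <- dim(x)
  s <- sqrt(d[1] * d[2])
  fftshift(fft_dim(fft_dim(fftshift(x, 1:2), 1L), 2L), 1:2) / s
}

#' @keywords internal
ifft2c <- function(x) {
  d <- dim(x)
  s <- sqrt(d[1] * d[2])
  fftshift(fft_dim(fft_dim(fftshift(x, 1:2), 1L, TRUE), 2L, TRUE), 1:2) / s
}

# Centered unitary 1-D DFT along the first dimension (readout axis).
fft1c <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  fftshift(fft_dim(fftshift(x, 1L), 1L), 1L) / sqrt(dim(x)[1])
}

ifft1c <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  fftshift(fft_dim(fftshift(x, 1L), 1L, TRUE), 1L) / sqrt(dim(x)[1])
}

#' Image-domain coordinates in FOV units
#' @keywords internal
fov_grid <- function(n) ((seq_len(n) - 1L) - n %/% 2L) / n

#' k-space coordinates in grid units (delta-k = 1/FOV)
#' @keywords internal
k_grid <- function(n) (seq_len(n) - 1L) - n %/% 2L

# Circular shift of the first two dims by integer steps (k-space of a DFT
# image is exactly periodic, so circular indexing is the natural convention).
roll2 <- function(x, dx = 0L, dy = 0L) {
  d <- dim(x)
  ii <- lapply(d, seq_len)
  if (dx != 0L) ii[[1]] <- 1L + (ii[[1]] - 1L - dx) %% d[1]
  if (dy != 0L) ii[[2]] <- 1L + (ii[[2]] - 1L - dy) %% d[2]
  do.call(`[`, c(list(x), ii, list(drop = FALSE)))
}

#' Normalised root-mean-square error
#'
#' @param x,ref arrays of identical dimension (complex or numeric).
#' @return `sqrt(sum(|x - ref|^2) / sum(|ref|^2))`.
#' @export
nrmse <- function(x, ref) {
  sqrt(sum(Mod(x - ref)^2) / sum(Mod(ref)^2))
}

#' Complex white Gaussian noise with total (complex) standard deviation sigma
#' @keywords internal
cnoise <- function(n, sigma) {
  complex(real = stats::rnorm(n, sd = sigma / sqrt(2)),
          imaginary = stats::rnorm(n, sd = sigma / sqrt(2)))
}

# Magnitude-weighted linear phase fit: angle(q[i]) ~ a + b * u[i].
# The slope comes from the lag-1 product (unwrap-free), the intercept from the
# demodulated weighted sum. Returns c(a, b).
fit_linear_phase <- function(q, u, w = Mod(q)) {
  stopifnot(length(q) == length(u))
  du <- diff(u)
  if (length(unique(round(du, 12))) != 1L)
    stop("fit_linear_phase expects a uniform grid")
  step <- du[1]
  lag <- sum(w[-1] * w[-length(w)] * q[-1] * Conj(q[-length(q)]))
  b <- Arg(lag) / step
  a <- Arg(sum(w * q * exp(-1i * b * u)))
  c(a = a, b = b)
}
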