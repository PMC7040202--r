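# Separable filtering along array axes with whole-sample reflection padding.
# Shared by the wavelet channels and the phantom's correlated-noise field.

reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  # whole-sample reflection: ..., 3, 2, 1, 2, 3, ..., n-1, n, n-1, ...
  period <- 2L * (n - 1L)
  j <- (idx - 1L) %% period
  j <- ifelse(j < 0L, j + period, j)
  as.integer(ifelse(j >= n, period - j, j) + 1L)
}

# convolve along one axis: out[i] = sum_t k[t] * x[i + t - anchor]
# anchor defaults to the filter centre (ceil(L/2)).
conv_axis <- function(arr, kernel, axis, anchor = ceiling(length(kernel) / 2)) {
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L),
                 `3` = c(3L, 1L, 2L))
  x <- aperm(arr, perm)
  n <- dim(x)[1]
  m <- prod(dim(x)[2:3])
  dim(x) <- c(n, m)
  out <- matrix(0, n, m)
  for (t in seq_along(kernel)) {
    idx <- reflect_index(seq_len(n) + (t - anchor), n)
    out <- out + kernel[t] * x[idx, , drop = FALSE]
  }
  dim(out) <- dim(aperm(arr, perm))
  aperm(out, order(perm))
}

gaussian_kernel_1d <- function(sigma_vox, radius = max(1L, ceiling(3 * sigma_vox))) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

smooth_gaussian <- function(arr, sigma_vox) {
  for (ax in 1:3) {
    k <- gaussian_kernel_1d(sigma_vox[ax])
    arr <- conv_axis(arr, k, ax, anchor = (length(k) + 1L) / 2)
  }
  arr
}
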