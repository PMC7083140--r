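`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a locally fixed RNG state, restoring the caller's
# .Random.seed afterwards so generators never perturb the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Global histogram threshold (Otsu) on arbitrary-dimensional data, via
# EBImage on the flattened, range-normalized intensities.
otsu_threshold <- function(x) {
  v <- as.numeric(x)
  rng <- range(v)
  if (diff(rng) <= 0) stop("cannot threshold a constant image")
  v01 <- (v - rng[1]) / diff(rng)
  th01 <- EBImage::otsu(EBImage::Image(matrix(v01, ncol = 1L)),
                        range = c(0, 1), levels = 256L)
  rng[1] + as.numeric(th01) * diff(rng)
}

# Circular (wrap-around) Gaussian blur of a 3D array via the FFT, with a
# per-axis sigma in voxels.  Exactly conserves total intensity.
blur3_fft <- function(arr, sigma_vox) {
  if (all(sigma_vox <= 0)) return(arr)
  d <- dim(arr)
  k1 <- function(n, s) {
    if (s <= 0) return(c(1, rep(0, n - 1L)))
    i <- 0:(n - 1L)
    dist <- pmin(i, n - i)
    k <- exp(-dist^2 / (2 * s^2))
    k / sum(k)
  }
  f1 <- stats::fft(k1(d[1], sigma_vox[1]))
  f2 <- stats::fft(k1(d[2], sigma_vox[2]))
  f3 <- stats::fft(k1(d[3], sigma_vox[3]))
  otf <- outer(outer(f1, f2), f3)
  out <- Re(stats::fft(stats::fft(arr) * otf, inverse = TRUE)) / length(arr)
  array(out, d)
}

# Morphological closing of a 3D mask with a Euclidean ball of radius r um,
# built from two distance transforms (anisotropy-aware).
morph_close <- function(mask, radius_um, voxel_size_um) {
  if (radius_um <= 0) return(mask)
  dil <- distance_transform(mask, voxel_size_um) <= radius_um
  ero <- distance_transform(!dil, voxel_size_um) > radius_um
  ero
}
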