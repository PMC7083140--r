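#' Generate a 2D mosaic of elongated myocytes with known orientations
#'
#' Emulates a WGA-stained tile scan: dim, elongated cell interiors
#' separated by bright membrane/matrix boundaries.  Cells sit on a square
#' grid of tiles; each is a rotated rectangle whose true long-axis
#' orientation is recorded.  A `disarray_fraction` of cells (exactly
#' `round(f * n)`) is drawn with an orientation offset of more than 30 deg
#' from `mean_angle_deg`; the remaining cells deviate by less than 25 deg.
#'
#' @param n_cells number of cells (>= 1).
#' @param mean_angle_deg main fiber orientation (deg from the image x axis,
#'   positive towards increasing row index).
#' @param angle_sd_deg SD of the aligned cells' orientation scatter
#'   (truncated at 25 deg).
#' @param disarray_fraction fraction of cells offset by more than 30 deg.
#' @param pixel_size_um pixel size (um).
#' @param tile_px tile edge length in pixels; cell length is `0.8 *
#'   tile_px`, width `0.3 * tile_px`.
#' @param intensity_levels named list, `interior` and `wga`.
#' @param noise_sd Gaussian noise SD.
#' @param rng_seed integer seed.
#' @return List with `image` (matrix, row = y), `truth` (class
#'   `synthetic_ground_truth`: `label_map`, `true_orientations_deg`,
#'   `disarray_ids`, `pixel_size_um`, `rng_seed`).
#' @export
gen_myocyte_mosaic <- function(n_cells, mean_angle_deg = 0,
                               angle_sd_deg = 10, disarray_fraction = 0,
                               pixel_size_um = 0.5, tile_px = 40L,
                               intensity_levels = list(interior = 10,
                                                       wga = 100),
                               noise_sd = 0, rng_seed = 1L) {
  if (n_cells < 1) stop("n_cells must be at least 1")
  if (disarray_fraction < 0 || disarray_fraction > 1)
    stop("disarray_fraction must lie in [0, 1]")
  ncol_t <- ceiling(sqrt(n_cells))
  nrow_t <- ceiling(n_cells / ncol_t)
  nr <- nrow_t * tile_px; ncp <- ncol_t * tile_px
  img <- matrix(intensity_levels$wga, nr, ncp)
  labels <- matrix(0L, nr, ncp)

  res <- with_seed(rng_seed, {
    n_dis <- round(disarray_fraction * n_cells)
    dis_ids <- if (n_dis > 0) sort(sample.int(n_cells, n_dis)) else integer(0)
    offs <- numeric(n_cells)
    aligned <- setdiff(seq_len(n_cells), dis_ids)
    offs[aligned] <- pmax(pmin(rnorm(length(aligned), 0, angle_sd_deg),
                               25), -25)
    offs[dis_ids] <- sample(c(-1, 1), n_dis, TRUE) * runif(n_dis, 35, 80)
    list(dis_ids = dis_ids, angles = mean_angle_deg + offs)
  })
  # wrap to axial range [-90, 90)
  ang <- ((res$angles + 90) %% 180) - 90

  hl <- 0.4 * tile_px; hw <- 0.15 * tile_px
  for (cid in seq_len(n_cells)) {
    tr <- (cid - 1L) %/% ncol_t; tc <- (cid - 1L) %% ncol_t
    r0 <- tr * tile_px; c0 <- tc * tile_px
    cy <- r0 + (tile_px + 1) / 2; cx <- c0 + (tile_px + 1) / 2
    th <- ang[cid] * pi / 180
    rr <- (r0 + 1L):(r0 + tile_px); cc <- (c0 + 1L):(c0 + tile_px)
    y <- matrix(rr - cy, tile_px, tile_px)
    x <- matrix(cc - cx, tile_px, tile_px, byrow = TRUE)
    u <- cos(th) * x + sin(th) * y
    v <- -sin(th) * x + cos(th) * y
    inside <- abs(u) <= hl & abs(v) <= hw
    tile_img <- img[rr, cc]
    tile_img[inside] <- intensity_levels$interior
    img[rr, cc] <- tile_img
    tile_lab <- labels[rr, cc]
    tile_lab[inside] <- cid
    labels[rr, cc] <- tile_lab
  }
  if (noise_sd > 0)
    img <- with_seed(rng_seed + 1L,
                     img + matrix(rnorm(length(img), 0, noise_sd), nr, ncp))
  img[img < 0] <- 0
  truth <- structure(list(
    label_map = labels, true_orientations_deg = ang,
    disarray_ids = res$dis_ids, disarray_fraction = disarray_fraction,
    pixel_size_um = pixel_size_um, rng_seed = rng_seed),
    class = "synthetic_ground_truth")
  list(image = img, truth = truth)
}

#' Generate a striated (sarcomere-like) intensity pattern
#'
#' Sinusoidal striation of period `length_um` whose direction of
#' periodicity makes `angle_deg` with the image x axis, plus optional
#' Gaussian noise.  Emulates alpha-actinin banding for spectral
#' sarcomere-length estimation.
#'
#' @param length_um striation period (um).
#' @param angle_deg direction of periodicity (deg).
#' @param image_size length-2 `(rows, cols)` in pixels.
#' @param pixel_size_um pixel size (um); must be at most `length_um / 4`.
#' @param noise_sd Gaussian noise SD.
#' @param rng_seed integer seed.
#' @return Intensity matrix (row = y).
#' @export
gen_sarcomere_pattern <- function(length_um = 2.05, angle_deg = 0,
                                  image_size = c(256L, 256L),
                                  pixel_size_um = 0.15, noise_sd = 0,
                                  rng_seed = 1L) {
  if (pixel_size_um > length_um / 4)
    stop("pixel_size_um violates the Nyquist margin (must be <= length_um / 4)")
  nr <- image_size[1]; ncp <- image_size[2]
  th <- angle_deg * pi / 180
  y <- matrix((seq_len(nr) - 1) * pixel_size_um, nr, ncp)
  x <- matrix((seq_len(ncp) - 1) * pixel_size_um, nr, ncp, byrow = TRUE)
  phase <- 2 * pi * (cos(th) * x + sin(th) * y) / length_um
  img <- 100 + 50 * cos(phase)
  if (noise_sd > 0)
    img <- with_seed(rng_seed,
                     img + matrix(rnorm(length(img), 0, noise_sd), nr, ncp))
  img[img < 0] <- 0
  img
}
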