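#' Iterative watershed segmentation of myocytes in a WGA tile scan
#'
#' Seeds are the regional maxima of the distance transform of the
#' thresholded WGA image's complement; a morphological watershed is run
#' on that distance transform.  Segments whose perimeter has a low
#' contact fraction with the WGA mask are then removed and the watershed
#' re-run from the surviving seeds, iterating until the label set is
#' stable or `max_iterations` is reached.
#'
#' @param wga_image numeric matrix (row = y), bright membrane/matrix.
#' @param pixel_size_um pixel size (um).
#' @param contact_threshold minimum fraction of a segment's perimeter
#'   touching the WGA mask.
#' @param max_iterations maximum removal/re-run cycles.
#' @param min_area_um2 segments smaller than this are discarded.
#' @param watershed_tolerance basin-merging tolerance of the watershed.
#' @return An object of class `myocyte_label_map`: `labels` (integer
#'   matrix, 0 = background/WGA), `pixel_size_um`, `cells` (data.frame
#'   with `cell_id`, `area_um2`, `contact_fraction`), `n_iterations`.
#' @export
watershed_segment <- function(wga_image, pixel_size_um,
                              contact_threshold = 0.6,
                              max_iterations = 5L,
                              min_area_um2 = 50,
                              watershed_tolerance = 1) {
  stopifnot(is.matrix(wga_image), pixel_size_um > 0)
  if (diff(range(wga_image)) <= 0) {
    warning("blank image: returning a single segment")
    labels <- matrix(1L, nrow(wga_image), ncol(wga_image))
    return(new_label_map(labels, pixel_size_um, n_iterations = 0L,
                         contact = NA_real_))
  }
  wga_mask <- wga_image > otsu_threshold(wga_image)
  interior <- !wga_mask
  # EBImage works in x-y order; transpose in and out
  dmap <- EBImage::distmap(EBImage::Image(t(interior)))
  labels_img <- EBImage::watershed(dmap, tolerance = watershed_tolerance)
  labels <- t(EBImage::imageData(labels_img))
  storage.mode(labels) <- "integer"
  labels <- drop_small_segments(labels, pixel_size_um, min_area_um2)

  n_iter <- 0L
  repeat {
    cf <- contact_fractions(labels, wga_mask)
    bad <- as.integer(names(cf))[cf < contact_threshold]
    if (length(bad) == 0L || n_iter >= max_iterations) break
    n_iter <- n_iter + 1L
    labels[labels %in% bad] <- 0L
    keep <- setdiff(sort(unique(as.vector(labels))), 0L)
    if (length(keep) == 0L) break
    # re-run from one seed per surviving segment (its distance maximum)
    dmat <- t(EBImage::imageData(dmap))
    seeds <- matrix(0L, nrow(labels), ncol(labels))
    for (k in seq_along(keep)) {
      idx <- which(labels == keep[k])
      seeds[idx[which.max(dmat[idx])]] <- k
    }
    prop <- EBImage::propagate(EBImage::Image(t(-dmat)),
                               seeds = EBImage::Image(t(seeds)),
                               mask = EBImage::Image(t(interior)))
    labels <- t(EBImage::imageData(prop))
    storage.mode(labels) <- "integer"
    labels <- drop_small_segments(labels, pixel_size_um, min_area_um2)
  }
  new_label_map(relabel_sequential(labels), pixel_size_um,
                n_iterations = n_iter, wga_mask = wga_mask)
}

new_label_map <- function(labels, pixel_size_um, n_iterations,
                          wga_mask = NULL, contact = NULL) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  area <- vapply(ids, function(i) sum(labels == i), numeric(1)) *
    pixel_size_um^2
  cf <- if (!is.null(wga_mask)) {
    unname(contact_fractions(labels, wga_mask)[as.character(ids)])
  } else rep(contact %||% NA_real_, length(ids))
  structure(list(labels = labels, pixel_size_um = pixel_size_um,
                 cells = data.frame(cell_id = ids, area_um2 = area,
                                    contact_fraction = cf),
                 n_iterations = n_iterations),
            class = "myocyte_label_map")
}

#' @export
print.myocyte_label_map <- function(x, ...) {
  cat(sprintf("myocyte_label_map: %d cells, %d x %d px at %.3g um/px\n",
              nrow(x$cells), nrow(x$labels), ncol(x$labels),
              x$pixel_size_um))
  invisible(x)
}

drop_small_segments <- function(labels, pixel_size_um, min_area_um2) {
  tab <- table(labels[labels > 0L])
  small <- as.integer(names(tab))[tab * pixel_size_um^2 < min_area_um2]
  if (length(small)) labels[labels %in% small] <- 0L
  labels
}

relabel_sequential <- function(labels) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (length(ids) == 0L) return(labels)
  out <- match(labels, ids, nomatch = 0L)
  matrix(as.integer(out), nrow(labels), ncol(labels))
}

# Fraction of each segment's perimeter pixels that touch (8-neighbour)
# the WGA mask.
contact_fractions <- function(labels, wga_mask) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (length(ids) == 0L) return(setNames(numeric(0), character(0)))
  nr <- nrow(labels); ncp <- ncol(labels)
  pad <- function(m, fill) {
    out <- matrix(fill, nr + 2L, ncp + 2L)
    out[2:(nr + 1L), 2:(ncp + 1L)] <- m
    out
  }
  lp <- pad(labels, 0L)
  wp <- pad(wga_mask, TRUE)   # image border counts as matrix contact
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  core <- lp[2:(nr + 1L), 2:(ncp + 1L)]
  boundary <- matrix(FALSE, nr, ncp)
  touches <- matrix(FALSE, nr, ncp)
  for (s in seq_len(nrow(shifts))) {
    rr <- 2:(nr + 1L) + shifts$dr[s]
    cc <- 2:(ncp + 1L) + shifts$dc[s]
    boundary <- boundary | (lp[rr, cc] != core)
    touches <- touches | wp[rr, cc]
  }
  boundary <- boundary & core > 0L
  vapply(ids, function(i) {
    b <- boundary & core == i
    if (!any(b)) return(1)
    mean(touches[b])
  }, numeric(1)) |> setNames(as.character(ids))
}

#' Per-cell long-axis orientation from image moments
#'
#' Orientation of each segment's dominant eigenvector of the 2nd-order
#' central image-moment (covariance) matrix, mapped to the axial range
#' \[-90, 90) degrees from the image x axis (positive towards increasing
#' row index).  Near-isotropic segments (eigenvalue ratio below
#' `min_eigen_ratio`) and segments below `min_pixels` get `NA`.
#'
#' @param label_map a [watershed_segment()] result (or integer matrix).
#' @param min_pixels minimum segment size in pixels.
#' @param min_eigen_ratio minimum major/minor eigenvalue ratio for a
#'   defined orientation.
#' @return data.frame with `cell_id`, `n_pixels`, `orientation_deg`.
#' @export
segment_orientation <- function(label_map, min_pixels = 10L,
                                min_eigen_ratio = 1.05) {
  labels <- if (inherits(label_map, "myocyte_label_map"))
    label_map$labels else label_map
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  res <- lapply(ids, function(i) {
    idx <- which(labels == i, arr.ind = TRUE)
    n <- nrow(idx)
    if (n < min_pixels)
      return(data.frame(cell_id = i, n_pixels = n,
                        orientation_deg = NA_real_))
    y <- idx[, 1]; x <- idx[, 2]
    xc <- x - mean(x); yc <- y - mean(y)
    mxx <- mean(xc^2); myy <- mean(yc^2); mxy <- mean(xc * yc)
    ev <- eigen(matrix(c(mxx, mxy, mxy, myy), 2L), symmetric = TRUE)
    if (ev$values[2] <= 0 || ev$values[1] / ev$values[2] < min_eigen_ratio)
      return(data.frame(cell_id = i, n_pixels = n,
                        orientation_deg = NA_real_))
    ang <- atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi
    ang <- ((ang + 90) %% 180) - 90
    data.frame(cell_id = i, n_pixels = n, orientation_deg = ang)
  })
  do.call(rbind, res)
}

#' Axial orientation statistics of a myocyte population
#'
#' The main fiber orientation is the axial circular mean (doubled-angle
#' method); each cell's deviation is the axial angular difference to it.
#' Dispersion is reported both as the RMS of the axial deviations (the
#' default summary) and as the plain SD of the signed deviations; the
#' disarray fraction is the share of cells deviating by more than
#' `disarray_cutoff_deg`.
#'
#' @param orientations_deg numeric vector of axial orientations (deg);
#'   `NA` (undefined) entries are dropped.
#' @param disarray_cutoff_deg deviation classifying a cell as disarrayed.
#' @return List with `main_orientation_deg`, `dispersion_deg` (RMS),
#'   `dispersion_sd_deg`, `disarray_fraction`, `deviations_deg`, `n`.
#' @export
orientation_stats <- function(orientations_deg, disarray_cutoff_deg = 30) {
  th <- orientations_deg[!is.na(orientations_deg)]
  if (length(th) < 2L) stop("need at least 2 defined orientations")
  rad <- th * pi / 180
  main <- 0.5 * atan2(mean(sin(2 * rad)), mean(cos(2 * rad))) * 180 / pi
  d <- abs(th - main) %% 180
  dev <- pmin(d, 180 - d)
  signed <- ((th - main + 90) %% 180) - 90
  list(main_orientation_deg = main,
       dispersion_deg = sqrt(mean(dev^2)),
       dispersion_sd_deg = sd(signed),
       disarray_fraction = mean(dev > disarray_cutoff_deg),
       deviations_deg = dev, n = length(th))
}

#' Sarcomere length from the band-limited power spectrum
#'
#' 2D Fourier transform of a striated (alpha-actinin) image; the
#' sarcomere length is the reciprocal of the radial spatial frequency of
#' the power-spectrum maximum restricted to the band `1/band_um[2]` to
#' `1/band_um[1]` per um, refined by parabolic sub-bin interpolation of
#' the log power along both frequency axes.  A Hann window suppresses
#' leakage; the DC component is excluded.  If the spectrum's global
#' (non-DC) maximum lies outside the band, or the in-band peak does not
#' stand out from the in-band noise floor, the result is flagged
#' undefined (`NA` with attribute `reason`).
#'
#' @param actinin_image numeric matrix, at least 64 px per axis.
#' @param pixel_size_um pixel size (um).
#' @param band_um length-2 period band searched (um), default 1.5-2.5.
#' @param min_prominence required ratio of in-band peak power to the
#'   median in-band power.
#' @return Sarcomere length (um), or `NA` when undefined.
#' @export
sarcomere_length <- function(actinin_image, pixel_size_um,
                             band_um = c(1.5, 2.5),
                             min_prominence = 20) {
  stopifnot(is.matrix(actinin_image))
  nr <- nrow(actinin_image); ncp <- ncol(actinin_image)
  if (nr < 64L || ncp < 64L) stop("image must be at least 64 px per axis")
  f_hi <- 1 / band_um[1]; f_lo <- 1 / band_um[2]
  if (f_hi > 0.5 / pixel_size_um)
    stop("analysis band exceeds the Nyquist frequency at this pixel size")
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  w <- outer(hann(nr), hann(ncp))
  x <- (actinin_image - mean(actinin_image)) * w
  P <- Mod(fft(x))^2
  ff <- function(n) {
    i <- seq_len(n) - 1L
    ifelse(i <= n / 2, i, i - n) / (n * pixel_size_um)
  }
  fy <- ff(nr); fx <- ff(ncp)
  R <- sqrt(outer(fy^2, fx^2, `+`))
  in_band <- R >= f_lo & R <= f_hi
  non_dc <- R > 1e-9
  flagged <- function(reason) {
    out <- NA_real_
    attr(out, "reason") <- reason
    out
  }
  if (!any(in_band)) return(flagged("empty band"))
  gmax <- which.max(ifelse(non_dc, P, -Inf))
  if (!in_band[gmax]) return(flagged("dominant frequency outside band"))
  pk <- arrayInd(which.max(ifelse(in_band, P, -Inf)), dim(P))
  if (P[pk] < min_prominence * median(P[in_band]))
    return(flagged("no in-band peak above noise floor"))
  refine <- function(vals, f_at, df) {
    lp <- log(pmax(vals, 1e-300))
    den <- lp[1] - 2 * lp[2] + lp[3]
    delta <- if (abs(den) < 1e-12) 0 else 0.5 * (lp[1] - lp[3]) / den
    f_at + max(min(delta, 0.5), -0.5) * df
  }
  wrap <- function(i, n) ((i - 1L) %% n) + 1L
  iy <- pk[1]; ix <- pk[2]
  fy_r <- refine(P[wrap(iy + c(-1L, 0L, 1L), nr), ix], fy[iy], 1 / (nr * pixel_size_um))
  fx_r <- refine(P[iy, wrap(ix + c(-1L, 0L, 1L), ncp)], fx[ix], 1 / (ncp * pixel_size_um))
  f <- sqrt(fy_r^2 + fx_r^2)
  1 / f
}
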