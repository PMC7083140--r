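#' Specification of a membrane-stained myocyte phantom
#'
#' Describes a synthetic cardiomyocyte volume for testing the t-system
#' pipeline: a closed surface "sarcolemma" shell around a box-shaped cell
#' plus internal t-tubules arranged per `geometry`.  The long cell axis is
#' x (the third array dimension).
#'
#' @param cell_extent_um length-3 cell extents `(z, y, x)` in um.
#' @param voxel_size_um length-3 voxel size `(dz, dy, dx)` in um.
#' @param geometry `"full-lattice"` (lines along x on a square z-y grid),
#'   `"sheets"` (planes normal to x), `"surface-only"` (no tubules), or
#'   `"custom"` (tubule mask supplied in `custom_mask`).
#' @param lattice_spacing_um tubule spacing d (um); must exceed
#'   `2 * tubule_radius_um`.
#' @param tubule_radius_um tubule radius; the default renders
#'   single-voxel-thin tubules.
#' @param surface_thickness_um thickness of the surface shell.
#' @param intensity_levels named list, `background` and `membrane`.
#' @param attenuation_coefficient_per_um exponential depth-attenuation
#'   coefficient applied along z.
#' @param noise_sd Gaussian read-noise standard deviation.
#' @param poisson logical, apply Poisson shot noise.
#' @param blur_sigma_um optional Gaussian blur (scalar or per-axis) before
#'   noise, emulating finite resolution.
#' @param custom_mask logical array for `geometry = "custom"`.
#' @param rng_seed integer seed (mandatory for reproducibility).
#' @return An object of class `tubule_phantom_spec`.
#' @export
tubule_phantom_spec <- function(cell_extent_um = c(5.8, 25.0, 25.0),
                                voxel_size_um = c(0.1, 0.1, 0.1),
                                geometry = c("full-lattice", "sheets",
                                             "surface-only", "custom"),
                                lattice_spacing_um = 1.0,
                                tubule_radius_um = 0.04,
                                surface_thickness_um = 0.3,
                                intensity_levels = list(background = 10,
                                                        membrane = 100),
                                attenuation_coefficient_per_um = 0,
                                noise_sd = 0,
                                poisson = FALSE,
                                blur_sigma_um = 0,
                                custom_mask = NULL,
                                rng_seed = 1L) {
  geometry <- match.arg(geometry)
  voxel_size_um <- rep(as.numeric(voxel_size_um), length.out = 3L)
  cell_extent_um <- rep(as.numeric(cell_extent_um), length.out = 3L)
  if (any(voxel_size_um <= 0)) stop("voxel_size_um must be positive")
  if (geometry %in% c("full-lattice", "sheets") &&
      lattice_spacing_um <= 2 * tubule_radius_um)
    stop("lattice_spacing_um must exceed twice tubule_radius_um")
  if (geometry %in% c("full-lattice", "sheets") &&
      lattice_spacing_um < 2 * max(voxel_size_um))
    stop("lattice_spacing_um is not resolvable at this voxel size")
  if (geometry == "custom" && is.null(custom_mask))
    stop("geometry 'custom' requires custom_mask")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  pad_um <- 0.3
  n_cell <- round(cell_extent_um / voxel_size_um)
  n_pad <- pmax(3L, ceiling(pad_um / voxel_size_um))
  dims <- as.integer(n_cell + 2L * n_pad)
  if (any(dims < 64L))
    stop("cell_extent_um too small: stacks must be at least 64 voxels per axis")
  structure(list(
    cell_extent_um = cell_extent_um, voxel_size_um = voxel_size_um,
    geometry = geometry, lattice_spacing_um = lattice_spacing_um,
    tubule_radius_um = tubule_radius_um,
    surface_thickness_um = surface_thickness_um,
    intensity_levels = intensity_levels,
    attenuation_coefficient_per_um = attenuation_coefficient_per_um,
    noise_sd = noise_sd, poisson = poisson,
    blur_sigma_um = rep(as.numeric(blur_sigma_um), length.out = 3L),
    custom_mask = custom_mask, rng_seed = as.integer(rng_seed),
    dims = dims, n_pad = n_pad, n_cell = as.integer(n_cell)),
    class = "tubule_phantom_spec")
}

#' Generate a membrane-stained t-system phantom stack
#'
#' Renders the phantom described by a [tubule_phantom_spec()]: bright
#' membrane signal on the surface shell and tubules, dim background
#' elsewhere, then optional blur, exponential z-attenuation and noise.
#' The ground truth carries exact tubule and cell masks together with the
#' true mean tubule distance.
#'
#' @param spec a [tubule_phantom_spec()].
#' @param compute_truth how to obtain the true mean tubule distance:
#'   `"auto"` (exhaustive oracle when affordable, else analytic),
#'   `"brute"`, `"analytic"` or `"none"`.
#' @return A list with elements `stack` (a [voxel_stack()]) and `truth`
#'   (class `synthetic_ground_truth`: `tubule_mask`, `cell_mask`,
#'   `true_delta_tt_um`, `analytic_delta_tt_um`, `rng_seed`).
#' @export
gen_tsystem_stack <- function(spec, compute_truth = c("auto", "brute",
                                                      "analytic", "none")) {
  stopifnot(inherits(spec, "tubule_phantom_spec"))
  compute_truth <- match.arg(compute_truth)
  d <- spec$dims; np <- spec$n_pad; nc <- spec$n_cell
  vs <- spec$voxel_size_um

  cell_rng <- lapply(1:3, function(a) (np[a] + 1L):(np[a] + nc[a]))
  cell_mask <- array(FALSE, d)
  cell_mask[cell_rng[[1]], cell_rng[[2]], cell_rng[[3]]] <- TRUE

  # depth of each cell voxel below the nearest cell face, in um
  face_depth <- function(a) {
    i <- seq_len(nc[a])
    (pmin(i - 1L, nc[a] - i) + 0.5) * vs[a]
  }
  depth <- outer(outer(face_depth(1), face_depth(2), pmin), face_depth(3),
                 pmin)
  shell_cell <- depth < spec$surface_thickness_um
  surface_mask <- array(FALSE, d)
  surface_mask[cell_rng[[1]], cell_rng[[2]], cell_rng[[3]]] <- shell_cell

  tubule_mask <- array(FALSE, d)
  analytic <- NA_real_
  sp <- spec$lattice_spacing_um
  # tubule positions: a centred train of period sp within the cell extent,
  # kept clear of the surface shell (tubules do not hug the sarcolemma)
  node_seq <- function(n, sp_vox, cl_vox) {
    usable <- n - 1L - 2L * cl_vox
    k <- max(floor(usable / sp_vox) + 1L, 1L)
    off <- floor((n - 1L - (k - 1L) * sp_vox) / 2) + 1L
    seq(off, by = sp_vox, length.out = k)
  }
  cl_vox <- ceiling(spec$surface_thickness_um / vs)
  if (spec$geometry == "sheets") {
    sp_vox <- round(sp / vs[3])
    planes <- node_seq(nc[3], sp_vox, cl_vox[3])
    r_vox <- floor(spec$tubule_radius_um / vs[3])
    idx <- unique(as.vector(outer(planes, -r_vox:r_vox, `+`)))
    idx <- idx[idx >= 1L & idx <= nc[3]]
    tub_cell <- array(FALSE, nc)
    tub_cell[, , idx] <- TRUE
    tubule_mask[cell_rng[[1]], cell_rng[[2]], cell_rng[[3]]] <- tub_cell
    analytic <- sp / 4
  } else if (spec$geometry == "full-lattice") {
    sp_z <- round(sp / vs[1]); sp_y <- round(sp / vs[2])
    nodes_z <- node_seq(nc[1], sp_z, cl_vox[1])
    nodes_y <- node_seq(nc[2], sp_y, cl_vox[2])
    gz <- outer(seq_len(nc[1]), nodes_z,
                function(i, p) abs(i - p) * vs[1])
    gy <- outer(seq_len(nc[2]), nodes_y,
                function(i, p) abs(i - p) * vs[2])
    dz <- apply(gz, 1L, min); dy <- apply(gy, 1L, min)
    cross <- outer(dz^2, dy^2, `+`) <= max(spec$tubule_radius_um,
                                           min(vs) / 4)^2
    tub_cell <- array(rep(cross, nc[3]), nc)
    tubule_mask[cell_rng[[1]], cell_rng[[2]], cell_rng[[3]]] <- tub_cell
    analytic <- (sp / 6) * (sqrt(2) + log(1 + sqrt(2)))
  } else if (spec$geometry == "custom") {
    if (!identical(dim(spec$custom_mask), dim(cell_mask)))
      stop("custom_mask dimensions must match the stack dimensions ",
           paste(d, collapse = "x"))
    tubule_mask <- spec$custom_mask & cell_mask
  }

  membrane <- surface_mask | tubule_mask
  lv <- spec$intensity_levels
  img <- array(lv$background, d)
  img[membrane] <- lv$membrane

  if (any(spec$blur_sigma_um > 0))
    img <- blur3_fft(img, spec$blur_sigma_um / vs)
  if (spec$attenuation_coefficient_per_um > 0) {
    z_um <- (seq_len(d[1]) - 1L) * vs[1]
    img <- img * exp(-spec$attenuation_coefficient_per_um * z_um)
  }
  img <- with_seed(spec$rng_seed, {
    if (spec$poisson) img <- array(rpois(length(img), pmax(img, 0)), d)
    if (spec$noise_sd > 0) img <- img + rnorm(length(img), 0, spec$noise_sd)
    img
  })
  img[img < 0] <- 0

  true_dtt <- NA_real_
  if (spec$geometry != "surface-only" && compute_truth != "none") {
    n_pairs <- as.numeric(sum(cell_mask)) * sum(tubule_mask)
    if (compute_truth == "brute" ||
        (compute_truth == "auto" && n_pairs <= 6e9)) {
      true_dtt <- brute_force_dtt(tubule_mask, cell_mask, vs)
    } else {
      true_dtt <- analytic
    }
  }

  truth <- structure(list(
    tubule_mask = tubule_mask, cell_mask = cell_mask,
    surface_mask = surface_mask,
    true_delta_tt_um = as.numeric(true_dtt),
    analytic_delta_tt_um = analytic,
    geometry = spec$geometry, rng_seed = spec$rng_seed),
    class = "synthetic_ground_truth")
  list(stack = voxel_stack(img, vs, channel = "WGA"), truth = truth)
}

#' Exhaustive mean tubule-distance oracle
#'
#' For every cell voxel, the minimum Euclidean distance to any tubule
#' voxel by direct all-pairs search (no distance transform involved);
#' returns the mean in micrometers.  Intended as an independent check of
#' [compute_dtt()] on small phantoms.
#'
#' @param tubule_mask,cell_mask logical arrays of one common dimension.
#' @param voxel_size_um length-3 voxel size `(dz, dy, dx)` in um.
#' @return Mean distance (um); `NaN` with attribute `flagged = TRUE` if the
#'   tubule mask is empty.
#' @export
brute_force_dtt <- function(tubule_mask, cell_mask, voxel_size_um) {
  stopifnot(identical(dim(tubule_mask), dim(cell_mask)))
  if (!any(cell_mask)) stop("cell_mask is empty")
  voxel_size_um <- rep(as.numeric(voxel_size_um), length.out = 3L)
  if (!any(tubule_mask)) {
    out <- NaN
    attr(out, "flagged") <- TRUE
    return(out)
  }
  phys <- function(mask) {
    idx <- which(mask)
    ai <- arrayInd(idx, dim(mask))
    sweep(ai - 1L, 2L, voxel_size_um, `*`)
  }
  dists <- cpp_min_dist(phys(cell_mask), phys(tubule_mask))
  out <- mean(dists)
  attr(out, "n_cell_voxels") <- length(dists)
  out
}
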