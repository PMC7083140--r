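#' Read and write calibrated stacks as multi-page TIFF with JSON sidecar
#'
#' Stacks are stored one z-plane per TIFF page (32-bit float, intensities
#' rescaled to \[0, 1\] with the scale factor recorded) next to a
#' `<file>.json` sidecar holding the voxel size, channel, scale factor and
#' optional metadata.  Reading without a sidecar voxel size is a hard
#' error: distances would be meaningless.
#'
#' @param stack a [voxel_stack()].
#' @param path TIFF file path (sidecar written at `<path>.json`).
#' @param metadata optional named list merged into the sidecar (e.g. seed,
#'   truth summary).
#' @return `write_stack()`: the path, invisibly.  `read_stack()`: a
#'   [voxel_stack()] with the sidecar attached as attribute `sidecar`.
#' @export
write_stack <- function(stack, path, metadata = list()) {
  stopifnot(is_voxel_stack(stack))
  x <- stack$intensities
  scale <- max(x)
  if (scale <= 0) scale <- 1
  pages <- lapply(seq_len(dim(x)[1]), function(z) x[z, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sidecar <- c(list(voxel_size_um = stack$voxel_size_um,
                    channel = stack$channel,
                    scale_factor = scale,
                    dims_zyx = dim(x)),
               metadata)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path))
    stop("missing sidecar ", sidecar_path,
         ": field 'voxel_size_um' is required")
  sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(sidecar$voxel_size_um))
    stop("sidecar lacks required field 'voxel_size_um'")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(length(pages), dim(pages[[1]]))
  x <- array(0, d)
  for (z in seq_along(pages)) x[z, , ] <- pages[[z]]
  x <- x * (sidecar$scale_factor %||% 1)
  out <- voxel_stack(x, as.numeric(sidecar$voxel_size_um),
                     sidecar$channel %||% "unknown")
  attr(out, "sidecar") <- sidecar
  out
}

#' Read and write force traces as CSV with JSON protocol sidecar
#'
#' The CSV holds columns `time_s` and `force_mN` (extra columns are
#' preserved on read but ignored by the analysis); the sidecar carries
#' the pacing protocol, sampling rate and stimulus times.
#'
#' @param trace a [force_trace()].
#' @param path CSV file path (sidecar at `<path>.json`).
#' @return `write_trace()`: the path, invisibly; `read_trace()`: a
#'   [force_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "force_trace"))
  write.csv(data.frame(time_s = trace$time_s, force_mN = trace$force_mN),
            path, row.names = FALSE)
  sidecar <- list(sampling_hz = trace$sampling_hz,
                  protocol = trace$protocol,
                  stimulus_times_s = trace$stimulus_times_s)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tab <- read.csv(path)
  if (!all(c("time_s", "force_mN") %in% names(tab)))
    stop("trace CSV must contain columns time_s and force_mN")
  sidecar_path <- paste0(path, ".json")
  protocol <- NULL; stim <- NULL; fs <- NULL
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    protocol <- if (!is.null(sc$protocol)) as.data.frame(sc$protocol)
    stim <- sc$stimulus_times_s
    fs <- sc$sampling_hz
  }
  force_trace(tab$time_s, tab$force_mN, sampling_hz = fs,
              protocol = protocol, stimulus_times_s = stim)
}

#' Thin CSV table helpers
#'
#' @param table data.frame.
#' @param path CSV path.
#' @return `write_table()`: the path, invisibly; `read_table()`: a
#'   data.frame.
#' @export
write_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) read.csv(path, check.names = FALSE)
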