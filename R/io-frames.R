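# Voltage frame-series I/O: flat binary float32 frames with a JSON sidecar
# describing the grid, frame interval and units. Layout is x-fastest
# (column-major over an nx x ny matrix), one frame after another.

#' Write a voltage frame series
#'
#' @param frames 3-D array `nx x ny x n_frames` of voltages (mV).
#' @param dt_frame_ms interval between frames (ms).
#' @param prefix output path prefix; writes `<prefix>.bin` and
#'   `<prefix>.json`.
#' @return The prefix, invisibly.
#' @export
write_frame_series <- function(frames, dt_frame_ms, prefix) {
  stopifnot(length(dim(frames)) == 3L)
  d <- dim(frames)
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(frames), con, size = 4L, endian = "little")
  jsonlite::write_json(
    list(nx = d[1], ny = d[2], n_frames = d[3], dt_frame_ms = dt_frame_ms,
         dtype = "float32", byte_order = "little", layout = "x-fastest",
         voltage_units = "mV"),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a voltage frame series written by [write_frame_series()]
#'
#' @param prefix path prefix used at write time.
#' @return List with `frames` (3-D array, mV) and `meta` (sidecar contents).
#' @export
read_frame_series <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  n <- meta$nx * meta$ny * meta$n_frames
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = n, size = 4L, endian = "little")
  if (length(vals) != n) stop("frame file truncated")
  list(frames = array(vals, dim = c(meta$nx, meta$ny, meta$n_frames)),
       meta = meta)
}
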