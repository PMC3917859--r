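#' Analytic spiral-wave fixture
#'
#' Closed-form rotating-spiral voltage field used as an oracle for the
#' phase-singularity detector: the spiral core position is known exactly, so a
#' detector can be checked against it without running a simulation.
#'
#' @param core length-2 numeric, core position in 0-based grid coordinates.
#' @param omega angular frequency in rad/ms (positive = counter-clockwise).
#' @param wavenumber spatial wavenumber k in rad/mm.
#' @param v_rest,v_peak resting and peak voltage (mV).
#' @return Object of class `spiral_fixture`.
#' @export
spiral_fixture <- function(core, omega = 2 * pi / 125, wavenumber = 2 * pi / 30,
                           v_rest = -85, v_peak = 30) {
  stopifnot(length(core) == 2L, is.finite(omega), is.finite(wavenumber),
            v_peak > v_rest)
  structure(list(core = as.numeric(core), omega = omega,
                 wavenumber = wavenumber, v_rest = v_rest, v_peak = v_peak),
            class = "spiral_fixture")
}

#' Evaluate a spiral fixture on a tissue sheet grid
#'
#' Voltage field
#' `V(x, t) = rest + (peak - rest) * (1 + cos(atan2(y - y0, x - x0) - k*r - omega*t)) / 2`
#' with `r` the distance from the core in mm. Bounded by `[rest, peak]` for
#' all `t`; the phase has winding number +/-1 around the core.
#'
#' @param fixture a [spiral_fixture()].
#' @param t time in ms (>= 0).
#' @param grid a [tissue_sheet()].
#' @return `nx x ny` voltage matrix (mV); rows index x, columns index y.
#' @export
make_spiral_field <- function(fixture, t, grid) {
  stopifnot(inherits(fixture, "spiral_fixture"), inherits(grid, "tissue_sheet"))
  if (!is.finite(t) || t < 0) stop("t must be >= 0")
  xi <- seq_len(grid$nx) - 1
  yi <- seq_len(grid$ny) - 1
  X <- matrix(xi, grid$nx, grid$ny)
  Y <- matrix(yi, grid$nx, grid$ny, byrow = TRUE)
  dxm <- X - fixture$core[1]
  dym <- Y - fixture$core[2]
  th <- atan2(dym, dxm)
  r_mm <- grid$dx * sqrt(dxm^2 + dym^2)
  ph <- th - fixture$wavenumber * r_mm - fixture$omega * t
  fixture$v_rest + (fixture$v_peak - fixture$v_rest) * (1 + cos(ph)) / 2
}

#' Synthetic action-potential pulse train fixture
#'
#' @param ap_times onset times (ms), sorted, all within the trace and
#'   separated by more than `ap_duration` (overlapping APs are rejected).
#' @param baseline resting voltage (mV); must be below -60 so every AP starts
#'   from a valid diastolic level.
#' @param amplitude AP amplitude (mV above baseline).
#' @param ap_duration total AP duration (ms).
#' @param duration trace duration (ms).
#' @param dt sample interval (ms).
#' @return Object of class `pulse_train` with fields `time` and `v`.
#' @export
make_pulse_train <- function(ap_times, baseline = -85, amplitude = 115,
                             ap_duration = 80, duration = 3000, dt = 1) {
  ap_times <- as.numeric(ap_times)
  if (is.unsorted(ap_times, strictly = TRUE) && length(ap_times) > 1L)
    stop("ap_times must be strictly increasing")
  if (length(ap_times) && (min(ap_times) < 0 ||
                           max(ap_times) + ap_duration > duration))
    stop("every AP must lie within the trace duration")
  if (length(ap_times) > 1L && any(diff(ap_times) < ap_duration))
    stop("overlapping APs are not allowed")
  if (baseline >= -60) stop("baseline must be below -60 mV")
  time <- seq(0, duration, by = dt)
  v <- rep(baseline, length(time))
  rise <- min(2, ap_duration / 4)
  for (t0 in ap_times) {
    tau <- time - t0
    on_rise <- tau >= 0 & tau < rise
    on_fall <- tau >= rise & tau <= ap_duration
    v[on_rise] <- baseline + amplitude * tau[on_rise] / rise
    v[on_fall] <- baseline +
      amplitude * (1 + cos(pi * (tau[on_fall] - rise) / (ap_duration - rise))) / 2
  }
  structure(list(time = time, v = v, ap_times = ap_times,
                 baseline = baseline, amplitude = amplitude,
                 ap_duration = ap_duration),
            class = "pulse_train")
}
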