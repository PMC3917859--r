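# Two-variable phenomenological excitable cell model (Mitchell-Schaeffer
# class) with separate Purkinje and myocardial parameter sets, plus the
# asymmetric resistive PMJ coupling parameters.
#
# Normalized state: u in [0, 1] (fast excitation variable), h in [0, 1]
# (recovery gate). Membrane voltage is the affine map V = v_rest + v_span * u
# with v_rest = -85 mV and v_span = 115 mV, so the standard -60/-40/-20 mV
# detection thresholds apply literally.
#
#   du/dt = h u^2 (1 - u) / tau_in - u / tau_out + I_stim
#   dh/dt = (1 - h) / tau_open   if u <  u_gate
#         = -h / tau_close       if u >= u_gate
#
# The optional short-diastolic-interval facilitation shortens the effective
# recovery time constant while the gate is still far from rest
# (tau_open_eff = tau_open / (1 + di_facilitation * (1 - h))), easing
# re-excitation at short diastolic intervals without touching steady state.

#' Cell model parameters (two-variable excitable model)
#'
#' @param tau_in upstroke time constant (ms).
#' @param tau_out repolarization time constant (ms).
#' @param tau_open recovery (gate reopening) time constant (ms).
#' @param tau_close gate closing time constant (ms); the dominant control of
#'   action potential duration (APD roughly `tau_close * log(tau_out /
#'   (4 * tau_in))`).
#' @param u_gate excitation threshold on the normalized voltage.
#' @param di_facilitation dimensionless >= 0; shortens the effective
#'   `tau_open` at short diastolic intervals (0 disables).
#' @param v_rest,v_span affine voltage map constants (mV).
#' @return Object of class `cell_params`.
#' @export
cell_params <- function(tau_in = 0.3, tau_out = 6, tau_open = 80,
                        tau_close = 60, u_gate = 0.13, di_facilitation = 0,
                        v_rest = -85, v_span = 115) {
  stopifnot(tau_in > 0, tau_out > 0, tau_open > 0, tau_close > 0,
            u_gate > 0, u_gate < 1, di_facilitation >= 0, v_span > 0)
  structure(list(tau_in = tau_in, tau_out = tau_out, tau_open = tau_open,
                 tau_close = tau_close, u_gate = u_gate,
                 di_facilitation = di_facilitation,
                 v_rest = v_rest, v_span = v_span),
            class = "cell_params")
}

#' Default myocardial cell parameters
#'
#' Calibrated for an APD shorter than the Purkinje APD at 500 ms pacing and a
#' wavelength that supports sustained spiral-wave reentry on the default
#' sheet.
#' @return A [cell_params()].
#' @export
myocyte_params <- function() {
  cell_params(tau_in = 0.3, tau_out = 6, tau_open = 80, tau_close = 50,
              u_gate = 0.13, di_facilitation = 0.5)
}

#' Default Purkinje cell parameters
#'
#' The Purkinje action potential is intrinsically longer than the ventricular
#' one, so its `tau_close` is larger.
#' @return A [cell_params()].
#' @export
purkinje_params <- function() {
  cell_params(tau_in = 0.3, tau_out = 5, tau_open = 100, tau_close = 90,
              u_gate = 0.13, di_facilitation = 0)
}

#' PMJ coupling parameters
#'
#' Each PMJ couples a terminal Purkinje node to its `k_coupled` nearest
#' myocardial nodes through a fixed resistance `r_pmj`. The current into
#' myocyte j is `I_j = (V_terminal - V_j) / r_pmj` (mV / MOhm = nA); the
#' current load on the terminal is the scaled sum
#' `loading_factor * sum(I_j)`, representing the electrotonic load of tissue
#' surrounding the junction. `current_conversion` maps nA of junctional
#' current into the normalized model's rate units (1/ms per nA) for a
#' myocyte; `terminal_capacitance_scale` is the effective capacitance of the
#' terminal Purkinje cell relative to a myocyte, so the terminal's rate
#' change per nA is `current_conversion / terminal_capacitance_scale`. Both
#' constants were calibrated once on the single-PMJ rig so that at
#' `r_pmj = 20` MOhm and `loading_factor = 20` the anterograde delay falls in
#' the physiological 4-14 ms window and the retrograde delay in 2-4 ms.
#'
#' @param r_pmj junctional resistance in MOhm (range of interest 10-25).
#' @param loading_factor dimensionless loading multiplier (range 10-30).
#' @param k_coupled number of coupled myocardial nodes per PMJ (>= 1).
#' @param current_conversion 1/ms of normalized-voltage rate per nA.
#' @param terminal_capacitance_scale terminal capacitance relative to a
#'   myocyte (> 0).
#' @return Object of class `pmj_coupling_params`.
#' @export
pmj_coupling_params <- function(r_pmj = 20, loading_factor = 20,
                                k_coupled = 6L,
                                current_conversion = 0.025,
                                terminal_capacitance_scale = 24) {
  stopifnot(r_pmj > 0, loading_factor > 0, k_coupled >= 1L,
            current_conversion > 0, terminal_capacitance_scale > 0)
  structure(list(r_pmj = r_pmj, loading_factor = loading_factor,
                 k_coupled = as.integer(k_coupled),
                 current_conversion = current_conversion,
                 terminal_capacitance_scale = terminal_capacitance_scale),
            class = "pmj_coupling_params")
}

#' Junctional exchange currents at one PMJ
#'
#' Ohm's-law bookkeeping across the junction: current into each coupled
#' myocyte and the scaled load on the terminal Purkinje cell. Exact charge
#' accounting — `load / loading_factor` equals `sum(i_myo_nA)` identically.
#'
#' @param v_terminal terminal Purkinje voltage (mV).
#' @param v_coupled voltages of the coupled myocytes (mV); length must equal
#'   `params$k_coupled`.
#' @param params a [pmj_coupling_params()].
#' @return List with `i_myo_nA` (nA into each myocyte) and `load_nA` (nA
#'   drawn from the terminal).
#' @export
pmj_exchange_currents <- function(v_terminal, v_coupled, params) {
  stopifnot(inherits(params, "pmj_coupling_params"))
  if (length(v_coupled) != params$k_coupled)
    stop("length(v_coupled) must equal k_coupled")
  i_myo <- (v_terminal - v_coupled) / params$r_pmj
  list(i_myo_nA = i_myo, load_nA = params$loading_factor * sum(i_myo))
}

#' Simulate a single uncoupled cell
#'
#' Forward-Euler integration of the two-variable model for one cell with a
#' stimulus schedule; the reference dynamics against which the tissue stepper
#' is checked.
#'
#' @param params a [cell_params()].
#' @param stim_times stimulus onset times (ms).
#' @param stim_duration,stim_amplitude stimulus duration (ms) and amplitude
#'   (1/ms in normalized units).
#' @param horizon total time (ms).
#' @param dt time step (ms).
#' @return data.frame with `time`, `u`, `h` and `v` (mV).
#' @export
simulate_cell <- function(params, stim_times = 5, stim_duration = 1,
                          stim_amplitude = 0.6, horizon = 500, dt = 0.05) {
  stopifnot(inherits(params, "cell_params"))
  n <- as.integer(ceiling(horizon / dt)) + 1L
  u <- numeric(n); h <- numeric(n)
  u[1] <- 0; h[1] <- 1
  tt <- (seq_len(n) - 1L) * dt
  for (i in seq_len(n - 1L)) {
    t <- tt[i]
    stim <- if (any(t >= stim_times & t < stim_times + stim_duration))
      stim_amplitude else 0
    du <- h[i] * u[i]^2 * (1 - u[i]) / params$tau_in - u[i] / params$tau_out + stim
    dh <- if (u[i] < params$u_gate) {
      topen <- params$tau_open / (1 + params$di_facilitation * (1 - h[i]))
      (1 - h[i]) / topen
    } else {
      -h[i] / params$tau_close
    }
    u[i + 1L] <- u[i] + dt * du
    h[i + 1L] <- h[i] + dt * dh
  }
  data.frame(time = tt, u = u, h = h, v = params$v_rest + params$v_span * u)
}

#' Action potential duration of a cell model
#'
#' APD measured at the -20 mV detection threshold from a paced single-cell
#' run (last beat of a pacing train, so restitution at the cycle length is
#' respected).
#'
#' @param params a [cell_params()].
#' @param cycle_length_ms pacing interval (ms).
#' @param n_beats number of paced beats.
#' @param dt time step (ms).
#' @return APD in ms.
#' @export
apd_at_pacing <- function(params, cycle_length_ms = 500, n_beats = 3L,
                          dt = 0.05) {
  stim_times <- 5 + cycle_length_ms * (seq_len(n_beats) - 1L)
  tr <- simulate_cell(params, stim_times = stim_times,
                      horizon = max(stim_times) + cycle_length_ms, dt = dt)
  th <- -20
  last_on <- max(stim_times)
  seg <- tr[tr$time >= last_on, ]
  above <- seg$v >= th
  up <- which(diff(above) == 1L)[1]
  down <- which(diff(above) == -1L)
  down <- down[down > up][1]
  if (is.na(up) || is.na(down)) return(NA_real_)
  seg$time[down] - seg$time[up]
}
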