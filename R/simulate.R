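# Assembly and execution of the coupled Purkinje-cable / tissue-sheet model.

#' Couple a Purkinje network to a tissue sheet
#'
#' Maps the network's (x, y) footprint onto the sheet interior by an affine
#' scaling (the sheet is the 2D stand-in for the myocardial wall), and couples
#' each PMJ terminal to its `k_coupled` nearest sheet nodes. Wall-depth
#' insertion has no 2D analog; `insertion_depth_fraction` rides along as
#' metadata.
#'
#' @param network a [grow_network()] result (or any `purkinje_network`).
#' @param pmjset a [place_pmjs()] result.
#' @param sheet a [tissue_sheet()].
#' @param coupling a [pmj_coupling_params()]; per-PMJ resistance and loading
#'   in `pmjset$pmjs` are overridden by `coupling$r_pmj` / `loading_factor`
#'   when `override = TRUE` (the sweep drivers do this).
#' @param myo,pk [cell_params()] for the two populations.
#' @param d_cable cable diffusivity (mm^2/ms); sets Purkinje conduction
#'   velocity.
#' @param margin_frac fraction of the sheet extent left clear around the
#'   mapped network.
#' @param override replace per-PMJ resistance/loading with `coupling` values.
#' @return Object of class `coupled_model` ready for [run_sinus()] /
#'   [run_s1s2()].
#' @export
build_coupled_model <- function(network, pmjset, sheet,
                                coupling = pmj_coupling_params(),
                                myo = myocyte_params(),
                                pk = purkinje_params(),
                                d_cable = 1.4, margin_frac = 0.1,
                                override = TRUE) {
  stopifnot(inherits(network, "purkinje_network"), inherits(pmjset, "pmj_set"),
            inherits(sheet, "tissue_sheet"),
            inherits(coupling, "pmj_coupling_params"))
  if (myo$v_rest != pk$v_rest || myo$v_span != pk$v_span)
    stop("both populations must share the affine voltage map")

  n_pmj <- nrow(pmjset$pmjs)
  # map terminals into sheet grid coordinates
  xy <- network$nodes[, 1:2, drop = FALSE]
  rng_x <- range(xy[, 1]); rng_y <- range(xy[, 2])
  span_x <- max(rng_x[2] - rng_x[1], 1e-9)
  span_y <- max(rng_y[2] - rng_y[1], 1e-9)
  gx0 <- margin_frac * (sheet$nx - 1); gx1 <- (1 - margin_frac) * (sheet$nx - 1)
  gy0 <- margin_frac * (sheet$ny - 1); gy1 <- (1 - margin_frac) * (sheet$ny - 1)
  to_grid <- function(p) {
    c(gx0 + (p[1] - rng_x[1]) / span_x * (gx1 - gx0),
      gy0 + (p[2] - rng_y[1]) / span_y * (gy1 - gy0))
  }

  coupled <- vector("list", n_pmj)
  if (n_pmj > 0L) for (q in seq_len(n_pmj)) {
    g <- to_grid(network$nodes[pmjset$pmjs$terminal_id[q], ])
    gi <- round(g[1]); gj <- round(g[2])
    # k nearest grid nodes around the mapped terminal (deterministic ties)
    w <- 3L
    repeat {
      ii <- max(0, gi - w):min(sheet$nx - 1, gi + w)
      jj <- max(0, gj - w):min(sheet$ny - 1, gj + w)
      cand <- as.matrix(expand.grid(i = ii, j = jj))
      if (nrow(cand) >= coupling$k_coupled) break
      w <- w + 2L
    }
    d2 <- (cand[, 1] - g[1])^2 + (cand[, 2] - g[2])^2
    ord <- order(d2, cand[, 1], cand[, 2])
    sel <- cand[ord[seq_len(coupling$k_coupled)], , drop = FALSE]
    coupled[[q]] <- as.integer(sel[, 1] + sheet$nx * sel[, 2] + 1L)  # 1-based
  }
  pmjs <- pmjset$pmjs
  if (override && n_pmj > 0L) {
    pmjs$r_pmj <- coupling$r_pmj
    pmjs$loading_factor <- coupling$loading_factor
  }

  structure(list(
    network = network, sheet = sheet, coupling = coupling,
    myo = myo, pk = pk, d_cable = d_cable,
    pmjs = pmjs, coupled = coupled,
    cmodel = list(
      nx = sheet$nx, ny = sheet$ny, dx = sheet$dx,
      d_sheet = sheet$diffusivity, d_cable = d_cable,
      edge_i = as.integer(network$edges$n1 - 1L),
      edge_j = as.integer(network$edges$n2 - 1L),
      edge_w = 1 / pmax(network$edges$length_mm, 1e-6)^2,
      n_cable = nrow(network$nodes),
      myo = unlist(myo[c("tau_in", "tau_out", "tau_open", "tau_close",
                         "u_gate", "di_facilitation")], use.names = FALSE),
      pk = unlist(pk[c("tau_in", "tau_out", "tau_open", "tau_close",
                       "u_gate", "di_facilitation")], use.names = FALSE),
      v_rest = myo$v_rest, v_span = myo$v_span,
      pmj_term = as.integer(pmjs$terminal_id - 1L),
      pmj_myo = as.integer(unlist(coupled) - 1L),
      pmj_off = as.integer(c(0L, cumsum(lengths(coupled)))),
      pmj_r = as.numeric(pmjs$r_pmj),
      pmj_load = as.numeric(pmjs$loading_factor),
      current_conversion = coupling$current_conversion,
      terminal_capacitance_scale = coupling$terminal_capacitance_scale)),
    class = "coupled_model")
}

#' Quiescent state for a coupled model
#' @param model a [build_coupled_model()] result.
#' @return List of state vectors (`u_s`, `h_s`, `u_c`, `h_c`, `t`).
#' @export
resting_state <- function(model) {
  stopifnot(inherits(model, "coupled_model"))
  ns <- model$sheet$nx * model$sheet$ny
  nc <- model$cmodel$n_cable
  list(u_s = numeric(ns), h_s = rep(1, ns),
       u_c = numeric(nc), h_c = rep(1, nc), t = 0)
}

check_dt <- function(model, dt, cable_substeps = 2L) {
  bound_s <- model$sheet$dx^2 / (4 * model$sheet$diffusivity)
  if (dt > bound_s + 1e-12)
    stop(sprintf("dt = %g ms violates sheet stability bound dx^2/(4 D) = %g ms",
                 dt, bound_s))
  if (nrow(model$network$edges) > 0L) {
    # graph-Laplacian bound: dt_sub <= 1 / (D * max_i sum_e 1/len_e^2)
    w <- model$cmodel$edge_w
    wsum <- rep(0, model$cmodel$n_cable)
    for (side in list(model$cmodel$edge_i, model$cmodel$edge_j)) {
      acc <- vapply(split(w, side), sum, numeric(1))
      idx <- as.integer(names(acc)) + 1L
      wsum[idx] <- wsum[idx] + acc
    }
    bound_c <- 1 / (model$d_cable * max(wsum))
    if (dt / cable_substeps > bound_c + 1e-12)
      stop(sprintf(
        "dt = %g ms violates cable stability bound %g ms (with %d substeps)",
        dt, bound_c * cable_substeps, cable_substeps))
  }
  invisible(TRUE)
}

run_core <- function(model, state, n_steps, dt, stims = NULL, stim_nodes = NULL,
                     frame_interval = 0, frame_t_start = 0,
                     trace_interval = 0, trace_cable = integer(0),
                     trace_sheet = integer(0), early_stop = FALSE,
                     record_sheet_acts = TRUE, cable_substeps = 2L) {
  check_dt(model, dt, cable_substeps)
  if (is.null(stims)) {
    stims <- matrix(numeric(0), 0, 4)
    stim_nodes <- list()
  }
  run <- list(dt = dt, t0 = state$t, n_steps = as.double(n_steps),
              stims = stims, stim_nodes = stim_nodes,
              frame_every = if (frame_interval > 0) as.integer(round(frame_interval / dt)) else 0L,
              frame_t_start = frame_t_start,
              trace_every = if (trace_interval > 0) as.integer(round(trace_interval / dt)) else 0L,
              trace_cable = as.integer(trace_cable - 1L),
              trace_sheet = as.integer(trace_sheet - 1L),
              act_thresh_mv = -20, act_start_mv = -60, blank_ms = 50,
              early_stop = early_stop,
              record_sheet_acts = record_sheet_acts,
              cable_substeps = as.integer(cable_substeps))
  res <- cpp_simulate(model$cmodel, state, run)
  if (isTRUE(res$aborted)) stop("simulation aborted: ", res$abort_msg)
  res
}

#' Advance the coupled system by one explicit step
#'
#' One operator-splitting step: reaction update of both cell populations,
#' diffusion on the sheet and along cable edges, and PMJ current exchange.
#' `dt` must satisfy the explicit stability bound `dt <= dx^2 / (4 D)`.
#'
#' @param model a [build_coupled_model()] result.
#' @param state state list as from [resting_state()].
#' @param dt time step (ms).
#' @return Updated state list.
#' @export
step_coupled_system <- function(model, state, dt) {
  res <- run_core(model, state, n_steps = 1, dt = dt)
  list(u_s = res$u_s, h_s = res$h_s, u_c = res$u_c, h_c = res$h_c,
       t = res$t_end)
}

# Cable nodes within stim_radius (mm) of any root: the paced His region.
# Point stimulation of a single branch node cannot overcome the diffusive
# drain of its neighbours, so pacing charges a small proximal segment.
his_stim_nodes <- function(model, stim_radius = 2) {
  pos <- model$network$nodes
  roots <- model$network$roots
  near <- rep(FALSE, nrow(pos))
  for (r in roots) {
    d2 <- rowSums(sweep(pos, 2, pos[r, ])^2)
    near <- near | d2 <= stim_radius^2
  }
  as.integer(which(near) - 1L)
}

# Wrap a raw cpp result into a sim_run object.
as_sim_run <- function(model, res, dt, label = NULL) {
  structure(list(
    model = model, dt = dt, t_end = res$t_end,
    sheet_acts = data.frame(node = res$act_s_node, time = res$act_s_time),
    cable_acts = data.frame(node = res$act_c_node, time = res$act_c_time),
    frames = res$frames %||% NULL,
    frame_times = res$frame_times %||% numeric(0),
    trace_cable_v = res$trace_cable_v %||% NULL,
    trace_sheet_v = res$trace_sheet_v %||% NULL,
    trace_times = res$trace_times %||% numeric(0),
    stopped_early = isTRUE(res$stopped_early),
    label = label), class = "sim_run")
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf("sim_run to t = %.1f ms: %d sheet activations, %d cable activations%s\n",
              x$t_end, nrow(x$sheet_acts), nrow(x$cable_acts),
              if (!is.null(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Simulate sinus-rhythm activation through the Purkinje network
#'
#' Stimulates the His root(s) of the network; excitation conducts along the
#' cable tree, crosses the PMJs anterogradely and activates the sheet.
#'
#' @param model a [build_coupled_model()] result.
#' @param pace_times His stimulus onset times (ms).
#' @param horizon total simulated time (ms).
#' @param dt time step (ms).
#' @param frame_interval frame recording interval (ms; 0 disables).
#' @param check_capture error if any PMJ fails anterogradely from rest (the
#'   junction calibration requires success from the resting state).
#' @return A `sim_run`.
#' @export
run_sinus <- function(model, pace_times = 5, horizon = 300, dt = 0.05,
                      frame_interval = 0, check_capture = FALSE) {
  stims <- cbind(pace_times, pace_times + 2, 0.8, 0)
  his <- his_stim_nodes(model)
  stim_nodes <- rep(list(his), length(pace_times))
  res <- run_core(model, resting_state(model), n_steps = ceiling(horizon / dt),
                  dt = dt, stims = stims, stim_nodes = stim_nodes,
                  frame_interval = frame_interval)
  run <- as_sim_run(model, res, dt, label = "sinus")
  if (check_capture && nrow(model$pmjs) > 0L) {
    for (q in seq_len(nrow(model$pmjs))) {
      myo_nodes <- model$coupled[[q]]
      if (!any(run$sheet_acts$node %in% myo_nodes))
        stop(sprintf("PMJ %d failed anterogradely from rest: junction calibration error", q))
    }
  }
  run
}

#' Induce reentry with the S1-S2 cross-field protocol
#'
#' S1: two His paces `s1_interval` apart (conditioning). S2: a premature
#' half-domain field stimulus applied to the sheet at coupling interval `ci`
#' after the second S1. The run is labeled sustained iff any sheet activation
#' occurs later than `sustained_after` (default 3000 ms) after S2.
#'
#' @param model a [build_coupled_model()] result.
#' @param ci S2 coupling interval after the second S1 (ms, > 0).
#' @param horizon time simulated after S2 (ms).
#' @param s1_times the two S1 pace times (ms).
#' @param s2_amplitude S2 strength (normalized rate units, 1/ms).
#' @param s2_duration S2 duration (ms).
#' @param s2_fraction fraction of the sheet (low-x half-domain) receiving S2.
#' @param sustained_after sustained-reentry horizon after S2 (ms).
#' @param dt time step (ms).
#' @param frame_interval frame recording interval (ms; 0 disables); frames
#'   are kept from S2 onward.
#' @param early_stop stop when the whole domain is quiescent (the run can
#'   then be labeled non-sustained without simulating the full horizon).
#' @return A `sim_run` with `$sustained`, `$s2_time` and `$ci` fields.
#' @export
run_s1s2 <- function(model, ci, horizon = 3200, s1_times = c(10, 510),
                     s2_amplitude = 3, s2_duration = 2, s2_fraction = 0.5,
                     sustained_after = 3000, dt = 0.05, frame_interval = 0,
                     early_stop = TRUE) {
  if (!is.finite(ci) || ci <= 0) stop("coupling interval must be > 0")
  s2_time <- s1_times[length(s1_times)] + ci
  nx <- model$sheet$nx; ny <- model$sheet$ny
  half_cols <- seq_len(ceiling(nx * s2_fraction)) - 1L
  s2_idx <- as.integer(outer(half_cols, (seq_len(ny) - 1L) * nx, "+"))
  his <- his_stim_nodes(model)
  stims <- rbind(cbind(s1_times, s1_times + 2, 0.8, 0),
                 c(s2_time, s2_time + s2_duration, s2_amplitude, 1))
  stim_nodes <- c(rep(list(his), length(s1_times)), list(s2_idx))
  total <- s2_time + horizon
  res <- run_core(model, resting_state(model), n_steps = ceiling(total / dt),
                  dt = dt, stims = stims, stim_nodes = stim_nodes,
                  frame_interval = frame_interval, frame_t_start = s2_time,
                  early_stop = early_stop)
  run <- as_sim_run(model, res, dt, label = "s1s2")
  run$s2_time <- s2_time
  run$ci <- ci
  run$sustained <- any(run$sheet_acts$time > s2_time + sustained_after)
  run
}

#' Scan the S2 coupling interval for sustained reentry
#'
#' @param model a [build_coupled_model()] result.
#' @param ci_grid coupling intervals to try (ms), in order.
#' @param ... passed to [run_s1s2()].
#' @return The first sustained `sim_run`, or the last attempted run (with
#'   `$sustained = FALSE`) if none sustains. The scanned CIs and outcomes are
#'   attached as `$ci_scan`.
#' @export
scan_vulnerable_window <- function(model, ci_grid = seq(120, 220, by = 10), ...) {
  outcomes <- logical(0)
  run <- NULL
  for (ci in ci_grid) {
    run <- run_s1s2(model, ci = ci, ...)
    outcomes <- c(outcomes, run$sustained)
    if (run$sustained) break
  }
  run$ci_scan <- data.frame(ci = ci_grid[seq_along(outcomes)], sustained = outcomes)
  run
}
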