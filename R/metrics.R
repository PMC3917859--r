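# Quantitative reentry measures: mean firing rate, phase singularities /
# wavebreak incidence, and junctional conduction classification.

#' Activation-detection configuration
#' @param detect_threshold upward-crossing threshold (mV).
#' @param blanking refractory lockout after an accepted activation (ms, > 0).
#' @param ap_start_max the trace must have been below this level (mV) since
#'   the previous accepted activation for a crossing to count as an AP; must
#'   be below `detect_threshold`.
#' @param counting_interval MFR counting interval (ms).
#' @return Object of class `activation_config`.
#' @export
activation_config <- function(detect_threshold = -20, blanking = 50,
                              ap_start_max = -60, counting_interval = 3000) {
  stopifnot(blanking > 0, ap_start_max < detect_threshold,
            counting_interval > 0)
  structure(list(detect_threshold = detect_threshold, blanking = blanking,
                 ap_start_max = ap_start_max,
                 counting_interval = counting_interval),
            class = "activation_config")
}

#' Phase-singularity detection configuration
#' @param iso_threshold voltage isoline level (mV).
#' @param slice_interval temporal interval between the two frames (ms, > 0).
#' @param dedupe_radius merge radius for duplicate intersections (grid cells).
#' @return Object of class `ps_config`.
#' @export
ps_config <- function(iso_threshold = -40, slice_interval = 8,
                      dedupe_radius = 2) {
  stopifnot(slice_interval > 0, dedupe_radius >= 0)
  structure(list(iso_threshold = iso_threshold,
                 slice_interval = slice_interval,
                 dedupe_radius = dedupe_radius),
            class = "ps_config")
}

#' Junction conduction-classification rule
#' @param retrograde_window ms within which the terminal must follow the
#'   coupled-myocyte majority (default 8).
#' @param anterograde_window ms within which the myocyte majority must follow
#'   the terminal (default 16).
#' @param majority_fraction strict majority fraction (> 0.5).
#' @return Object of class `junction_rule`.
#' @export
junction_rule <- function(retrograde_window = 8, anterograde_window = 16,
                          majority_fraction = 0.5) {
  stopifnot(retrograde_window > 0, anterograde_window > 0,
            majority_fraction >= 0.5, majority_fraction < 1)
  structure(list(retrograde_window = retrograde_window,
                 anterograde_window = anterograde_window,
                 majority_fraction = majority_fraction),
            class = "junction_rule")
}

#' Detect activations in a voltage trace
#'
#' Upward crossings of the detection threshold, each at least `blanking` ms
#' after the previous accepted activation and each preceded by the trace
#' having dropped below `ap_start_max` since the previous accepted one (a
#' crossing that "starts" from a partially repolarized level is not an AP).
#' Blanking applies to accepted activations only.
#'
#' @param v voltage samples (mV).
#' @param time sample times (ms), uniform, interval <= 2 ms.
#' @param cfg an [activation_config()].
#' @return Numeric vector of activation times (ms).
#' @export
detect_activations <- function(v, time, cfg = activation_config()) {
  if (length(v) == 0L) stop("empty trace")
  if (length(v) != length(time)) stop("v and time lengths differ")
  if (length(time) > 1L && max(diff(time)) > 2 + 1e-9)
    stop("sampling interval must be <= 2 ms")
  th <- cfg$detect_threshold
  cross <- which(v[-length(v)] < th & v[-1L] >= th) + 1L
  acts <- numeric(0)
  last_t <- -Inf
  last_i <- 1L
  was_below <- v[1L] <= cfg$ap_start_max
  for (ci in cross) {
    if (!was_below)
      was_below <- any(v[last_i:ci] <= cfg$ap_start_max)
    if (was_below && time[ci] - last_t >= cfg$blanking) {
      acts <- c(acts, time[ci])
      last_t <- time[ci]
      last_i <- ci
      was_below <- FALSE
    }
  }
  acts
}

#' Mean firing rate
#' @param activations activation times (ms); only their count matters.
#' @param counting_interval counting interval (ms, > 0).
#' @return Rate in Hz.
#' @export
mean_firing_rate <- function(activations, counting_interval = 3000) {
  if (!is.finite(counting_interval) || counting_interval <= 0)
    stop("counting_interval must be > 0")
  length(activations) / (counting_interval / 1000)
}

# Marching-squares isolines of a frame at `level`, as a segment matrix
# (x1, y1, x2, y2) in 0-based grid coordinates.
iso_segments <- function(frame, level) {
  nx <- nrow(frame); ny <- ncol(frame)
  cl <- grDevices::contourLines(x = 0:(nx - 1), y = 0:(ny - 1), z = frame,
                                levels = level)
  if (length(cl) == 0L) return(matrix(numeric(0), 0, 4))
  do.call(rbind, lapply(cl, function(ln) {
    n <- length(ln$x)
    if (n < 2L) return(matrix(numeric(0), 0, 4))
    cbind(ln$x[-n], ln$y[-n], ln$x[-1L], ln$y[-1L])
  }))
}

# All intersection points between two segment sets (each m x 4); grid-bucketed
# exact pairwise test in compiled code.
segment_intersections <- function(A, B) {
  if (nrow(A) == 0L || nrow(B) == 0L) return(matrix(numeric(0), 0, 2))
  cpp_segment_intersections(A, B)
}

#' Detect phase singularities between two voltage frames
#'
#' 2D reduction of the isosurface-intersection filament method: the
#' marching-squares isolines of both frames at the iso threshold are
#' intersected; where the isoline at t crosses the isoline at t + slice the
#' temporal derivative of the iso level is zero — a phase singularity.
#' Intersections closer than `dedupe_radius` grid cells are merged.
#'
#' @param frame_t,frame_t_plus voltage matrices (mV) on the same grid,
#'   separated in time by `cfg$slice_interval`.
#' @param cfg a [ps_config()].
#' @return Matrix with columns `x`, `y` (0-based grid coordinates), one row
#'   per phase singularity.
#' @export
detect_phase_singularities <- function(frame_t, frame_t_plus,
                                       cfg = ps_config()) {
  if (!all(dim(frame_t) == dim(frame_t_plus)))
    stop("frames must share the grid")
  A <- iso_segments(frame_t, cfg$iso_threshold)
  B <- iso_segments(frame_t_plus, cfg$iso_threshold)
  pts <- segment_intersections(A, B)
  if (nrow(pts) <= 1L || cfg$dedupe_radius <= 0) {
    colnames(pts) <- c("x", "y")
    return(pts)
  }
  keep <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    if (nrow(keep) == 0L ||
        min((keep[, 1] - p[1])^2 + (keep[, 2] - p[2])^2) > cfg$dedupe_radius^2)
      keep <- rbind(keep, p)
  }
  dimnames(keep) <- list(NULL, c("x", "y"))
  keep
}

#' Per-frame phase-singularity counts for a recorded run
#'
#' Pairs frames separated by the slice interval and counts singularities in
#' each pair.
#'
#' @param run a `sim_run` recorded with a frame interval dividing
#'   `cfg$slice_interval`.
#' @param cfg a [ps_config()].
#' @return data.frame with `time` (ms, first frame of each pair) and `n_ps`.
#' @export
ps_counts_per_frame <- function(run, cfg = ps_config()) {
  if (is.null(run$frames) || length(run$frame_times) < 2L)
    stop("run carries no frame series")
  dt_f <- run$frame_times[2] - run$frame_times[1]
  stride <- round(cfg$slice_interval / dt_f)
  if (stride < 1 || abs(stride * dt_f - cfg$slice_interval) > 1e-6)
    stop("frame interval does not divide the slice interval")
  nx <- run$model$sheet$nx; ny <- run$model$sheet$ny
  n <- length(run$frame_times)
  idx <- seq(1L, n - stride, by = stride)
  counts <- vapply(idx, function(i) {
    f1 <- matrix(run$frames[, i], nx, ny)
    f2 <- matrix(run$frames[, i + stride], nx, ny)
    nrow(detect_phase_singularities(f1, f2, cfg))
  }, numeric(1))
  data.frame(time = run$frame_times[idx], n_ps = counts)
}

#' Wavebreak incidence
#'
#' Time-averaged phase-singularity count normalized by surface area and by
#' the number of excitation cycles (MFR x duration):
#' `WBI = mean(ps_counts) / (area * mfr * duration)`.
#'
#' @param ps_counts per-frame PS counts.
#' @param area surface area (cm^2, > 0).
#' @param mfr mean firing rate (Hz); must be > 0 if any PS were seen.
#' @param duration reentry duration (s, > 0).
#' @return WBI in PS / (cm^2 * cycle).
#' @export
wavebreak_incidence <- function(ps_counts, area, mfr, duration) {
  if (!is.finite(area) || area <= 0) stop("area must be positive")
  if (!is.finite(duration) || duration <= 0) stop("duration must be positive")
  if (length(ps_counts) == 0L || all(ps_counts == 0)) return(0)
  if (!is.finite(mfr) || mfr <= 0) stop("mfr must be > 0 when PS are present")
  mean(ps_counts) / (area * mfr * duration)
}

#' Classify one junctional conduction event
#'
#' Direction is set by which side activated first. Anterograde conduction is
#' successful iff a strict majority of the coupled myocytes activate within
#' the anterograde window after the terminal; retrograde conduction iff the
#' terminal activates within the retrograde window after the time at which
#' the myocyte majority was reached.
#'
#' @param event list with `terminal_time` (ms or NA), `myo_times` (numeric,
#'   NA for myocytes that never activated) and `k` (junction size).
#' @param rule a [junction_rule()].
#' @return List with `direction` (`"anterograde"`/`"retrograde"`) and
#'   `success` (logical).
#' @export
classify_pmj_event <- function(event, rule = junction_rule()) {
  if (!is.list(event) || is.null(event$myo_times) || is.null(event$k))
    stop("malformed junction event")
  t_term <- event$terminal_time %||% NA_real_
  myo <- event$myo_times
  k <- event$k
  if (length(myo) != k) stop("malformed junction event: myo_times length != k")
  if (is.na(t_term) && all(is.na(myo)))
    stop("malformed junction event: no activation on either side")
  myo_sorted <- sort(myo[!is.na(myo)])
  need <- floor(k * rule$majority_fraction) + 1L   # strict majority count

  anterograde <- !is.na(t_term) &&
    (length(myo_sorted) == 0L || t_term <= myo_sorted[1])
  if (anterograde) {
    n_in <- sum(myo_sorted >= t_term &
                  myo_sorted <= t_term + rule$anterograde_window)
    list(direction = "anterograde", success = n_in >= need)
  } else {
    if (length(myo_sorted) < need)
      return(list(direction = "retrograde", success = FALSE))
    t_maj <- myo_sorted[need]
    ok <- !is.na(t_term) && t_term <= t_maj + rule$retrograde_window
    list(direction = "retrograde", success = isTRUE(ok))
  }
}

#' Build the junction event log for a run
#'
#' Groups each PMJ's terminal and coupled-myocyte activations into episodes
#' (separated by quiet gaps) and classifies every episode with
#' [classify_pmj_event()]. Every episode maps to exactly one outcome.
#'
#' @param run a `sim_run`.
#' @param rule a [junction_rule()].
#' @param gap_ms quiet gap separating episodes (ms); defaults to the 50 ms
#'   blanking interval.
#' @param t_min ignore activations before this time (ms), e.g. the S2 time.
#' @return data.frame: `pmj_id`, `direction`, `t_terminal_ms`,
#'   `t_myo_mean_ms`, `outcome` (`"success"`/`"failure"`).
#' @export
build_pmj_events <- function(run, rule = junction_rule(), gap_ms = 50,
                             t_min = -Inf) {
  model <- run$model
  n_pmj <- nrow(model$pmjs)
  sheet_by_node <- split(run$sheet_acts$time, run$sheet_acts$node)
  cable_by_node <- split(run$cable_acts$time, run$cable_acts$node)
  get_times <- function(tbl, nd) {
    ts <- tbl[[as.character(nd)]]
    if (is.null(ts)) numeric(0) else sort(ts[ts >= t_min])
  }
  rows <- list()
  for (q in seq_len(n_pmj)) {
    tnode <- model$pmjs$terminal_id[q]
    myo_nodes <- model$coupled[[q]]
    k <- length(myo_nodes)
    t_term_all <- get_times(cable_by_node, tnode)
    myo_all <- lapply(myo_nodes, function(nd) get_times(sheet_by_node, nd))
    ev_t <- c(t_term_all, unlist(myo_all))
    if (length(ev_t) == 0L) next
    ev_t <- sort(ev_t)
    brk <- c(0, which(diff(ev_t) > gap_ms), length(ev_t))
    for (b in seq_len(length(brk) - 1L)) {
      lo <- ev_t[brk[b] + 1L]; hi <- ev_t[brk[b + 1L]]
      tt <- t_term_all[t_term_all >= lo & t_term_all <= hi]
      t_term <- if (length(tt)) tt[1] else NA_real_
      myo_times <- vapply(myo_all, function(ts) {
        x <- ts[ts >= lo & ts <= hi]
        if (length(x)) x[1] else NA_real_
      }, numeric(1))
      cls <- classify_pmj_event(list(terminal_time = t_term,
                                     myo_times = myo_times, k = k), rule)
      rows[[length(rows) + 1L]] <- data.frame(
        pmj_id = q, direction = cls$direction,
        t_terminal_ms = t_term,
        t_myo_mean_ms = if (all(is.na(myo_times))) NA_real_
                        else mean(myo_times, na.rm = TRUE),
        outcome = if (cls$success) "success" else "failure")
    }
  }
  if (length(rows) == 0L)
    return(data.frame(pmj_id = integer(0), direction = character(0),
                      t_terminal_ms = numeric(0), t_myo_mean_ms = numeric(0),
                      outcome = character(0)))
  do.call(rbind, rows)
}

#' Junctional success ratios per direction
#'
#' @param events event log from [build_pmj_events()], or a data.frame with
#'   `direction` and `outcome` columns.
#' @return data.frame: `direction`, `n_success`, `n_failure`, `ratio`
#'   (`NA` when a direction has no events — missing, not 0).
#' @export
junction_success_ratio <- function(events) {
  out <- data.frame(direction = c("anterograde", "retrograde"),
                    n_success = 0L, n_failure = 0L, ratio = NA_real_)
  for (i in 1:2) {
    d <- out$direction[i]
    n_s <- sum(events$direction == d & events$outcome == "success")
    n_f <- sum(events$direction == d & events$outcome == "failure")
    out$n_success[i] <- n_s
    out$n_failure[i] <- n_f
    out$ratio[i] <- if (n_s + n_f > 0) n_s / (n_s + n_f) else NA_real_
  }
  out
}

#' Full metrics report for a reentry run
#'
#' Mean firing rates per population (over the counting interval ending at the
#' run end), per-frame phase-singularity counts, wavebreak incidence and
#' junctional conduction tallies.
#'
#' @param run a `sim_run` with frames recorded (for WBI) and activations.
#' @param acfg an [activation_config()].
#' @param pscfg a [ps_config()].
#' @param rule a [junction_rule()].
#' @param t_start start of the analysis window (ms); defaults to
#'   `t_end - counting_interval`.
#' @return Object of class `metrics_report`.
#' @export
compute_metrics <- function(run, acfg = activation_config(),
                            pscfg = ps_config(), rule = junction_rule(),
                            t_start = NULL) {
  t_end <- run$t_end
  if (is.null(t_start)) t_start <- max(0, t_end - acfg$counting_interval)
  interval <- t_end - t_start
  nsheet <- run$model$sheet$nx * run$model$sheet$ny
  ncab <- nrow(run$model$network$nodes)

  sa <- run$sheet_acts[run$sheet_acts$time >= t_start, ]
  ca <- run$cable_acts[run$cable_acts$time >= t_start, ]
  mfr_sheet <- tabulate(sa$node, nbins = nsheet) / (interval / 1000)
  mfr_cable <- tabulate(ca$node, nbins = ncab) / (interval / 1000)

  ps <- if (!is.null(run$frames) && length(run$frame_times) > 1L) {
    pc <- ps_counts_per_frame(run, pscfg)
    pc[pc$time >= t_start, ]
  } else data.frame(time = numeric(0), n_ps = numeric(0))

  mfr_tissue_mean <- mean(mfr_sheet)
  wbi <- if (nrow(ps) > 0 && any(ps$n_ps > 0) && mfr_tissue_mean > 0)
    wavebreak_incidence(ps$n_ps, run$model$sheet$area_cm2,
                        mfr_tissue_mean, interval / 1000)
  else 0

  events <- build_pmj_events(run, rule, t_min = t_start)
  ratios <- junction_success_ratio(events)

  structure(list(
    mfr_tissue = mfr_sheet, mfr_purkinje = mfr_cable,
    mean_mfr_tissue = mfr_tissue_mean,
    mean_mfr_purkinje = mean(mfr_cable),
    ps = ps, wbi = wbi,
    events = events, ratios = ratios,
    window = c(t_start = t_start, t_end = t_end),
    ps_aggregation = "time-averaged per-frame PS count",
    sustained = run$sustained %||% NA), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report [%.0f-%.0f ms]\n", x$window[1], x$window[2]))
  cat(sprintf("  MFR: tissue %.2f Hz, Purkinje %.2f Hz\n",
              x$mean_mfr_tissue, x$mean_mfr_purkinje))
  cat(sprintf("  WBI: %.4g PS/(cm^2 cycle) (%s)\n", x$wbi, x$ps_aggregation))
  a <- x$ratios[x$ratios$direction == "anterograde", ]
  r <- x$ratios[x$ratios$direction == "retrograde", ]
  cat(sprintf("  junctions: anterograde %d/%d (ratio %.3g), retrograde %d/%d (ratio %.3g)\n",
              a$n_success, a$n_success + a$n_failure, a$ratio,
              r$n_success, r$n_success + r$n_failure, r$ratio))
  invisible(x)
}
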