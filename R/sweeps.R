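# End-to-end experiment drivers: PMJ-density, junctional-resistance and
# junction-size sweeps over reentry runs, with tidy tabular output and full
# provenance (config hash + seed per row).

#' Sweep specification
#'
#' @param variable one of `"min_distance"` (PMJ density), `"r_pmj"`
#'   (junctional resistance) or `"k_coupled"` (junction size).
#' @param values non-empty grid of values for `variable`.
#' @param seeds replicate seeds (>= 1); each seed regrows the tree and
#'   replaces the PMJs, so replicates vary the geometry.
#' @param base named list of fixed parameters overriding the defaults:
#'   `r_pmj`, `loading_factor`, `k_coupled`, `min_distance`, `semi_axes`,
#'   `target_edge`, `n_seeds_tree`, `iterations`, `sheet_nx`, `sheet_ny`,
#'   `sheet_dx`, `diffusivity`, `d_cable`, `ci_grid`, `s2_amplitude`,
#'   `horizon`.
#' @param horizon time simulated after S2 (ms).
#' @return Object of class `sweep_spec`.
#' @export
sweep_spec <- function(variable = c("min_distance", "r_pmj", "k_coupled"),
                       values, seeds = 1:3, base = list(), horizon = 3200) {
  variable <- match.arg(variable)
  if (length(values) == 0L) stop("value grid must be non-empty")
  if (length(seeds) < 1L) stop("at least one replicate seed is required")
  defaults <- list(
    r_pmj = 20, loading_factor = 20, k_coupled = 6L, min_distance = 4,
    semi_axes = c(20, 20, 20), target_edge = 2, n_seeds_tree = 6L,
    iterations = 6L, sheet_nx = 256L, sheet_ny = 256L, sheet_dx = 0.25,
    diffusivity = 0.05, d_cable = 1.4,
    ci_grid = seq(120, 220, by = 10), s2_amplitude = 3)
  base <- utils::modifyList(defaults, base)
  structure(list(variable = variable, values = values,
                 seeds = as.integer(seeds), base = base, horizon = horizon),
            class = "sweep_spec")
}

# Seed points for tree growth: a ring near the apex of the dome.
apex_seed_points <- function(semi_axes, n_seeds) {
  th <- pi / 8
  phi <- 2 * pi * (seq_len(n_seeds) - 1L) / n_seeds
  cbind(semi_axes[1] * sin(th) * cos(phi),
        semi_axes[2] * sin(th) * sin(phi),
        semi_axes[3] * cos(th))
}

# Build geometry + model for one sweep condition.
build_condition <- function(spec, value, seed) {
  p <- spec$base
  p[[spec$variable]] <- value
  surface <- make_hemiellipsoid_surface(p$semi_axes, p$target_edge, seed = 1L)
  rule <- growth_rule(iterations = p$iterations, rng_seed = seed)
  network <- grow_network(surface, apex_seed_points(p$semi_axes, p$n_seeds_tree),
                          rule)
  pmjset <- place_pmjs(network, min_distance = p$min_distance,
                       rng_seed = seed, r_pmj = p$r_pmj,
                       loading_factor = p$loading_factor)
  coupling <- pmj_coupling_params(r_pmj = p$r_pmj,
                                  loading_factor = p$loading_factor,
                                  k_coupled = p$k_coupled)
  sheet <- tissue_sheet(p$sheet_nx, p$sheet_ny, dx = p$sheet_dx,
                        diffusivity = p$diffusivity)
  model <- build_coupled_model(network, pmjset, sheet, coupling = coupling,
                               d_cable = p$d_cable)
  list(model = model, params = p, n_pmjs = nrow(pmjset$pmjs))
}

run_sweep <- function(spec, frame_interval = 8, verbose = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  chash <- config_hash(unclass(spec))
  rows <- list()
  logs <- list()
  for (value in spec$values) {
    for (seed in spec$seeds) {
      cond <- build_condition(spec, value, seed)
      t0 <- proc.time()[["elapsed"]]
      run <- scan_vulnerable_window(cond$model, ci_grid = spec$base$ci_grid,
                                    horizon = spec$horizon,
                                    s2_amplitude = spec$base$s2_amplitude,
                                    frame_interval = frame_interval)
      mr <- compute_metrics(run)
      elapsed <- proc.time()[["elapsed"]] - t0
      a <- mr$ratios[mr$ratios$direction == "anterograde", ]
      r <- mr$ratios[mr$ratios$direction == "retrograde", ]
      rows[[length(rows) + 1L]] <- data.frame(
        condition = value, seed = seed, sustained = isTRUE(run$sustained),
        ci = run$ci,
        mean_mfr_purkinje = mr$mean_mfr_purkinje,
        mean_mfr_tissue = mr$mean_mfr_tissue,
        wbi = mr$wbi,
        ante_success = a$n_success, ante_fail = a$n_failure,
        retro_success = r$n_success, retro_fail = r$n_failure,
        ante_ratio = a$ratio, retro_ratio = r$ratio,
        n_pmjs = cond$n_pmjs,
        config_hash = chash,
        run_id = config_hash(list(chash, value, seed)))
      logs[[length(logs) + 1L]] <- list(condition = value, seed = seed,
                                        events = mr$events,
                                        elapsed_s = elapsed)
      if (verbose)
        message(sprintf("%s = %g, seed %d: sustained=%s ante=%.3g retro=%.3g (%.0f s)",
                        spec$variable, value, seed, isTRUE(run$sustained),
                        a$ratio, r$ratio, elapsed))
    }
  }
  structure(list(spec = spec, table = do.call(rbind, rows), logs = logs,
                 config_hash = chash), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result over %s (%d conditions x %d seeds)\n",
              x$spec$variable, length(x$spec$values), length(x$spec$seeds)))
  print(x$table[, c("condition", "seed", "sustained", "n_pmjs",
                    "mean_mfr_purkinje", "mean_mfr_tissue", "wbi",
                    "ante_ratio", "retro_ratio")])
  invisible(x)
}

#' PMJ-density sweep
#'
#' Varies the minimum distance between PMJ sites (hence PMJ density) at
#' fixed junctional resistance 20 MOhm and loading factor 20, inducing
#' reentry at each condition and reporting the reentry metrics.
#'
#' @param spec a [sweep_spec()] with `variable = "min_distance"`; defaults to
#'   seven density values.
#' @param ... passed to the sweep engine (e.g. `verbose = TRUE`).
#' @return A `sweep_result`; `$table` is the tidy per-run data.frame.
#' @export
run_density_sweep <- function(spec = sweep_spec("min_distance",
                                                values = c(8, 6, 5, 4, 3, 2.5, 2)),
                              ...) {
  if (spec$variable != "min_distance") stop("spec$variable must be min_distance")
  run_sweep(spec, ...)
}

#' Junctional-resistance sweep
#'
#' Varies the PMJ resistance over 10-25 MOhm at fixed loading factor 20.
#'
#' @param spec a [sweep_spec()] with `variable = "r_pmj"`.
#' @param ... passed to the sweep engine.
#' @return A `sweep_result`.
#' @export
run_resistance_sweep <- function(spec = sweep_spec("r_pmj",
                                                   values = c(10, 15, 20, 25)),
                                 ...) {
  if (spec$variable != "r_pmj") stop("spec$variable must be r_pmj")
  if (spec$base$loading_factor != 20)
    stop("resistance sweep fixes the loading factor at 20")
  run_sweep(spec, ...)
}

#' Junction-size sweep
#'
#' Varies the number of coupled myocytes per PMJ at fixed resistance 20 MOhm.
#'
#' @param spec a [sweep_spec()] with `variable = "k_coupled"`.
#' @param ... passed to the sweep engine.
#' @return A `sweep_result`.
#' @export
run_size_sweep <- function(spec = sweep_spec("k_coupled", values = c(3L, 6L, 12L)),
                           ...) {
  if (spec$variable != "k_coupled") stop("spec$variable must be k_coupled")
  if (spec$base$r_pmj != 20) stop("size sweep fixes the PMJ resistance at 20 MOhm")
  run_sweep(spec, ...)
}

#' Write a sweep result as tidy CSV + YAML manifest
#'
#' @param result a `sweep_result`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_sweep_result <- function(result, dir) {
  stopifnot(inherits(result, "sweep_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(result$table, file.path(dir, "sweep.csv"), row.names = FALSE)
  yaml::write_yaml(list(variable = result$spec$variable,
                        values = result$spec$values,
                        seeds = result$spec$seeds,
                        base = result$spec$base,
                        config_hash = result$config_hash),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a sweep specification from a YAML config file
#'
#' @param path YAML file with fields `variable`, `values`, `seeds`, and
#'   optionally `base` and `horizon`.
#' @return A [sweep_spec()].
#' @export
read_sweep_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  sweep_spec(variable = cfg$variable, values = unlist(cfg$values),
             seeds = unlist(cfg$seeds %||% 1:3),
             base = cfg$base %||% list(),
             horizon = cfg$horizon %||% 3200)
}
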