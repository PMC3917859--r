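# Coupled monodomain sheet / Purkinje cable simulator.

# sheet-only model: a trivial far-away 2-node cable and no PMJs
sheet_only_model <- function(nx = 96, ny = 48, dx = 0.25, D = 0.05) {
  net <- structure(list(
    nodes = rbind(c(0, 0, 0), c(0.5, 0, 0)),
    on_surface = c(TRUE, TRUE), grown = c(FALSE, TRUE),
    edges = data.frame(n1 = 1L, n2 = 2L, length_mm = 0.5),
    roots = 1L, terminals = 2L, rule = NULL), class = "purkinje_network")
  pmj <- structure(list(pmjs = data.frame(terminal_id = integer(0),
                                          r_pmj = numeric(0),
                                          loading_factor = numeric(0)),
                        coupled = list(), min_distance = NA_real_,
                        rng_seed = NA_integer_,
                        insertion_depth_fraction = 0.2), class = "pmj_set")
  build_coupled_model(net, pmj, tissue_sheet(nx, ny, dx, D))
}

test_that("the quiescent state is an exact fixed point of one step", {
  model <- sheet_only_model(32, 32)
  st <- resting_state(model)
  st2 <- step_coupled_system(model, st, dt = 0.05)
  expect_lt(max(abs(st2$u_s - st$u_s)), 1e-12)
  expect_lt(max(abs(st2$h_s - st$h_s)), 1e-12)
  expect_lt(max(abs(st2$u_c - st$u_c)), 1e-12)
})

test_that("time steps violating the stability bound are rejected", {
  model <- sheet_only_model(32, 32)
  st <- resting_state(model)
  expect_error(step_coupled_system(model, st, dt = 0.5), "stability")
})

test_that("planar wave speed is constant along propagation", {
  model <- sheet_only_model(96, 48)
  nx <- 96; ny <- 48
  idx <- as.integer(outer(0:1, (seq_len(ny) - 1L) * nx, "+"))
  res <- pmjsim:::run_core(model, resting_state(model),
                           n_steps = 100 / 0.05, dt = 0.05,
                           stims = matrix(c(5, 7, 0.8, 1), 1, 4),
                           stim_nodes = list(idx))
  acts <- data.frame(node = res$act_s_node, time = res$act_s_time)
  col <- ((acts$node - 1L) %/% nx)  # unused; columns here index x
  xcol <- (acts$node - 1L) %% nx
  at <- tapply(acts$time, xcol, median)
  x <- as.numeric(names(at))
  # mid-domain local speeds
  mid <- x >= 24 & x <= 72
  tmid <- at[mid]; xmid <- x[mid]
  cv_local <- 0.25 * diff(xmid) / diff(tmid)   # mm/ms
  expect_lt(max(abs(cv_local - mean(cv_local))) / mean(cv_local), 0.05)
})

test_that("halving dt changes conduction times by less than 1 percent", {
  rig <- build_delay_rig()
  r1 <- run_delay_rig(rig, "anterograde", dt = 0.05)
  r2 <- run_delay_rig(rig, "anterograde", dt = 0.025)
  t1 <- r1$cable_acts$time[match(1:41, r1$cable_acts$node)]
  t2 <- r2$cable_acts$time[match(1:41, r2$cable_acts$node)]
  # propagation latency along the distal cable (the marginal ignition time at
  # the stimulus site shifts all nodes equally and cancels in every delay)
  lat1 <- t1[41] - t1[10]
  lat2 <- t2[41] - t2[10]
  expect_lt(abs(lat1 - lat2) / lat2, 0.01)
  d1 <- measure_pmj_delay(r1, 1, "anterograde")
  d2 <- measure_pmj_delay(r2, 1, "anterograde")
  expect_lt(abs(d1 - d2) / d2, 0.05)
})

test_that("cable conduction is uniform: terminal time follows L / CV", {
  # unbranched, unloaded cable (no junction): terminal activation predicted
  # by the conduction velocity fitted mid-cable
  n <- 41L
  net <- structure(list(
    nodes = cbind(seq(0, 20, length.out = n), 0, 0),
    on_surface = rep(TRUE, n), grown = c(FALSE, rep(TRUE, n - 1L)),
    edges = data.frame(n1 = seq_len(n - 1L), n2 = 2:n,
                       length_mm = rep(0.5, n - 1L)),
    roots = 1L, terminals = n, rule = NULL), class = "purkinje_network")
  pmj <- structure(list(pmjs = data.frame(terminal_id = integer(0),
                                          r_pmj = numeric(0),
                                          loading_factor = numeric(0)),
                        coupled = list(), min_distance = NA_real_,
                        rng_seed = NA_integer_,
                        insertion_depth_fraction = 0.2), class = "pmj_set")
  model <- build_coupled_model(net, pmj, tissue_sheet(32, 32, 0.25, 0.05))
  res <- pmjsim:::run_core(model, resting_state(model), n_steps = 100 / 0.05,
                           dt = 0.05,
                           stims = matrix(c(5, 6, 0.8, 0), 1, 4),
                           stim_nodes = list(0L))
  tt <- res$act_c_time[match(seq_len(n), res$act_c_node)]
  x <- seq(0, 20, length.out = n)
  mid <- 10:32
  fit <- lm(t ~ x, data = data.frame(t = tt[mid], x = x[mid]))
  cv <- 1 / coef(fit)[2]
  # terminal activation predicted by steady conduction at the fitted CV
  # (launch transient near the paced end excluded by the mid-cable fit)
  t_pred <- unname(predict(fit, data.frame(x = 20)))
  t_travel <- (20 - x[mid][1]) / cv
  expect_lt(abs(tt[n] - t_pred) / t_travel, 0.1)
  expect_gt(cv, 1)   # Purkinje-like conduction velocity (> 1 mm/ms)
})

test_that("sinus pacing through PMJs activates every sheet node once", {
  model <- fix_model_small()
  run <- run_sinus(model, horizon = 300, check_capture = TRUE)
  cnt <- tabulate(run$sheet_acts$node, model$sheet$nx * model$sheet$ny)
  expect_true(all(cnt == 1L))
  # all Purkinje nodes activate exactly once too
  ccnt <- tabulate(run$cable_acts$node, nrow(model$network$nodes))
  expect_true(all(ccnt == 1L))
})

test_that("without PMJs the sheet never activates under His pacing", {
  model <- sheet_only_model(48, 48)
  run <- run_sinus(model, horizon = 200)
  expect_identical(nrow(run$sheet_acts), 0L)
  # but the cable itself does activate
  expect_gt(nrow(run$cable_acts), 0L)
})

test_that("sheet activation completes no later with more PMJs", {
  net <- fix_network()
  sheet <- tissue_sheet(96, 96, dx = 0.25, diffusivity = 0.05)
  total_act <- vapply(c(6, 1.5), function(md) {
    pmj <- place_pmjs(net, md, rng_seed = 5)
    model <- build_coupled_model(net, pmj, sheet)
    run <- run_sinus(model, horizon = 300)
    max(run$sheet_acts$time)
  }, numeric(1))
  expect_lte(total_act[2], total_act[1])
})

test_that("S1 alone paces every sheet node exactly twice", {
  model <- fix_model_small()
  run <- run_sinus(model, pace_times = c(10, 510), horizon = 1000)
  cnt <- tabulate(run$sheet_acts$node, model$sheet$nx * model$sheet$ny)
  expect_true(all(cnt == 2L))
})

test_that("reruns with identical configuration are bit-identical", {
  model <- fix_model_small()
  r1 <- run_sinus(model, horizon = 150)
  r2 <- run_sinus(model, horizon = 150)
  expect_identical(r1$sheet_acts, r2$sheet_acts)
  expect_identical(r1$cable_acts, r2$cable_acts)
})

test_that("online activation detection matches the trace-based detector", {
  rig <- build_delay_rig()
  nx <- rig$sheet$nx
  probe_sheet <- rig$coupled[[1]][1:3]
  res <- pmjsim:::run_core(rig, resting_state(rig), n_steps = 200 / 0.05,
                           dt = 0.05,
                           stims = matrix(c(5, 6, 0.8, 0), 1, 4),
                           stim_nodes = list(0L),
                           trace_interval = 1,
                           trace_cable = c(1L, 41L),
                           trace_sheet = probe_sheet)
  run <- pmjsim:::as_sim_run(rig, res, 0.05)
  cfg <- activation_config()
  for (i in seq_along(probe_sheet)) {
    ref <- detect_activations(res$trace_sheet_v[i, ], res$trace_times, cfg)
    got <- run$sheet_acts$time[run$sheet_acts$node == probe_sheet[i]]
    expect_identical(length(ref), length(got))
    if (length(ref)) expect_lt(max(abs(ref - got)), 1.1)
  }
})
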