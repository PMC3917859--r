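# Activation detection, MFR, phase singularities, WBI, junction
# classification.

test_that("activation detector applies threshold, blanking and validity", {
  cfg <- activation_config()
  tt <- seq(0, 400, by = 1)
  # two well-separated APs
  tr <- make_pulse_train(c(50, 250), ap_duration = 80, duration = 400)
  expect_length(detect_activations(tr$v, tr$time, cfg), 2L)
  # two crossings 30 ms apart: blanking keeps only the first
  v <- rep(-85, length(tt))
  v[tt >= 50 & tt < 60] <- 10
  v[tt >= 80 & tt < 90] <- 10
  expect_length(detect_activations(v, tt, cfg), 1L)
  # a dip only to -50 mV between two crossings invalidates the second
  v2 <- rep(-85, length(tt))
  v2[tt >= 50 & tt < 100] <- 10
  v2[tt >= 100 & tt < 150] <- -50
  v2[tt >= 150 & tt < 200] <- 10
  expect_length(detect_activations(v2, tt, cfg), 1L)
  # but a dip below -60 mV revalidates it
  v2[tt >= 100 & tt < 150] <- -70
  expect_length(detect_activations(v2, tt, cfg), 2L)
  expect_error(detect_activations(numeric(0), numeric(0)), "empty")
})

test_that("detector matches a brute-force scan on random pulse trains", {
  cfg <- activation_config()
  withr::with_seed(31, {
    for (i in 1:200) {
      n_ap <- sample(0:24, 1)
      times <- rand_ap_times(n_ap)
      tr <- make_pulse_train(times, ap_duration = 80, duration = 3000, dt = 1)
      got <- detect_activations(tr$v, tr$time, cfg)
      expect_identical(length(got),
                       as.integer(oracle_count_activations(tr$v, tr$time)))
      expect_identical(length(got), as.integer(n_ap))
    }
  })
})

test_that("mean firing rate is count over interval", {
  expect_equal(mean_firing_rate(seq_len(24), 3000), 8)
  expect_equal(mean_firing_rate(numeric(0), 3000), 0)
  expect_error(mean_firing_rate(1:3, 0), "> 0")
})

test_that("MFR is bounded by the blanking limit of 20 Hz", {
  cfg <- activation_config()
  tt <- seq(0, 3000, by = 1)
  # pathological trace oscillating as fast as possible
  v <- ifelse(tt %% 20 < 10, 30, -85)
  acts <- detect_activations(v, tt, cfg)
  expect_lte(mean_firing_rate(acts, 3000), 1000 / cfg$blanking)
})

test_that("plane waves produce no phase singularities", {
  sh <- tissue_sheet(64, 64, dx = 0.25)
  x <- matrix(0:(63), 64, 64)
  f1 <- -85 + 115 * exp(-((x - 20)^2) / 50)
  f2 <- -85 + 115 * exp(-((x - 26)^2) / 50)   # translated copy
  ps <- detect_phase_singularities(f1, f2, ps_config())
  expect_identical(nrow(ps), 0L)
})

test_that("the analytic spiral core is recovered within two cells", {
  sh <- tissue_sheet(96, 96, dx = 0.25)
  fx <- spiral_fixture(core = c(47.3, 46.1))
  f1 <- make_spiral_field(fx, 100, sh)
  f2 <- make_spiral_field(fx, 108, sh)
  ps <- detect_phase_singularities(f1, f2, ps_config())
  expect_identical(nrow(ps), 1L)
  expect_lt(sqrt(sum((ps[1, ] - fx$core)^2)), 2)
})

test_that("mirrored counter-rotating spirals give two symmetric PS", {
  sh <- tissue_sheet(64, 128, dx = 0.25)
  fx <- spiral_fixture(core = c(31.5, 31.5))
  f1a <- make_spiral_field(fx, 40, sh_half <- tissue_sheet(64, 64, 0.25))
  f2a <- make_spiral_field(fx, 48, sh_half)
  # mirror in y: the reflected spiral rotates the opposite way
  f1 <- cbind(f1a, f1a[, 64:1])
  f2 <- cbind(f2a, f2a[, 64:1])
  ps <- detect_phase_singularities(f1, f2, ps_config())
  expect_identical(nrow(ps), 2L)
  mid <- (128 - 1) / 2
  expect_equal(abs(ps[1, "y"] - mid), abs(ps[2, "y"] - mid), tolerance = 1e-6)
  expect_equal(ps[1, "x"], ps[2, "x"], tolerance = 1e-6)
})

test_that("PS detection is invariant under a global voltage offset", {
  sh <- tissue_sheet(96, 96, dx = 0.25)
  fx <- spiral_fixture(core = c(47.3, 46.1))
  f1 <- make_spiral_field(fx, 100, sh)
  f2 <- make_spiral_field(fx, 108, sh)
  ps0 <- detect_phase_singularities(f1, f2, ps_config())
  ps5 <- detect_phase_singularities(f1 + 5, f2 + 5, ps_config())
  expect_equal(dim(ps0), dim(ps5))
  expect_lt(max(abs(ps0 - ps5)), 1)
})

test_that("every detected PS lies near both input isolines", {
  sh <- tissue_sheet(96, 96, dx = 0.25)
  fx <- spiral_fixture(core = c(47.3, 46.1))
  f1 <- make_spiral_field(fx, 100, sh)
  f2 <- make_spiral_field(fx, 108, sh)
  ps <- detect_phase_singularities(f1, f2, ps_config())
  seg_dist <- function(frame, p) {
    segs <- pmjsim:::iso_segments(frame, -40)
    mids <- cbind((segs[, 1] + segs[, 3]) / 2, (segs[, 2] + segs[, 4]) / 2)
    sqrt(min((mids[, 1] - p[1])^2 + (mids[, 2] - p[2])^2))
  }
  for (i in seq_len(nrow(ps))) {
    expect_lt(seg_dist(f1, ps[i, ]), 1)
    expect_lt(seg_dist(f2, ps[i, ]), 1)
  }
})

test_that("WBI follows the normalization arithmetic", {
  # constant 12 PS, 2 cm^2, 8 Hz, 3 s: 12 / (2 * 24) = 0.25
  expect_equal(wavebreak_incidence(rep(12, 100), 2, 8, 3), 0.25)
  expect_identical(wavebreak_incidence(rep(0, 10), 2, 8, 3), 0)
  # doubling the area halves WBI
  w1 <- wavebreak_incidence(c(3, 5, 4), 2, 8, 3)
  w2 <- wavebreak_incidence(c(3, 5, 4), 4, 8, 3)
  expect_equal(w2, w1 / 2)
  expect_error(wavebreak_incidence(1:3, 0, 8, 3), "area")
})

test_that("junction events classify per the majority/window rules", {
  rule <- junction_rule()
  # terminal fires, 4 of 6 myocytes within 16 ms: anterograde success
  ev <- list(terminal_time = 100,
             myo_times = c(104, 106, 108, 112, 130, NA), k = 6)
  cls <- classify_pmj_event(ev, rule)
  expect_identical(cls$direction, "anterograde")
  expect_true(cls$success)
  # exactly 3 of 6: strict majority fails
  ev3 <- list(terminal_time = 100,
              myo_times = c(104, 106, 108, 130, 140, NA), k = 6)
  cls3 <- classify_pmj_event(ev3, rule)
  expect_identical(cls3$direction, "anterograde")
  expect_false(cls3$success)
  # myocytes fire first, terminal follows 6 ms after the majority:
  # retrograde success
  evr <- list(terminal_time = 109,
              myo_times = c(100, 101, 102, 103, NA, NA), k = 6)
  clsr <- classify_pmj_event(evr, rule)
  expect_identical(clsr$direction, "retrograde")
  expect_true(clsr$success)
  # terminal beyond the 8 ms retrograde window: failure
  evf <- list(terminal_time = 115,
              myo_times = c(100, 101, 102, 103, NA, NA), k = 6)
  expect_false(classify_pmj_event(evf, rule)$success)
  # terminal never activates: retrograde failure
  evn <- list(terminal_time = NA,
              myo_times = c(100, 101, 102, 103, 104, 105), k = 6)
  clsn <- classify_pmj_event(evn, rule)
  expect_identical(clsn$direction, "retrograde")
  expect_false(clsn$success)
  expect_error(classify_pmj_event(list(terminal_time = NA,
                                       myo_times = rep(NA_real_, 6), k = 6)),
               "malformed")
})

test_that("classification is exhaustive and exclusive on random events", {
  rule <- junction_rule()
  withr::with_seed(7, {
    for (i in 1:200) {
      k <- sample(c(4, 6, 9), 1)
      myo <- runif(k, 0, 40)
      myo[runif(k) < 0.3] <- NA
      t_term <- if (runif(1) < 0.85) runif(1, 0, 40) else NA_real_
      if (is.na(t_term) && all(is.na(myo))) next
      cls <- classify_pmj_event(list(terminal_time = t_term, myo_times = myo,
                                     k = k), rule)
      expect_true(cls$direction %in% c("anterograde", "retrograde"))
      expect_true(is.logical(cls$success) && length(cls$success) == 1L)
    }
  })
})

test_that("success ratios handle empty tallies as missing", {
  ev <- data.frame(direction = c(rep("anterograde", 40)),
                   outcome = c(rep("success", 30), rep("failure", 10)))
  r <- junction_success_ratio(ev)
  expect_equal(r$ratio[r$direction == "anterograde"], 0.75)
  expect_true(is.na(r$ratio[r$direction == "retrograde"]))
  r0 <- junction_success_ratio(ev[0, ])
  expect_true(all(is.na(r0$ratio)))
})
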