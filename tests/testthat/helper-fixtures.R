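# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small hemisphere surface (r = 10 mm, ~2 mm edges)
fix_sphere <- function() memo("sphere", {
  make_hemiellipsoid_surface(c(10, 10, 10), 2, seed = 42)
})

# finer hemisphere for area / projection checks
fix_sphere_fine <- function() memo("sphere_fine", {
  make_hemiellipsoid_surface(c(10, 10, 10), 1, seed = 42)
})

# a grown network on the small sphere
fix_network <- function() memo("network", {
  grow_network(fix_sphere(), fix_seed_points(),
               growth_rule(iterations = 5, rng_seed = 7))
})

fix_seed_points <- function() {
  th <- pi / 8
  phi <- 2 * pi * (0:3) / 4
  cbind(10 * sin(th) * cos(phi), 10 * sin(th) * sin(phi), 10 * cos(th))
}

# small coupled model for simulator tests: grown net on sphere + 96x96 sheet
fix_model_small <- function() memo("model_small", {
  net <- fix_network()
  pmj <- place_pmjs(net, 3, rng_seed = 5)
  sheet <- tissue_sheet(96, 96, dx = 0.25, diffusivity = 0.05)
  build_coupled_model(net, pmj, sheet)
})

# n_ap AP onset times with gaps >= min_gap, all APs inside the trace:
# constructive (jittered regular spacing), valid by design
rand_ap_times <- function(n_ap, duration = 3000, ap_duration = 80,
                          min_gap = 90) {
  if (n_ap == 0) return(numeric(0))
  budget <- (duration - ap_duration - 20) - (n_ap - 1) * min_gap
  stopifnot(budget >= 0)
  extras <- runif(n_ap, 0, budget / n_ap)
  10 + cumsum(c(extras[1], min_gap + extras[-1]))
}

# independent brute-force activation counter: plain scan over samples with
# the -20 mV / -60 mV / 50 ms rules, written without reference to the
# package's detector
oracle_count_activations <- function(v, time, thresh = -20, lo = -60,
                                     blank = 50) {
  n <- 0L
  armed <- v[1] <= lo
  t_last <- -Inf
  for (i in 2:length(v)) {
    if (v[i] <= lo) armed <- TRUE
    if (v[i - 1] < thresh && v[i] >= thresh && armed &&
        time[i] - t_last >= blank) {
      n <- n + 1L
      t_last <- time[i]
      armed <- FALSE
    }
  }
  n
}
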