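test_that("F-V points are extracted exactly from noiseless traces", {
  prot <- voltage_protocol()
  fv <- c(1.25, 1.22, 1.18, 1.1, 1.0, 0.95, 0.9, 0.87, 0.85, 0.84, 0.83)
  names(fv) <- as.character(prot$voltages)
  tr <- build_fv_trace(fv, prot, f0 = 800, background = 120)
  s <- extract_fv_points(tr, prot, background = 120)
  expect_s3_class(s, "fv_series")
  expect_equal(s$f_norm, unname(fv[as.character(s$voltage_mV)]),
               tolerance = 1e-12)
  # constant fluorescence: f_norm = 1 everywhere
  flat <- build_fv_trace(setNames(rep(1, 11), names(fv)), prot, f0 = 500)
  expect_equal(extract_fv_points(flat, prot)$f_norm, rep(1, 11))
  # truncated trace is a protocol mismatch
  expect_error(extract_fv_points(tr[1:3000, ], prot, background = 120),
               "protocol mismatch")
  expect_error(extract_fv_points(tr[, c("time_ms", "fluorescence")], prot),
               "voltage_mV")
  expect_warning(extract_fv_points(flat, prot, background = 600),
                 "over-subtraction")
})

test_that("Boltzmann fit recovers exact parameters and flags flat series", {
  v <- seq(-180, 120, by = 30)
  f <- 0.75 + (1.2 - 0.75) / (1 + exp((v - (-30)) / 25))
  s <- data.frame(voltage_mV = v, f_norm = f)
  fit <- fit_boltzmann(s)
  expect_true(fit$converged)
  expect_equal(fit$top, 1.2, tolerance = 1e-6)
  expect_equal(fit$bottom, 0.75, tolerance = 1e-6)
  expect_equal(fit$v50, -30, tolerance = 1e-4)
  expect_equal(fit$slope, 25, tolerance = 1e-4)
  expect_equal(fit$dff, 0.45, tolerance = 1e-6)
  # flat series: degenerate, dff ~ 0
  flat <- data.frame(voltage_mV = v, f_norm = rep(1, 11))
  ffit <- fit_boltzmann(flat)
  expect_true(ffit$degenerate)
  expect_equal(ffit$dff, 0)
  expect_error(fit_boltzmann(data.frame(voltage_mV = c(-60, 0, 60),
                                        f_norm = c(1, 0.9, 0.8))),
               "at least 4")
})

test_that("fit-free delta-F/F is plain arithmetic on the extremes", {
  s <- data.frame(voltage_mV = c(-180, -90, 0, 120),
                  f_norm = c(1.1, 1.0, 0.8, 0.6))
  expect_equal(fit_free_dff(s), 0.5)
  flat <- data.frame(voltage_mV = c(-180, -90, 0, 120), f_norm = rep(1, 4))
  expect_equal(fit_free_dff(flat), 0)
  expect_error(fit_free_dff(s[-1, ]), "extreme voltages")
})

test_that("delta-F/F is invariant to detector gain", {
  sim <- simulate_fv_experiment(n_cells = 1, seed = 11)
  tr <- sim$traces[[1]]
  s1 <- extract_fv_points(tr, sim$protocol, background = sim$background)
  tr2 <- tr
  # gain rescales signal and background together
  tr2$fluorescence <- tr2$fluorescence * 3.7
  s2 <- extract_fv_points(tr2, sim$protocol,
                          background = sim$background * 3.7)
  expect_equal(s2$f_norm, s1$f_norm, tolerance = 1e-12)
  expect_equal(fit_boltzmann(s2)$dff, fit_boltzmann(s1)$dff, tolerance = 1e-6)
})

test_that("noiseless generator output round-trips exactly and noisy output within tolerance", {
  # noise off: pipeline reproduces truth to numerical precision
  sim0 <- simulate_fv_experiment(dff = 0.45, n_cells = 1, readout_sd = 0,
                                 photon_rate = 1e6, seed = 5)
  s0 <- extract_fv_points(sim0$traces[[1]], sim0$protocol,
                          background = sim0$background)
  expect_equal(fit_boltzmann(s0)$dff, 0.45, tolerance = 2e-3)
  # zero-quenching truth stays near zero
  simz <- simulate_fv_experiment(dff = 0, n_cells = 1, seed = 6)
  sz <- extract_fv_points(simz$traces[[1]], simz$protocol,
                          background = simz$background)
  expect_lt(abs(fit_boltzmann(sz)$dff), 0.05)
  # no-DPA condition gives a flat relation regardless of requested dff
  simnd <- simulate_fv_experiment(dff = 0.45, dpa = FALSE, n_cells = 1,
                                  seed = 7)
  expect_equal(simnd$truth$dff, 0)
  snd <- extract_fv_points(simnd$traces[[1]], simnd$protocol,
                           background = simnd$background)
  expect_lt(abs(fit_free_dff(snd)), 0.05)
  # realistic shot + readout noise, small batch: estimates land near truth
  sim <- simulate_fv_experiment(dff = 0.45, n_cells = 4, seed = 8)
  dffs <- vapply(sim$traces, function(tr) {
    fit_boltzmann(extract_fv_points(tr, sim$protocol,
                                    background = sim$background))$dff
  }, 0)
  expect_lt(max(abs(dffs - 0.45)), 0.05)
})

test_that("fv generator is seed-deterministic", {
  a <- simulate_fv_experiment(n_cells = 2, seed = 123)
  b <- simulate_fv_experiment(n_cells = 2, seed = 123)
  expect_identical(a, b)
  c <- simulate_fv_experiment(n_cells = 2, seed = 124)
  expect_false(identical(a$traces[[1]]$fluorescence,
                         c$traces[[1]]$fluorescence))
})
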