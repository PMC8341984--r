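test_that("lifetime fit is exact on noiseless decays and flags degenerate input", {
  t <- seq(0, 12.475, by = 0.025)
  h <- decay_histogram(t, 1000 * exp(-t / 4.06))
  fit <- fit_decay(h, fit_range = c(0, 12))
  expect_true(fit$converged)
  expect_equal(fit$tau, 4.06, tolerance = 1e-6)
  expect_equal(fit$offset, 0, tolerance = 1e-3)
  # constant counts: tau runs away; flagged
  hc <- decay_histogram(t, rep(50, length(t)))
  fitc <- fit_decay(hc)
  expect_true(fitc$flagged || !fitc$converged)
  expect_error(fit_decay(decay_histogram(t, rep(0, length(t)))), "all-zero")
  expect_error(fit_decay(h, fit_range = c(12.3, 12.45)), "10 bins")
  expect_error(fit_decay(h, fit_range = c(-1, 5)), "within the histogram")
})

test_that("Poisson TCSPC round trip recovers the lifetime within 1 percent", {
  errs <- vapply(1:5, function(s) {
    h <- simulate_tcspc(data.frame(tau = 2.68, weight = 1),
                        counts_total = 1e6, seed = 300 + s)
    abs(fit_decay(h)$tau - 2.68) / 2.68
  }, 0)
  expect_lt(max(errs), 0.01)
})

test_that("tcspc generator: bracketing, empty histograms, determinism, wrap-around flag", {
  # two equal components fitted mono-exponentially land between the taus
  h2 <- simulate_tcspc(data.frame(tau = c(2, 4), weight = c(0.5, 0.5)),
                       counts_total = 5e5, seed = 9)
  tau_hat <- fit_decay(h2)$tau
  expect_gt(tau_hat, 2)
  expect_lt(tau_hat, 4)
  # zero photons
  h0 <- simulate_tcspc(counts_total = 0, seed = 1)
  expect_true(all(h0$counts == 0))
  # byte-identical for identical seeds
  expect_identical(simulate_tcspc(counts_total = 1e4, seed = 77),
                   simulate_tcspc(counts_total = 1e4, seed = 77))
  expect_warning(simulate_tcspc(data.frame(tau = 40, weight = 1),
                                counts_total = 1e3, seed = 1),
                 "wrap-around")
})

test_that("FRET efficiency reproduces the worked lifetime pairs", {
  expect_equal(round(100 * fret_efficiency(4.06, 3.08)), 24)
  expect_equal(round(100 * fret_efficiency(3.86, 3.28)), 15)
  expect_equal(fret_efficiency(3.5, 3.5), 0)
  # antitone in tau_da
  taus <- seq(1, 4, by = 0.5)
  expect_true(all(diff(fret_efficiency(4.06, taus)) < 0))
  expect_warning(fret_efficiency(3, 3.5), "exceeds")
  expect_error(fret_efficiency(-1, 2), "positive")
})

test_that("dilution plateau recovers single-subunit FRET from the trimer generator", {
  # pure intra-subunit transfer: plateau CI covers the single-pair value
  ser_i <- simulate_trimer_mixture(e_intra = 0.25, e_inter = 0,
                                   n_cells_per_ratio = 40, seed = 20)
  pl_i <- suppressWarnings(dilution_plateau(ser_i, seed = 19))
  expect_lt(pl_i$ci[1], 0.25)
  expect_gt(pl_i$ci[2], 0.25)
  # with inter-subunit transfer present the highest dilution still isolates
  # the single-subunit value to within a few percent
  ser <- simulate_trimer_mixture(e_intra = 0.25, e_inter = 0.08,
                                 n_cells_per_ratio = 40, seed = 21)
  # noise can make neighbouring per-ratio means non-monotone (warning only)
  pl <- suppressWarnings(dilution_plateau(ser, seed = 22))
  expect_lt(abs(pl$plateau - 0.25), 0.03)
  # all lifetimes at the donor-only value: plateau efficiency 0
  flat <- dilution_series(rep(c("1:1", "1:3", "1:7"), each = 5),
                          rep(4.06, 15), donor_only_tau = 4.06)
  expect_equal(dilution_plateau(flat, n_boot = 50, seed = 1)$plateau, 0)
  # two ratios only: error
  two <- dilution_series(rep(c("1:1", "1:3"), each = 5), rep(3, 10), 4.06)
  expect_error(dilution_plateau(two), "at least 3")
})

test_that("trimer generator limits and monotonicity match the assembly model", {
  # all efficiencies zero: every lifetime is the donor lifetime
  ser0 <- simulate_trimer_mixture(e_intra = 0, e_inter = 0, tau_sd = 0,
                                  n_cells_per_ratio = 3, seed = 2)
  expect_true(all(abs(ser0$tau_ns - 4.06) < 1e-12))
  # high dilution limit: apparent efficiency -> e_intra
  tr <- attr(simulate_trimer_mixture(ratios = c("1:0", "1:7", "1:511"),
                                     e_intra = 0.25, e_inter = 0.08,
                                     tau_sd = 0, n_cells_per_ratio = 1,
                                     seed = 3), "truth")
  expect_equal(tr$eff_apparent[3], 0.25, tolerance = 0.005)
  # crowding raises apparent efficiency with labeled fraction
  trc <- attr(simulate_trimer_mixture(ratios = c("1:31", "1:3", "1:0"),
                                      e_intra = 0.2, e_inter = 0,
                                      e_crowding = 0.3, tau_sd = 0,
                                      n_cells_per_ratio = 1, seed = 4),
              "truth")
  expect_true(all(diff(trc$eff_apparent) > 0))
  expect_error(simulate_trimer_mixture(e_intra = 1.2), "\\[0, 1\\)")
})
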