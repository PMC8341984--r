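test_that("pair efficiency follows the sixth-power law", {
  expect_equal(pair_efficiency(47, 47), 0.5)
  expect_equal(pair_efficiency(0, 47), 1)
  expect_equal(pair_efficiency(2 * 47, 47), 1 / 65)
  d <- seq(0, 150, by = 0.5)
  expect_true(all(diff(pair_efficiency(d, 36.5)) < 0))
  expect_error(pair_efficiency(10, 0), "positive")
  expect_error(pair_efficiency(-1, 47), "non-negative")
})

test_that("closed-form tail integral matches adaptive quadrature", {
  expect_equal(quench_integral(0), 2 * pi / (3 * sqrt(3)), tolerance = 1e-12)
  for (a in c(0, 0.05, 0.3, 1, 4, 20)) {
    num <- stats::integrate(function(u) 1 / (1 + u^3), a, Inf,
                            rel.tol = 1e-10)$value
    expect_equal(quench_integral(a), num, tolerance = 1e-8)
  }
  expect_error(quench_integral(-0.1), "non-negative")
})

test_that("unquenched fraction behaves as the planar model predicts", {
  cfp <- cfp_system()
  expect_equal(unquenched_fraction(24, cfp), 0.4387853, tolerance = 1e-6)
  # no acceptors, no quenching
  empty <- donor_acceptor_system("none", r0 = 47, sigma = 0)
  expect_equal(unquenched_fraction(c(0, 10, 50), empty), rep(1, 3))
  # ra = 0 closed form
  expect_equal(unquenched_fraction(0, cfp),
               exp(-cfp$sigma * pi * cfp$r0^2 * 2 * pi / (3 * sqrt(3))),
               tolerance = 1e-12)
  # monotone non-decreasing in ra; outer leaflet always less quenched
  ra <- seq(0, 80, by = 0.5)
  p_in <- unquenched_fraction(ra, cfp, "inner")
  p_out <- unquenched_fraction(ra, cfp, "outer")
  expect_true(all(diff(p_in) > 0))
  expect_true(all(p_in <= p_out))
  expect_error(unquenched_fraction(-1, cfp), "non-negative")
})

test_that("Monte-Carlo oracle agrees with the continuum formula", {
  # reduced replicate count here; the full 1e5-replicate sweep runs in the
  # acceptance suite
  for (sys in list(cfp_system(), yfp_system())) {
    for (ra in c(5, 25)) {
      mc <- mc_quench_oracle(ra, sys, replicates = 2e4, seed = 100 + ra)
      expect_lt(abs(mc$estimate - unquenched_fraction(ra, sys)), 3 * mc$se)
    }
  }
  # sigma = 0: exactly 1 with zero SE
  none <- donor_acceptor_system("none", r0 = 47, sigma = 0)
  mc0 <- mc_quench_oracle(20, none, replicates = 100, seed = 1)
  expect_identical(mc0$estimate, 1)
  expect_identical(mc0$se, 0)
  # far field: essentially no quenching
  far <- mc_quench_oracle(100 * 47, cfp_system(), replicates = 500, seed = 2)
  expect_equal(far$estimate, 1, tolerance = 1e-6)
  expect_warning(mc_quench_oracle(10, cfp_system(), disc_radius = 100,
                                  replicates = 10, seed = 3),
                 "truncation")
})

test_that("quench curve invariants hold and peaks sit on the expected limbs", {
  crv <- quench_curve(cfp_system(), seq(0, 60, by = 0.5))
  expect_true(all(crv$p_inner <= crv$p_outer))
  expect_true(all(crv$dff_norm >= 0 & crv$dff_norm <= 1))
  # humped CFP curve: interior maximum, near-equal flanks at 20 and 28 A
  pk <- peak_distance(crv)
  expect_gt(pk, 0)
  expect_lt(pk, 60)
  f20 <- crv$dff_norm[crv$distance_A == 20]
  f28 <- crv$dff_norm[crv$distance_A == 28]
  expect_lt(abs(f20 - f28), 0.02)
  # YFP curve peaks lower and falls off beyond the peak
  crv_y <- quench_curve(yfp_system(), seq(0, 60, by = 0.5))
  expect_lt(peak_distance(crv_y), pk)
  post <- crv_y$dff_norm[crv_y$distance_A >= 20]
  expect_true(all(diff(post) < 0))
  # no acceptors: identically zero quenching
  none <- donor_acceptor_system("none", r0 = 47, sigma = 0)
  expect_true(all(quench_curve(none, seq(0, 60, 1))$dff_norm == 0))
  expect_error(quench_curve(cfp_system(), c(3, 2, 1)), "increasing")
  expect_error(quench_curve(cfp_system(), numeric(0)), "non-empty")
})

test_that("distance inversion round-trips through the forward model", {
  sys <- cfp_system()
  crv <- quench_curve(sys, seq(0, 80, by = 0.25))
  fwd <- function(x) {
    po <- unquenched_fraction(x, sys, "outer")
    (po - unquenched_fraction(x, sys, "inner")) / po
  }
  # at the maximum: a single peak candidate
  est_pk <- invert_distance(max(crv$dff_norm), crv)
  expect_length(est_pk$candidates, 1)
  expect_equal(est_pk$candidates, peak_distance(crv), tolerance = 0.3)
  # just below the peak: two candidates straddling it, both limbs labelled
  target <- max(crv$dff_norm) - 0.01
  est2 <- invert_distance(target, crv, tolerance = 1e-8)
  expect_length(est2$candidates, 2)
  expect_setequal(est2$branch, c("ascending", "descending"))
  expect_lt(est2$candidates[1], peak_distance(crv))
  expect_gt(est2$candidates[2], peak_distance(crv))
  for (x in est2$candidates) expect_equal(fwd(x), target, tolerance = 1e-6)
  # monotone-descending YFP limb: round trip at 35 A
  sys_y <- yfp_system()
  crv_y <- quench_curve(sys_y, seq(0, 80, by = 0.25))
  fwd_y <- function(x) {
    po <- unquenched_fraction(x, sys_y, "outer")
    (po - unquenched_fraction(x, sys_y, "inner")) / po
  }
  est35 <- invert_distance(fwd_y(35), crv_y, tolerance = 1e-9)
  desc <- est35$candidates[est35$branch == "descending"]
  expect_length(desc, 1)
  expect_equal(desc, 35, tolerance = 0.01)
  # above the maximum: explicit no-solution result, not an error
  none <- invert_distance(max(crv$dff_norm) + 0.05, crv)
  expect_true(none$no_solution)
  expect_length(none$candidates, 0)
  expect_error(invert_distance(-0.1, crv), "non-negative")
  # chromophore offset subtracts a constant from every candidate
  est_off <- invert_distance(target, crv, tolerance = 1e-8,
                             chromophore_offset = 10)
  expect_equal(est_off$candidates, est2$candidates - 10, tolerance = 1e-6)
})

test_that("system constructor validates its invariants", {
  expect_error(donor_acceptor_system("x", r0 = -1), "positive")
  expect_error(donor_acceptor_system("x", r0 = 47, sigma = -1), "non-negative")
  expect_error(donor_acceptor_system("x", r0 = 47, displacement = -5),
               "non-negative")
})
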