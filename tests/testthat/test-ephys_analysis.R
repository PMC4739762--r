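test_that("Hill fits recover noiseless generator parameters to 1%", {
  dr <- make_dose_response(ec50 = 30e-6, nh = 1.8, imax = 1)
  fit <- fit_hill(dr)
  expect_true(fit$converged)
  expect_equal(fit$EC50, 30e-6, tolerance = 0.01)
  expect_equal(fit$nH, 1.8, tolerance = 0.01)
  expect_equal(fit$Imax, 1, tolerance = 0.01)
  # response at c = EC50 is Imax/2 by construction
  at_ec50 <- fit$Imax * fit$EC50^fit$nH / (fit$EC50^fit$nH + fit$EC50^fit$nH)
  expect_equal(at_ec50, fit$Imax / 2)
  expect_error(fit_hill(dose_response(c(1e-6, 1e-5, 1e-4), c(.1, .5, .9))),
               "at least 4")
})

test_that("a 25-fold EC50 shift is recovered from paired synthetic curves", {
  concs <- 10^seq(-7, -2.5, by = 0.5)
  d_hi <- make_dose_response(ec50 = 4e-6, nh = 1.5, concentrations = concs,
                             noise_sd = 0.02, seed = 41)
  d_lo <- make_dose_response(ec50 = 1e-4, nh = 1.5, concentrations = concs,
                             noise_sd = 0.02, seed = 42)
  ratio <- fit_hill(d_lo)$EC50 / fit_hill(d_hi)$EC50
  expect_equal(ratio, 25, tolerance = 0.05)
})

test_that("exponential fits recover tau and flag degenerate traces", {
  tr <- make_trace("decay", list(i0 = 0.1, a = 1, tau = 0.131, duration = 1))
  fit <- fit_exponential(tr)
  expect_true(fit$converged)
  expect_equal(fit$tau, 0.131, tolerance = 1e-4)
  expect_equal(fit$I0, 0.1, tolerance = 1e-4)

  flat <- current_trace(seq(0, 1, by = 1e-3), rep(2, 1001))
  ffit <- fit_exponential(flat)
  expect_false(ffit$converged)
  expect_true(is.na(ffit$tau))
})

test_that("tau recovery under 5% noise is unbiased at the s.e.m. scale", {
  taus <- vapply(1:50, function(k) {
    tr <- make_trace("decay", list(i0 = 0, a = 1, tau = 0.131, duration = 1),
                     noise_sd = 0.05, seed = 100 + k)
    fit_exponential(tr)$tau
  }, numeric(1))
  expect_lt(abs(mean(taus) - 0.131), 0.009)
})

test_that("relative current follows the printed formula", {
  expect_equal(relative_current(10, 4, 5), 1.2)
  expect_equal(relative_current(7, 7, 3), 0)
  expect_equal(relative_current(10, 4, 5, flip_sign = TRUE), -1.2)
  set.seed(2)
  for (i in 1:25) {
    v <- runif(3, -10, 10)
    if (abs(v[3]) < 1e-6) next
    expect_equal(relative_current(v[1], v[2], v[3]), (v[1] - v[2]) / v[3])
  }
  expect_error(relative_current(1, 2, 0), "non-zero")
})

test_that("desensitization ratio is end-over-peak magnitude", {
  sq <- make_trace("square", list(level = -8, t_on = 0.1, t_off = 0.9,
                                  duration = 1))
  expect_equal(desensitization_ratio(sq, c(0.1, 0.85)), 1.0)
  # decaying current: closed form I0 / (I0 + A) once the decay has completed
  dc <- make_trace("decay", list(i0 = -2, a = -6, tau = 0.05, duration = 2))
  expect_equal(desensitization_ratio(dc, c(0, 2)), 2 / 8, tolerance = 1e-4)
  # full decay to baseline approaches zero
  dc0 <- make_trace("decay", list(i0 = 0, a = -5, tau = 0.05, duration = 2))
  expect_lt(desensitization_ratio(dc0, c(0, 2)), 1e-8)
})

test_that("GHK ratios invert the closed forms and round-trip to 1e-9 mV", {
  rtf <- photoruler:::.RT_F(295)
  # symmetric solutions, Erev 0 -> unity ratio
  sym <- permeability_ratios(
    c(na = 0), list(na = list(ion = "Na", valence = 1, out = 0.147,
                              in_ref = 0.147, protocol = "biionic")))
  expect_equal(unname(sym$ratios["na"]), 1)
  # bi-ionic with equal concentrations: ratio = exp(Erev / (RT/F))
  e <- rtf * log(0.15)
  bi <- permeability_ratios(
    c(nmdg = e), list(nmdg = list(ion = "NMDG", valence = 1, out = 0.15,
                                  in_ref = 0.15, protocol = "biionic")))
  expect_equal(unname(bi$ratios["nmdg"]), 0.15, tolerance = 1e-12)

  # round trips across protocols
  sols <- list(
    list(ion = "NMDG", valence = 1, out = 0.15, in_ref = 0.147,
         protocol = "biionic"),
    list(ion = "Ca", valence = 2, out = 0.112, in_ref = 0.147,
         protocol = "divalent"),
    list(ion = "Cl", valence = -1, cation_out = 0.075, cation_in = 0.147,
         anion_out = 0.075, anion_in = 0.147, protocol = "dilution"))
  set.seed(5)
  for (sol in sols) for (ratio in c(0.05, 0.3, 1, 2.5)) {
    e0 <- ghk_erev(ratio, sol)
    nm <- "x"
    got <- permeability_ratios(setNames(e0, nm), setNames(list(sol), nm))
    e1 <- ghk_erev(unname(got$ratios[nm]), sol)
    expect_lt(abs(e1 - e0), 1e-9)
    expect_equal(unname(got$ratios[nm]), ratio, tolerance = 1e-9)
  }
  # junction correction is a plain subtraction
  jc <- permeability_ratios(
    c(nmdg = e + 3), list(nmdg = list(ion = "NMDG", valence = 1, out = 0.15,
                                      in_ref = 0.15, protocol = "biionic")),
    junction_potentials = c(nmdg = 3))
  expect_equal(unname(jc$ratios["nmdg"]), 0.15, tolerance = 1e-12)
  expect_error(permeability_ratios(
    c(x = 0), list(x = list(ion = "X", valence = 3, out = 1, in_ref = 1,
                            protocol = "divalent"))), "valence")
})

test_that("dilution potentials match the analytic GHK expression", {
  rtf <- photoruler:::.RT_F(295)
  sol <- list(cation_out = 0.0735, cation_in = 0.147, anion_out = 0.0735,
              anion_in = 0.147, protocol = "dilution")
  for (r in c(0, 0.1, 0.5)) {
    e <- rtf * log((sol$cation_out + r * sol$anion_in) /
                     (sol$cation_in + r * sol$anion_out))
    got <- permeability_ratios(c(d = e), list(d = sol))
    expect_equal(unname(got$ratios["d"]), r, tolerance = 1e-9)
  }
})

test_that("three-level records yield the generator's means and conductances", {
  rates <- matrix(c(0, 8, 2,
                    30, 0, 6,
                    10, 15, 0), 3, 3, byrow = TRUE)
  rec <- make_single_channel(levels = c(0, -2, -6), rates = rates,
                             noise_sd = 0.3, duration = 20, rate = 5000,
                             v_hold = -120, seed = 14)
  h <- all_points_histogram(rec, bin = 0.1)
  fit <- fit_levels(h, k = 3, v_hold = rec$v_hold)
  expect_true(fit$converged)
  expect_equal(fit$means, c(-6, -2, 0), tolerance = 0.05)
  # conductance = (level - baseline) / V; baseline is the 0-pA component
  expect_equal(fit$conductances_pS[fit$means < -4], 50, tolerance = 1)
  expect_equal(fit$conductances_pS[abs(fit$means + 2) < 0.5], 50 / 3,
               tolerance = 1)
  # component areas approximately exhaust the histogram mass
  expect_equal(fit$total_mass, 1, tolerance = 0.05)
  expect_identical(order(fit$means), 1:3)  # means reported sorted
})

test_that("single-level records fit a baseline near zero", {
  rec <- make_single_channel(levels = 0, rates = matrix(0, 1, 1),
                             noise_sd = 0.3, duration = 5, seed = 3)
  fit <- fit_levels(all_points_histogram(rec), k = 1, v_hold = -120)
  expect_equal(fit$means, 0, tolerance = 0.02)
})
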