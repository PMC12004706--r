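# Fitting primitives: noiseless round trips, invariances, degenerate inputs.

test_that("Hill fits recover generating parameters from noiseless data", {
  cc <- c(1, 3, 10, 30, 100)
  y <- cc / (cc + 6.7)                       # IC50 = 6.7, h = 1
  f <- fit_hill(cc, y)
  expect_rel_equal(f$ic50, 6.7, 1e-6)
  expect_rel_equal(f$hill, 1, 1e-6)
  # midpoint identity: predicted response at C = IC50 is one half
  expect_equal(f$ic50 / (f$ic50 + f$ic50), 0.5)

  y2 <- cc^1.6 / (cc^1.6 + 12^1.6)
  f2 <- fit_hill(cc, y2)
  expect_rel_equal(f2$ic50, 12, 1e-6)
  expect_rel_equal(f2$hill, 1.6, 1e-6)

  f3 <- fit_hill(c(3, 30), c(3, 30) / (c(3, 30) + 9), fix_slope = 1)
  expect_rel_equal(f3$ic50, 9, 1e-6)
  expect_identical(f3$hill, 1)
  expect_true(f3$slope_fixed)
})

test_that("Hill fits are invariant under concentration unit rescaling", {
  cc <- c(1, 3, 10, 30, 100)
  y <- cc / (cc + 6.7)
  f_uM <- fit_hill(cc, y)
  f_nM <- fit_hill(cc * 1000, y)
  expect_rel_equal(f_nM$ic50 / f_uM$ic50, 1000, 1e-6)
  expect_rel_equal(f_nM$hill, f_uM$hill, 1e-6)
})

test_that("flat responses get a no-inhibition flag, not a fit", {
  f <- fit_hill(c(1, 3, 10, 30), c(0.01, -0.02, 0.03, 0.01))
  expect_true(is_no_inhibition(f))
  expect_true(is.na(f$ic50))
  expect_error(fit_hill(c(10, 10, 10), c(0.2, 0.3, 0.25)), "distinct")
  expect_error(fit_hill(c(1, 3, 10), c(0.2, 0.5, 1.5)), "\\[-0.2, 1.2\\]")
})

test_that("Hill fit is robust to multiplicative noise (seeded)", {
  # 5% noise, 8 replicates per point: IC50 within 15% of truth in >= 95%
  # of 200 repetitions
  cc <- rep(c(1, 3, 10, 30, 100), each = 8)
  y0 <- cc / (cc + 6.7)
  ok <- withr::with_seed(2024, {
    vapply(1:200, function(i) {
      f <- fit_hill(cc, pmin(pmax(y0 * (1 + rnorm(length(y0), 0, 0.05)),
                                  -0.2), 1.2))
      abs(f$ic50 / 6.7 - 1) < 0.15
    }, logical(1))
  })
  expect_gte(mean(ok), 0.95)
})

test_that("Boltzmann fits recover midpoint and slope exactly", {
  v <- seq(-120, -40, by = 5)
  y <- 1 / (1 + exp((v + 80) / 8))
  f <- fit_boltzmann(v, y, "inactivation")
  expect_rel_equal(f$v_half, -80, 1e-6)
  expect_rel_equal(f$k, 8, 1e-6)
  expect_rel_equal(f$amplitude, 1, 1e-6)
  # value at the midpoint is half the amplitude
  expect_equal(predict(f, f$v_half), f$amplitude / 2, tolerance = 1e-9)

  va <- seq(-70, 10, by = 5)
  ya <- 1 / (1 + exp((-32 - va) / 7))
  fa <- fit_boltzmann(va, ya, "activation")
  expect_rel_equal(fa$v_half, -32, 1e-6)
  expect_rel_equal(fa$k, 7, 1e-6)

  # free-floor variant for partially inactivating populations
  yf <- 0.3 + 0.7 / (1 + exp((v + 85) / 6))
  ff <- fit_boltzmann(v, yf, "inactivation", floor = "free")
  expect_rel_equal(ff$v_half, -85, 1e-5)
  expect_rel_equal(ff$floor, 0.3, 1e-5)
})

test_that("non-sigmoidal input is rejected by the Boltzmann fitter", {
  v <- seq(-100, -60, by = 5)
  y <- 0.5 + 0.01 * rep_len(c(1, -1), length(v))  # flat with jitter
  expect_error(fit_boltzmann(v, y, "inactivation"), "not sigmoidal")
  expect_error(fit_boltzmann(c(-100, -80), c(1, 0), "inactivation"),
               "at least 4")
})

test_that("mono-exponential fits recover Y0, plateau and tau", {
  t <- seq(0, 120, by = 5)
  y <- (1 - 0.4) * exp(-0.05 * t) + 0.4
  f <- fit_monoexp(t, y)
  expect_rel_equal(f$y0, 1, 1e-6)
  expect_rel_equal(f$plateau, 0.4, 1e-6)
  expect_rel_equal(f$tau, 20, 1e-6)
  expect_error(fit_monoexp(t, rep(1, length(t))), "constant")
  expect_error(fit_monoexp(rev(t), y), "increasing")
})

test_that("bi-exponential fits recover both components", {
  t <- c(seq(0.005, 0.1, by = 0.005), seq(0.15, 5, by = 0.15))
  y <- 1 + (0.05 - 1) * (0.7 * exp(-40 * t) + 0.3 * exp(-0.8 * t))
  f <- fit_biexp(t, y)
  expect_rel_equal(f$y0, 0.05, 1e-5)
  expect_rel_equal(f$plateau, 1, 1e-5)
  expect_rel_equal(f$percent_fast, 70, 1e-4)
  expect_rel_equal(f$k_fast, 40, 1e-4)
  expect_rel_equal(f$k_slow, 0.8, 1e-4)
  expect_false(f$degenerate)
  expect_true(f$k_fast >= f$k_slow)
  # spans reconstruct the t = 0 value
  expect_equal(f$plateau + f$span_fast + f$span_slow, f$y0,
               tolerance = 1e-9)
})

test_that("a single-exponential decay collapses the bi-exponential fit", {
  t <- c(seq(0.01, 0.2, by = 0.01), seq(0.3, 10, by = 0.3))
  y <- 0.2 + 0.8 * exp(-2 * t)
  f <- fit_biexp(t, y)
  expect_true(f$degenerate)
  expect_true(f$percent_fast %in% c(0, 100))
  expect_error(fit_biexp(t[1:5], y[1:5]), "at least 6")
  expect_error(fit_biexp(seq(1, 2, length.out = 10),
                         exp(-seq(1, 2, length.out = 10))), "decade")
})

test_that("fitters are deterministic", {
  cc <- c(1, 3, 10, 30, 100)
  y <- withr::with_seed(1, cc / (cc + 5) + rnorm(5, 0, 0.03))
  expect_identical(fit_hill(cc, y), fit_hill(cc, y))
  v <- seq(-120, -40, 5)
  yb <- withr::with_seed(2, 1 / (1 + exp((v + 80) / 8)) + rnorm(17, 0, 0.02))
  expect_identical(fit_boltzmann(v, yb), fit_boltzmann(v, yb))
})

test_that("reversal potential estimation interpolates the zero crossing", {
  v <- seq(-20, 80, by = 5)
  expect_equal(estimate_reversal(data.frame(step_mV = v,
                                            peak_pA = 12 * (v - 65))), 65)
  iv <- data.frame(step_mV = c(-30, 0, 40, 75),
                   peak_pA = c(-900, -700, -300, 75))
  expect_equal(estimate_reversal(iv),
               40 + 300 * 35 / 375)  # linear interpolation by hand
  expect_error(estimate_reversal(data.frame(step_mV = v[1:5],
                                            peak_pA = rep(-1, 5))),
               "nernst_potential")
})

test_that("the Nernst fallback reproduces the recording-solution value", {
  expect_equal(nernst_potential(145, 10, 22), 68.0, tolerance = 0.05)
  expect_equal(nernst_potential(100, 100), 0)
})

test_that("conductance transform handles the reversal singularity", {
  iv <- data.frame(step_mV = c(-25, 0, 67.5, 68.5),
                   peak_pA = c(-1000, -500, -1, 1))
  g <- conductance_from_iv(iv, 68)
  expect_equal(g$g_nS[1], -1000 / (-25 - 68))
  expect_equal(g$g_nS[1], 10.75, tolerance = 1e-2)
  expect_true(all(is.na(g$g_nS[3:4])) && all(g$excluded[3:4]))
  g0 <- conductance_from_iv(data.frame(step_mV = -40, peak_pA = 0), 68)
  expect_equal(g0$g_nS, 0)
})
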