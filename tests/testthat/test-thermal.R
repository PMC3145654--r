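test_that("ellipticity conversion applies the normalisation exactly and inverts", {
  expect_equal(mdeg_to_mre(-10), -10 * 16706 / (1 * 0.4 * 148),
               tolerance = 1e-12)
  expect_equal(mdeg_to_mre(-10), -2821.96, tolerance = 1e-5)
  expect_equal(mdeg_to_mre(0), 0)
  # linear in the signal, exactly invertible
  expect_equal(mdeg_to_mre(3) + mdeg_to_mre(4), mdeg_to_mre(7),
               tolerance = 1e-12)
  for (x in c(-10, -1.3, 0.002, 25)) {
    expect_equal(mre_to_mdeg(mdeg_to_mre(x)), x, tolerance = 1e-12)
  }
  expect_error(mdeg_to_mre(-10, conc_mg_ml = 0), "> 0")
})

test_that("the Gibbs-Helmholtz free energy has its defining properties", {
  expect_equal(gibbs_helmholtz(320, 320, 30, 0), 0)
  expect_equal(gibbs_helmholtz(320, 320, 30, 0.6), 0)   # any dCp at Tm
  expect_equal(gibbs_helmholtz(160, 320, 30, 0), 15)    # dCp=0, T = Tm/2
  # strictly decreasing through the midpoint for dHm > 0
  g <- gibbs_helmholtz(seq(310, 330, 0.5), 320, 30, 0)
  expect_true(all(diff(g) < 0))
  expect_gt(gibbs_helmholtz(300, 320, 30), 0)           # folded favoured below Tm
})

test_that("two-state signal interpolates between its baselines", {
  b_n <- c(-15000, 10); b_u <- c(-3000, 5)
  Tm <- 330
  at_tm <- two_state_signal(Tm, Tm, 40, 0, b_n, b_u)
  expect_equal(at_tm, ((b_n[1] + b_n[2] * Tm) + (b_u[1] + b_u[2] * Tm)) / 2,
               tolerance = 1e-12)
  expect_equal(two_state_signal(200, Tm, 40, 0, b_n, b_u),
               b_n[1] + b_n[2] * 200, tolerance = 1e-6)
  # mid-transition value equals direct K arithmetic
  T0 <- 335
  K <- exp(-gibbs_helmholtz(T0, Tm, 40, 0) / (1.98720425864083e-3 * T0))
  fu <- K / (1 + K)
  expect_equal(two_state_signal(T0, Tm, 40, 0, b_n, b_u),
               (1 - fu) * (b_n[1] + b_n[2] * T0) + fu * (b_u[1] + b_u[2] * T0),
               tolerance = 1e-12)
})

test_that("three-state populations normalise and hit their limits", {
  TT <- seq(278, 368, 2)
  pops <- unfold_populations(TT, Tm1 = 320, dHm1 = 27, Tm2 = 335, dHm2 = 43)
  expect_equal(pops$f_n + pops$f_i + pops$f_u, rep(1, length(TT)),
               tolerance = 1e-12)
  # K1 = 1, K2 ~ 0: half native, half intermediate
  p <- unfold_populations(320, Tm1 = 320, dHm1 = 27, Tm2 = 1000, dHm2 = 200)
  expect_equal(p$f_n, 0.5, tolerance = 1e-9)
  expect_equal(p$f_i, 0.5, tolerance = 1e-9)
  expect_lt(p$f_u, 1e-12)
  # both transitions saturated: pure unfolded baseline
  b <- list(b_n = c(-15000, 0), b_i = c(-9000, 0), b_u = c(-2000, 0))
  y_hot <- three_state_signal(500, 320, 50, 0, 340, 50, 0,
                              b$b_n, b$b_i, b$b_u)
  expect_equal(y_hot, -2000, tolerance = 1e-6)
})

test_that("the two-state model is the vanishing-K2 limit of the three-state model", {
  TT <- seq(278, 368, 1)
  b_n <- c(-15000, 12); b_u <- c(-4000, 8)
  y2 <- two_state_signal(TT, 325, 35, 0, b_n, b_u)
  # second transition pushed far away: K2 = 0 to machine precision,
  # the "intermediate" takes the unfolded baseline
  y3 <- three_state_signal(TT, 325, 35, 0, 2000, 500, 0, b_n, b_u, b_u)
  expect_lt(max(abs(y2 - y3)), 1e-10)
})

test_that("noise-free synthetic curves are recovered essentially exactly", {
  truth2 <- list(Tm = 340, dHm = 60, dCp = 0.5,
                 b_n = c(-16000, 8), b_u = c(-5000, 14))
  cv <- generate_melting_curve(truth2, seq(5, 95, 1), noise_sd = 0,
                               model = "two_state")
  ft <- fit_unfolding(cv, "two_state")
  expect_lt(abs(ft$estimate["Tm"] - truth2$Tm) / truth2$Tm, 1e-3)
  expect_lt(abs(ft$estimate["dHm"] - truth2$dHm) / truth2$dHm, 1e-3)

  truth3 <- list(Tm1 = 46.6 + 273.15, dHm1 = 27.2, dCp1 = 0,
                 Tm2 = 61.3 + 273.15, dHm2 = 43.0, dCp2 = 0,
                 b_n = c(-21000, 12), b_i = c(-14500, 5), b_u = c(-9000, 18))
  cv3 <- generate_melting_curve(truth3, seq(5, 95, 1), noise_sd = 0)
  ft3 <- fit_unfolding(cv3, "three_state", fix = c(dCp = 0))
  for (nm in c("Tm1", "dHm1", "Tm2", "dHm2")) {
    expect_lt(abs(ft3$estimate[nm] - truth3[[nm]]) / truth3[[nm]], 1e-3)
  }
  expect_false(ft3$ill_conditioned)
  td <- tidy(ft3)
  expect_true(all(td$fixed[td$term %in% c("dCp1", "dCp2")]))
  expect_true(all(is.na(td$std.error[td$fixed])))
  gl <- glance(ft3)
  expect_equal(gl$model, "three_state")
  expect_lt(gl$sigma, 1)
})

test_that("fitting a featureless straight line is flagged as ill-conditioned", {
  cv <- melting_curve(seq(5, 95, 1), -12000 + 30 * seq(5, 95, 1))
  expect_warning(ft <- fit_unfolding(cv, "two_state"), "ill-conditioned")
  expect_true(ft$ill_conditioned)
})

test_that("the melting-curve generator is deterministic with calibrated noise", {
  truth <- list(Tm1 = 319.75, dHm1 = 27.2, dCp1 = 0, Tm2 = 334.45,
                dHm2 = 43.0, dCp2 = 0, b_n = c(-21000, 12),
                b_i = c(-14500, 5), b_u = c(-9000, 18))
  c0 <- generate_melting_curve(truth, noise_sd = 0)
  c1 <- generate_melting_curve(truth, noise_sd = 25, seed = 4)
  c1b <- generate_melting_curve(truth, noise_sd = 25, seed = 4)
  c2 <- generate_melting_curve(truth, noise_sd = 25, seed = 5)
  expect_identical(c1$signal, c1b$signal)
  expect_false(identical(c1$signal, c2$signal))
  # residual scatter reproduces the requested noise level
  big <- generate_melting_curve(truth, seq(5, 95, 0.1), noise_sd = 25,
                                seed = 6)
  ref <- generate_melting_curve(truth, seq(5, 95, 0.1), noise_sd = 0)
  expect_equal(stats::sd(big$signal - ref$signal), 25, tolerance = 0.05 * 25)
  # melting curves round-trip through delimited text
  f <- withr::local_tempfile(fileext = ".tsv")
  write_melting_curve(c1, f)
  c1r <- read_melting_curve(f)
  expect_equal(c1r$signal, c1$signal, tolerance = 1e-9)
  expect_equal(attr(c1r, "unit"), "C")
  expect_error(melting_curve(c(1, 1, 2), c(0, 0, 0)), "increasing")
})
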