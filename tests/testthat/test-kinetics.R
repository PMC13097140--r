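test_that("deconvolution solves the three-wavelength system", {
  calib <- default_test_calibration()

  zero <- deconvolve_spectra(list(abs250 = 0, abs320 = 0, abs400 = 0), calib)
  expect_equal(as.numeric(zero), c(0, 0, 0))

  # round trip against the forward Beer-Lambert model
  for (conc in list(c(0.4, 0.6, 0.2), c(1, 0, 0), c(0.01, 0.93, 0.81))) {
    a <- forward_absorbance(conc, calib)
    back <- deconvolve_spectra(as.list(a), calib)
    expect_equal(as.numeric(back), conc, tolerance = 1e-12)
  }

  # decoupled system: no ester absorbance at 400 nm
  dec <- calibration_set(list(
    `4NP4HB` = c(`250` = 2, `320` = 9, `400` = 0),
    `4NP` = c(`250` = 1.5, `320` = 1.2, `400` = 12),
    `4HB` = c(`250` = 6)))
  r1 <- deconvolve_spectra(list(abs250 = 0.5, abs320 = 0.3, abs400 = 0.6,
                                dilution_factor = 1), dec)
  r2 <- deconvolve_spectra(list(abs250 = 0.5, abs320 = 0.9, abs400 = 0.6,
                                dilution_factor = 1), dec)
  expect_equal(unname(r1["c_4np"]), 0.6 / 12)
  expect_equal(unname(r2["c_4np"]), unname(r1["c_4np"]))
})

test_that("invalid calibration and negative concentrations are surfaced", {
  expect_error(calibration_set(list(
    `4NP4HB` = c(`320` = 1, `400` = 2),
    `4NP` = c(`320` = 2, `400` = 4),
    `4HB` = c(`250` = 6))), "singular")
  calib <- default_test_calibration()
  expect_warning(
    out <- deconvolve_spectra(list(abs250 = 0, abs320 = 0, abs400 = -0.5),
                              calib),
    "below -tol")
  expect_true(attr(out, "flagged"))
  expect_lt(min(out), 0)   # never clipped
})

test_that("conversion, yield and carbon balance follow the carbon counts", {
  expect_equal(unname(conversion_yield_balance(c(1, 0, 0), 1)),
               c(0, 0, 100))
  expect_equal(unname(conversion_yield_balance(c(0, 1, 1), 1)),
               c(100, 100, 100))
  m <- conversion_yield_balance(c(0.5, 0.3, 0.2), 1.0)
  expect_equal(unname(m["conversion_pct"]), 50)
  expect_equal(unname(m["yield_pct"]), 30)
  expect_equal(unname(m["carbon_balance_pct"]),
               (13 * 0.5 + 6 * 0.3 + 7 * 0.2) / 13 * 100)
  expect_error(conversion_yield_balance(c(1, 0, 0), 0), "positive")

  # stoichiometric closure: balance is exactly 100% along any trajectory
  # with c_4np = c_4hb = c_i - c_ester
  set.seed(42)
  for (i in 1:20) {
    ci <- runif(1, 0.1, 2)
    ce <- runif(1, 0, ci)
    m <- conversion_yield_balance(c(ce, ci - ce, ci - ce), ci)
    expect_equal(unname(m["carbon_balance_pct"]), 100)
  }
})

test_that("first-order fit recovers noiseless rate constants", {
  calib <- default_test_calibration()
  for (k in c(0.02, 0.1, 0.5)) {
    run <- gen_kinetics(k_app = k, c0 = 1.0, times = c(0, 5, 10, 20, 40),
                        calib = calib, noise_sd = 0, seed = 1)
    f <- fit_first_order(run, calib)
    expect_lt(abs(f$k_app - k) / k, 1e-6)
    expect_equal(f$fitted_c0, 1.0, tolerance = 1e-6)
  }
})

test_that("degenerate and malformed runs are handled", {
  conc <- cbind(c_ester = rep(0.8, 5), c_4np = rep(0, 5), c_4hb = rep(0, 5))
  run <- kinetic_run(times = c(0, 5, 10, 20, 40), conc = conc,
                     c_ester_initial = 0.8)
  f <- fit_first_order(run)
  expect_equal(f$k_app, 0, tolerance = 1e-10)

  expect_error(
    fit_first_order(kinetic_run(times = c(0, 5),
                                conc = conc[1:2, ], c_ester_initial = 0.8)),
    "insufficient")
  expect_error(kinetic_run(times = c(0, 5, 5), conc = conc[1:3, ],
                           c_ester_initial = 0.8), "strictly increasing")
})

test_that("fit methods are consistent (coef, predict, residuals, confint)", {
  calib <- default_test_calibration()
  run <- gen_kinetics(0.08, 1.2, c(0, 5, 10, 20, 40, 60), calib,
                      noise_sd = 0.005, seed = 11)
  f <- fit_first_order(run, calib)
  expect_named(coef(f), c("k_app", "c0"))
  pr <- predict(f, c(0, 10))
  expect_equal(pr$c_ester[1], f$fitted_c0)
  expect_equal(pr$c_ester + pr$c_4np, rep(f$fitted_c0, 2))
  expect_length(residuals(f), 12)
  ci <- confint(f)
  expect_equal(unname(ci[1, 2] - ci[1, 1]) / 2, f$ci95_halfwidth)
  sims <- simulate(f, nsim = 2, seed = 3)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "kinetic_run")

  # fixed-c0 variant fits one fewer parameter
  f0 <- fit_first_order(run, calib, fix_c0 = TRUE)
  expect_equal(f0$fitted_c0, run$c_ester_initial)
  expect_gt(f0$dof, f$dof)
})

test_that("activity correction and TOF follow the background subtraction", {
  # full background: corrected rate is exactly zero
  r0 <- compute_activity(k_app = 0.02 + 0.5 * 0.001, k_app_blank = 0.02,
                         k_piperidine = 0.5, c_piperidine = 0.001,
                         c_catalyst = 5e-4, c_ester_initial = 1e-3)
  expect_equal(r0$k_cat, 0)
  expect_equal(r0$tof, 0)

  # linearity: doubling the excess over background doubles k_cat
  r1 <- compute_activity(0.02 + 0.01, 0.02, 0, 0, 5e-4, 1e-3)
  r2 <- compute_activity(0.02 + 0.02, 0.02, 0, 0, 5e-4, 1e-3)
  expect_equal(r2$k_cat, 2 * r1$k_cat)

  # TOF proportionality holds exactly for any result
  set.seed(7)
  for (i in 1:10) {
    ka <- runif(1, 0, 0.1); cc <- runif(1, 1e-5, 1e-3)
    ci <- runif(1, 1e-5, 2e-3)
    r <- compute_activity(ka, 0, 0, 0, cc, ci)
    expect_equal(r$tof / ci, r$k_cat)
  }

  expect_error(compute_activity(0.1, 0, 0, 0, 0, 1e-3), "undefined")
  expect_warning(compute_activity(0.01, 0.02, 0, 0, 5e-4, 1e-3), "negative")
})

test_that("catalyst loading arithmetic matches hand calculations", {
  comp <- catalyst_composition(metal_wt_frac = 0.048, dispersion = 0.04,
                               s_wt_frac = 0.00085)
  pd <- surface_metal_loading(comp)
  expect_equal(signif(pd, 2), 0.018)
  th <- linker_loading_from_sulfur(comp)
  expect_equal(signif(th, 2), 0.013)
  expect_equal(round(coverage_ratio(0.013, 0.018), 2), 0.72)
  expect_equal(round(coverage_ratio(0.007, 0.018), 2), 0.39)

  # molar-mass identity: full dispersion at one molar mass of metal per
  # 10 g gives 1 mmol/g
  expect_equal(surface_metal_loading(
    catalyst_composition(metal_wt_frac = 0.10642, dispersion = 1)), 1.0)
  expect_equal(surface_metal_loading(
    catalyst_composition(metal_wt_frac = 0.05, dispersion = 0.10)),
    50 / 106.42 * 0.1, tolerance = 1e-12)
  # monothiol: 1 S per linker
  expect_equal(linker_loading_from_sulfur(
    catalyst_composition(s_wt_frac = 0.0032, s_per_linker = 1)),
    3.2 / 32.06, tolerance = 1e-12)
  expect_equal(linker_loading_from_sulfur(
    catalyst_composition(s_wt_frac = 0)), 0)
  expect_equal(coverage_ratio(0.5, 0.5), 1)
  expect_error(coverage_ratio(0.1, 0), "undefined")
})
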