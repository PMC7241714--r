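test_that("Beer-Lambert conversions are exact", {
  assay <- assay_spec(extinction = 3850, wavelength = 240)
  v <- rate_from_absorbance(0.00385, assay)
  expect_equal(v$M_per_min, 1e-6)          # 1 uM/min
  expect_equal(v$mM_per_min, 1e-3)
  expect_equal(rate_from_absorbance(0, assay)$M_per_min, 0)
  # doubling the path length halves the velocity
  assay2 <- assay_spec(3850, path_length = 2)
  expect_equal(rate_from_absorbance(0.00385, assay2)$M_per_min, 0.5e-6)
  # enzyme normalisation to turnover
  assay_e <- assay_spec(3850, enzyme_concentration = 1e-7)
  expect_equal(rate_from_absorbance(0.00385, assay_e)$turnover_per_s,
               1e-6 / 60 / 1e-7)
  expect_error(assay_spec(-1), "extinction")
})

test_that("extinction coefficient inverts Beer-Lambert", {
  # the published product coefficient back-computed from its spectrum point
  expect_equal(extinction_from_spectrum(5240 * 200e-6, 200e-6), 5240)
  expect_equal(extinction_from_spectrum(0, 1e-4), 0)
  eps <- extinction_from_spectrum(0.77, 2e-4)
  expect_equal(eps * 2e-4 * 1, 0.77)
  expect_error(extinction_from_spectrum(1, 0), "concentration")
})

test_that("noiseless Michaelis-Menten data is recovered to 1e-6 relative", {
  d <- generate_kinetics("mm", kcat = 17.6, Km = 1.00, noise_cv = 0, seed = 1)
  fit <- fit_michaelis_menten(d)
  expect_equal(fit$kcat, 17.6, tolerance = 1e-6)
  expect_equal(fit$Km, 1.00, tolerance = 1e-6)
  expect_true(fit$valid)
  # model identity: v(S = Km) = kcat / 2
  expect_equal(fit$kcat * fit$Km / (fit$Km + fit$Km), fit$kcat / 2)
  expect_error(fit_michaelis_menten(d[d$substrate_mM < 3, ]),
               "4 distinct")
})

test_that("noisy Michaelis-Menten estimates stay within 5% of truth", {
  d <- generate_kinetics("mm", kcat = 17.6, Km = 1.00, noise_cv = 0.02,
                         replicates = 3, seed = 42)
  fit <- fit_michaelis_menten(d)
  expect_lt(abs(fit$kcat - 17.6) / 17.6, 0.05)
  expect_lt(abs(fit$Km - 1.00) / 1.00, 0.05)
})

test_that("noiseless global inhibition fits recover generating parameters", {
  cases <- list(
    list(model = "competitive", kcat = 17.6, Km = 1.00, Ki = 1.7,
         I = c(0, 2, 5, 10)),
    list(model = "noncompetitive", kcat = 17.6, Km = 1.00, Ki = 71,
         I = c(0, 25, 50, 100)),
    list(model = "noncompetitive", kcat = 4.4, Km = 141, Ki = 128,
         I = c(0, 50, 100, 150)),
    list(model = "competitive", kcat = 66, Km = 1.38, Ki = 5,
         I = c(0, 2, 5, 10)))
  for (cs in cases) {
    d <- generate_kinetics(cs$model, kcat = cs$kcat, Km = cs$Km, Ki = cs$Ki,
                           I_levels = cs$I, noise_cv = 0, seed = 1)
    fit <- fit_inhibition(d, cs$model)
    expect_equal(fit$kcat, cs$kcat, tolerance = 1e-6)
    expect_equal(fit$Km, cs$Km, tolerance = 1e-6)
    expect_equal(fit$Ki, cs$Ki, tolerance = 1e-6)
    expect_gt(fit$global_r_squared, 1 - 1e-10)
  }
})

test_that("the wrong inhibition model leaves a strictly larger residual", {
  d <- generate_kinetics("noncompetitive", Ki = 71, I_levels = c(0, 25, 50, 100),
                         noise_cv = 0, seed = 1)
  right <- fit_inhibition(d, "noncompetitive")
  wrong <- fit_inhibition(d, "competitive")
  expect_gt(wrong$fit$deviance, right$fit$deviance)
})

test_that("a single inhibitor level degenerates to Michaelis-Menten", {
  d <- generate_kinetics("mm", noise_cv = 0, seed = 1)
  fit <- fit_inhibition(d, "competitive")
  expect_false(fit$ki_identifiable)
  expect_true(is.na(fit$Ki))
  expect_equal(fit$kcat, 17.6, tolerance = 1e-6)
})

test_that("model discrimination recovers the generating mechanism", {
  d <- generate_kinetics("competitive", Ki = 1.7, I_levels = c(0, 2, 5, 10),
                         noise_cv = 0.02, seed = 7)
  expect_equal(classify_inhibition(d)$model, "competitive")

  d <- generate_kinetics("noncompetitive", Ki = 128,
                         I_levels = c(0, 50, 100, 150),
                         noise_cv = 0.02, seed = 7)
  expect_equal(classify_inhibition(d)$model, "noncompetitive")

  # effectively no inhibition (mirrors lysine, inactive up to 100 mM)
  d <- generate_kinetics("competitive", Ki = 1e6, I_levels = c(0, 25, 50, 100),
                         noise_cv = 0.02, seed = 7)
  cl <- classify_inhibition(d)
  expect_equal(cl$model, "none")
  expect_length(attr(cl, "aicc_table"), 3L)
})

test_that("model curves are monotone in substrate and inhibitor", {
  S <- seq(0.5, 20, by = 0.5)
  I <- c(0, 1, 2, 5, 10)
  for (model in c("competitive", "noncompetitive")) {
    fn <- maltriage:::.inhibition_model_fn(model)
    for (ic in I) {
      v <- fn(list(kcat = 17.6, Km = 1, Ki = 1.7),
              data.frame(substrate_mM = S, inhibitor_mM = ic))
      expect_true(all(v >= 0))
      expect_true(all(diff(v) > 0))       # increasing in S
    }
    for (s in c(1.25, 5, 15)) {
      v <- fn(list(kcat = 17.6, Km = 1, Ki = 1.7),
              data.frame(substrate_mM = s, inhibitor_mM = I))
      expect_true(all(diff(v) < 0))       # decreasing in Ic
    }
  }
})

test_that("Lineweaver-Burk intercept patterns match the model algebra", {
  comp <- generate_kinetics("competitive", Ki = 1.7, I_levels = c(0, 2, 5, 10),
                            noise_cv = 0, seed = 1)
  lb <- lineweaver_burk(comp)
  expect_lte(attr(lb, "y_intercept_spread"), 1e-9)
  expect_match(attr(lb, "pattern"), "competitive \\(common y-intercept\\)")
  expect_equal(lb$y_intercept, rep(1 / 17.6, 4), tolerance = 1e-9)

  nonc <- generate_kinetics("noncompetitive", Ki = 71,
                            I_levels = c(0, 25, 50, 100),
                            noise_cv = 0, seed = 1)
  lbn <- lineweaver_burk(nonc)
  expect_lte(attr(lbn, "x_intercept_spread"), 1e-9)
  expect_equal(lbn$x_intercept, rep(-1, 4), tolerance = 1e-9)  # -1/Km, Km = 1

  # slopes increase monotonically with inhibitor under both models
  expect_true(all(diff(lb$slope) > 0))
  expect_true(all(diff(lbn$slope) > 0))

  # non-positive velocities are excluded with a warning
  broken <- comp
  broken$velocity[1] <- -1
  expect_warning(lineweaver_burk(broken), "non-positive")
})

test_that("efficiency and fold change reproduce simple ratios", {
  expect_equal(efficiency(66, 1.38), 47.8)
  expect_equal(round(efficiency(4.4, 141), 3), 0.031)
  expect_equal(efficiency(17.6, 1.00), 17.6)
  expect_equal(efficiency(2, 2), 1.0)
  fit <- fit_michaelis_menten(generate_kinetics("mm", noise_cv = 0, seed = 1))
  expect_equal(efficiency(fit), 17.6)

  expect_equal(fold_change(141, 1.00), 141)
  expect_equal(fold_change(17.6, 4.4), 4.0)
  expect_equal(fold_change(3, 3), 1.0)
  expect_error(fold_change(1, 0), "zero")
})

test_that("kinetics tables round-trip through CSV with fit reports", {
  d <- generate_kinetics("competitive", Ki = 1.7, I_levels = c(0, 2, 5, 10),
                         noise_cv = 0.02, seed = 3)
  csv <- withr::local_tempfile(fileext = ".csv")
  truth <- withr::local_tempfile(fileext = ".json")
  write_table_csv(d, csv, truth_json = truth)
  back <- read_kinetics(csv)
  expect_equal(back$velocity, d$velocity, tolerance = 1e-12)
  expect_equal(jsonlite::read_json(truth)$Ki, 1.7)

  fit <- classify_inhibition(back)
  report <- withr::local_tempfile(fileext = ".json")
  write_fit_report(fit, report)
  parsed <- jsonlite::read_json(report)
  expect_equal(parsed$model, "competitive")
  expect_equal(parsed$Ki, fit$Ki)
})
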