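wt_params <- itc_params(n = 1, K = 1 / 0.47e-6, delta_H = -8000)

test_that("closed-form cumulative heat matches the mass-action oracle", {
  for (p in list(wt_params,
                 itc_params(n = 0.8, K = 1 / 12.5e-6, delta_H = 3000),
                 itc_params(n = 2, K = 1e7, delta_H = -5000,
                            Mt0 = 10e-6, X0 = 150e-6))) {
    for (i in c(1L, 5L, 10L, 19L))
      expect_equal(one_site_cumulative_heat(p, i),
                   oracle_cumulative_heat(p, i), tolerance = 1e-8)
  }
})

test_that("limiting cases behave analytically", {
  # zero enthalpy: no heat anywhere
  p0 <- itc_params(n = 1, K = 1e6, delta_H = 0)
  expect_equal(injection_heats(p0), rep(0, 19))
  # heats scale linearly in delta_H
  p1 <- itc_params(n = 1, K = 1e6, delta_H = -8000)
  p2 <- itc_params(n = 1, K = 1e6, delta_H = -16000)
  expect_equal(injection_heats(p2), 2 * injection_heats(p1),
               tolerance = 1e-12)
  # near-infinite affinity: all injected ligand binds until saturation,
  # so the first injection's heat is dH * moles injected (less the
  # displaced-volume loss, < 1% here)
  ps <- itc_params(n = 1, K = 1e12, delta_H = -8000)
  q1 <- injection_heats(ps)[1]
  expect_equal(q1, -8000 * 300e-6 * 2e-6, tolerance = 0.01)
  # heats carry the sign of delta_H
  expect_true(all(injection_heats(p1) < 0))
  expect_true(all(injection_heats(itc_params(n = 1, K = 1e6,
                                             delta_H = 8000)) > 0))
})

test_that("simulated thermograms are deterministic and flag the purge injection", {
  tg1 <- simulate_thermogram(wt_params, noise_sd = 0.1, seed = 7L)
  tg2 <- simulate_thermogram(wt_params, noise_sd = 0.1, seed = 7L)
  expect_identical(tg1$data, tg2$data)
  expect_equal(nrow(tg1$data), 20L)          # 0.4 uL purge + 19 injections
  expect_equal(tg1$data$volume[1], 0.4e-6)
  expect_true(tg1$data$exclude[1])
  expect_false(any(tg1$data$exclude[-1]))
})

test_that("a noiseless fit recovers the generating parameters", {
  tg <- simulate_thermogram(wt_params, noise_sd = 0, seed = 1L)
  fit <- fit_one_site(tg)
  expect_true(fit$converged)
  expect_lt(abs(fit$n_hat - 1), 1e-6)
  expect_lt(abs(fit$Kd_uM - 0.47) / 0.47, 1e-6)
  expect_lt(abs(fit$delta_H_hat + 8000) / 8000, 1e-6)
  expect_false(any(fit$used & tg$data$exclude))
})

test_that("itc_fit behaves like a classed model object", {
  tg <- simulate_thermogram(wt_params, noise_sd = 0.05, seed = 3L)
  fit <- fit_one_site(tg)
  expect_s3_class(fit, "itc_fit")
  expect_named(coef(fit), c("n", "K", "Kd_uM", "delta_H", "offset"))
  expect_length(fitted(fit), nrow(tg$data))
  expect_equal(residuals(fit), tg$data$heat_ucal - fitted(fit))
  expect_lt(sum(residuals(fit)[fit$used]^2), sum(residuals(fit)^2) + 1e-9)
  expect_output(print(fit), "Kd")
  est <- summary(fit)
  expect_true(all(c("n", "Kd_uM") %in% rownames(est)))
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, tg), fitted(fit), tolerance = 1e-9)
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "thermogram")
  pdf(NULL)
  expect_invisible(plot(fit))
  dev.off()
})

test_that("a low-c titration is flagged as low information", {
  weak <- itc_params(n = 1, K = 1 / 60e-6, delta_H = -8000)  # c = 0.5
  tg <- simulate_thermogram(weak, noise_sd = 0, seed = 2L)
  fit <- fit_one_site(tg)
  expect_true(fit$converged)
  expect_true(any(grepl("low-information", fit$warnings)))
})

test_that("fold reduction and replicate averaging follow reporting conventions", {
  wt <- fit_one_site(simulate_thermogram(wt_params, seed = 1L))
  mut <- fit_one_site(simulate_thermogram(
    itc_params(n = 1, K = 1 / 4.23e-6, delta_H = -8000), seed = 1L))
  expect_equal(fold_reduction(mut, wt), 9, tolerance = 1e-6)
  expect_identical(fold_reduction(NULL, wt), "ND")
  reps <- average_replicates(list(wt, wt))
  expect_equal(reps$Kd_uM, wt$Kd_uM)
  expect_equal(reps$half_range_uM, 0)
})

test_that("thermogram CSV + JSON round trip preserves the fit input", {
  tg <- simulate_thermogram(wt_params, noise_sd = 0.1, seed = 9L)
  csv <- tempfile(fileext = ".csv")
  write_thermogram(tg, csv)
  back <- read_thermogram(csv)
  expect_equal(back$data$heat_ucal, tg$data$heat_ucal, tolerance = 1e-9)
  expect_equal(back$data$volume, tg$data$volume, tolerance = 1e-12)
  expect_equal(back$data$exclude, tg$data$exclude)
  expect_equal(back$meta$Mt0, tg$meta$Mt0)
  f1 <- fit_one_site(tg)
  f2 <- fit_one_site(back)
  expect_equal(f2$Kd_uM, f1$Kd_uM, tolerance = 1e-6)
})

test_that("thermogram construction validates its inputs", {
  expect_error(thermogram(data.frame(injection = 1:3, volume = 2e-6),
                          meta = list(V0 = 2e-4, Mt0 = 3e-5, X0 = 3e-4)),
               "lacks columns")
  expect_error(thermogram(data.frame(injection = c(1, 1), volume = 2e-6,
                                     heat_ucal = 0),
                          meta = list(V0 = 2e-4, Mt0 = 3e-5, X0 = 3e-4)),
               "strictly increasing")
  expect_error(thermogram(data.frame(injection = 1:2, volume = 2e-6,
                                     heat_ucal = 0),
                          meta = list(V0 = 2e-4, Mt0 = 3e-5)),
               "lacks X0")
  expect_error(itc_params(n = 1, K = -5, delta_H = 1), "K > 0")
})
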