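test_that("specific binding subtracts controls elementwise and clips at zero", {
  d <- tibble::tibble(concentration_nM = c(1, 2),
                      response = c(0.5, 0.9),
                      control_response = c(0.1, 0.1))
  out <- specific_binding(d)
  expect_equal(out$response, c(0.4, 0.8))
  expect_false("control_response" %in% names(out))

  zero <- specific_binding(dplyr::mutate(d, control_response = 0))
  expect_equal(zero$response, d$response)

  expect_warning(
    clipped <- specific_binding(dplyr::mutate(d, control_response = c(0.6, 0.1))),
    "clipped"
  )
  expect_equal(clipped$response, c(0, 0.8))
  expect_error(specific_binding(d[, 1:2]), "columns")
})

test_that("noiseless Hill-Langmuir data refit to the generating parameters", {
  d <- simulate_binding_curve(kd = 10, bmax = 2, concentrations = 2^(0:7) * 0.25)
  fit <- fit_hill_langmuir(d)
  expect_true(fit$converged)
  expect_equal(fit$kd, 10, tolerance = 1e-6)
  expect_equal(fit$bmax, 2, tolerance = 1e-6)
  # printed STAND-A36 affinity over the assayed 0.22-36 nM range
  fit2 <- fit_hill_langmuir(simulate_binding_curve(kd = 12.18, bmax = 1))
  expect_equal(fit2$kd, 12.18, tolerance = 1e-6)
})

test_that("the fitted curve passes through Bmax/2 at c = Kd", {
  fit <- fit_hill_langmuir(simulate_binding_curve(kd = 7.3, bmax = 1.4))
  expect_equal(predict(fit, fit$kd), fit$bmax / 2, tolerance = 1e-9)
  expect_equal(predict(fit, 0), 0)
  expect_lt(predict(fit, 1e9), fit$bmax)
  got <- predict(fit, seq(5, 100, by = 5))
  expect_true(all(diff(got) > 0))           # monotone increasing
  expect_true(all(diff(diff(got)) < 0))     # concave on an even grid
  expect_error(predict(fit, -1), "non-negative")
})

test_that("sub-saturating (linear) responses are flagged as unidentified", {
  d <- tibble::tibble(concentration_nM = 1:8, response = 0.01 * (1:8))
  fit <- fit_hill_langmuir(d)
  expect_false(fit$converged)
  expect_match(fit$diagnostic, "saturation|identified|failure|non-physical")
  expect_error(predict(fit, 1), "converge")
})

test_that("optimizer solution matches a grid-search RSS oracle", {
  d <- simulate_binding_curve(kd = 12, bmax = 1, noise_sd = 0.05, seed = 321)
  fit <- fit_hill_langmuir(d)
  grid <- tidyr::expand_grid(kd = seq(6, 24, by = 0.1),
                             bmax = seq(0.7, 1.3, by = 0.005))
  grid$rss <- purrr::map2_dbl(grid$kd, grid$bmax, function(k, b) {
    sum((d$response - b * d$concentration_nM / (k + d$concentration_nM))^2)
  })
  best <- grid[which.min(grid$rss), ]
  expect_lte(fit$rss, best$rss + 1e-12)
  expect_equal(fit$kd, best$kd, tolerance = 0.2 / best$kd)
  expect_equal(fit$bmax, best$bmax, tolerance = 0.01)
})

test_that("fits are scale-equivariant and pooled replicates are accepted", {
  d <- simulate_binding_curve(kd = 9, bmax = 1, noise_sd = 0.03, seed = 17)
  f1 <- fit_hill_langmuir(d)
  f10 <- fit_hill_langmuir(dplyr::mutate(d, response = response * 10))
  expect_equal(f10$kd, f1$kd, tolerance = 1e-6)
  expect_equal(f10$bmax, 10 * f1$bmax, tolerance = 1e-6)
  expect_equal(f10$rss, 100 * f1$rss, tolerance = 1e-6)
  pooled <- dplyr::bind_rows(d, d)   # stacked replicate wells
  expect_equal(fit_hill_langmuir(pooled)$kd, f1$kd, tolerance = 1e-6)
})

test_that("Kd recovery under 2% noise: median relative error below 10%", {
  errs <- vapply(1:200, function(i) {
    kd <- 10^((i %% 100) / 99 * 2)   # deterministic spread over 1-100 nM
    d <- simulate_binding_curve(kd, bmax = 1, noise_sd = 0.02, seed = 40000 + i)
    f <- fit_hill_langmuir(d)
    if (f$converged) abs(f$kd - kd) / kd else Inf   # failed fit = no recovery
  }, numeric(1))
  expect_lt(median(errs), 0.10)
  # same-seed rerun is bit-identical
  d1 <- simulate_binding_curve(12, 1, noise_sd = 0.02, seed = 9)
  d2 <- simulate_binding_curve(12, 1, noise_sd = 0.02, seed = 9)
  expect_identical(fit_hill_langmuir(d1)$kd, fit_hill_langmuir(d2)$kd)
})

test_that("noiseless unfolding curves refit to the generating half-life", {
  fit <- fit_half_life(simulate_unfolding_curve(t_half = 1.68))
  expect_true(fit$converged)
  expect_equal(fit$t_half, 1.68, tolerance = 1e-6)
  expect_equal(fit$f0, 0, tolerance = 1e-6)
  expect_equal(fit$fmax, 1, tolerance = 1e-6)
  # model identity at t = t_half
  at_half <- fit$f0 + (fit$fmax - fit$f0) * fit$t_half / (fit$t_half + fit$t_half)
  expect_equal(at_half, (fit$f0 + fit$fmax) / 2, tolerance = 1e-9)
  # nonzero baseline is absorbed by F0
  fit2 <- fit_half_life(simulate_unfolding_curve(0.877, f0 = 0.2, fmax = 1.6))
  expect_equal(fit2$t_half, 0.877, tolerance = 1e-6)
  expect_equal(fit2$f0, 0.2, tolerance = 1e-6)
})

test_that("degenerate unfolding signals are diagnosed, not fitted", {
  flat <- tibble::tibble(time_min = seq(0, 5, 0.5), fluorescence = 1)
  expect_false(fit_half_life(flat)$converged)
  expect_match(fit_half_life(flat)$diagnostic, "constant")
  declining <- tibble::tibble(time_min = seq(0, 5, 0.5),
                              fluorescence = seq(2, 1, length.out = 11))
  expect_false(fit_half_life(declining)$converged)
  expect_match(fit_half_life(declining)$diagnostic, "declining")
  expect_error(fit_half_life(tibble::tibble(time_min = c(0, 1, 2),
                                            fluorescence = 1:3)), "4 time")
  expect_error(fit_half_life(tibble::tibble(time_min = c(0, 2, 1, 3),
                                            fluorescence = 1:4)), "increasing")
})

test_that("tidy and glance expose fit results as tibbles", {
  bf <- fit_hill_langmuir(simulate_binding_curve(10, 2))
  tb <- tidy(bf)
  expect_equal(tb$term, c("kd", "bmax"))
  expect_equal(tb$estimate[1], 10, tolerance = 1e-6)
  expect_true(glance(bf)$converged)
  hf <- fit_half_life(simulate_unfolding_curve(1.68))
  expect_equal(tidy(hf)$estimate[1], 1.68, tolerance = 1e-6)
  expect_equal(glance(hf)$n, 21L)
})

test_that("assay CSV readers validate their schemas", {
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(simulate_binding_curve(10, 1), p, row.names = FALSE)
  expect_equal(nrow(read_binding_csv(p)), 8L)
  utils::write.csv(simulate_unfolding_curve(1.68), p, row.names = FALSE)
  expect_equal(nrow(read_unfolding_csv(p)), 21L)
  writeLines("x,y\n1,2", p)
  expect_error(read_binding_csv(p), "columns")
  expect_error(read_unfolding_csv(p), "columns")
})
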