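test_that("noiseless Hill curves are refit exactly", {
  conc <- 5.27 * 10^seq(-1.5, 1.5, length.out = 8)
  s <- generate_dose_response(5.27, 1.20, response_type = "activation",
                              concentrations = conc)
  f <- fit_hill(s)
  expect_equal(f$ec50_or_ic50, 5.27, tolerance = 0.01)
  expect_equal(f$hill_h, 1.20, tolerance = 0.01)
  expect_equal(f$i_max, 1, tolerance = 0.01)
  # half-maximal response at EC50 by construction
  expect_equal(predict(f, f$ec50_or_ic50), f$i_max / 2)

  si <- generate_dose_response(1.34, 1.04, response_type = "inhibition")
  fi <- fit_inhibition(si)
  expect_equal(fi$ec50_or_ic50, 1.34, tolerance = 0.01)
  expect_equal(fi$hill_h, 1.04, tolerance = 0.01)
  expect_equal(predict(fi, fi$ec50_or_ic50), 0.5)
})

test_that("fitted curves are monotone with correct asymptotes", {
  s <- generate_dose_response(5, 1.3, response_type = "activation")
  f <- fit_hill(s)
  grid <- 10^seq(-3, 4, length.out = 100)
  act <- predict(f, grid)
  expect_true(all(diff(act) > 0))
  si <- generate_dose_response(2, 0.9, response_type = "inhibition")
  fi <- fit_inhibition(si)
  inh <- predict(fi, grid)
  expect_true(all(diff(inh) < 0))
  expect_equal(predict(fi, 1e-8), 1, tolerance = 1e-4)
  expect_lt(predict(fi, 1e8), 1e-4)
})

test_that("EC50 is scale-equivariant and h scale-invariant", {
  conc <- 4 * 10^seq(-1.2, 1.2, length.out = 7)
  s1 <- generate_dose_response(4, 1.5, response_type = "activation",
                               concentrations = conc, noise_sigma = 0.03,
                               seed = 11)
  f1 <- fit_hill(s1)
  s10 <- dose_response_series(10 * s1$concentrations, s1$responses,
                              "activation")
  f10 <- fit_hill(s10)
  expect_equal(f10$ec50_or_ic50, 10 * f1$ec50_or_ic50, tolerance = 1e-6)
  expect_equal(f10$hill_h, f1$hill_h, tolerance = 1e-6)
})

test_that("degenerate and malformed series are rejected", {
  expect_error(dose_response_series(c(1, 2, 3), c(1, 1, 1)), "at least 4")
  expect_error(dose_response_series(c(1, 2, 2, 4), rep(0.5, 4), "activation"),
               "unique")
  flat <- dose_response_series(c(1, 3, 10, 30), rep(0.5, 4), "activation")
  expect_error(fit_hill(flat), "degenerate")
  s <- generate_dose_response(5, 1, response_type = "activation")
  expect_error(fit_inhibition(s), "inhibition series")
})

test_that("IC50 recovery under multiplicative noise meets the Monte-Carlo
           bound", {
  errs <- vapply(1:100, function(seed) {
    s <- generate_dose_response(1.34, 1.04, response_type = "inhibition",
                                noise_sigma = 0.05, seed = seed)
    f <- tryCatch(fit_inhibition(s), error = function(e) NULL)
    if (is.null(f)) return(NA_real_)
    abs(f$ec50_or_ic50 - 1.34) / 1.34
  }, numeric(1))
  expect_lte(stats::median(errs, na.rm = TRUE), 0.15)
})

test_that("normalize_series divides by the reference magnitude", {
  expect_equal(normalize_series(c(-2, -4), -4), c(-0.5, -1))
  expect_equal(normalize_series(c(1, 2), 4), 0.5 * normalize_series(c(1, 2), 2))
  expect_error(normalize_series(1:3, 0), "nonzero")
})

test_that("per-cell fitting averages parameters across cells", {
  conc <- 3 * 10^seq(-1.2, 1.2, length.out = 6)
  tabs <- lapply(1:4, function(i) {
    s <- generate_dose_response(3, 1.1, response_type = "activation",
                                concentrations = conc, noise_sigma = 0.04,
                                seed = 100 + i)
    data.frame(conc_um = s$concentrations, response = s$responses,
               cell_id = paste0("cell", i))
  })
  res <- fit_dose_response_by_cell(do.call(rbind, tabs), "activation")
  expect_equal(nrow(res$per_cell), 4)
  expect_equal(res$summary$n, rep(4, 3))
  expect_equal(res$summary$mean[res$summary$parameter == "ec50_or_ic50"],
               3, tolerance = 0.15)
  pooled <- fit_dose_response_by_cell(do.call(rbind, tabs), "activation",
                                      pooled = TRUE)
  expect_s3_class(pooled, "hill_fit")
})
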