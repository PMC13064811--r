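test_that("EM recovers the generating mixture and the pyknotic fraction", {
  s <- generate_nuclei(means = c(40, 90), sds = c(8, 15),
                       weights = c(0.3, 0.7), n = 2000, seed = 21)
  fit <- fit_two_gaussian(s, seed = 21)
  expect_true(fit$converged)
  expect_equal(fit$weights[1], 0.3, tolerance = 0.1)
  expect_lt(abs(fit$means[1] - 40), 2)
  expect_lt(abs(fit$means[2] - 90), 2)
  cl <- classify_nuclei(fit, s$areas)
  # compare against the realized label fraction of this draw
  expect_lt(abs(cl$pyknotic_fraction -
                  mean(s$true_labels == "pyknotic")), 0.03)
  # against ground-truth labels most assignments agree
  expect_gt(mean(cl$labels == s$true_labels), 0.9)
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  s <- generate_nuclei(n = 1500, seed = 5)
  fit <- fit_two_gaussian(s, seed = 5)
  ref <- Mclust(s$areas, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$means), sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.01)
  expect_equal(fit$loglik, ref$loglik, tolerance = 1e-4)
})

test_that("posteriors normalize and classification is translation-equivariant", {
  s <- generate_nuclei(n = 800, seed = 9)
  fit <- fit_two_gaussian(s, seed = 9)
  p <- posterior_pyknotic(fit, s$areas)
  expect_equal(unname(rowSums(p)), rep(1, length(s$areas)))
  cl <- classify_nuclei(fit, s$areas)

  shift <- 500
  s2 <- list(areas = s$areas + shift)
  fit2 <- fit_two_gaussian(s2, seed = 9)
  expect_equal(fit2$means, fit$means + shift, tolerance = 1e-3)
  expect_equal(fit2$weights, fit$weights, tolerance = 1e-5)
  cl2 <- classify_nuclei(fit2, s2$areas)
  expect_identical(cl2$labels, cl$labels)
  expect_equal(cl2$pyknotic_fraction, cl$pyknotic_fraction)
})

test_that("permuting input order leaves the fitted parameters unchanged", {
  s <- generate_nuclei(n = 600, seed = 13)
  fit <- fit_two_gaussian(s, seed = 13)
  set.seed(1)
  perm <- sample(length(s$areas))
  fit_p <- fit_two_gaussian(list(areas = s$areas[perm]), seed = 13)
  expect_equal(fit_p$means, fit$means, tolerance = 1e-6)
  expect_equal(fit_p$weights, fit$weights, tolerance = 1e-6)
})

test_that("equal-sd mixtures have the closed-form posterior crossover", {
  fit <- structure(list(means = c(40, 90), sds = c(10, 10),
                        weights = c(0.5, 0.5)), class = "pyknosis_fit")
  # equal weights, equal sds: crossover at the midpoint of the means
  p_lo <- classify_nuclei(fit, 64.9)$labels
  p_hi <- classify_nuclei(fit, 65.1)$labels
  expect_identical(p_lo, "pyknotic")
  expect_identical(p_hi, "nonpyknotic")
  # exact tie assigns nonpyknotic (conservative toward survival)
  expect_identical(classify_nuclei(fit, 65)$labels, "nonpyknotic")
})

test_that("single-population and undersized samples are handled", {
  set.seed(2)
  one <- list(areas = stats::rnorm(400, 70, 0.5))
  fit <- fit_two_gaussian(one, seed = 2)  # regularized, must not error
  expect_true(all(fit$sds > 0))
  expect_error(fit_two_gaussian(list(areas = stats::runif(10, 1, 2))),
               "insufficient")
  expect_error(fit_two_gaussian(list(areas = c(rep(1, 60), -1))), "positive")
})

test_that("pooled-model conditions are classified against one mixture", {
  ctrl <- generate_nuclei(weights = c(0.1, 0.9), n = 700, seed = 31)
  test <- generate_nuclei(weights = c(0.5, 0.5), n = 700, seed = 32)
  tab <- rbind(data.frame(area_um2 = ctrl$areas, condition = "control"),
               data.frame(area_um2 = test$areas, condition = "nmda"))
  res <- pyknosis_by_condition(tab, seed = 1)
  fr <- res$fractions
  expect_equal(sort(fr$condition), c("control", "nmda"))
  expect_lt(fr$pyknotic_fraction[fr$condition == "control"],
            fr$pyknotic_fraction[fr$condition == "nmda"])
  expect_lt(abs(fr$pyknotic_fraction[fr$condition == "nmda"] - 0.5), 0.06)
})
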