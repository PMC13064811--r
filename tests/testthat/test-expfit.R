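test_that("weighted_tau is the amplitude-weighted mean of the taus", {
  expect_equal(weighted_tau(0.3, 7, 0.3, 2), 0.3)
  expect_equal(weighted_tau(0.1, 5, 0.5, 5), 0.3)
  expect_equal(weighted_tau(0.1, 3, 0.5, 1), 0.2)
  # bounded by the two taus for random admissible amplitudes
  set.seed(4)
  for (i in 1:25) {
    tf <- stats::runif(1, 0.01, 0.3)
    ts <- tf * stats::runif(1, 1, 20)
    a <- -stats::runif(2, 0.1, 10)
    tw <- weighted_tau(tf, a[1], ts, a[2])
    expect_gte(tw, tf)
    expect_lte(tw, ts)
  }
  expect_error(weighted_tau(0.1, 1, 0.5, -1), "share sign")
  expect_error(weighted_tau(-0.1, 1, 0.5, 1), "positive")
})

test_that("noiseless exponentials are recovered to optimizer tolerance", {
  t <- seq(0, 2, by = 5e-4)
  # single
  f1 <- fit_exponential(data.frame(time_s = t,
                                   current_pA = 5 - 80 * exp(-t / 0.2)))
  expect_equal(f1$n_components, 1L)
  expect_equal(f1$tau_w, 0.2, tolerance = 1e-4)
  expect_equal(f1$offset, 5, tolerance = 1e-3)
  # double, taus separated 8x
  y2 <- 2 - 50 * exp(-t / 0.05) - 30 * exp(-t / 0.4)
  f2 <- fit_exponential(data.frame(time_s = t, current_pA = y2))
  expect_equal(f2$n_components, 2L)
  expect_equal(f2$tau_fast, 0.05, tolerance = 1e-3)
  expect_equal(f2$tau_slow, 0.4, tolerance = 1e-3)
  expect_equal(f2$tau_w, weighted_tau(0.05, -50, 0.4, -30), tolerance = 1e-3)
  # flat window errors
  expect_error(fit_exponential(data.frame(time_s = t,
                                          current_pA = rep(3, length(t)))),
               "degenerate")
})

test_that("tau estimates are shift- and scale-equivariant", {
  t <- seq(0, 1.5, by = 1e-3)
  set.seed(9)
  y <- 1 - 60 * exp(-t / 0.15) + stats::rnorm(length(t), sd = 0.5)
  f <- fit_exponential(data.frame(time_s = t, current_pA = y))
  f_shift <- fit_exponential(data.frame(time_s = t + 10, current_pA = y))
  f_scale <- fit_exponential(data.frame(time_s = t, current_pA = 3 * y))
  expect_equal(f_shift$tau_w, f$tau_w, tolerance = 1e-8)
  expect_equal(f_scale$tau_w, f$tau_w, tolerance = 1e-6)
  expect_equal(f_scale$a_fast, 3 * f$a_fast, tolerance = 1e-6)
})

test_that("peak and steady-state measurement recovers generator truth", {
  tr <- generate_trace(po = 0.1, extent_D = 0.5, tau_d = 0.4,
                       noise_sigma = 0, seed = 1,
                       protocol = trace_protocol(agonist = c(0.3, 4),
                                                 blocker = NULL,
                                                 noise_sigma = 0))
  ps <- measure_peak_steady(tr)
  expect_lte(abs(ps$i_max), abs(ps$i_peak))
  expect_false(ps$below_noise)
  # corrected desensitization measurement: inverting the steady/peak ratio
  # through the gating equilibrium at the true ko recovers the extent
  des <- measure_desensitization(tr, exchange_tau = 0.017)
  r <- 0.1 / 0.9                      # true ko / kc
  q <- (1 + r) * (1 - des$ratio) / des$ratio
  expect_equal(q / (1 + q), 0.5, tolerance = 0.04)
  expect_equal(des$tau_d, 1 / (1.25 + 1.25 * 250 / (250 + 250 * r)),
               tolerance = 0.03)      # slow eigenvalue of D<->C<->O

  # non-desensitizing trace: peak equals steady state within noise
  tr0 <- generate_trace(po = 0.1, extent_D = 0, noise_sigma = 0.005,
                        seed = 2,
                        protocol = trace_protocol(agonist = c(0.3, 4),
                                                  blocker = NULL))
  ps0 <- measure_peak_steady(tr0)
  expect_equal(abs(ps0$i_max) / abs(ps0$i_peak), 1, tolerance = 0.03)

  # baseline-only trace flagged below the noise floor
  set.seed(3)
  flat <- current_trace(seq(0, 2, by = 5e-4),
                        stats::rnorm(4001, sd = 2),
                        data.frame(name = "agonist", start_s = 0.5,
                                   end_s = 2, solution = "agonist",
                                   conc_um = NA))
  psf <- measure_peak_steady(flat)
  expect_true(psf$below_noise)
})

test_that("blocker onset tau responds to concentration and matches the
           eigenvalue oracle without desensitization", {
  # no desensitization, Po = 0.5, kb' = 25 /s
  sch <- gating_scheme(kd = 0, kr = 1, ko = 250, kc = 250, kb = 25,
                       blocker_conc = 1)
  pr <- trace_protocol(agonist = c(0.3, 2.5), blocker = c(0.8, 2.5),
                       noise_sigma = 0)
  tr <- generate_trace(scheme = sch, protocol = pr, seed = 1)
  # skip the solution-exchange ramp so the decay is single-exponential
  fit <- blocker_onset_tau(tr, start_offset_s = 0.1)
  # with kd = 0 the desensitized state is decoupled and unoccupied; the
  # relevant modes are those of the C, O, B block
  ev <- eigen(rate_matrix(sch)[2:4, 2:4])$values
  slow <- min(abs(Re(ev[abs(Re(ev)) > 1e-9])))
  expect_equal(1 / fit$tau_w, slow, tolerance = 0.02)

  # halving the blocker concentration slows the onset
  sch_half <- gating_scheme(kd = 0, kr = 1, ko = 250, kc = 250, kb = 25,
                            blocker_conc = 0.5)
  pr_half <- trace_protocol(agonist = c(0.3, 4.5), blocker = c(0.8, 4.5),
                            blocker_conc = 0.5, noise_sigma = 0)
  tr_half <- generate_trace(scheme = sch_half, protocol = pr_half, seed = 1)
  expect_gt(blocker_onset_tau(tr_half)$tau_w, fit$tau_w)

  # no blocker -> flat segment, no decay to fit
  sch0 <- gating_scheme(kd = 0, kr = 1, ko = 250, kc = 250, kb = 25,
                        blocker_conc = 0)
  trf <- generate_trace(scheme = sch0, protocol = pr, seed = 1)
  ep0 <- rbind(trf$epochs,
               data.frame(name = "blocker", start_s = 0.8, end_s = 2.5,
                          solution = "blocker", conc_um = 0))
  tr0 <- current_trace(trf$time, trf$current, ep0)
  expect_error(blocker_onset_tau(tr0), "degenerate")
})

test_that("memantine kinetics recover generator on/off rates", {
  pr <- trace_protocol(agonist = c(0.3, 12), blocker = c(2, 6),
                       noise_sigma = 0.01)
  tr <- generate_reversible_block_trace(on_rate = 2, off_rate = 1.25,
                                        protocol = pr, seed = 5)
  mk <- memantine_kinetics(tr)
  expect_false(mk$partial)
  expect_equal(mk$tau_on, 0.5, tolerance = 0.05)
  expect_equal(mk$tau_off, 0.8, tolerance = 0.05)
  expect_lt(mk$tau_on, mk$tau_off)

  # symmetric rates give tau_on ~ tau_off within 5%
  tr_sym <- generate_reversible_block_trace(on_rate = 1.5, off_rate = 1.5,
                                            protocol = pr, seed = 6)
  mk_sym <- memantine_kinetics(tr_sym)
  expect_equal(mk_sym$tau_on / mk_sym$tau_off, 1, tolerance = 0.05)

  # no wash segment -> partial result
  pr_nw <- trace_protocol(agonist = c(0.3, 6), blocker = c(2, 6),
                          noise_sigma = 0.01)
  tr_nw <- generate_reversible_block_trace(protocol = pr_nw, seed = 7)
  mk_nw <- memantine_kinetics(tr_nw)
  expect_true(mk_nw$partial)
  expect_true(is.na(mk_nw$tau_off))
})
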