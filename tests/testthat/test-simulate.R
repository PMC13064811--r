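test_that("trajectories conserve occupancy and match the matrix exponential", {
  set.seed(11)
  tg <- seq(0, 2, by = 0.01)
  for (i in 1:20) {
    sch <- random_scheme()
    init <- c(0, 1, 0, 0)
    ode <- simulate_scheme(sch, tg, init, method = "ode")
    ref <- simulate_scheme(sch, tg, init, method = "matexp")
    expect_lt(max(abs(as.matrix(ode[, -1]) - as.matrix(ref[, -1]))), 1e-6)
    expect_lt(max(abs(rowSums(ode[, -1]) - 1)), 1e-8)
  }
})

test_that("the unblocked equilibrium is stationary and block absorbs", {
  sch <- scheme_mk801(po = 0.2, extent = 0.4)
  tg <- seq(0, 1, by = 0.005)
  # no blocker: start at equilibrium, stay there
  sch0 <- gating_scheme(kd = sch$kd, kr = sch$kr, ko = sch$ko, kc = sch$kc,
                        kb = 25, blocker_conc = 0)
  ss <- steady_state_unblocked(sch0)
  tr <- simulate_scheme(sch0, tg, ss)
  expect_lt(max(abs(as.matrix(tr[, -1]) -
                      matrix(ss, nrow(tr), 4, byrow = TRUE))), 1e-7)
  # with blocker: B nondecreasing, O -> 0
  trb <- simulate_scheme(sch, seq(0, 30, by = 0.05), ss)
  expect_true(all(diff(trb$B) >= -1e-10))
  expect_lt(trb$O[nrow(trb)], 1e-4)
})

test_that("slow decay of O matches the smallest-magnitude eigenvalue, not
           the naive Po * kb' approximation", {
  # kd = 0 and kb' small against kc + ko
  sch <- gating_scheme(kd = 0, kr = 5, ko = 100, kc = 250, kb = 25,
                       blocker_conc = 0.4)  # kb' = 10 /s
  ss <- steady_state_unblocked(sch)
  tg <- seq(0, 5, by = 0.01)
  tr <- simulate_scheme(sch, tg, ss, method = "matexp")
  # empirical tail rate of O(t)
  tail_idx <- tr$time_s > 2
  rate_hat <- -stats::coef(stats::lm(log(tr$O[tail_idx]) ~
                                       tr$time_s[tail_idx]))[[2]]
  ev <- eigen(rate_matrix(sch))$values
  ev <- Re(ev[abs(Re(ev)) > 1e-9])
  slow <- min(abs(ev))
  expect_equal(rate_hat, slow, tolerance = 1e-3)
  naive <- po_from_ko(sch$ko, sch$kc) * sch$kb_eff
  # the naive rate overestimates: the exact eigenvalue is discernibly smaller
  expect_gt(abs(naive - slow) / slow, 0.01)
})

test_that("predicted_current is proportional to open occupancy", {
  sch <- scheme_mk801()
  tr <- simulate_scheme(sch, seq(0, 0.2, by = 0.001), c(0, 1, 0, 0))
  cur <- predicted_current(tr, scale = -100)
  expect_equal(cur$current_pA, -100 * tr$O)
  cur2 <- predicted_current(tr, scale = -200)
  expect_equal(cur2$current_pA, 2 * cur$current_pA)
  zero <- tr; zero$O <- 0
  expect_equal(predicted_current(zero, -100)$current_pA, rep(0, nrow(tr)))
  expect_error(predicted_current(tr[0, ], -100), "non-empty")
  expect_error(predicted_current(tr, 0), "nonzero")
})

test_that("simulate_scheme rejects malformed input", {
  sch <- scheme_mk801()
  expect_error(simulate_scheme(sch, c(0, 0.1, 0.05), c(0, 1, 0, 0)),
               "increasing")
  expect_error(simulate_scheme(sch, c(0, 0.1), c(0.5, 0.2, 0, 0)),
               "summing to 1")
})

test_that("the filtered blocker-onset path agrees with brute integration", {
  sch <- scheme_mk801(po = 0.15)
  te <- 0.017
  tt <- seq(0.002, 0.6, length.out = 120)
  hyb <- simulate_blocker_onset(sch, tt, exchange_tau = te)
  ss <- steady_state_unblocked(sch)
  rhs <- function(s, x, p) {
    kbe <- sch$kb_eff * (1 - exp(-s / te))
    list(as.vector(rate_matrix(sch, kb_eff = kbe) %*% x))
  }
  ref <- deSolve::lsoda(ss, c(0, tt), rhs, NULL, rtol = 1e-10, atol = 1e-12)
  # agreement at the integrator's own tolerance scale
  expect_lt(max(abs(hyb$O - ref[-1, 4])), 1e-5)
})
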