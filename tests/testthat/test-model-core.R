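test_that("dose response follows the affine laws and rejects bad doses", {
  dr <- dose_response(c(0, 0.4, 1))
  expect_equal(dr$K_TP, c(10000, 6040, 100))
  expect_equal(dr$mu, c(1.5, 1.1, 0.5))
  expect_error(dose_response(-0.1), "dose")
  expect_error(dose_response(1.2), "dose")
  # strictly decreasing in the dose
  grid <- dose_response(seq(0, 1, by = 0.05))
  expect_true(all(diff(grid$K_TP) < 0))
  expect_true(all(diff(grid$mu) < 0))
})

test_that("growth rates derive from doubling times", {
  expect_equal(growth_rate_from_doubling_time(60), 0.27726, tolerance = 1e-4)
  expect_equal(growth_rate_from_doubling_time(25), 0.66542, tolerance = 1e-4)
  expect_equal(growth_rate_from_doubling_time(48, scale = 1e-2), 3.4657e-3,
               tolerance = 1e-4)
  # the package defaults are exactly the scaled doubling-time rates
  expect_equal(default_params$r,
               growth_rate_from_doubling_time(c(60, 48, 25), scale = 1e-2),
               tolerance = 1e-4)
  expect_error(growth_rate_from_doubling_time(0), "positive")
  expect_error(growth_rate_from_doubling_time(10, scale = -1), "positive")
})

test_that("vector field vanishes on extinct or at-capacity components", {
  expect_equal(lv_vector_field(c(0, 0, 10000), 0.7), c(0, 0, 0))
  expect_equal(lv_vector_field(c(0, 0, 0), 0), c(0, 0, 0))
  # published two-species equilibrium is a fixed point at lam = 0.4
  rate <- lv_vector_field(c(2082.76, 5206.90, 0), 0.4)
  expect_lt(max(abs(rate)), 1e-2)
  rate_exact <- lv_vector_field(two_species_star(), 0.4)
  expect_lt(max(abs(rate_exact)), 1e-9)
})

test_that("T+ collapses without producer cells", {
  p <- default_params
  rate <- lv_vector_field(c(100, p$tp_floor / 2, 0), 0, p)
  expect_lt(rate[1], -1)  # strongly negative: K_T+ has hit the floor
})

test_that("parameter validation enforces model invariants", {
  expect_error(lv_params(r = c(-1, 1, 1) * 1e-3), "positive")
  A <- default_params$A; A[3, 2] <- -0.5
  expect_error(lv_params(A = A), "non-negative")
  expect_error(lv_params(K_TP_law = c(100, -9900)), "K_TP_law")
  expect_error(lv_params(mu_law = c(0.9, -1)), "mu_law")
})

test_that("parameters round-trip through YAML and JSON", {
  p <- lv_params(viability_cap = 8500)
  for (ext in c(".yaml", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    write_lv_params(p, f)
    q <- read_lv_params(f)
    expect_equal(q$A, p$A)
    expect_equal(q$viability_cap, 8500)
    expect_equal(q$r, p$r)
  }
})

test_that("a fixed point of the flow stays fixed over the full horizon", {
  xs <- two_species_star()
  traj <- simulate_tumor(xs, 0.4, tf = 10000)
  expect_state_equal(unlist(tail(traj, 1)[, c("x_Tplus", "x_TP", "x_Tminus")]),
                     xs, tol = NULL)
  expect_lt(max(abs(tail(traj, 1)$x_Tplus - xs[1]),
                abs(tail(traj, 1)$x_TP - xs[2])), 0.1)
  expect_true(is.na(breach_time(traj)))
})

test_that("a pure T- tumor follows the closed-form logistic curve", {
  p <- default_params
  r <- p$r[3]; K <- p$K_Tminus; x0 <- 100
  traj <- simulate_tumor(c(0, 0, x0), 0, tf = 3000)
  analytic <- K * x0 * exp(r * traj$t) / (K + x0 * (exp(r * traj$t) - 1))
  expect_lt(max(abs(traj$x_Tminus - analytic) / analytic), 1e-4)
  # breach when the logistic curve crosses the cap
  t_star <- log((p$viability_cap / x0) * (K - x0) / (K - p$viability_cap)) / r
  expect_lt(abs(breach_time(traj) - t_star) / t_star, 0.01)
})

test_that("maximum dose drives a mixed tumor to resistant takeover", {
  traj <- simulate_tumor(c(3000, 3000, 2900), 1, tf = 10000,
                         stop_on_breach = TRUE)
  bt <- breach_time(traj)
  expect_false(is.na(bt))
  final <- tail(traj, 1)
  expect_gt(final$x_Tminus / final$total_volume, 0.8)
})

test_that("densities stay non-negative under arbitrary schedules", {
  set.seed(42)
  for (i in 1:5) {
    x0 <- runif(3, 0, 3000)
    sched <- dose_schedule(seq(0, 9000, by = 1000),
                           sample(seq(0, 1, by = 0.1), 10, replace = TRUE))
    traj <- simulate_tumor(x0, sched, tf = 10000)
    expect_true(all(traj$x_Tplus >= 0 & traj$x_TP >= 0 & traj$x_Tminus >= 0))
  }
})

test_that("dose schedules are right-continuous step functions", {
  sched <- dose_schedule(c(0, 500, 1000), c(0, 0.2, 0.4))
  expect_equal(dose_at(sched, c(-5, 0, 499, 500, 999, 1000, 5000)),
               c(0, 0, 0, 0.2, 0.2, 0.4, 0.4))
  expect_error(dose_schedule(c(0, 0), c(0, 1)), "increasing")
  expect_error(dose_schedule(0, 1.5), "dose")
})

test_that("analytic and finite-difference Jacobians agree", {
  set.seed(7)
  for (i in 1:10) {
    x <- runif(3, 0, 5000)
    lam <- runif(1)
    Ja <- lv_jacobian(x, lam)
    Jf <- lv_jacobian(x, lam, finite_diff = TRUE)
    expect_lt(max(abs(Ja - Jf)) / max(abs(Ja)), 1e-5)
  }
})
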