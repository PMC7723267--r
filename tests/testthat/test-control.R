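test_that("running cost is squared distance to the target", {
  xs <- c(3, 4, 0)
  expect_equal(running_cost(xs, xs), 0)
  expect_equal(running_cost(xs + c(1, 0, 0), xs), 1)
  expect_equal(running_cost(c(0, 0, 0), xs), 25)
  expect_equal(running_cost(rbind(xs, c(0, 0, 0)), xs), c(0, 25))
})

test_that("costates satisfy transversality and vanish on equilibrium paths", {
  xs <- two_species_star()
  traj <- simulate_tumor(xs, 0.4, tf = 500)
  cs <- costate_backward(traj, xs)
  expect_equal(unlist(tail(cs, 1)[, -1]), c(costate_Tplus = 0,
                                            costate_TP = 0,
                                            costate_Tminus = 0))
  expect_lt(max(abs(as.matrix(cs[, -1]))), 1e-6)
  # transversality holds for any trajectory
  traj2 <- simulate_tumor(c(2000, 3000, 1000), 0.7, tf = 500)
  cs2 <- costate_backward(traj2, xs)
  expect_equal(as.numeric(tail(cs2, 1)[, -1]), c(0, 0, 0))
})

test_that("analytic and finite-difference costate sweeps agree", {
  xs <- two_species_star()
  traj <- simulate_tumor(c(2500, 2500, 1500), 0.2, tf = 1000)
  ca <- as.matrix(costate_backward(traj, xs)[, -1])
  cf <- as.matrix(costate_backward(traj, xs, gradient = "fd")[, -1])
  expect_lt(max(abs(ca - cf)) / max(abs(ca)), 1e-3)
})

test_that("pointwise dose minimizer matches a brute-force scan", {
  p <- default_params
  grid <- seq(0, 1, length.out = 1e5)
  ham <- function(state, cs, lam) {
    f <- vapply(lam, function(l) {
      sum(cs * lv_vector_field(state, l, p))
    }, numeric(1))
    f  # the running cost does not depend on the dose
  }
  set.seed(3)
  for (i in 1:8) {
    state <- runif(3, 10, 6000)
    cs <- runif(3, -1, 1) * 10^sample(-2:2, 1)
    lam_hat <- pointwise_dose_minimizer(state, cs, p)
    h_hat <- ham(state, cs, lam_hat)
    h_min <- min(ham(state, cs, grid))
    scale <- max(abs(h_min), 1)
    expect_lte(h_hat, h_min + 1e-9 * scale)
  }
})

test_that("dose-independent Hamiltonians return the tie-break value", {
  expect_equal(pointwise_dose_minimizer(c(100, 100, 100), c(0, 0, 0)), 0)
  expect_equal(pointwise_dose_minimizer(c(100, 100, 100), c(0, 0, 0),
                                        prev = 0.37), 0.37)
})

test_that("negative TP costate below capacity pulls the dose to zero", {
  # maximizing producer growth requires maximal K_TP, hence no drug
  state <- c(100, 2000, 500)
  lam <- pointwise_dose_minimizer(state, c(0, -1, 0))
  expect_equal(lam, 0)
})

test_that("the target equilibrium is a fixed point of the FBS map", {
  xs <- two_species_star()
  sol <- fbs_solve(control_problem(xs, xs), control_init = 0.4)
  expect_true(sol$converged)
  expect_lt(sol$objective, 1e-3 * 10000)
  expect_equal(unique(round(sol$path$control, 6)), 0.4)
})

test_that("FBS produces a rising titration-shaped schedule", {
  xs <- two_species_star()
  sol <- fbs_solve(control_problem(c(4000, 4000, 500), xs), max_iter = 100)
  u <- sol$path$control
  n <- length(u)
  early <- mean(u[1:500])
  late <- mean(u[(n - 600):(n - 100)])
  expect_lt(early, late)           # rises over the horizon
  expect_lt(abs(late - 0.4), 0.05) # stabilizes at the equilibrium dose
  expect_true(all(u >= 0 & u <= 1))
  # objective non-increase across accepted iterations (0.1% guard)
  oh <- sol$objective_history
  expect_true(all(diff(oh) <= 1e-3 * oh[-length(oh)] + 1e-9))
})

test_that("ensemble control summaries use sample standard deviation", {
  fake <- function(u) {
    structure(list(path = tibble::tibble(t = 0:10, control = u),
                   converged = TRUE),
              class = "control_solution")
  }
  em <- ensemble_mean_control(list(fake(0.2), fake(0.6)))
  expect_equal(unique(em$mean_control), 0.4)
  expect_equal(unique(em$sd_control), sqrt(0.08))  # sample SD convention
  # identical members have zero spread
  em0 <- ensemble_mean_control(list(fake(0.3), fake(0.3)))
  expect_equal(unique(em0$sd_control), 0)
  expect_error(ensemble_mean_control(list()), "empty")
  # mismatched grids are rejected
  other <- fake(0.2); other$path$t <- other$path$t + 1
  expect_error(ensemble_mean_control(list(fake(0.2), other)), "grid")
})
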