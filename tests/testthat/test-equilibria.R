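test_that("candidate equilibria contain the known states at lam = 0.4", {
  eq <- candidate_equilibria(0.4)
  ts <- dplyr::filter(eq, support == "T+,TP")
  expect_equal(nrow(ts), 1)
  expect_equal(ts$x_Tplus, 2082.76, tolerance = 1e-4)
  expect_equal(ts$x_TP, 5206.90, tolerance = 1e-4)
  mono <- dplyr::filter(eq, support == "T-")
  expect_equal(mono$x_Tminus, 10000)
  # every candidate is a true equilibrium of the flow
  resid <- purrr::pmap_dbl(eq[, c("x_Tplus", "x_TP", "x_Tminus")],
                           function(x_Tplus, x_TP, x_Tminus)
                             max(abs(lv_vector_field(c(x_Tplus, x_TP, x_Tminus),
                                                     0.4))))
  expect_lt(max(resid), 1e-8)
})

test_that("the interior equilibrium solves the three-species linear system", {
  # independent oracle: direct 3x3 solve at lam = 0.4848
  lam <- 0.4848
  p <- default_params
  mu <- 1.5 - lam
  K2 <- 10000 - 9900 * lam
  M <- rbind(c(1, 0.7 - mu, 0.8), c(0.4, 1, 0.6), c(0.5, 2, 1))
  oracle <- solve(M, c(0, K2, 10000))
  eq <- candidate_equilibria(lam, p)
  int <- dplyr::filter(eq, support == "T+,TP,T-")
  expect_equal(c(int$x_Tplus, int$x_TP, int$x_Tminus), oracle,
               tolerance = 1e-10)
  expect_equal(oracle, c(961.4, 4478.3, 562.8), tolerance = 1e-3)
})

test_that("stability classification recovers the invasion analysis", {
  # resistant monoculture: stable above the invasion threshold, not below
  expect_true(stability_classify(c(0, 0, 10000), 0.5)$stable)
  expect_false(stability_classify(c(0, 0, 10000), 0.3)$stable)
  # two-species equilibrium stable at its own dose
  expect_true(stability_classify(two_species_star(), 0.4)$stable)
  # non-equilibrium input is rejected
  expect_error(stability_classify(c(500, 500, 500), 0.4), "not an equilibrium")
})

test_that("the dose sweep reproduces the stable-branch structure", {
  sw <- sweep_equilibria(c(0.1, 0.4, 0.6))
  at <- function(l) dplyr::filter(sw, lam == l, stable)
  # lam = 0.4: exactly one stable viable record, the two-species branch
  s4 <- at(0.4)
  expect_equal(nrow(dplyr::filter(s4, viable)), 1)
  expect_equal(dplyr::filter(s4, viable)$support, "T+,TP")
  # lam = 0.6: the resistant monoculture is stable but beyond the cap
  s6 <- at(0.6)
  expect_true(any(s6$support == "T-" & s6$total == 10000 & !s6$viable))
  # lam = 0.1: the two-species branch exists but exceeds the cap
  s1 <- dplyr::filter(at(0.1), support == "T+,TP")
  expect_gt(s1$total, 9000)
  expect_false(s1$viable)
  expect_equal(s1$x_TP, 9010 / 1.28, tolerance = 1e-6)
})

test_that("at most one stable equilibrium carries producer cells per dose", {
  sw <- sweep_equilibria(seq(0, 1, by = 0.02))
  with_tp <- dplyr::filter(sw, stable, grepl("TP", support))
  counts <- dplyr::count(with_tp, lam)
  expect_true(all(counts$n <= 1))
})

test_that("analytic thresholds match their closed forms and the sweep", {
  th <- analytic_thresholds()
  expect_equal(th$lam_Tminus_mono, 4000 / 9900, tolerance = 1e-10)
  # quadratic roots computed independently
  bif_oracle <- min(Re(polyroot(c(1080, -2476, 495))))
  lo_oracle <- min(Re(polyroot(c(306, -1211, 495))))
  expect_equal(th$lam_bifurcation, bif_oracle, tolerance = 1e-8)
  expect_equal(th$viability_lo, lo_oracle, tolerance = 1e-8)
  expect_gt(th$viability_hi, th$lam_bifurcation)

  # empirical stability flips agree with the closed forms to grid spacing
  grid <- seq(0.40, 0.49, by = 1e-3)
  sw <- sweep_equilibria(grid)
  mono_stable <- dplyr::filter(sw, support == "T-", stable)
  expect_equal(min(mono_stable$lam), 0.405, tolerance = 1e-9)
  expect_lt(abs(min(mono_stable$lam) - th$lam_Tminus_mono), 1e-3 + 1e-9)
  two_stable <- dplyr::filter(sw, support == "T+,TP", stable)
  expect_lt(abs(max(two_stable$lam) - th$lam_bifurcation), 1e-3 + 1e-9)
  three_stable <- dplyr::filter(sw, support == "T+,TP,T-", stable)
  expect_equal(min(three_stable$lam), 0.483, tolerance = 1e-9)
  expect_lt(abs(max(three_stable$lam) - th$viability_hi), 1e-3 + 1e-9)
})

test_that("stable viable equilibria attract perturbed trajectories", {
  sw <- sweep_equilibria(c(0.3, 0.4, 0.45, 0.4848))
  recs <- dplyr::filter(sw, stable, viable)
  expect_gt(nrow(recs), 0)
  # horizon 1e5: the branch eigenvalues shrink to O(1e-5) near the upper
  # window endpoint, so relaxation from a 1% kick is slow there
  for (i in seq_len(nrow(recs))) {
    xs <- c(recs$x_Tplus[i], recs$x_TP[i], recs$x_Tminus[i])
    traj <- simulate_tumor(xs * 1.01, recs$lam[i], tf = 1e5, dt = 1)
    xf <- unlist(tail(traj, 1)[, c("x_Tplus", "x_TP", "x_Tminus")])
    expect_lt(max(abs(xf - xs)), 0.5)
  }
})
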