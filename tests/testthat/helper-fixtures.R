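# Shared fixtures: default parameters and the reference stable equilibria.
default_params <- lv_params()

# two-species T+/TP equilibrium at lam = 0.4 (exact closed form)
two_species_star <- function(lam = 0.4, p = default_params) {
  dr <- dose_response(lam, p)
  d <- dr$mu - p$A[1, 2]
  x2 <- dr$K_TP / (1 + p$A[2, 1] * d)
  c(d * x2, x2, 0)
}

expect_state_equal <- function(x, y, tol = 1e-6) {
  expect_equal(as.numeric(x), as.numeric(y), tolerance = tol)
}
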