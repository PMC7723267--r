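#' Piecewise-constant dose schedule
#'
#' A dosing schedule is a right-continuous step function of time: the dose
#' `doses[i]` applies from `times[i]` until the next breakpoint.
#'
#' @param times Strictly increasing breakpoint times.
#' @param doses Dose fractions in `[0, 1]`, one per breakpoint.
#' @return An object of class `dose_schedule`.
#' @examples
#' sched <- dose_schedule(c(0, 500, 1000), c(0, 0.2, 0.4))
#' dose_at(sched, c(0, 499, 500, 2000))
#' @export
dose_schedule <- function(times, doses) {
  times <- as.numeric(times)
  doses <- as.numeric(doses)
  stopifnot(length(times) == length(doses), length(times) >= 1)
  if (is.unsorted(times, strictly = TRUE))
    stop("breakpoint times must be strictly increasing", call. = FALSE)
  check_dose(doses)
  structure(list(times = times, doses = doses), class = "dose_schedule")
}

#' @rdname dose_schedule
#' @param schedule A `dose_schedule`.
#' @param t Times at which to evaluate the schedule.
#' @export
dose_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "dose_schedule"))
  idx <- findInterval(t, schedule$times, rightmost.closed = FALSE)
  schedule$doses[pmax(idx, 1L)]
}

as_schedule <- function(dose) {
  if (inherits(dose, "dose_schedule")) return(dose)
  if (is.numeric(dose) && length(dose) == 1) return(dose_schedule(0, dose))
  stop("dose must be a scalar or a dose_schedule", call. = FALSE)
}

#' Lotka-Volterra vector field of the tumor model
#'
#' Instantaneous density rates \eqn{\dot x_i = r_i x_i (1 - \sum_j
#' \alpha_{ij} x_j / K_i)} with dose-dependent carrying capacities:
#' `K_T+ = mu(lam) * max(x_TP, tp_floor)`, `K_TP = K_TP(lam)` and constant
#' `K_T-`.
#'
#' @param state Length-3 non-negative densities `(T+, TP, T-)`.
#' @param lam Dose fraction in `[0, 1]`.
#' @param params An [lv_params()] object.
#' @return Length-3 numeric vector of rates.
#' @examples
#' lv_vector_field(c(2082.76, 5206.90, 0), 0.4)
#' @export
lv_vector_field <- function(state, lam, params = lv_params()) {
  state <- check_state(state)
  check_dose(lam)
  as.numeric(cpp_vector_field(state, lam, params))
}

#' Jacobian of the regularized vector field
#'
#' @inheritParams lv_vector_field
#' @param finite_diff Use central finite differences
#'   (`h = 1e-4 * max(1, x_i)`) instead of the analytic derivatives; the two
#'   routes cross-validate each other.
#' @return 3x3 numeric matrix.
#' @export
lv_jacobian <- function(state, lam, params = lv_params(), finite_diff = FALSE) {
  state <- check_state(state)
  check_dose(lam)
  cpp_jacobian(state, lam, params, finite_diff)
}

#' Simulate tumor dynamics under a dosing schedule
#'
#' Integrates the model with a fixed-step fourth-order Runge-Kutta scheme on
#' a uniform grid. Densities are clipped at zero and clones whose density
#' falls below `extinction_snap` are set extinct. The total burden is checked
#' against the viability cap at every step; the first grid time where it is
#' exceeded is recorded as `breach_time`.
#'
#' @param x0 Initial densities `(T+, TP, T-)`.
#' @param dose A constant dose fraction or a [dose_schedule()].
#' @param t0,tf Start and end of the integration window (model time units).
#' @param dt Step size; the default 1 resolves rates of order `1e-3` easily.
#' @param stop_on_breach Stop integrating once the viability cap is exceeded.
#' @param params An [lv_params()] object.
#' @return A tibble of class `lv_trajectory` with columns `t`, `x_Tplus`,
#'   `x_TP`, `x_Tminus`, `dose`, `total_volume`, and attribute `breach_time`
#'   (`NA` if the cap is never exceeded).
#' @examples
#' traj <- simulate_tumor(c(1000, 4000, 500), dose = 0.4, tf = 2000)
#' breach_time(traj)
#' @export
simulate_tumor <- function(x0, dose, t0 = 0, tf = 10000, dt = 1,
                           stop_on_breach = FALSE, params = lv_params()) {
  x0 <- check_state(x0)
  if (t0 >= tf) stop("t0 must be earlier than tf", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  sched <- as_schedule(dose)
  res <- cpp_simulate(x0, sched$times, sched$doses, t0, tf, dt, params,
                      stop_on_breach)
  new_trajectory(res$t, res$x, res$dose, res$breach_time)
}

new_trajectory <- function(t, x, dose, breach_time) {
  out <- tibble::tibble(
    t = as.numeric(t),
    x_Tplus = x[, 1], x_TP = x[, 2], x_Tminus = x[, 3],
    dose = as.numeric(dose))
  out$total_volume <- out$x_Tplus + out$x_TP + out$x_Tminus
  class(out) <- c("lv_trajectory", class(out))
  attr(out, "breach_time") <- breach_time
  out
}

#' @rdname simulate_tumor
#' @param traj An `lv_trajectory`.
#' @return `breach_time()` returns the first grid time at which the total
#'   burden exceeded the viability cap, or `NA`.
#' @export
breach_time <- function(traj) {
  attr(traj, "breach_time")
}

#' @exportS3Method ggplot2::autoplot
autoplot.lv_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("t", state_cols)],
    cols = dplyr::all_of(state_cols),
    names_to = "type", values_to = "density")
  long$type <- factor(long$type, levels = state_cols, labels = cell_types)
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$density,
                                     color = .data$type)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (model units)", y = "cell density",
                  color = "cell type") +
    ggplot2::theme_minimal()
}
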