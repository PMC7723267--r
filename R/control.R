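#' Reach-the-equilibrium optimal control problem
#'
#' Packages an initial tumor composition, a target stable equilibrium and a
#' time window into a control problem: find the dosing schedule
#' \eqn{\Lambda(t) \in [0,1]} minimizing the integrated squared distance of
#' the state from the target,
#' \deqn{\int_{t_0}^{t_f} \lVert x(t) - x^* \rVert^2 \, dt.}
#'
#' @param x0 Initial densities `(T+, TP, T-)`.
#' @param x_star Target equilibrium densities.
#' @param t0,tf Time window (model units).
#' @param params An [lv_params()] object.
#' @return An object of class `control_problem`.
#' @examples
#' xs <- c(2082.76, 5206.90, 0)
#' control_problem(c(4000, 4000, 500), xs, tf = 2000)
#' @export
control_problem <- function(x0, x_star, t0 = 0, tf = 10000,
                            params = lv_params()) {
  x0 <- check_state(x0)
  x_star <- check_state(x_star)
  if (t0 >= tf) stop("t0 must be earlier than tf", call. = FALSE)
  structure(list(x0 = x0, x_star = x_star, t0 = t0, tf = tf, params = params),
            class = "control_problem")
}

#' Running cost of the control objective
#'
#' Squared Euclidean distance of the state from the target equilibrium, the
#' integrand of the control objective.
#'
#' @param state Length-3 densities (or an n-by-3 matrix of states).
#' @param x_star Target densities.
#' @return Non-negative scalar (or vector, one per row).
#' @examples
#' running_cost(c(0, 0, 0), c(3, 4, 0))
#' @export
running_cost <- function(state, x_star) {
  if (is.matrix(state)) {
    unname(rowSums(sweep(state, 2, as.numeric(x_star))^2))
  } else {
    sum((as.numeric(state) - as.numeric(x_star))^2)
  }
}

#' Backward costate sweep along a trajectory
#'
#' Integrates the adjoint equations \eqn{\dot\lambda_i = -\partial H /
#' \partial x_i} backward from the transversality condition
#' \eqn{\lambda(t_f) = 0}, where the Hamiltonian is the running cost plus
#' the costate-weighted dynamics. The state-gradient of the dynamics
#' includes the dependence of the `T+` carrying capacity on the producer
#' density; analytic derivatives are the default, with a central
#' finite-difference route for cross-validation.
#'
#' @param traj An `lv_trajectory` (covering the full window, with its dose
#'   column).
#' @param x_star Target densities.
#' @param params An [lv_params()] object.
#' @param gradient `"analytic"` or `"fd"` Jacobian of the dynamics.
#' @return A tibble with columns `t`, `costate_Tplus`, `costate_TP`,
#'   `costate_Tminus`.
#' @export
costate_backward <- function(traj, x_star, params = lv_params(),
                             gradient = c("analytic", "fd")) {
  gradient <- match.arg(gradient)
  x_star <- check_state(x_star)
  X <- as.matrix(traj[, state_cols])
  L <- cpp_costate_backward(traj$t, X, traj$dose, x_star, params,
                            finite_diff = gradient == "fd")
  tibble::tibble(t = traj$t, costate_Tplus = L[, 1], costate_TP = L[, 2],
                 costate_Tminus = L[, 3])
}

#' Pointwise Hamiltonian-minimizing dose
#'
#' Returns the dose in `[0, 1]` minimizing the Hamiltonian at one state /
#' costate pair. Only the `T+` and `TP` drift terms depend on the dose
#' (through the symbiosis coefficient and the `TP` carrying capacity), so
#' the scan reduces to a one-dimensional minimization, performed on a dense
#' grid with golden-section refinement. A dose-independent Hamiltonian (for
#' instance a zero costate) returns the tie-break value: `prev` if supplied,
#' else 0.
#'
#' @param state Length-3 densities.
#' @param costate Length-3 adjoint values.
#' @param params An [lv_params()] object.
#' @param prev Previous control value used to break ties.
#' @param ngrid Number of grid points on `[0, 1]`.
#' @return A dose fraction.
#' @export
pointwise_dose_minimizer <- function(state, costate, params = lv_params(),
                                     prev = NULL, ngrid = 1001) {
  state <- check_state(state)
  cpp_pointwise_dose(state, as.numeric(costate),
                     if (is.null(prev)) NA_real_ else prev, params, ngrid)
}

#' Solve the control problem by Forward-Backward Sweep
#'
#' Alternates (i) forward state integration under the current control, (ii)
#' backward costate integration from the transversality condition, and
#' (iii) a relaxed pointwise Hamiltonian-minimizing control update
#' `u <- (1 - omega) u + omega u_min`, until the maximum absolute control
#' change falls below `tol` or `max_iter` is reached. Non-convergence is
#' reported through the `converged` flag, not an error.
#'
#' @param prob A [control_problem()].
#' @param omega Relaxation weight in `(0, 1]`.
#' @param tol Convergence threshold on the maximum absolute control change.
#' @param max_iter Iteration cap.
#' @param dt Grid step for both sweeps.
#' @param control_init Initial control guess: a scalar or a vector over the
#'   grid. The default 0 (no drug) reflects that optimal schedules start
#'   drug-free.
#' @param ngrid Grid size of the pointwise dose minimization.
#' @return An object of class `control_solution`: list with tibble `path`
#'   (`t`, states, costates, `control`), `objective`, `iterations`,
#'   `converged`, `objective_history`, and `objective_increases` (count of
#'   iterations whose objective rose by more than 0.1%).
#' @examples
#' xs <- c(2082.76, 5206.90, 0)
#' sol <- fbs_solve(control_problem(xs, xs, tf = 200))
#' glance(sol)
#' @export
fbs_solve <- function(prob, omega = 0.2, tol = 1e-3, max_iter = 500, dt = 1,
                      control_init = 0, ngrid = 1001) {
  stopifnot(inherits(prob, "control_problem"))
  if (omega <= 0 || omega > 1) stop("omega must be in (0, 1]", call. = FALSE)
  res <- cpp_fbs(prob$x0, prob$x_star, prob$params, prob$t0, prob$tf, dt,
                 omega, tol, max_iter, as.numeric(control_init), ngrid)
  path <- tibble::tibble(
    t = res$t,
    x_Tplus = res$x[, 1], x_TP = res$x[, 2], x_Tminus = res$x[, 3],
    costate_Tplus = res$costate[, 1], costate_TP = res$costate[, 2],
    costate_Tminus = res$costate[, 3],
    control = res$control)
  oh <- res$objective_history
  incr <- sum(diff(oh) > 1e-3 * pmax(oh[-length(oh)], .Machine$double.eps))
  structure(list(path = path, objective = res$objective,
                 iterations = res$iterations, converged = res$converged,
                 objective_history = oh, objective_increases = incr,
                 step_rejections = res$step_rejections,
                 problem = prob),
            class = "control_solution")
}

#' @export
print.control_solution <- function(x, ...) {
  cat("<control_solution> objective", format(x$objective, digits = 6),
      "| iterations", x$iterations,
      "| converged", x$converged, "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.control_solution <- function(x, ...) x$path

#' @exportS3Method generics::glance
glance.control_solution <- function(x, ...) {
  tibble::tibble(objective = x$objective, iterations = x$iterations,
                 converged = x$converged,
                 objective_increases = x$objective_increases)
}

#' @exportS3Method ggplot2::autoplot
autoplot.control_solution <- function(object, ...) {
  ggplot2::ggplot(object$path, ggplot2::aes(.data$t, .data$control)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (model units)", y = "abiraterone dose") +
    ggplot2::theme_minimal()
}

#' Pointwise mean and spread of an ensemble of optimal controls
#'
#' Averages the control paths of several solutions on their shared time
#' grid. The spread is the sample standard deviation (`n - 1` denominator).
#' Non-converged members are included and counted.
#'
#' @param solutions List of `control_solution` objects on a common grid.
#' @return A tibble with columns `t`, `mean_control`, `sd_control`,
#'   `n`, `n_converged`.
#' @export
ensemble_mean_control <- function(solutions) {
  if (length(solutions) == 0)
    stop("empty solution ensemble", call. = FALSE)
  grids <- purrr::map(solutions, function(s) s$path$t)
  if (!all(purrr::map_lgl(grids, identical, grids[[1]])))
    stop("solutions must share a time grid", call. = FALSE)
  U <- vapply(solutions, function(s) s$path$control,
              numeric(nrow(solutions[[1]]$path)))
  U <- matrix(U, ncol = length(solutions))
  tibble::tibble(
    t = grids[[1]],
    mean_control = rowMeans(U),
    sd_control = apply(U, 1, sd),
    n = length(solutions),
    n_converged = sum(purrr::map_lgl(solutions, `[[`, "converged")))
}
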