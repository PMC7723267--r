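#' Candidate equilibria of the model at a constant dose
#'
#' Enumerates every non-negative equilibrium over all feasible supports of
#' the three-species Lotka-Volterra system at constant dose `lam`: the
#' trivial state, the `T-` and `TP` monocultures, the `TP`/`T-` and
#' `T+`/`TP` pairs, and the interior three-species solution. Supports
#' containing `T+` without `TP` are infeasible, because the `T+` carrying
#' capacity is proportional to the producer density. Candidates with a
#' negative component, and supports whose linear system is singular, are
#' dropped.
#'
#' @param lam Dose fraction in `[0, 1]`.
#' @param params An [lv_params()] object.
#' @return A tibble with columns `lam`, `support` (e.g. `"T+,TP"`),
#'   `x_Tplus`, `x_TP`, `x_Tminus`.
#' @examples
#' candidate_equilibria(0.4)
#' @export
candidate_equilibria <- function(lam, params = lv_params()) {
  check_dose(lam)
  stopifnot(length(lam) == 1)
  A <- params$A
  dr <- dose_response(lam, params)
  K2 <- dr$K_TP
  K3 <- params$K_Tminus
  mu <- dr$mu

  cand <- list(c(0, 0, 0),
               c(0, 0, K3),
               c(0, K2, 0))
  # TP / T- pair: [a22, a23; a32, a33] (x2, x3) = (K2, K3)
  M <- matrix(c(A[2, 2], A[2, 3], A[3, 2], A[3, 3]), 2, 2, byrow = TRUE)
  sol <- try_solve(M, c(K2, K3))
  if (!is.null(sol)) cand <- c(cand, list(c(0, sol[1], sol[2])))
  # T+ / TP pair: x1 = (mu - a12) x2 (from K_T+ = mu x2) and a21 x1 + x2 = K2
  d <- mu - A[1, 2]
  den <- A[2, 2] + A[2, 1] * d
  if (abs(den) > 1e-12) {
    x2 <- K2 / den
    cand <- c(cand, list(c(d * x2, x2, 0)))
  }
  # interior: substitute K_T+ = mu x2 into the three balance conditions
  M3 <- rbind(c(A[1, 1], A[1, 2] - mu, A[1, 3]),
              c(A[2, 1], A[2, 2], A[2, 3]),
              c(A[3, 1], A[3, 2], A[3, 3]))
  sol <- try_solve(M3, c(0, K2, K3))
  if (!is.null(sol)) cand <- c(cand, list(sol))

  keep <- vapply(cand, function(x) all(x >= 0), logical(1))
  cand <- cand[keep]
  out <- tibble::tibble(
    lam = lam,
    support = vapply(cand, support_label, character(1),
                     tp_floor = params$tp_floor),
    x_Tplus = vapply(cand, `[`, numeric(1), 1),
    x_TP = vapply(cand, `[`, numeric(1), 2),
    x_Tminus = vapply(cand, `[`, numeric(1), 3))
  dplyr::distinct(out, .data$support, .keep_all = TRUE)
}

try_solve <- function(M, b) {
  out <- tryCatch(solve(M, b), error = function(e) NULL)
  if (is.null(out) || any(!is.finite(out))) return(NULL)
  out
}

support_label <- function(x, tp_floor) {
  pos <- x > tp_floor
  if (!any(pos)) return("none")
  paste(cell_types[pos], collapse = ",")
}

#' Classify the stability of an equilibrium
#'
#' Evaluates the Jacobian of the regularized vector field at `x_star` and
#' classifies the equilibrium by the eigenvalue real parts: stable when all
#' are negative, marginal when the largest real part sits within `margin` of
#' zero. For boundary equilibria the Jacobian row of an absent species
#' reduces to its invasion growth rate, so invasion analysis is recovered
#' automatically.
#'
#' @param x_star Equilibrium densities (vector-field residual must be below
#'   `residual_tol`).
#' @param lam Constant dose fraction.
#' @param params An [lv_params()] object.
#' @param margin Stability margin on eigenvalue real parts.
#' @param residual_tol Largest admissible vector-field norm at `x_star`.
#' @return A list with `eigenvalues` (complex, decreasing real part),
#'   `stable`, and `marginal`.
#' @examples
#' stability_classify(c(0, 0, 10000), lam = 0.5)$stable
#' @export
stability_classify <- function(x_star, lam, params = lv_params(),
                               margin = 1e-12, residual_tol = 1e-8) {
  x_star <- check_state(x_star)
  resid <- sqrt(sum(lv_vector_field(x_star, lam, params)^2))
  if (resid >= residual_tol)
    stop("x_star is not an equilibrium (residual ", format(resid), ")",
         call. = FALSE)
  J <- lv_jacobian(x_star, lam, params)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  list(eigenvalues = ev,
       stable = all(Re(ev) < -margin),
       marginal = any(abs(Re(ev)) <= margin))
}

#' Sweep equilibria and their stability across the dose axis
#'
#' For each dose in `lam_grid`, enumerates all candidate equilibria,
#' classifies their stability and flags viability (equilibrium total burden
#' within the cap). The default grid resolves the narrow dose window where
#' the stable equilibrium carries all three species.
#'
#' @param lam_grid Dose fractions in `[0, 1]`.
#' @param params An [lv_params()] object.
#' @return A tibble of class `equilibrium_sweep`: one row per (dose,
#'   equilibrium) with columns `lam`, `support`, `x_Tplus`, `x_TP`,
#'   `x_Tminus`, `total`, `eig_real_max`, `stable`, `marginal`, `viable`.
#' @examples
#' sweep_equilibria(c(0.3, 0.45, 0.6))
#' @export
sweep_equilibria <- function(lam_grid = seq(0, 1, by = 1e-3),
                             params = lv_params()) {
  check_dose(lam_grid)
  out <- purrr::map_dfr(lam_grid, function(lam) {
    eq <- candidate_equilibria(lam, params)
    cls <- purrr::pmap(eq[, state_cols], function(x_Tplus, x_TP, x_Tminus) {
      stability_classify(c(x_Tplus, x_TP, x_Tminus), lam, params)
    })
    eq$total <- eq$x_Tplus + eq$x_TP + eq$x_Tminus
    eq$eig_real_max <- vapply(cls, function(z) max(Re(z$eigenvalues)),
                              numeric(1))
    eq$stable <- vapply(cls, `[[`, logical(1), "stable")
    eq$marginal <- vapply(cls, `[[`, logical(1), "marginal")
    eq$viable <- eq$total <= params$viability_cap
    eq
  })
  class(out) <- c("equilibrium_sweep", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.equilibrium_sweep <- function(object, ...) {
  st <- dplyr::filter(object, .data$stable)
  long <- tidyr::pivot_longer(
    st[, c("lam", "viable", state_cols)],
    cols = dplyr::all_of(state_cols),
    names_to = "type", values_to = "density")
  long$type <- factor(long$type, levels = state_cols, labels = cell_types)
  ggplot2::ggplot(long, ggplot2::aes(.data$lam, .data$density,
                                     color = .data$type,
                                     alpha = .data$viable)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.25)) +
    ggplot2::labs(x = "abiraterone dose", y = "stable equilibrium density",
                  color = "cell type", alpha = "within viability cap") +
    ggplot2::theme_minimal()
}

#' Analytic dose thresholds of the stable-equilibrium structure
#'
#' Computes, in closed form where available, the organizing thresholds of
#' the dose sweep:
#' \describe{
#'   \item{`lam_Tminus_mono`}{smallest dose at which the resistant
#'     monoculture at `K_Tminus` is stable, i.e. where the `TP` invasion
#'     rate crosses zero: `K_TP(lam) = alpha23 * K_Tminus`.}
#'   \item{`lam_bifurcation`}{dose where the two-species `T+`/`TP` branch
#'     loses stability to `T-` invasion (root of a quadratic obtained by
#'     substituting the branch into the invasion condition).}
#'   \item{`viability_lo`, `viability_hi`}{dose window over which the stable
#'     branch sits within the viability cap; the lower endpoint solves
#'     "two-species branch total = cap" and the upper endpoint is where the
#'     three-species branch loses stability (its leading eigenvalue real
#'     part crossing zero, before the branch loses feasibility), found by
#'     root bracketing.}
#' }
#'
#' @param params An [lv_params()] object.
#' @return A tibble with one row and the four threshold columns (values are
#'   `NA` when no root exists in `[0, 1]`).
#' @examples
#' analytic_thresholds()
#' @export
analytic_thresholds <- function(params = lv_params()) {
  A <- params$A
  k0 <- params$K_TP_law[1]; k1 <- params$K_TP_law[2]
  m0 <- params$mu_law[1]; m1 <- params$mu_law[2]
  K3 <- params$K_Tminus

  # TP invasion of the T- monoculture: K_TP(lam) = a23 * K3
  lam_mono <- (A[2, 3] * K3 - k0) / k1
  if (!is.finite(lam_mono) || lam_mono < 0 || lam_mono > 1) lam_mono <- NA_real_

  two_species <- function(lam) {
    d <- (m0 + m1 * lam) - A[1, 2]
    x2 <- (k0 + k1 * lam) / (1 + A[2, 1] * d)
    c(x1 = d * x2, x2 = x2)
  }
  # T- invasion eigenvalue sign on the two-species branch
  invasion_gap <- function(lam) {
    xs <- two_species(lam)
    A[3, 1] * xs[1] + A[3, 2] * xs[2] - K3
  }
  lam_bif <- root_in_unit(invasion_gap)

  branch_total_gap <- function(lam) {
    xs <- two_species(lam)
    sum(xs) - params$viability_cap
  }
  hi_search <- if (is.na(lam_bif)) 1 else lam_bif
  viab_lo <- root_in_unit(branch_total_gap, upper = hi_search)

  # upper endpoint: the three-species branch loses stability (leading
  # eigenvalue real part crossing zero) inside its feasibility window
  interior_eq <- function(lam) {
    mu <- m0 + m1 * lam
    M3 <- rbind(c(A[1, 1], A[1, 2] - mu, A[1, 3]),
                c(A[2, 1], A[2, 2], A[2, 3]),
                c(A[3, 1], A[3, 2], A[3, 3]))
    try_solve(M3, c(0, k0 + k1 * lam, K3))
  }
  interior_max_re <- function(lam) {
    sol <- interior_eq(lam)
    if (is.null(sol) || any(sol <= 0)) return(NA_real_)
    max(Re(eigen(lv_jacobian(sol, lam, params),
                 only.values = TRUE)$values))
  }
  viab_hi <- NA_real_
  if (!is.na(lam_bif)) {
    feas_end <- root_in_unit(function(lam) interior_eq(lam)[1],
                             lower = lam_bif)
    if (is.na(feas_end)) feas_end <- 1
    probe <- seq(lam_bif + 1e-6, feas_end - 1e-6, length.out = 64)
    vals <- vapply(probe, interior_max_re, numeric(1))
    ok <- which(is.finite(vals))
    flip <- ok[which(diff(sign(vals[ok])) > 0)]
    if (length(flip))
      viab_hi <- uniroot(interior_max_re, probe[c(flip[1], flip[1] + 1)],
                         tol = 1e-12)$root
  }

  tibble::tibble(lam_Tminus_mono = lam_mono,
                 lam_bifurcation = lam_bif,
                 viability_lo = viab_lo,
                 viability_hi = viab_hi)
}

root_in_unit <- function(f, lower = 0, upper = 1) {
  flo <- f(lower); fhi <- f(upper)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) return(NA_real_)
  uniroot(f, c(lower, upper), tol = 1e-12)$root
}
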