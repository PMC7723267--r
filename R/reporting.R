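#' Kaplan-Meier product-limit survival curve
#'
#' Nonparametric survival estimate \eqn{S(t) = \prod_{t_i \le t} (1 -
#' d_i/n_i)} over the distinct event times, with right-censoring. The
#' estimate is computed through the standard fitter in the survival
#' package and returned as a tidy step function.
#'
#' @param times Positive event/censoring times, or a [run_cohort()] result.
#' @param events Logical event flags (`TRUE` = event, `FALSE` = censored).
#' @return A tibble of class `km_curve` with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`.
#' @examples
#' kaplan_meier(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, TRUE))
#' @export
kaplan_meier <- function(times, events) {
  if (inherits(times, "cohort_result")) {
    ki <- km_input(times)
    times <- ki$time
    events <- ki$event
  }
  if (length(times) == 0) stop("no survival data supplied", call. = FALSE)
  stopifnot(length(times) == length(events), all(times > 0))
  fit <- survival::survfit(
    survival::Surv(times, as.integer(events)) ~ 1,
    conf.type = "none")
  out <- tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                        n_event = fit$n.event, n_censor = fit$n.censor,
                        survival = fit$surv)
  class(out) <- c("km_curve", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.km_curve <- function(object, ...) {
  steps <- tibble::tibble(time = c(0, object$time),
                          survival = c(1, object$survival))
  ggplot2::ggplot(steps, ggplot2::aes(.data$time, .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (model units)", y = "survival") +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves for several protocols
#'
#' @param results Named list of [run_cohort()] results.
#' @return A ggplot object.
#' @export
plot_km_protocols <- function(results) {
  curves <- purrr::imap_dfr(results, function(res, nm) {
    km <- kaplan_meier(res)
    tibble::tibble(protocol = nm,
                   time = c(0, km$time),
                   survival = c(1, km$survival))
  })
  ggplot2::ggplot(curves, ggplot2::aes(.data$time, .data$survival,
                                       color = .data$protocol)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (model units)", y = "survival") +
    ggplot2::theme_minimal()
}

#' End-of-study death summary of a cohort run
#'
#' Fraction of patients breaching the viability constraint before the
#' horizon, and the mean and sample standard deviation of the breach time
#' among breached patients only (`NA` when nobody breached).
#'
#' @param result A [run_cohort()] result.
#' @return A one-row tibble: `protocol`, `n`, `n_breached`,
#'   `fraction_breached`, `pct_breached`, `mean_breach_time`,
#'   `sd_breach_time`.
#' @export
summarize_deaths <- function(result) {
  stopifnot(inherits(result, "cohort_result"))
  oc <- result$outcomes
  bt <- oc$breach_time[oc$breached]
  tibble::tibble(
    protocol = protocol_label(result$spec),
    n = nrow(oc),
    n_breached = length(bt),
    fraction_breached = length(bt) / nrow(oc),
    pct_breached = 100 * length(bt) / nrow(oc),
    mean_breach_time = if (length(bt)) mean(bt) else NA_real_,
    sd_breach_time = if (length(bt) > 1) sd(bt) else NA_real_)
}

#' Tumor composition at the time of viability breach
#'
#' Normalizes the densities at breach to frequencies and flags whether the
#' patient failed in the resistant corner of the composition simplex
#' (strictly more than 80% `T-`).
#'
#' @param outcome A one-row [run_protocol()] outcome (or several rows).
#' @param threshold Resistant-fraction cutoff for the corner flag.
#' @return A tibble with `freq_Tplus`, `freq_TP`, `freq_Tminus`,
#'   `top_triangle`.
#' @export
breach_composition_class <- function(outcome, threshold = 0.8) {
  if (any(!outcome$breached))
    stop("breach composition is only defined for breached patients",
         call. = FALSE)
  tibble::tibble(freq_Tplus = outcome$freq_Tplus,
                 freq_TP = outcome$freq_TP,
                 freq_Tminus = outcome$freq_Tminus,
                 top_triangle = outcome$freq_Tminus > threshold)
}

#' Characterize the initial conditions of surviving patients
#'
#' Survival under burden-feedback protocols selects for particular initial
#' tumors; this summarizes the selection by the extrema over survivors.
#'
#' @param cohort The cohort the result was run on.
#' @param result The matching [run_cohort()] result.
#' @return A one-row tibble: `n_survivors`, `min_initial_volume`,
#'   `max_initial_Tminus_share` (both `NA` when nobody survived).
#' @export
surviving_initials_summary <- function(cohort, result) {
  stopifnot(inherits(result, "cohort_result"),
            nrow(cohort) == nrow(result$outcomes))
  surv <- !result$outcomes$breached
  if (!any(surv))
    return(tibble::tibble(n_survivors = 0L, min_initial_volume = NA_real_,
                          max_initial_Tminus_share = NA_real_))
  x <- cohort[surv, , drop = FALSE]
  tot <- x$x_Tplus + x$x_TP + x$x_Tminus
  tibble::tibble(n_survivors = sum(surv),
                 min_initial_volume = min(tot),
                 max_initial_Tminus_share = max(x$x_Tminus / tot))
}
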