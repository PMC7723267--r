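#' Sample a virtual-patient cohort of initial tumor compositions
#'
#' Draws initial density triples uniformly on the solid simplex
#' `{x >= 0, v_min <= sum(x) <= cap}` by rejection from the cube
#' `[0, cap]^3`, so initial compositions fill the viable region evenly.
#' Sampling is fully reproducible given the seed and leaves the caller's
#' random-number state untouched.
#'
#' @param n Number of patients.
#' @param seed Integer seed.
#' @param cap Viability cap on the initial total volume (cells).
#' @param v_min Optional minimum initial total volume (cells).
#' @return A tibble of class `lv_cohort` with columns `patient`, `x_Tplus`,
#'   `x_TP`, `x_Tminus`; attributes `seed` and `sampler` record provenance.
#' @examples
#' sample_cohort(5, seed = 1)
#' @export
sample_cohort <- function(n, seed, cap = 9000, v_min = 0) {
  stopifnot(n > 0, v_min >= 0, v_min < cap)
  draws <- withr::with_seed(as.integer(seed), {
    acc <- matrix(numeric(0), 0, 3)
    while (nrow(acc) < n) {
      m <- max(2L * (n - nrow(acc)) * 6L, 64L)
      x <- matrix(stats::runif(3 * m, 0, cap), m, 3)
      tot <- rowSums(x)
      acc <- rbind(acc, x[tot <= cap & tot >= v_min, , drop = FALSE])
    }
    acc[seq_len(n), , drop = FALSE]
  })
  out <- tibble::tibble(patient = seq_len(n),
                        x_Tplus = draws[, 1],
                        x_TP = draws[, 2],
                        x_Tminus = draws[, 3])
  class(out) <- c("lv_cohort", class(out))
  attr(out, "seed") <- as.integer(seed)
  attr(out, "sampler") <- sprintf(
    "uniform cube-rejection on {x >= 0, %g <= sum <= %g}", v_min, cap)
  out
}

#' Run one protocol over a whole cohort
#'
#' Applies [run_protocol()] independently to every cohort member and
#' aggregates the outcomes. Results are order-independent: each patient is
#' a separate closed-loop simulation.
#'
#' @param cohort A tibble with columns `x_Tplus`, `x_TP`, `x_Tminus` (for
#'   instance from [sample_cohort()]).
#' @param spec A [protocol_spec()].
#' @param params An [lv_params()] object.
#' @param dt Integration step.
#' @return An object of class `cohort_result`: list with `outcomes` (one
#'   [run_protocol()] row per patient), the protocol `spec`, and `horizon`.
#'   Use [tidy()] for per-patient rows, [glance()] or [summarize_deaths()]
#'   for cohort summaries, and [km_input()] for survival arrays.
#' @examples
#' co <- sample_cohort(4, seed = 1)
#' res <- run_cohort(co, protocol_spec("mtd", horizon = 2000))
#' glance(res)
#' @export
run_cohort <- function(cohort, spec, params = lv_params(), dt = 1) {
  stopifnot(all(state_cols %in% names(cohort)))
  outcomes <- purrr::pmap_dfr(
    cohort[, state_cols],
    function(x_Tplus, x_TP, x_Tminus) {
      run_protocol(c(x_Tplus, x_TP, x_Tminus), spec, params, dt)
    })
  outcomes$patient <- seq_len(nrow(outcomes))
  structure(list(outcomes = outcomes, spec = spec, horizon = spec$horizon),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  s <- summarize_deaths(x)
  cat("<cohort_result>", protocol_label(x$spec), "| n =", s$n,
      "| breached", sprintf("%.1f%%", s$pct_breached), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cohort_result <- function(x, ...) x$outcomes

#' @exportS3Method generics::glance
glance.cohort_result <- function(x, ...) summarize_deaths(x)

#' Survival-analysis input arrays of a cohort run
#'
#' Event times and status flags for the product-limit estimator: breached
#' patients contribute their breach time as an event; survivors are
#' censored at the horizon.
#'
#' @param result A [run_cohort()] result.
#' @return A tibble with columns `patient`, `time`, `event`.
#' @export
km_input <- function(result) {
  stopifnot(inherits(result, "cohort_result"))
  oc <- result$outcomes
  tibble::tibble(patient = oc$patient,
                 time = ifelse(oc$breached, oc$breach_time, result$horizon),
                 event = oc$breached)
}
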