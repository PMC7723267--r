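#' Specify a clinically feasible dosing protocol
#'
#' Three closed-loop policies on the measured total tumor volume:
#' \describe{
#'   \item{MTD}{maximum tolerated dose, `lam = 1` throughout.}
#'   \item{adaptive}{full dose until the volume halves from baseline, then
#'     drug holiday until the volume returns to baseline, repeating.}
#'   \item{titration}{dose moves by `dose_step` on the `{0, 0.1, ..., 1}`
#'     grid whenever the measured volume leaves the `(90%, 110%)` band
#'     around the target volume — the incoming baseline volume (`"va"`) or
#'     a fixed maximum tolerable volume (`"vb"`, default 7000 cells).}
#' }
#' Volume is measured every `measurement_interval` model time units (100,
#' about three months) and the dose may only change at measurement times.
#'
#' @param kind `"mtd"`, `"adaptive"` or `"titration"`.
#' @param target_volume_mode For titration: `"va"` (baseline at t0) or
#'   `"vb"` (fixed value).
#' @param target_volume_value Target volume in cells when mode is `"vb"`.
#' @param initial_dose Starting dose for titration, 0 or 1.
#' @param dose_step Titration increment on the dose grid.
#' @param band Lower/upper multipliers of the target volume bounding the
#'   no-change band.
#' @param measurement_interval Time between volume measurements.
#' @param horizon End of simulation `tf` (model time units).
#' @return An object of class `protocol_spec`.
#' @examples
#' protocol_spec("titration", target_volume_mode = "vb", initial_dose = 0)
#' @export
protocol_spec <- function(kind = c("mtd", "adaptive", "titration"),
                          target_volume_mode = c("va", "vb"),
                          target_volume_value = 7000,
                          initial_dose = 0,
                          dose_step = 0.1,
                          band = c(0.9, 1.1),
                          measurement_interval = 100,
                          horizon = 10000) {
  kind <- match.arg(kind)
  target_volume_mode <- match.arg(target_volume_mode)
  check_dose(initial_dose)
  stopifnot(length(band) == 2, band[1] < 1, band[2] > 1,
            measurement_interval > 0, horizon > 0, dose_step > 0)
  if (abs(initial_dose * 10 - round(initial_dose * 10)) > 1e-9)
    stop("initial_dose must sit on the dose grid", call. = FALSE)
  structure(list(kind = kind, target_volume_mode = target_volume_mode,
                 target_volume_value = target_volume_value,
                 initial_dose = initial_dose, dose_step = dose_step,
                 band = band, measurement_interval = measurement_interval,
                 horizon = horizon),
            class = "protocol_spec")
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat("<protocol_spec>", protocol_label(x), "\n")
  invisible(x)
}

protocol_label <- function(spec) {
  switch(spec$kind,
         mtd = "MTD",
         adaptive = "adaptive",
         titration = sprintf("titration(%s, lam0=%g)",
                             toupper(spec$target_volume_mode),
                             spec$initial_dose))
}

#' The six clinically feasible protocols
#'
#' Maximum tolerated dose, adaptive therapy, and the four titration
#' variants crossing target volume (baseline `Va` vs fixed `Vb`) with
#' initial dose (1 vs 0).
#'
#' @param V_b Fixed maximum tolerable target volume (cells) for the `Vb`
#'   titration variants.
#' @param horizon Simulation end time.
#' @return A named list of six [protocol_spec()] objects.
#' @examples
#' names(protocol_catalog())
#' @export
protocol_catalog <- function(V_b = 7000, horizon = 10000) {
  list(
    mtd = protocol_spec("mtd", horizon = horizon),
    adaptive = protocol_spec("adaptive", horizon = horizon),
    titration_va_lam1 = protocol_spec("titration", "va", initial_dose = 1,
                                      horizon = horizon),
    titration_va_lam0 = protocol_spec("titration", "va", initial_dose = 0,
                                      horizon = horizon),
    titration_vb_lam1 = protocol_spec("titration", "vb", V_b,
                                      initial_dose = 1, horizon = horizon),
    titration_vb_lam0 = protocol_spec("titration", "vb", V_b,
                                      initial_dose = 0, horizon = horizon))
}

#' Titration dose update rule
#'
#' One step of the titration feedback: increase the dose by one grid step
#' when the measured volume exceeds 110% of the target, decrease it below
#' 90%, hold inside the band; clamped to `[0, 1]`.
#'
#' @param current_dose Current dose on the `{0, 0.1, ..., 1}` grid
#'   (vectorized).
#' @param V_measured Measured total volume (cells).
#' @param V_target Volume being maintained (cells).
#' @param dose_step Grid increment.
#' @param band Length-2 band multipliers.
#' @return Updated dose(s) on the grid.
#' @examples
#' titration_update(0.2, 7800, 7000)
#' @export
titration_update <- function(current_dose, V_measured, V_target,
                             dose_step = 0.1, band = c(0.9, 1.1)) {
  delta <- ifelse(V_measured > band[2] * V_target, dose_step,
                  ifelse(V_measured < band[1] * V_target, -dose_step, 0))
  # integer-tenths arithmetic keeps the result exactly on the grid
  round(pmin(pmax(round(current_dose * 10) + round(delta * 10), 0), 10)) / 10
}

#' Adaptive therapy update rule
#'
#' On-phase dosing at `lam = 1` until the volume drops to half of baseline,
#' then a drug holiday until the volume regrows to baseline.
#'
#' @param phase `"on"` or `"off"`.
#' @param V_measured Measured total volume.
#' @param V_baseline Baseline volume at treatment start.
#' @return A list with the new `phase` and `dose`.
#' @examples
#' adaptive_update("on", 2000, 5000)
#' @export
adaptive_update <- function(phase = c("on", "off"), V_measured, V_baseline) {
  phase <- match.arg(phase)
  if (V_baseline <= 0) stop("V_baseline must be positive", call. = FALSE)
  if (phase == "on" && V_measured <= 0.5 * V_baseline) phase <- "off"
  else if (phase == "off" && V_measured >= V_baseline) phase <- "on"
  list(phase = phase, dose = if (phase == "on") 1 else 0)
}

#' Run a protocol on one virtual patient
#'
#' Simulates the closed loop: integrate the model between measurement
#' times under the current dose, measure the total volume every
#' `measurement_interval`, update the dose per the protocol rule, and stop
#' at the first viability breach or at the horizon. Breach is checked at
#' every integration step, not only at measurement times.
#'
#' @param x0 Initial densities `(T+, TP, T-)`; must be viable.
#' @param spec A [protocol_spec()].
#' @param params An [lv_params()] object.
#' @param dt Integration step.
#' @param keep_path Attach the full trajectory (as an `lv_trajectory`) to
#'   the outcome.
#' @return A one-row tibble of class `patient_outcome`: initial state,
#'   `breached`, `breach_time` (`NA` when censored at the horizon), final
#'   state, final dose, and the composition frequencies at end of
#'   follow-up. With `keep_path = TRUE` the trajectory is in
#'   `attr(, "path")`.
#' @examples
#' run_protocol(c(1000, 4000, 500), protocol_spec("mtd", horizon = 2000))
#' @export
run_protocol <- function(x0, spec, params = lv_params(), dt = 1,
                         keep_path = FALSE) {
  x0 <- check_state(x0)
  stopifnot(inherits(spec, "protocol_spec"))
  if (sum(x0) > params$viability_cap)
    stop("initial state violates the viability cap", call. = FALSE)
  kind <- match(spec$kind, c("mtd", "adaptive", "titration")) - 1L
  v_target <- if (spec$kind == "titration" && spec$target_volume_mode == "va")
    sum(x0) else spec$target_volume_value
  res <- cpp_run_protocol(x0, params, kind, v_target, spec$initial_dose,
                          0, spec$horizon, dt, spec$measurement_interval,
                          spec$band[1], spec$band[2], spec$dose_step,
                          keep_path)
  xf <- res$final_state
  tot <- sum(xf)
  freq <- if (tot > 0) xf / tot else rep(NA_real_, 3)
  out <- tibble::tibble(
    protocol = protocol_label(spec),
    x0_Tplus = x0[1], x0_TP = x0[2], x0_Tminus = x0[3],
    initial_volume = sum(x0),
    breached = !is.na(res$breach_time),
    breach_time = res$breach_time,
    final_Tplus = xf[1], final_TP = xf[2], final_Tminus = xf[3],
    final_volume = tot,
    final_dose = res$final_dose,
    freq_Tplus = freq[1], freq_TP = freq[2], freq_Tminus = freq[3])
  class(out) <- c("patient_outcome", class(out))
  if (keep_path)
    attr(out, "path") <- new_trajectory(res$t, res$x, res$dose,
                                        res$breach_time)
  out
}
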