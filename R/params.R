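#' Model parameters for the three-species tumor model
#'
#' Bundles every constant of the Lotka-Volterra competition model of
#' metastatic castrate-resistant prostate cancer: intrinsic growth rates of
#' the androgen-dependent (`T+`), testosterone-producing (`TP`) and
#' androgen-independent (`T-`) subpopulations, the competition matrix, the
#' dose-response laws mapping the abiraterone dose to the `TP` carrying
#' capacity and to the symbiosis coefficient, and the patient viability cap.
#'
#' The dose \eqn{\Lambda \in [0, 1]} acts on two quantities only:
#' \deqn{K_{TP}(\Lambda) = 10000 - 9900\,\Lambda, \qquad
#'       \mu(\Lambda) = 1.5 - \Lambda,}
#' and the `T+` carrying capacity is slaved to the producer density,
#' \eqn{K_{T+} = \mu(\Lambda)\, x_{TP}}. Because \eqn{K_{T+}} vanishes with
#' \eqn{x_{TP}}, the field is regularized with a small floor `tp_floor` so
#' the ODE stays well-posed while `T+` still collapses without producers.
#'
#' @param r Length-3 vector of intrinsic growth rates (per model time unit)
#'   for `(T+, TP, T-)`. Defaults are the doubling-time-derived per-day rates
#'   scaled by `1e-2`.
#' @param A 3x3 competition matrix; `A[i, j]` is the per-capita effect of
#'   type `j` on type `i`. Unit diagonal, off-diagonals must be >= 0. The
#'   default uses `alpha32 = 2`, the parameterization under which viable
#'   stable equilibria exist.
#' @param K_Tminus Carrying capacity of the resistant `T-` type (cells).
#' @param K_TP_law Length-2 `(intercept, slope)` of the affine dose response
#'   of the `TP` carrying capacity.
#' @param mu_law Length-2 `(intercept, slope)` of the affine dose response of
#'   the symbiosis coefficient.
#' @param viability_cap Maximum tolerated total tumor burden (cells);
#'   exceeding it is scored as patient death.
#' @param tp_floor Regularization floor (cells) applied to `x_TP` inside
#'   `K_T+`.
#' @param extinction_snap Densities below this value are set to zero after
#'   each integration step, preventing negative drift and revival of extinct
#'   clones.
#'
#' @return An object of class `lv_params` (a named list).
#' @examples
#' p <- lv_params()
#' dose_response(c(0, 0.4, 1), p)
#' @export
lv_params <- function(r = c(2.7726e-3, 3.4657e-3, 6.6542e-3),
                      A = matrix(c(1, 0.7, 0.8,
                                   0.4, 1, 0.6,
                                   0.5, 2, 1), 3, 3, byrow = TRUE),
                      K_Tminus = 10000,
                      K_TP_law = c(intercept = 10000, slope = -9900),
                      mu_law = c(intercept = 1.5, slope = -1),
                      viability_cap = 9000,
                      tp_floor = 1e-6,
                      extinction_snap = 1e-9) {
  r <- as.numeric(r)
  A <- unname(as.matrix(A))
  stopifnot(length(r) == 3, all(dim(A) == c(3, 3)),
            length(K_TP_law) == 2, length(mu_law) == 2)
  if (any(r <= 0)) stop("all growth rates must be positive", call. = FALSE)
  if (any(A < 0)) stop("competition coefficients must be non-negative",
                       call. = FALSE)
  if (K_Tminus <= 0) stop("K_Tminus must be positive", call. = FALSE)
  if (tp_floor <= 0) stop("tp_floor must be positive", call. = FALSE)
  ktp <- unname(as.numeric(K_TP_law))
  mul <- unname(as.numeric(mu_law))
  # the dose laws must stay positive across the admissible dose range
  if (min(ktp[1], ktp[1] + ktp[2]) <= 0)
    stop("K_TP_law must be positive on [0, 1]", call. = FALSE)
  if (min(mul[1], mul[1] + mul[2]) <= 0)
    stop("mu_law must be positive on [0, 1]", call. = FALSE)
  structure(
    list(r = r, A = A, K_Tminus = as.numeric(K_Tminus),
         K_TP_law = ktp, mu_law = mul,
         viability_cap = as.numeric(viability_cap),
         tp_floor = as.numeric(tp_floor),
         extinction_snap = as.numeric(extinction_snap)),
    class = "lv_params")
}

#' @export
print.lv_params <- function(x, ...) {
  cat("<lv_params>\n")
  cat("  r:", format(x$r, digits = 5), "\n")
  cat("  A:\n")
  print(x$A)
  cat("  K_Tminus:", x$K_Tminus,
      "| K_TP(lam):", x$K_TP_law[1], "+", x$K_TP_law[2], "* lam",
      "| mu(lam):", x$mu_law[1], "+", x$mu_law[2], "* lam\n")
  cat("  viability_cap:", x$viability_cap, "| tp_floor:", x$tp_floor, "\n")
  invisible(x)
}

#' Dose response of the drug-sensitive carrying capacities
#'
#' Evaluates the two affine laws through which abiraterone acts on the model:
#' the `TP` carrying capacity `K_TP(lam)` and the symbiosis coefficient
#' `mu(lam)` (per-producer-cell contribution to the `T+` carrying capacity).
#'
#' @param lam Numeric vector of dose fractions in `[0, 1]`.
#' @param params An [lv_params()] object.
#' @return A tibble with columns `lam`, `K_TP`, `mu`.
#' @examples
#' dose_response(c(0, 1))
#' @export
dose_response <- function(lam, params = lv_params()) {
  check_dose(lam)
  tibble::tibble(
    lam = as.numeric(lam),
    K_TP = params$K_TP_law[1] + params$K_TP_law[2] * lam,
    mu = params$mu_law[1] + params$mu_law[2] * lam)
}

#' Per-day growth rate from a cell-line doubling time
#'
#' Converts a measured doubling time in hours to an exponential growth rate
#' per day, `log(2) / (hours / 24)`, optionally rescaled. Cell-line rates are
#' faster than in-tumor growth, so the model uses a downscaling factor of
#' `1e-2` to map the per-day rates onto the model time unit.
#'
#' @param hours Doubling time(s) in hours; must be positive.
#' @param scale Positive multiplicative rescaling, default 1.
#' @return Numeric vector of growth rates.
#' @examples
#' growth_rate_from_doubling_time(c(60, 48, 25))        # per-day rates
#' growth_rate_from_doubling_time(48, scale = 1e-2)     # model-scale rate
#' @export
growth_rate_from_doubling_time <- function(hours, scale = 1) {
  if (any(hours <= 0)) stop("doubling time must be positive", call. = FALSE)
  if (any(scale <= 0)) stop("scale must be positive", call. = FALSE)
  log(2) / (hours / 24) * scale
}

#' Read or write model parameters
#'
#' Parameters round-trip through YAML or JSON (chosen by file extension) with
#' keys mirroring the [lv_params()] fields, so runs are configurable without
#' touching code.
#'
#' @param params An [lv_params()] object.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_lv_params()` returns `path` invisibly; `read_lv_params()`
#'   returns an [lv_params()] object.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_lv_params(lv_params(), f)
#' read_lv_params(f)
#' @export
write_lv_params <- function(params, path) {
  stopifnot(inherits(params, "lv_params"))
  x <- unclass(params)
  x$A <- apply(x$A, 1, as.numeric, simplify = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_lv_params
#' @export
read_lv_params <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- lv_params()
  for (nm in names(defaults)) if (is.null(x[[nm]])) x[[nm]] <- defaults[[nm]]
  A <- x$A
  if (is.list(A)) A <- do.call(rbind, lapply(A, as.numeric))
  lv_params(r = x$r, A = A, K_Tminus = x$K_Tminus, K_TP_law = x$K_TP_law,
            mu_law = x$mu_law, viability_cap = x$viability_cap,
            tp_floor = x$tp_floor, extinction_snap = x$extinction_snap)
}

check_dose <- function(lam) {
  if (any(!is.finite(lam)) || any(lam < 0) || any(lam > 1))
    stop("dose must lie in [0, 1]", call. = FALSE)
  invisible(lam)
}

check_state <- function(x) {
  x <- as.numeric(x)
  if (length(x) != 3 || any(!is.finite(x)) || any(x < 0))
    stop("state must be 3 non-negative finite densities", call. = FALSE)
  x
}

cell_types <- c("T+", "TP", "T-")
state_cols <- c("x_Tplus", "x_TP", "x_Tminus")
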