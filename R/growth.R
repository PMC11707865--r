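#' von Bertalanffy growth parameters
#'
#' Stores the VBGF in the additive-shift form
#' `FL = l_inf * (1 - exp(-k * (age + age_shift)))`, i.e. `age_shift = -t0`
#' in the classical parameterisation (see [vbgf_t0()]).
#'
#' @param l_inf asymptotic fork length, mm.
#' @param k growth coefficient, per year.
#' @param age_shift additive age constant inside the exponent, years.
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(l_inf, k, age_shift) {
  if (!is.numeric(l_inf) || l_inf <= 0) stopf("l_inf must be positive")
  if (!is.numeric(k) || k <= 0) stopf("k must be positive")
  if (!is.numeric(age_shift) || !is.finite(age_shift))
    stopf("age_shift must be finite")
  structure(list(l_inf = l_inf, k = k, age_shift = age_shift),
            class = "growth_params")
}

#' Reference walleye growth curves
#'
#' Published VBGF parameter sets for the Hamilton Harbour subpopulation
#' (`vbgf_hamilton`) and the pooled coastal Lake Ontario samples
#' (`vbgf_ontario`). Lengths are fork lengths in mm, ages in years.
#'
#' @return A [growth_params()].
#' @export
vbgf_hamilton <- function() growth_params(642.5, 0.375, 0.5)

#' @rdname vbgf_hamilton
#' @export
vbgf_ontario <- function() growth_params(601.4, 0.31, 1.006)

#' Convert to the classical t0 parameterisation
#' @param params a [growth_params()].
#' @return Named numeric `c(l_inf, k, t0)` with `t0 = -age_shift`.
#' @export
vbgf_t0 <- function(params) {
  c(l_inf = params$l_inf, k = params$k, t0 = -params$age_shift)
}

#' Predict fork length at age
#'
#' @param params a [growth_params()].
#' @param age age in years (vectorised, must be non-negative).
#' @return Fork length(s), mm.
#' @examples
#' predict_length(vbgf_hamilton(), 5)
#' @export
predict_length <- function(params, age) {
  if (!inherits(params, "growth_params")) stopf("params must be growth_params")
  if (any(!is.finite(age)) || any(age < 0)) stopf("age must be non-negative")
  params$l_inf * (1 - exp(-params$k * (age + params$age_shift)))
}

#' Estimate integer age from fork length
#'
#' Inverts the VBGF, `age = -log(1 - FL / l_inf) / k - age_shift`, and rounds
#' to the nearest non-negative whole year (ties round half-up).
#'
#' @param params a [growth_params()].
#' @param fork_length_mm observed fork length(s), mm; must be positive and
#'   below `l_inf`.
#' @param round round to integer years (default `TRUE`).
#' @return Estimated age(s), years.
#' @export
estimate_age <- function(params, fork_length_mm, round = TRUE) {
  if (!inherits(params, "growth_params")) stopf("params must be growth_params")
  if (any(!is.finite(fork_length_mm)) || any(fork_length_mm <= 0))
    stopf("fork length must be positive")
  if (any(fork_length_mm >= params$l_inf))
    stopf("fork length at or above the asymptote (%.1f mm): age undefined",
          params$l_inf)
  age <- -log(1 - fork_length_mm / params$l_inf) / params$k - params$age_shift
  if (round) pmax(0, round_half_up(age)) else age
}

#' Fit a VBGF to age-length data
#'
#' Bounded Levenberg-Marquardt least squares of observed fork length on the
#' VBGF, with starting values `l_inf = 1.1 * max(FL)`, `k = 0.3`,
#' `age_shift = 1` and box constraints `l_inf` in (0.5 max FL, 3 max FL),
#' `k` in (0.01, 2), `age_shift` in (-5, 5) to stabilise small samples. The
#' lower asymptote bound sits below the largest observed fish because under
#' measurement noise the sample maximum routinely exceeds the true
#' asymptote, and clamping there would bias the growth coefficient.
#'
#' @param age ages, years (or a data frame with columns `age_years` and
#'   `fork_length_mm`).
#' @param fork_length_mm fork lengths, mm (omit when `age` is a data frame).
#' @return A [growth_params()] with extra fields `residual_se`, `converged`,
#'   `n`, and the `nls` fit as attribute `fit`.
#' @export
fit_vbgf <- function(age, fork_length_mm = NULL) {
  if (is.data.frame(age)) {
    assert_cols(age, c("age_years", "fork_length_mm"), "age-length table")
    fork_length_mm <- age$fork_length_mm
    age <- age$age_years
  }
  ok <- is.finite(age) & is.finite(fork_length_mm)
  age <- age[ok]; fl <- fork_length_mm[ok]
  if (length(unique(age)) < 3L)
    stopf("at least 3 distinct ages are required to fit a VBGF")
  if (any(age < 0) || any(fl <= 0)) stopf("ages must be >= 0 and lengths > 0")
  maxfl <- max(fl)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      fl ~ l_inf * (1 - exp(-k * (age + age_shift))),
      start = list(l_inf = 1.1 * maxfl, k = 0.3, age_shift = 1),
      lower = c(l_inf = 0.5 * maxfl, k = 0.01, age_shift = -5),
      upper = c(l_inf = 3 * maxfl, k = 2, age_shift = 5),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stopf("VBGF fit failed to converge: %s", conditionMessage(e)))
  cf <- stats::coef(fit)
  out <- growth_params(cf[["l_inf"]], cf[["k"]], cf[["age_shift"]])
  out$residual_se <- summary(fit)$sigma
  out$converged <- fit$convInfo$isConv %||% TRUE
  out$n <- length(age)
  attr(out, "fit") <- fit
  out
}

#' Project fork lengths over the study years
#'
#' Estimates the (integer) age at capture from the capture length, then
#' predicts length at `age + elapsed` for each study year. The projection
#' curve defaults to the pooled Lake Ontario parameters, the convention used
#' when a local sample is too small to age fish reliably.
#'
#' @param length_at_capture_mm fork length at tagging, mm.
#' @param capture_year calendar year of capture.
#' @param study_years vector of years to project to (each `>= capture_year`).
#' @param params projection curve, default [vbgf_ontario()].
#' @return Data frame `year`, `age_years`, `projected_fork_length_mm`; the raw
#'   capture length is kept as attribute `length_at_capture_mm`.
#' @export
project_lengths <- function(length_at_capture_mm, capture_year, study_years,
                            params = vbgf_ontario()) {
  if (any(study_years < capture_year))
    stopf("study years must not precede the capture year")
  age0 <- estimate_age(params, length_at_capture_mm)
  ages <- age0 + (study_years - capture_year)
  out <- data.frame(year = study_years, age_years = ages,
                    projected_fork_length_mm = predict_length(params, ages))
  attr(out, "length_at_capture_mm") <- length_at_capture_mm
  out
}
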