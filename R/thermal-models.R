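#' Evaluate the Ratkowsky-1 temperature response
#'
#' rT = cc * \[k1 (T - T1) (1 - exp(k2 (T - T2)))\]^2 for T1 <= T <= T2,
#' and exactly 0 outside the biological range \[T1, T2\] (the squared
#' expression is mathematically positive there, but the response is defined
#' as zero beyond the cardinal temperatures). With the scale factor outside
#' the square the response stays on a proportion scale, so a virulence fit
#' can be read directly as expected mortality.
#'
#' @param temp Temperature(s), deg C. Vectorized.
#' @param params A [thermal_params()] object with `model_id = "ratkowsky1"`.
#' @return Non-negative response, same length as `temp`.
#' @export
#' @examples
#' p <- cjavanica_params("virulence")
#' eval_ratkowsky1(c(25, 30), p)  # ~0.607, ~0.680
eval_ratkowsky1 <- function(temp, params) {
  check_thermal(params, "ratkowsky1")
  ratkowsky1_core(temp, params$cc, params$k1, params$k2,
                  params$T1, params$T2)
}

#' Evaluate the Ratkowsky-2 temperature response
#'
#' rT = \[cc (T - T1) (1 - exp(k (T - T2)))\]^2 for T1 <= T <= T2, and
#' exactly 0 outside. The response scale follows the units of the data the
#' model was fitted to (colony growth rate, arbitrary units).
#'
#' @inheritParams eval_ratkowsky1
#' @param params A [thermal_params()] object with `model_id = "ratkowsky2"`.
#' @return Non-negative response, same length as `temp`.
#' @export
eval_ratkowsky2 <- function(temp, params) {
  check_thermal(params, "ratkowsky2")
  ratkowsky2_core(temp, params$cc, params$k, params$T1, params$T2)
}

# raw kernels, used by the fitting layer on bare numeric vectors
ratkowsky1_core <- function(temp, cc, k1, k2, T1, T2) {
  r <- cc * (k1 * (temp - T1) * (1 - exp(k2 * (temp - T2))))^2
  r[temp < T1 | temp > T2] <- 0
  r
}

ratkowsky2_core <- function(temp, cc, k, T1, T2) {
  r <- (cc * (temp - T1) * (1 - exp(k * (temp - T2))))^2
  r[temp < T1 | temp > T2] <- 0
  r
}

#' Evaluate a thermal response model (either family)
#'
#' Dispatches on `params$model_id`; convenience wrapper used by the
#' projection and simulation layers.
#'
#' @inheritParams eval_ratkowsky1
#' @param params A [thermal_params()] object.
#' @export
eval_thermal <- function(temp, params) {
  if (!inherits(params, "thermal_params"))
    stop("params must be a thermal_params object", call. = FALSE)
  switch(params$model_id,
         ratkowsky1 = eval_ratkowsky1(temp, params),
         ratkowsky2 = eval_ratkowsky2(temp, params))
}

check_thermal <- function(params, expected) {
  if (!inherits(params, "thermal_params"))
    stop("params must be a thermal_params object", call. = FALSE)
  if (params$model_id != expected)
    stop("params are for model '", params$model_id,
         "', expected '", expected, "'", call. = FALSE)
  invisible(params)
}

#' Evaluate a cumulative time-mortality curve
#'
#' Cumulative mortality proportion at `t` days post-inoculation for the
#' family/parameterization declared in `params` (see
#' [time_course_params()] for the closed forms). Every family is monotone
#' non-decreasing in `t` and bounded in \[0, d\].
#'
#' @param t Days post-inoculation, >= 0. Vectorized.
#' @param params A [time_course_params()] object.
#' @return Cumulative mortality proportion(s) in \[0, d\].
#' @export
#' @examples
#' eval_time_course(5, time_course_params("gompertz", b = 1, d = 1, e = 5))
eval_time_course <- function(t, params) {
  if (!inherits(params, "time_course_params"))
    stop("params must be a time_course_params object", call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and >= 0", call. = FALSE)
  time_course_core(t, params$family, params$b, params$d, params$e)
}

time_course_core <- function(t, family, b, d, e) {
  switch(family,
    logistic     = d / (1 + exp(-b * (t - e))),
    log_logistic = ifelse(t == 0, 0, d / (1 + (t / e)^(-b))),
    log_normal   = ifelse(t == 0, 0, d * stats::pnorm(b * log(t / e))),
    weibull      = d * (1 - exp(-(t / e)^b)),
    gompertz     = d * exp(-exp(-b * (t - e))),
    stop("unknown time-course family: ", family, call. = FALSE)
  )
}

#' Find the thermal optimum of a fitted response
#'
#' Locates the temperature maximizing the response on \[T1, T2\] by a
#' deterministic coarse grid scan (0.1 deg C) followed by golden-section
#' (Brent) refinement around the best grid cell; no randomness involved.
#'
#' @param params A [thermal_params()] object.
#' @param resolution Required precision of the optimum, deg C
#'   (default 0.01).
#' @return A list with `T_opt` (deg C) and `r_max` (response at the
#'   optimum); `T1 < T_opt < T2`.
#' @export
#' @examples
#' thermal_optimum(cjavanica_params("virulence"))$T_opt  # 28.1
thermal_optimum <- function(params, resolution = 0.01) {
  if (!inherits(params, "thermal_params"))
    stop("params must be a thermal_params object", call. = FALSE)
  T1 <- params$T1; T2 <- params$T2
  if (!(T1 < T2)) stop("degenerate interval: T1 >= T2", call. = FALSE)
  f <- function(x) eval_thermal(x, params)
  grid <- seq(T1, T2, by = min(0.1, (T2 - T1) / 20))
  i <- which.max(f(grid))
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(f, lower = lo, upper = hi, maximum = TRUE,
                         tol = resolution / 10)
  list(T_opt = opt$maximum, r_max = opt$objective)
}
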