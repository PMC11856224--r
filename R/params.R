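#' Thermal model parameter sets
#'
#' Construct a validated parameter set for one of the two Ratkowsky-type
#' temperature-response models. Both models are zero at the cardinal
#' temperatures `T1` (lower) and `T2` (upper) and unimodal in between.
#'
#' * `ratkowsky1`: rT = cc * \[k1 (T - T1) (1 - exp(k2 (T - T2)))\]^2,
#'   with an outer scale factor `cc` so that the squared term stays on a
#'   proportion-like scale.
#' * `ratkowsky2`: rT = \[cc (T - T1) (1 - exp(k (T - T2)))\]^2.
#'
#' @param model_id `"ratkowsky1"` or `"ratkowsky2"`.
#' @param cc Scale factor (dimensionless), >= 0.
#' @param k1,k2 Slope (per deg C) and rate constant (per deg C); required
#'   for `ratkowsky1`.
#' @param k Rate constant (per deg C); required for `ratkowsky2`.
#' @param T1,T2 Lower and upper zero-response temperatures (deg C), `T1 < T2`.
#' @return An object of class `thermal_params`.
#' @seealso [eval_ratkowsky1()], [eval_ratkowsky2()], [thermal_optimum()],
#'   [cjavanica_params()] for the published parameter sets.
#' @export
#' @examples
#' p <- thermal_params("ratkowsky2", cc = 5.919, k = 0.177,
#'                     T1 = 22.907, T2 = 33.250)
#' thermal_optimum(p)
thermal_params <- function(model_id = c("ratkowsky1", "ratkowsky2"),
                           cc, k1 = NULL, k2 = NULL, k = NULL, T1, T2) {
  model_id <- match.arg(model_id)
  num1 <- function(x, name, allow_null = FALSE) {
    if (is.null(x)) {
      if (allow_null) return(NULL)
      stop("missing parameter '", name, "' for model ", model_id,
           call. = FALSE)
    }
    x <- as.numeric(x)
    if (length(x) != 1L || !is.finite(x))
      stop("parameter '", name, "' must be a single finite number",
           call. = FALSE)
    x
  }
  cc <- num1(cc, "cc"); T1 <- num1(T1, "T1"); T2 <- num1(T2, "T2")
  if (cc < 0) stop("cc must be >= 0", call. = FALSE)
  if (!(T1 < T2)) stop("T1 must be strictly below T2", call. = FALSE)
  if (model_id == "ratkowsky1") {
    k1 <- num1(k1, "k1"); k2 <- num1(k2, "k2"); k <- NULL
  } else {
    k <- num1(k, "k"); k1 <- NULL; k2 <- NULL
  }
  structure(
    list(model_id = model_id, cc = cc, k1 = k1, k2 = k2, k = k,
         T1 = T1, T2 = T2),
    class = "thermal_params"
  )
}

#' @export
print.thermal_params <- function(x, ...) {
  cat("Thermal response model:", x$model_id, "\n")
  fields <- x[!vapply(x, is.null, logical(1))]
  fields$model_id <- NULL
  cat(paste0("  ", names(fields), " = ",
             vapply(fields, format, character(1))), sep = "\n")
  invisible(x)
}

#' Time-mortality curve parameters
#'
#' Parameters of a cumulative mortality time course F(t): the proportion of
#' the cohort dead by `t` days post-inoculation. All families share a
#' steepness `b`, an upper asymptote `d` (the mortality plateau) and a
#' location `e` (days). Parameterizations:
#'
#' * logistic: `F(t) = d / (1 + exp(-b (t - e)))`
#' * log_logistic: `F(t) = d / (1 + (t/e)^(-b))`
#' * log_normal: `F(t) = d * pnorm(b * log(t/e))`
#' * weibull: `F(t) = d * (1 - exp(-(t/e)^b))`
#' * gompertz: `F(t) = d * exp(-exp(-b (t - e)))`
#'
#' @param family One of `"logistic"`, `"log_logistic"`, `"log_normal"`,
#'   `"weibull"`, `"gompertz"`.
#' @param b Steepness (> 0), per day or per log-day depending on family.
#' @param d Upper asymptote, a proportion in \[0, 1\].
#' @param e Location (days, > 0 for log-scale families).
#' @return An object of class `time_course_params`.
#' @export
time_course_params <- function(family = c("logistic", "log_logistic",
                                          "log_normal", "weibull",
                                          "gompertz"),
                               b, d, e) {
  family <- match.arg(family)
  stopifnot(is.finite(b), is.finite(d), is.finite(e))
  if (b <= 0) stop("steepness b must be > 0", call. = FALSE)
  if (d < 0 || d > 1) stop("asymptote d must lie in [0, 1]", call. = FALSE)
  log_scale <- family %in% c("log_logistic", "log_normal", "weibull")
  if (log_scale && e <= 0)
    stop("location e must be > 0 for family ", family, call. = FALSE)
  structure(list(family = family, b = as.numeric(b), d = as.numeric(d),
                 e = as.numeric(e)),
            class = "time_course_params")
}

#' @export
print.time_course_params <- function(x, ...) {
  cat(sprintf("Time-mortality curve [%s]: b = %g, d = %g, e = %g days\n",
              x$family, x$b, x$d, x$e))
  invisible(x)
}

#' Published Cordyceps javanica parameter sets
#'
#' Fitted Ratkowsky parameter sets for the C. javanica strain BRM 27666:
#' the virulence model (7-day mortality of second-instar B. tabaci nymphs
#' vs constant temperature) and the three mycelial-growth models (colony
#' size vs constant temperature, Experiments 1-3). These are the fixture
#' sets bundled under `inst/extdata/params/`.
#'
#' @param set One of `"virulence"`, `"growth_exp1"`, `"growth_exp2"`,
#'   `"growth_exp3"`.
#' @return A [thermal_params()] object.
#' @export
#' @examples
#' thermal_optimum(cjavanica_params("virulence"))  # ~28.1 deg C
cjavanica_params <- function(set = c("virulence", "growth_exp1",
                                     "growth_exp2", "growth_exp3")) {
  set <- match.arg(set)
  path <- system.file("extdata", "params", paste0(set, ".json"),
                      package = "epftherm", mustWork = TRUE)
  read_params_json(path)
}

#' Read / write thermal model parameters as JSON
#'
#' Parameter sets are serialized as a flat key-value JSON document with
#' fields `model_id`, `cc`, `k1`, `k2`, `k`, `T1`, `T2` (absent fields
#' omitted).
#'
#' @param path File path.
#' @return `read_params_json()` returns a [thermal_params()] object;
#'   `write_params_json()` returns `path` invisibly.
#' @export
read_params_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$model_id))
    stop("parameter document lacks 'model_id': ", path, call. = FALSE)
  thermal_params(model_id = doc$model_id, cc = doc$cc,
                 k1 = doc$k1, k2 = doc$k2, k = doc$k,
                 T1 = doc$T1, T2 = doc$T2)
}

#' @rdname read_params_json
#' @param params A [thermal_params()] object.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "thermal_params"))
  doc <- params[!vapply(params, is.null, logical(1))]
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
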