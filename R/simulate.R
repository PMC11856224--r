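#' Temperature exposure regime
#'
#' Describes how an experimental cohort is exposed to temperature:
#' constant incubation, a single pulse at the treatment temperature
#' followed by ambient conditions, or a daily alternation (e.g. 6 h at the
#' treatment temperature and 18 h at ambient). Under the pulse and
#' alternating kinds the mortality plateau follows the ambient mean, not
#' the treatment temperature — the empirical signature that once the
#' fungus has penetrated the host, short temperature excursions no longer
#' drive the outcome.
#'
#' @param kind `"constant"`, `"pulse_then_ambient"`, or
#'   `"daily_alternating"`.
#' @param treatment_temp Treatment temperature, deg C.
#' @param ambient_mean Ambient mean temperature, deg C (required for the
#'   non-constant kinds).
#' @param pulse_hours Daily hours at the treatment temperature, in
#'   (0, 24\] (non-constant kinds; default 6).
#' @param label Regime label used in output datasets (default derived
#'   from kind and temperature).
#' @return Object of class `temperature_regime`.
#' @export
temperature_regime <- function(kind = c("constant", "pulse_then_ambient",
                                        "daily_alternating"),
                               treatment_temp, ambient_mean = NULL,
                               pulse_hours = 6, label = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.finite(treatment_temp))
  if (kind != "constant") {
    if (is.null(ambient_mean) || !is.finite(ambient_mean))
      stop("ambient_mean is required for regime kind ", kind, call. = FALSE)
    if (pulse_hours <= 0 || pulse_hours > 24)
      stop("pulse_hours must be in (0, 24]", call. = FALSE)
  }
  label <- label %||% paste0(kind, "_", format(treatment_temp))
  structure(list(kind = kind, treatment_temp = treatment_temp,
                 ambient_mean = ambient_mean, pulse_hours = pulse_hours,
                 label = label),
            class = "temperature_regime")
}

#' Ground truth for simulation and recovery tests
#'
#' Bundles the parameters the synthetic generators draw from, so that
#' recovery tests can compare estimates against a known truth. Defaults
#' describe the virulence study conditions: the fitted nymphal-mortality
#' thermal response, median lethal times of 6.3 days at 25 deg C and 5.4
#' days at 30 deg C under constant temperature, low spontaneous control
#' mortality, and a logistic time course of steepness 2 per day.
#'
#' @param thermal A [thermal_params()] object driving plateaus/rates.
#' @param lt50_by_temp Named numeric vector mapping temperature (deg C,
#'   as names) to median lethal time (days).
#' @param control_rate Daily spontaneous mortality probability of
#'   untreated controls (default 0.005, about 3.5% over 7 days).
#' @param noise_sd Gaussian noise sd for growth trajectories; `NULL`
#'   (default) means 5% of the peak response.
#' @param b Steepness of the logistic time course, per day.
#' @param lt50_default Fallback LT50 (days) for temperatures absent from
#'   `lt50_by_temp`.
#' @return Object of class `simulation_truth`.
#' @export
simulation_truth <- function(thermal = cjavanica_params("virulence"),
                             lt50_by_temp = c("25" = 6.3, "30" = 5.4),
                             control_rate = 0.005, noise_sd = NULL,
                             b = 2, lt50_default = 5.5) {
  stopifnot(inherits(thermal, "thermal_params"),
            control_rate >= 0, control_rate <= 1, b > 0)
  structure(list(thermal = thermal, lt50_by_temp = lt50_by_temp,
                 control_rate = control_rate, noise_sd = noise_sd,
                 b = b, lt50_default = lt50_default),
            class = "simulation_truth")
}

# Choose logistic (d, e) so that F(final_day) = target (the quantity the
# thermal response model is fitted to) AND F(lt50) = 0.5 when target > 0.5.
# Fixed-point iteration on e; converges in a handful of steps. When the
# target never reaches 50% the location is pinned at the nominal lt50 and
# only the plateau is calibrated (no absolute LT50 exists).
calibrate_logistic <- function(target, lt50, b, final_day) {
  shape <- function(e) 1 / (1 + exp(-b * (final_day - e)))
  e <- lt50
  if (target > 0.5) {
    for (i in 1:100) {
      d <- min(target / shape(e), 1)
      if (d <= 0.5) break
      e_new <- lt50 + log(2 * d - 1) / b
      if (abs(e_new - e) < 1e-10) { e <- e_new; break }
      e <- e_new
    }
  }
  list(d = min(target / shape(e), 1), e = e)
}

truth_lt50 <- function(truth, temp) {
  key <- format(temp)
  if (key %in% names(truth$lt50_by_temp)) truth$lt50_by_temp[[key]]
  else truth$lt50_default
}

#' Simulate colony growth trajectories
#'
#' Colony area grows linearly in time at the thermal-response rate of the
#' incubation temperature, with additive Gaussian noise floored at zero.
#' Colony length and width are emitted alongside area under the ellipse
#' convention `area = pi * L * W / 4` with circular colonies (`L = W`).
#' With `noise_sd = 0`, refitting the thermal model to areas at the final
#' day recovers the generating optimum exactly (areas are proportional to
#' the rate).
#'
#' @param truth A [simulation_truth()].
#' @param temps Incubation temperatures, deg C.
#' @param days Assessment days.
#' @param reps Replicates (plates) per temperature.
#' @param seed Integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @return Data frame: `temp, day, replicate, area, length, width`.
#' @export
simulate_growth <- function(truth, temps, days = c(3:7, 10), reps = 10L,
                            seed = 1L) {
  stopifnot(inherits(truth, "simulation_truth"))
  rate <- eval_thermal(temps, truth$thermal)
  sd <- truth$noise_sd %||% (0.05 * max(rate))
  grid <- expand.grid(replicate = seq_len(reps), day = days, temp = temps,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$temp, grid$day, grid$replicate), ]
  mu <- eval_thermal(grid$temp, truth$thermal) * grid$day
  area <- with_preserved_seed(seed,
    pmax(0, mu + stats::rnorm(nrow(grid), 0, sd)))
  len <- sqrt(4 * area / pi)
  data.frame(temp = grid$temp, day = grid$day, replicate = grid$replicate,
             area = area, length = len, width = len, row.names = NULL)
}

#' Simulate binomial mortality time courses
#'
#' For each regime, the cumulative mortality curve is logistic in time
#' with location equal to the regime's true LT50 and a plateau tied to the
#' thermal response: constant regimes plateau at the response evaluated at
#' the treatment temperature, while pulse/alternating regimes plateau at
#' the response of the ambient mean (temperature-insensitive across
#' treatments). The plateau is calibrated so that expected cumulative
#' mortality at the final assessment day equals the thermal-response
#' value, since that is the quantity the response model is fitted to.
#' Each assessment day examines a fresh leaf from the replicate pot, so
#' the day-t dead count is an independent Binomial(n, F(t)) draw per
#' replicate; the cumulative curve is monotone in expectation, and
#' sampling noise can produce small day-to-day dips just as fresh-leaf
#' counts do. Dead nymphs show confirmed mycosis with probability
#' `mycosis_prob`. An untreated control series with daily spontaneous
#' mortality `truth$control_rate` is appended.
#'
#' @param truth A [simulation_truth()].
#' @param regimes List of [temperature_regime()] objects.
#' @param days Assessment days (default 3:7).
#' @param n_per_rep Nymphs per replicate leaf (default 60).
#' @param reps Replicates per regime (default 4).
#' @param seed Integer seed.
#' @param mycosis_prob Probability a killed nymph shows sporulation.
#' @param include_control Append the untreated control series?
#' @return A [mortality_dataset()] with extra columns `mycosed` and `temp`.
#' @export
simulate_mortality <- function(truth, regimes, days = 3:7, n_per_rep = 60L,
                               reps = 4L, seed = 1L, mycosis_prob = 0.95,
                               include_control = TRUE) {
  stopifnot(inherits(truth, "simulation_truth"), length(days) >= 1L)
  days <- sort(unique(as.integer(days)))
  final_day <- max(days)
  if (inherits(regimes, "temperature_regime")) regimes <- list(regimes)

  with_preserved_seed(seed, {
    rows <- list()
    for (rg in regimes) {
      stopifnot(inherits(rg, "temperature_regime"))
      drive_temp <- if (rg$kind == "constant") rg$treatment_temp
                    else rg$ambient_mean
      target <- min(eval_thermal(drive_temp, truth$thermal), 1)
      lt50 <- truth_lt50(truth, if (rg$kind == "constant") rg$treatment_temp
                                else drive_temp)
      curve <- calibrate_logistic(target, lt50, truth$b, final_day)
      Fd <- curve$d / (1 + exp(-truth$b * (days - curve$e)))
      for (rep_i in seq_len(reps)) {
        dead <- stats::rbinom(length(days), n_per_rep, Fd)
        mycosed <- stats::rbinom(length(days), dead, mycosis_prob)
        rows[[length(rows) + 1L]] <- data.frame(
          regime = rg$label, day = days, dead = dead,
          total = n_per_rep, replicate = rep_i, mycosed = mycosed,
          temp = rg$treatment_temp)
      }
    }
    if (include_control) {
      Fc <- 1 - (1 - truth$control_rate)^days
      for (rep_i in seq_len(reps)) {
        dead <- stats::rbinom(length(days), n_per_rep, Fc)
        rows[[length(rows) + 1L]] <- data.frame(
          regime = "control", day = days, dead = dead, total = n_per_rep,
          replicate = rep_i, mycosed = 0L, temp = NA_real_)
      }
    }
    mortality_dataset(do.call(rbind, rows))
  })
}

#' Simulate a monthly climate stack with known structure
#'
#' Generates 12 monthly Tmin/Tmax grid pairs emulating a country-scale
#' layer set: a north-south latitudinal gradient (warmer toward the
#' equator), a seasonal sinusoid peaking in the austral summer (January)
#' whose amplitude grows with latitude, a monthly diurnal range drawn in
#' 6-12 deg C, and optional nodata holes. The generator also returns the
#' analytic cell midpoints and, when a model is supplied, the truth
#' performance class of every cell computed directly from those midpoints
#' (not through the raster pipeline), so projection output can be checked
#' against generator-side truth.
#'
#' @param nrows,ncols Grid dimensions.
#' @param lat_range Latitude span, degrees, `c(south, north)` (default
#'   Brazil-like `c(-34, 5)`).
#' @param seed Integer seed.
#' @param t_equator Annual-mean midpoint at the northern (equatorial)
#'   edge, deg C.
#' @param gradient Cooling per degree of latitude southwards, deg C.
#' @param noise_sd Cell-level spatial noise sd on the midpoint, deg C.
#' @param n_holes Number of random nodata cells punched in every layer.
#' @param params Optional [thermal_params()]; when given, truth classes
#'   are computed with `months` and `edges`.
#' @param months,edges Aggregation months and class edges for the truth
#'   classes (defaults as in [project_response()] /
#'   [classify_performance()]).
#' @return List with `stack` (a [monthly_stack()]), `midpoint` (12-row
#'   matrix list: per-month midpoint matrices), and `truth_classes`
#'   (integer matrix or NULL).
#' @export
simulate_climate <- function(nrows, ncols, lat_range = c(-34, 5),
                             seed = 1L, t_equator = 28, gradient = 0.35,
                             noise_sd = 0.3, n_holes = 0L, params = NULL,
                             months = c(10:12, 1:3), edges = c(10, 25, 60)) {
  stopifnot(nrows >= 1L, ncols >= 1L, lat_range[1] < lat_range[2])
  with_preserved_seed(seed, {
    lat <- seq(lat_range[2], lat_range[1], length.out = nrows)  # north first
    base <- t_equator - gradient * (lat_range[2] - lat)          # per row
    amp <- 1 + 0.12 * abs(lat)
    spatial_noise <- matrix(stats::rnorm(nrows * ncols, 0, noise_sd),
                            nrows, ncols)
    diurnal <- stats::runif(12, 6, 12)
    holes <- if (n_holes > 0L)
      sample(nrows * ncols, min(n_holes, nrows * ncols)) else integer(0)

    cellsize <- (lat_range[2] - lat_range[1]) / nrows
    midpoint <- vector("list", 12L)
    tmin <- vector("list", 12L); tmax <- vector("list", 12L)
    for (mo in 1:12) {
      season <- cos(2 * pi * (mo - 1) / 12)   # peak in January
      mid <- matrix(base + amp * season, nrows, ncols) + spatial_noise
      midpoint[[mo]] <- mid
      lo <- mid - diurnal[mo] / 2
      hi <- mid + diurnal[mo] / 2
      lo[holes] <- NA_real_; hi[holes] <- NA_real_
      tmin[[mo]] <- climate_grid(lo, cellsize, xllcorner = -60,
                                 yllcorner = lat_range[1])
      tmax[[mo]] <- climate_grid(hi, cellsize, xllcorner = -60,
                                 yllcorner = lat_range[1])
    }
    truth_classes <- NULL
    if (!is.null(params)) {
      acc <- Reduce(`+`, lapply(months, function(mo)
        eval_thermal(midpoint[[mo]], params)))
      mort <- pmin(acc / length(months) * 100, 100)
      truth_classes <- matrix(findInterval(mort, edges) + 1L, nrows, ncols)
      truth_classes[holes] <- NA_integer_
    }
    list(stack = monthly_stack(tmin, tmax), midpoint = midpoint,
         truth_classes = truth_classes)
  })
}
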