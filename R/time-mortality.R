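#' Assemble a replicate-level mortality dataset
#'
#' Validates records of cumulative dead counts per assessment day. Each
#' day's count comes from a fresh leaf of the replicate pot, so the
#' recorded cumulative proportion is monotone in expectation but can show
#' small sampling dips day to day; monotonicity is therefore checked on
#' the replicate-aggregated curve of each regime, with a tolerance, and
#' violations beyond it raise a warning rather than an error.
#'
#' @param records Data frame with columns `regime` (label), `day`
#'   (integer >= 0), `dead`, `total` (counts, `0 <= dead <= total`) and
#'   `replicate` (id).
#' @param monotone_tol Largest tolerated decrease of the aggregated
#'   cumulative proportion between consecutive days (default 0.1,
#'   about three standard deviations of aggregate binomial noise at
#'   typical cohort sizes).
#' @return The validated data frame with class `mortality_dataset` and an
#'   added `prop` column (`dead / total`).
#' @export
mortality_dataset <- function(records, monotone_tol = 0.1) {
  req <- c("regime", "day", "dead", "total", "replicate")
  stopifnot(is.data.frame(records), all(req %in% names(records)))
  records$day <- as.integer(records$day)
  if (any(records$day < 0)) stop("day must be >= 0", call. = FALSE)
  if (any(records$dead < 0 | records$dead > records$total))
    stop("dead counts must satisfy 0 <= dead <= total", call. = FALSE)
  records$prop <- records$dead / records$total
  for (grp in split(records, records$regime)) {
    agg <- stats::aggregate(prop ~ day, grp, mean)
    agg <- agg[order(agg$day), ]
    if (nrow(agg) > 1L && any(diff(agg$prop) < -monotone_tol))
      warning("aggregated cumulative mortality decreases by more than ",
              monotone_tol, " within regime '", grp$regime[1], "'",
              call. = FALSE)
  }
  class(records) <- c("mortality_dataset", "data.frame")
  records
}

#' Read a delimited mortality table
#'
#' Columns: `regime, day, dead, total, replicate` (header required;
#' comma, tab or semicolon separated).
#'
#' @param path File path.
#' @return A [mortality_dataset()].
#' @export
read_mortality_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(";", first)) ";" else ","
  mortality_dataset(utils::read.table(path, header = TRUE, sep = sep,
                                      stringsAsFactors = FALSE))
}

#' Fit a time-mortality curve to one temperature regime
#'
#' Fits the chosen cumulative time-course family to replicate-level
#' cumulative mortality proportions versus day, by least squares through
#' [fit_model()]. Proportions are fitted untransformed.
#'
#' @param data A [mortality_dataset()] (a single regime; if several are
#'   present, pass `regime` to select one).
#' @param family Time-course family (see [time_course_params()]).
#' @param regime Optional regime label to subset on.
#' @param options A [fit_options()] list.
#' @return An `epf_fit` (see [fit_model()]); all-zero mortality yields a
#'   degenerate fit flagged via `converged = FALSE` or `d ~ 0`.
#' @export
fit_time_mortality <- function(data, family = "logistic", regime = NULL,
                               options = fit_options()) {
  stopifnot(inherits(data, "mortality_dataset"))
  if (!is.null(regime)) data <- data[data$regime == regime, ]
  if (nrow(data) == 0L) stop("no records for requested regime", call. = FALSE)
  if (length(unique(data$day)) < 3L)
    stop("insufficient data: need at least 3 distinct days", call. = FALSE)
  pts <- data.frame(x = data$day, y = data$prop)
  fit <- fit_model(pts, family, options)
  if (all(data$dead == 0L)) fit$converged <- FALSE
  fit$mortality_data <- data
  fit
}

# closed-form solution of F(t) = 0.5 for each family; NA when d <= 0.5
lt50_closed_form <- function(params) {
  b <- params$b; d <- params$d; e <- params$e
  if (!is.finite(d) || d <= 0.5) return(NA_real_)
  switch(params$family,
    logistic     = e - log(d / 0.5 - 1) / b,
    log_logistic = e * (2 * d - 1)^(-1 / b),
    log_normal   = e * exp(stats::qnorm(0.5 / d) / b),
    weibull      = e * (-log(1 - 0.5 / d))^(1 / b),
    gompertz     = e - log(-log(0.5 / d)) / b
  )
}

#' Estimate the median lethal time (LT50)
#'
#' Solves `F(t) = 0.5` in closed form for the fitted time-course family.
#' The 50% level is absolute mortality, not half the fitted plateau: when
#' the plateau `d` stays below 0.5 the LT50 is reported as not estimable
#' (`defined = FALSE`), matching the convention of leaving LT50 blank for
#' treatments whose cumulative mortality never reaches 50%. The confidence
#' interval is a seeded two-stage percentile bootstrap: replicates are
#' resampled with replacement and, within each drawn replicate, each
#' day's dead count is redrawn as Binomial(total, observed proportion) —
#' each assessment day is a fresh leaf, so day counts resample
#' independently. The second stage matters because with a handful of
#' replicates the dominant variance is binomial sampling within a
#' replicate, which a pure cluster bootstrap cannot see. The curve is
#' refitted to every resample and the LT50 recomputed.
#'
#' @param fit A converged `epf_fit` from [fit_time_mortality()].
#' @param data The [mortality_dataset()] the fit used (defaults to the one
#'   stored in `fit`).
#' @param n_boot Bootstrap replicates (default 999).
#' @param seed Integer seed for resampling.
#' @param level Confidence level (default 0.95).
#' @param options [fit_options()] for the bootstrap refits.
#' @return List of class `lt50_estimate`: `lt50`, `ci_low`, `ci_high`
#'   (days), `defined`, `n_boot_ok`.
#' @export
estimate_lt50 <- function(fit, data = fit$mortality_data, n_boot = 999L,
                          seed = 1L, level = 0.95,
                          options = fit_options(n_starts = 5L)) {
  if (!inherits(fit, "epf_fit") || !isTRUE(fit$converged))
    stop("estimate_lt50 requires a converged time-course fit",
         call. = FALSE)
  lt50 <- lt50_closed_form(fit$params)
  if (is.na(lt50))
    return(structure(list(lt50 = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, defined = FALSE,
                          n_boot_ok = 0L),
                     class = "lt50_estimate"))
  if (is.null(data) || n_boot < 1L)
    return(structure(list(lt50 = lt50, ci_low = NA_real_,
                          ci_high = NA_real_, defined = TRUE,
                          n_boot_ok = 0L),
                     class = "lt50_estimate"))
  stopifnot(inherits(data, "mortality_dataset"))
  reps <- unique(data$replicate)
  rep_info <- lapply(reps, function(r) {
    grp <- data[data$replicate == r, , drop = FALSE]
    grp <- grp[order(grp$day), ]
    list(days = grp$day, n = grp$total, p = grp$prop)
  })
  boot_lt50 <- with_preserved_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      take <- sample(seq_along(reps), length(reps), replace = TRUE)
      resampled <- do.call(rbind, lapply(take, function(j) {
        ri <- rep_info[[j]]
        data.frame(x = ri$days,
                   y = stats::rbinom(length(ri$days), ri$n, ri$p) / ri$n)
      }))
      bf <- tryCatch(fit_model(resampled, fit$model_id, options),
                     error = function(e) NULL)
      if (is.null(bf) || is.null(bf$params)) return(NA_real_)
      lt50_closed_form(bf$params)
    }, numeric(1))
  })
  ok <- boot_lt50[is.finite(boot_lt50)]
  alpha <- (1 - level) / 2
  ci <- if (length(ok) >= 20L)
    unname(stats::quantile(ok, c(alpha, 1 - alpha), type = 7))
  else c(NA_real_, NA_real_)
  structure(list(lt50 = lt50, ci_low = ci[1], ci_high = ci[2],
                 defined = TRUE, n_boot_ok = length(ok)),
            class = "lt50_estimate")
}

#' @export
print.lt50_estimate <- function(x, ...) {
  if (!x$defined) {
    cat("LT50: not estimated (cumulative mortality < 50%)\n")
  } else if (is.na(x$ci_low)) {
    cat(sprintf("LT50: %.2f days (no CI)\n", x$lt50))
  } else {
    cat(sprintf("LT50: %.2f days (95%% CI %.2f-%.2f, %d bootstrap fits)\n",
                x$lt50, x$ci_low, x$ci_high, x$n_boot_ok))
  }
  invisible(x)
}

#' Compare two LT50 estimates by confidence-interval overlap
#'
#' Two median lethal times are declared different when their confidence
#' intervals are disjoint — the comparison rule used when replicate-level
#' data cannot support a formal test.
#'
#' @param a,b `lt50_estimate` objects with `defined = TRUE` and CIs.
#' @return `TRUE` if the intervals do not overlap (the LT50s differ),
#'   `FALSE` otherwise.
#' @export
#' @examples
#' est <- function(l, lo, hi) structure(
#'   list(lt50 = l, ci_low = lo, ci_high = hi, defined = TRUE),
#'   class = "lt50_estimate")
#' ci_overlap(est(5.4, 5.3, 5.4), est(6.3, 6.1, 6.6))  # TRUE: differ
ci_overlap <- function(a, b) {
  for (x in list(a, b)) {
    if (!inherits(x, "lt50_estimate") || !isTRUE(x$defined) ||
        is.na(x$ci_low) || is.na(x$ci_high))
      stop("ci_overlap requires two defined LT50 estimates with CIs",
           call. = FALSE)
  }
  a$ci_high < b$ci_low || b$ci_high < a$ci_low
}

#' Abbott's correction for control mortality
#'
#' Rescales treatment mortality for spontaneous mortality observed in an
#' untreated control: `(p_t - p_c) / (1 - p_c)`, floored at 0. Provided as
#' a utility; the analysis pipeline fits raw mortality by default and
#' compares against controls statistically instead.
#'
#' @param p_treatment,p_control Mortality proportions in \[0, 1\].
#' @return Corrected proportion(s).
#' @export
abbott_correction <- function(p_treatment, p_control) {
  stopifnot(all(p_control >= 0 & p_control < 1))
  pmax(0, (p_treatment - p_control) / (1 - p_control))
}

#' Tabulate LT50 estimates across regimes
#'
#' Fits the chosen family per regime, estimates LT50 with bootstrap CIs,
#' and returns one row per regime; regimes whose plateau stays below 50%
#' get `defined = FALSE` and NA times.
#'
#' @param data A [mortality_dataset()] with one or more regimes.
#' @inheritParams estimate_lt50
#' @param family Time-course family.
#' @return Data frame with columns `regime, lt50, ci_low, ci_high, defined`.
#' @export
lt50_table <- function(data, family = "logistic", n_boot = 999L, seed = 1L,
                       options = fit_options()) {
  stopifnot(inherits(data, "mortality_dataset"))
  regimes <- unique(data$regime)
  rows <- lapply(regimes, function(rg) {
    est <- tryCatch({
      f <- fit_time_mortality(data, family, regime = rg, options = options)
      if (!isTRUE(f$converged))
        return(data.frame(regime = rg, lt50 = NA, ci_low = NA,
                          ci_high = NA, defined = FALSE))
      e <- estimate_lt50(f, n_boot = n_boot, seed = seed)
      data.frame(regime = rg, lt50 = e$lt50, ci_low = e$ci_low,
                 ci_high = e$ci_high, defined = e$defined)
    }, error = function(err)
      data.frame(regime = rg, lt50 = NA, ci_low = NA, ci_high = NA,
                 defined = FALSE))
    est
  })
  do.call(rbind, rows)
}
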