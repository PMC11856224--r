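#' Fitting options
#'
#' Controls for the multi-start bounded nonlinear least-squares used by
#' [fit_model()]. Ratkowsky RSS surfaces are multimodal in (T1, T2), so a
#' single local fit is unreliable; instead `n_starts` starting points are
#' drawn from a Latin hypercube over the parameter bounds (plus one
#' data-driven heuristic start) and the best local optimum is kept. The
#' hypercube is seeded, so identical input always yields identical
#' estimates.
#'
#' @param n_starts Number of Latin-hypercube starting points (default 20).
#' @param seed Integer seed for the start-point hypercube (default 127).
#' @param lower,upper Optional named numeric vectors overriding the default
#'   parameter bounds (defaults: `T1` in \[0, 25\], `T2` in \[25, 45\],
#'   positive scale/rate parameters in (0, 100\], asymptote `d` in
#'   \[0, 1\], location `e` in (0, 100\]).
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(n_starts = 20L, seed = 127L,
                        lower = NULL, upper = NULL, maxiter = 200L) {
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 lower = lower, upper = upper,
                 maxiter = as.integer(maxiter)),
            class = "fit_options")
}

# model registry: parameter names, default bounds, prediction kernel and
# conversion of a raw estimate vector into the user-facing params object
model_info <- function(model_id) {
  tc_families <- c("logistic", "log_logistic", "log_normal", "weibull",
                   "gompertz")
  if (model_id == "ratkowsky1") {
    # cc and k1 enter the response only through cc * k1^2 (any rescaling
    # cc -> a^2 cc, k1 -> k1 / a leaves the curve unchanged), so the
    # 5-parameter surface is rank-deficient and destabilizes the
    # optimizer. The fit therefore estimates the identifiable slope
    # k1' = sqrt(cc) * k1 with cc normalized to 1; the reported (cc, k1)
    # follow that normalization.
    list(
      par_names = c("k1", "k2", "T1", "T2"),
      lower = c(k1 = 1e-6, k2 = 1e-6, T1 = 0,  T2 = 25),
      upper = c(k1 = 100,  k2 = 100,  T1 = 25, T2 = 45),
      predict = function(th, x)
        ratkowsky1_core(x, 1, th["k1"], th["k2"], th["T1"], th["T2"]),
      as_params = function(th)
        thermal_params("ratkowsky1", cc = 1, k1 = th["k1"],
                       k2 = th["k2"], T1 = th["T1"], T2 = th["T2"])
    )
  } else if (model_id == "ratkowsky2") {
    list(
      par_names = c("cc", "k", "T1", "T2"),
      lower = c(cc = 1e-6, k = 1e-6, T1 = 0,  T2 = 25),
      upper = c(cc = 100,  k = 100,  T1 = 25, T2 = 45),
      predict = function(th, x)
        ratkowsky2_core(x, th["cc"], th["k"], th["T1"], th["T2"]),
      as_params = function(th)
        thermal_params("ratkowsky2", cc = th["cc"], k = th["k"],
                       T1 = th["T1"], T2 = th["T2"])
    )
  } else if (model_id %in% tc_families) {
    list(
      par_names = c("b", "d", "e"),
      lower = c(b = 1e-3, d = 0, e = 0.01),
      upper = c(b = 100,  d = 1, e = 100),
      predict = function(th, x)
        time_course_core(x, model_id, th["b"], th["d"], th["e"]),
      as_params = function(th) {
        # constructors reject b or e on the boundary; nudge off zero
        time_course_params(model_id, b = max(th["b"], 1e-3),
                           d = min(max(th["d"], 0), 1),
                           e = max(th["e"], 1e-3))
      }
    )
  } else {
    stop("unknown model_id: ", model_id, call. = FALSE)
  }
}

#' Fit a thermal or time-course model by nonlinear least squares
#'
#' Minimizes the residual sum of squares of `y` against the model response
#' at `x`, using bounded Levenberg-Marquardt from multiple deterministic
#' Latin-hypercube starting points (see [fit_options()]). Non-convergence
#' from every start is flagged, not thrown.
#'
#' @param points A data frame with numeric columns `x` (temperature deg C,
#'   or day) and `y` (response); extra columns (`group`, `replicate`) are
#'   ignored here.
#' @param model_id `"ratkowsky1"`, `"ratkowsky2"`, or a time-course family
#'   (`"logistic"`, `"log_logistic"`, `"log_normal"`, `"weibull"`,
#'   `"gompertz"`).
#' @param options A [fit_options()] list.
#' @return An object of class `epf_fit`: list with `model_id`, `params`
#'   (a [thermal_params()] or [time_course_params()] object), `estimates`
#'   (named numeric), `stats` (a [fit_statistics()] list), `converged`,
#'   `n_starts_used`, `fitted`, `data`.
#' @export
#' @examples
#' truth <- cjavanica_params("growth_exp2")
#' pts <- data.frame(x = 23:33, y = eval_ratkowsky2(23:33, truth))
#' fit <- fit_model(pts, "ratkowsky2")
#' fit$estimates[c("T1", "T2")]
fit_model <- function(points, model_id, options = fit_options()) {
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  x <- as.numeric(points$x); y <- as.numeric(points$y)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  info <- model_info(model_id)
  npar <- length(info$par_names)
  if (length(unique(x)) < npar + 1L)
    stop("insufficient data: need at least ", npar + 1L,
         " distinct x values to fit ", model_id, call. = FALSE)

  lower <- info$lower; upper <- info$upper
  if (!is.null(options$lower)) lower[names(options$lower)] <- options$lower
  if (!is.null(options$upper)) upper[names(options$upper)] <- options$upper

  starts <- make_starts(info, x, y, lower, upper,
                        options$n_starts, options$seed)
  resid_fn <- function(th) {
    names(th) <- info$par_names
    y - info$predict(th, x)
  }

  best <- NULL
  n_used <- 0L
  for (s in seq_len(nrow(starts))) {
    n_used <- n_used + 1L
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[s, ], lower = lower, upper = upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = options$maxiter, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res)) next
    ok <- res$info %in% 1:4
    rss <- res$deviance
    if (!is.finite(rss)) next
    if (is.null(best) || rss < best$rss - 1e-15 ||
        (abs(rss - best$rss) <= 1e-15 && ok && !best$ok)) {
      best <- list(par = stats::setNames(res$par, info$par_names),
                   rss = rss, ok = ok)
    }
  }
  if (is.null(best))
    return(structure(list(model_id = model_id, params = NULL,
                          estimates = NULL, stats = NULL, converged = FALSE,
                          n_starts_used = n_used,
                          data = data.frame(x = x, y = y)),
                     class = "epf_fit"))

  fitted <- info$predict(best$par, x)
  tss <- sum((y - mean(y))^2)
  stats <- if (tss > 0 && length(y) >= npar + 2L)
    fit_statistics(y, fitted, npar) else NULL
  structure(
    list(model_id = model_id,
         params = info$as_params(best$par),
         estimates = best$par,
         stats = stats,
         converged = best$ok,
         n_starts_used = n_used,
         fitted = fitted,
         data = data.frame(x = x, y = y)),
    class = "epf_fit")
}

# LHS over the box [lower, upper], plus a heuristic start from the data
make_starts <- function(info, x, y, lower, upper, n_starts, seed) {
  npar <- length(lower)
  cube <- with_preserved_seed(seed, lhs::randomLHS(n_starts, npar))
  starts <- sweep(cube, 2L, upper - lower, `*`)
  starts <- sweep(starts, 2L, lower, `+`)
  colnames(starts) <- info$par_names
  heur <- (lower + upper) / 2
  if ("T1" %in% info$par_names) {
    heur["T1"] <- min(max(lower["T1"], min(x) - 1), upper["T1"])
    heur["T2"] <- min(max(lower["T2"], max(x) + 1), upper["T2"])
    for (nm in intersect(c("k", "k2"), info$par_names))
      heur[nm] <- 0.2
    scale <- sqrt(max(y, 0))
    if ("cc" %in% info$par_names) {
      heur["cc"] <- max(scale, 0.5)
    } else {
      heur["k1"] <- max(scale, 0.05) / max(1, (max(x) - min(x)) / 2)
    }
  } else {
    heur["d"] <- min(max(max(y, 0.01), lower["d"]), upper["d"])
    heur["e"] <- min(max(stats::median(x), lower["e"]), upper["e"])
    heur["b"] <- 1
  }
  rbind(heur, starts)
}

#' Goodness-of-fit statistics for a least-squares fit
#'
#' @param observed,predicted Numeric vectors of equal length `n >= k + 2`.
#' @param k Number of free model parameters.
#' @return List of class `fit_stats` with `r2` (1 - RSS/TSS), `adj_r2`,
#'   `aic` (least-squares form `n log(RSS/n) + 2 (k + 1)`, counting the
#'   error variance as a parameter), `rmse` (`sqrt(RSS/n)`), `rss`, `n`,
#'   `k`.
#' @export
#' @examples
#' fit_statistics(c(1, 2, 3), c(1, 2, 4), k = 1)$rmse  # sqrt(1/3)
fit_statistics <- function(observed, predicted, k) {
  stopifnot(length(observed) == length(predicted))
  n <- length(observed)
  if (n < k + 2L)
    stop("need n >= k + 2 points for fit statistics", call. = FALSE)
  rss <- sum((observed - predicted)^2)
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0)
    stop("total sum of squares is zero; R^2 undefined", call. = FALSE)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - k - 1)
  aic <- if (rss > 0) n * log(rss / n) + 2 * (k + 1) else -Inf
  structure(list(r2 = r2, adj_r2 = adj_r2, aic = aic,
                 rmse = sqrt(rss / n), rss = rss, n = n, k = k),
            class = "fit_stats")
}

#' Rank fitted models by information criteria
#'
#' Deterministic ordering used for model selection: ascending AIC, ties
#' broken by descending adjusted R^2, then ascending RSS; non-converged
#' fits always rank last (in input order).
#'
#' @param fits A list of `epf_fit` objects, at least one converged.
#' @return The same list, reordered best-first.
#' @export
rank_models <- function(fits) {
  if (length(fits) == 0L) stop("no fits to rank", call. = FALSE)
  conv <- vapply(fits, function(f) isTRUE(f$converged) && !is.null(f$stats),
                 logical(1))
  if (!any(conv)) stop("no converged fit to rank", call. = FALSE)
  key <- function(f) c(f$stats$aic, -f$stats$adj_r2, f$stats$rss)
  keys <- t(vapply(fits[conv], key, numeric(3)))
  ord <- order(keys[, 1], keys[, 2], keys[, 3])
  c(fits[conv][ord], fits[!conv])
}

#' Compare two response curves by a chi-square likelihood-ratio test
#'
#' Fits one pooled curve to both groups and separate curves to each, and
#' tests whether the separate fit improves on the pooled fit. Under
#' Gaussian errors the statistic `n_total * log(RSS_pooled / RSS_separate)`
#' is asymptotically chi-square with degrees of freedom equal to the number
#' of parameters freed (one extra parameter set for the second group).
#'
#' @param group_a,group_b Data frames of points (columns `x`, `y`), each
#'   fittable on its own.
#' @param model_id Model family to fit (see [fit_model()]).
#' @param options A [fit_options()] list.
#' @return List of class `curve_comparison`: `statistic`, `df`, `p_value`,
#'   plus the three underlying fits.
#' @export
compare_curves <- function(group_a, group_b, model_id,
                           options = fit_options()) {
  fit_a <- fit_model(group_a, model_id, options)
  fit_b <- fit_model(group_b, model_id, options)
  pooled <- fit_model(rbind(group_a[c("x", "y")], group_b[c("x", "y")]),
                      model_id, options)
  if (!isTRUE(fit_a$converged) || !isTRUE(fit_b$converged) ||
      !isTRUE(pooled$converged))
    stop("curve comparison requires all three fits to converge",
         call. = FALSE)
  rss_sep <- sum((fit_a$data$y - fit_a$fitted)^2) +
             sum((fit_b$data$y - fit_b$fitted)^2)
  rss_pool <- sum((pooled$data$y - pooled$fitted)^2)
  n_total <- nrow(pooled$data)
  df <- length(model_info(model_id)$par_names)
  if (rss_sep == 0 && rss_pool > 0) {
    stat <- Inf
  } else if (rss_sep == 0 && rss_pool == 0) {
    stat <- 0
  } else {
    stat <- max(0, n_total * log(rss_pool / rss_sep))
  }
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 fit_a = fit_a, fit_b = fit_b, fit_pooled = pooled),
            class = "curve_comparison")
}

#' @export
print.epf_fit <- function(x, ...) {
  cat("Nonlinear least-squares fit:", x$model_id, "\n")
  if (!isTRUE(x$converged)) cat("  (not converged)\n")
  if (!is.null(x$estimates)) {
    cat("  estimates:",
        paste(names(x$estimates), signif(x$estimates, 5),
              sep = " = ", collapse = ", "), "\n")
  }
  if (!is.null(x$stats))
    cat(sprintf("  R2 = %.4f, adj R2 = %.4f, AIC = %.2f, RMSE = %.4g, RSS = %.4g\n",
                x$stats$r2, x$stats$adj_r2, x$stats$aic, x$stats$rmse,
                x$stats$rss))
  invisible(x)
}

#' @export
print.curve_comparison <- function(x, ...) {
  cat(sprintf("Curve comparison (chi-square LR): X2 = %.3f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Read a delimited response table
#'
#' Expects a header with at least `x` and `y`; optional `group` and
#' `replicate` columns are preserved. Field separator is auto-detected
#' among comma, tab and semicolon.
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_response_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(";", first)) ";" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(df)))
    stop("response table must have columns 'x' and 'y': ", path,
         call. = FALSE)
  df
}
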