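test_that("mortality dataset validation enforces count sanity", {
  good <- data.frame(regime = "a", day = rep(3:5, 2), dead = c(1, 2, 3, 0, 2, 2),
                     total = 10, replicate = rep(1:2, each = 3))
  md <- mortality_dataset(good)
  expect_s3_class(md, "mortality_dataset")
  expect_equal(md$prop, md$dead / md$total)
  bad <- good; bad$dead[1] <- 11
  expect_error(mortality_dataset(bad), "dead counts")
  neg <- good; neg$day[1] <- -1
  expect_error(mortality_dataset(neg), "day")
  dip <- good; dip$dead <- c(8, 1, 8, 8, 1, 8)  # aggregate crashes mid-course
  expect_warning(mortality_dataset(dip), "decreases")
})

test_that("LT50 closed forms invert F(t) = 0.5 for every family", {
  # anchor cases with hand-derived values
  expect_equal(
    epftherm:::lt50_closed_form(time_course_params("logistic", b = 2,
                                                   d = 1, e = 5)),
    5, tolerance = 1e-12)
  expect_equal(
    epftherm:::lt50_closed_form(time_course_params("logistic", b = 1,
                                                   d = 0.8, e = 5)),
    5 - log(0.6), tolerance = 1e-12)  # 5.5108
  # round-trip property across families and random valid parameters
  set.seed(17)
  for (family in tc_families) {
    for (i in 1:10) {
      p <- random_time_course(family, d_min = 0.51)
      t50 <- epftherm:::lt50_closed_form(p)
      expect_true(is.finite(t50))
      expect_equal(eval_time_course(t50, p), 0.5, tolerance = 1e-9,
                   label = family)
    }
    # plateau below one half: no absolute LT50
    low <- time_course_params(family, b = 1, d = 0.4, e = 5)
    expect_true(is.na(epftherm:::lt50_closed_form(low)))
  }
})

test_that("time-mortality fitting recovers a known logistic curve", {
  tr <- simulation_truth(lt50_by_temp = c("30" = 5.4))
  md <- simulate_mortality(tr, temperature_regime("constant", 30),
                           seed = 301, include_control = FALSE)
  fit <- fit_time_mortality(md, "logistic", regime = "constant_30")
  expect_true(fit$converged)
  # noise-free curve interpolates exactly
  p <- time_course_params("logistic", b = 1.5, d = 0.7, e = 5.5)
  days <- 1:9
  clean <- mortality_dataset(data.frame(
    regime = "clean", day = days,
    dead = round(eval_time_course(days, p) * 1e6), total = 1e6,
    replicate = 1))
  cf <- fit_time_mortality(clean, "logistic")
  expect_lt(cf$stats$rss, 1e-10)
  expect_lt(abs(cf$estimates[["e"]] - 5.5), 0.01)
  # insufficient days error
  one_day <- mortality_dataset(data.frame(regime = "x", day = 7, dead = 3,
                                          total = 10, replicate = 1:4))
  expect_error(fit_time_mortality(one_day, "logistic"), "3 distinct days")
})

test_that("logistic parameter recovery from binomial data lands near truth", {
  # truth: d = 0.7, b = 1.5, e = 5.5; 60 nymphs/day, 4 replicates
  p <- time_course_params("logistic", b = 1.5, d = 0.7, e = 5.5)
  set.seed(77)
  days <- 3:7
  recs <- do.call(rbind, lapply(1:4, function(r)
    data.frame(regime = "t", day = days,
               dead = rbinom(length(days), 60, eval_time_course(days, p)),
               total = 60, replicate = r)))
  fit <- fit_time_mortality(mortality_dataset(recs), "logistic")
  expect_lt(abs(fit$estimates[["e"]] - 5.5), 0.3)
})

test_that("LT50 estimation honours the 50%-mortality rule and covers truth", {
  tr <- simulation_truth(lt50_by_temp = c("30" = 5.4))
  md <- simulate_mortality(tr, temperature_regime("constant", 30),
                           seed = 42, include_control = FALSE)
  fit <- fit_time_mortality(md, "logistic", regime = "constant_30")
  est <- estimate_lt50(fit, n_boot = 199, seed = 9)
  expect_true(est$defined)
  expect_lt(abs(est$lt50 - 5.4), 0.5)
  expect_true(est$ci_low <= est$lt50 && est$lt50 <= est$ci_high)
  # identical seed gives identical interval
  est2 <- estimate_lt50(fit, n_boot = 199, seed = 9)
  expect_identical(est, est2)
  # plateau below 50%: not estimable
  low_fit <- fit
  low_fit$params <- time_course_params("logistic", b = 2, d = 0.4, e = 5)
  low_est <- estimate_lt50(low_fit, n_boot = 0)
  expect_false(low_est$defined)
  expect_true(is.na(low_est$lt50))
  expect_error(estimate_lt50(structure(list(converged = FALSE),
                                       class = "epf_fit")), "converged")
})

test_that("bootstrap CI contains the point estimate and the generating LT50", {
  tr <- simulation_truth(lt50_by_temp = c("30" = 5.4))
  rg <- temperature_regime("constant", 30)
  res <- vapply(1:10, function(s) {
    md <- simulate_mortality(tr, rg, seed = s, include_control = FALSE)
    f <- fit_time_mortality(md, "logistic", regime = "constant_30")
    e <- estimate_lt50(f, n_boot = 99, seed = s)
    c(point_in = e$ci_low <= e$lt50 && e$lt50 <= e$ci_high,
      truth_in = e$ci_low <= 5.4 && 5.4 <= e$ci_high)
  }, logical(2))
  expect_true(all(res["point_in", ]))
  expect_gte(mean(res["truth_in", ]), 0.9)
})

test_that("CI-overlap comparison reproduces the published interval calls", {
  est <- function(l, lo, hi) structure(
    list(lt50 = l, ci_low = lo, ci_high = hi, defined = TRUE),
    class = "lt50_estimate")
  # constant 30 vs 25 deg C: disjoint intervals, LT50s differ
  expect_true(ci_overlap(est(5.4, 5.3, 5.4), est(6.3, 6.1, 6.6)))
  # fluctuating 35 vs 30 deg C: overlapping, no difference
  expect_false(ci_overlap(est(4.9, 4.6, 5.3), est(4.7, 3.8, 5.7)))
  e <- est(5, 4.8, 5.2)
  expect_false(ci_overlap(e, e))
  undef <- structure(list(lt50 = NA, ci_low = NA, ci_high = NA,
                          defined = FALSE), class = "lt50_estimate")
  expect_error(ci_overlap(e, undef), "defined")
})

test_that("Abbott correction rescales for control mortality", {
  expect_equal(abbott_correction(0.55, 0.1), 0.5)
  expect_equal(abbott_correction(0.05, 0.1), 0)
  expect_equal(abbott_correction(0.1, 0), 0.1)
})

test_that("lt50_table summarizes regimes and mortality files round-trip", {
  tr <- simulation_truth(lt50_by_temp = c("25" = 6.3, "30" = 5.4))
  regs <- list(temperature_regime("constant", 30),
               temperature_regime("constant", 15))  # below T1: plateau ~ 0
  md <- simulate_mortality(tr, regs, seed = 12)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(md)[c("regime", "day", "dead", "total",
                                "replicate")], tmp, row.names = FALSE)
  back <- read_mortality_table(tmp)
  expect_s3_class(back, "mortality_dataset")
  tab <- lt50_table(back, n_boot = 49, seed = 2)
  expect_setequal(tab$regime, c("constant_30", "constant_15", "control"))
  r30 <- tab[tab$regime == "constant_30", ]
  expect_true(r30$defined)
  expect_lt(abs(r30$lt50 - 5.4), 0.6)
  expect_false(tab[tab$regime == "constant_15", "defined"])
  expect_false(tab[tab$regime == "control", "defined"])
})
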