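test_that("generators are pure functions of parameters and seed", {
  tr <- simulation_truth()
  g1 <- simulate_growth(tr, temps = c(20, 25, 30), seed = 4)
  g2 <- simulate_growth(tr, temps = c(20, 25, 30), seed = 4)
  expect_identical(g1, g2)
  rg <- temperature_regime("constant", 25)
  m1 <- simulate_mortality(tr, rg, seed = 4)
  m2 <- simulate_mortality(tr, rg, seed = 4)
  expect_identical(m1, m2)
  c1 <- simulate_climate(5, 5, seed = 4)
  c2 <- simulate_climate(5, 5, seed = 4)
  expect_identical(c1, c2)
  expect_false(identical(simulate_climate(5, 5, seed = 5)$stack,
                         c1$stack))
})

test_that("growth is null at the lower cardinal temperature", {
  tr <- simulation_truth(thermal = cjavanica_params("growth_exp2"),
                         noise_sd = 0)
  g <- simulate_growth(tr, temps = 22.907, days = c(3, 7, 10), seed = 1)
  expect_true(all(g$area == 0))
  expect_true(all(g$length == 0))
})

test_that("areas follow the ellipse convention and noise-free refits recover T_opt", {
  tr <- simulation_truth(thermal = cjavanica_params("growth_exp3"),
                         noise_sd = 0)
  g <- simulate_growth(tr, temps = seq(20, 31, by = 1), days = c(5, 10),
                       reps = 2, seed = 1)
  expect_equal(g$area, pi * g$length * g$width / 4, tolerance = 1e-12)
  d10 <- g[g$day == 10 & g$replicate == 1, ]
  fit <- fit_model(data.frame(x = d10$temp, y = d10$area), "ratkowsky2")
  t_true <- thermal_optimum(tr$thermal)$T_opt
  expect_lt(abs(thermal_optimum(fit$params)$T_opt - t_true), 0.1)
})

test_that("constant-regime mortality plateaus follow the thermal response", {
  tr <- simulation_truth()
  md <- simulate_mortality(tr, temperature_regime("constant", 30),
                           seed = 8, n_per_rep = 2000L, reps = 4L,
                           include_control = FALSE)
  d7 <- md[md$day == 7, ]
  # large-n day-7 mortality approaches the response value ~0.680
  expect_lt(abs(sum(d7$dead) / sum(d7$total) -
                  eval_ratkowsky1(30, tr$thermal)), 0.02)
  # below the lower cardinal temperature mortality is essentially absent
  cold <- simulate_mortality(tr, temperature_regime("constant", 15),
                             seed = 8, n_per_rep = 2000L,
                             include_control = FALSE)
  c7 <- cold[cold$day == 7, ]
  expect_lt(sum(c7$dead) / sum(c7$total), 0.01)
})

test_that("mycosis confirmation tracks dead counts", {
  tr <- simulation_truth()
  md <- simulate_mortality(tr, temperature_regime("constant", 30),
                           seed = 3, n_per_rep = 1000L,
                           include_control = FALSE)
  expect_true(all(md$mycosed <= md$dead))
  d7 <- md[md$day == 7, ]
  expect_lt(abs(sum(d7$mycosed) / sum(d7$dead) - 0.95), 0.03)
})

test_that("pulse and alternating regimes are temperature-insensitive", {
  tr <- simulation_truth()
  regs <- lapply(c(15, 20, 25, 30, 35), function(tp)
    temperature_regime("daily_alternating", tp, ambient_mean = 30.2))
  # pairwise curve comparisons reject far less often than separated groups
  # would, and close to a calibrated test's nominal rate
  rejections <- 0L; n_pairs <- 0L
  for (s in 1:3) {
    md <- simulate_mortality(tr, regs, seed = s, include_control = FALSE)
    labs <- unique(md$regime)
    for (i in 1:(length(labs) - 1)) for (j in (i + 1):length(labs)) {
      ga <- md[md$regime == labs[i], ]
      gb <- md[md$regime == labs[j], ]
      p <- compare_curves(data.frame(x = ga$day, y = ga$prop),
                          data.frame(x = gb$day, y = gb$prop),
                          "logistic", fit_options(n_starts = 8))$p_value
      n_pairs <- n_pairs + 1L
      rejections <- rejections + (p < 0.05)
    }
  }
  expect_lt(rejections / n_pairs, 0.2)
  # ...whereas a genuinely different (constant cold) regime is detected
  cold <- simulate_mortality(tr, temperature_regime("constant", 20),
                             seed = 1, include_control = FALSE)
  warm <- simulate_mortality(tr, temperature_regime("constant", 30),
                             seed = 1, include_control = FALSE)
  p_diff <- compare_curves(
    data.frame(x = cold$day, y = cold$prop),
    data.frame(x = warm$day, y = warm$prop),
    "logistic", fit_options(n_starts = 8))$p_value
  expect_lt(p_diff, 0.001)
})

test_that("end-to-end optimum recovery from simulated bioassays", {
  tr <- simulation_truth()
  t_true <- thermal_optimum(tr$thermal)$T_opt
  temps <- c(18, 21, 24, 27, 30, 33, 35)
  regs <- lapply(temps, function(tp) temperature_regime("constant", tp))
  errs <- vapply(1:20, function(s) {
    md <- simulate_mortality(tr, regs, seed = s, include_control = FALSE)
    d7 <- md[md$day == 7, ]
    agg <- stats::aggregate(cbind(dead, total) ~ temp, d7, sum)
    f <- fit_model(data.frame(x = agg$temp, y = agg$dead / agg$total),
                   "ratkowsky1")
    abs(thermal_optimum(f$params)$T_opt - t_true)
  }, numeric(1))
  expect_lt(median(errs), 0.5)
})

test_that("synthetic climate has the advertised structure", {
  sim <- simulate_climate(30, 8, lat_range = c(-34, 5), seed = 10)
  s <- sim$stack
  # north (row 1) warmer than south (last row) in every month
  for (mo in c(1, 7)) {
    expect_gt(mean(s$tmin[[mo]]$values[1, ]),
              mean(s$tmin[[mo]]$values[30, ]))
  }
  # diurnal range within 6-12 deg C everywhere
  rng <- s$tmax[[4]]$values - s$tmin[[4]]$values
  expect_true(all(rng >= 6 & rng <= 12))
  # seasonal cycle: January warmer than July (austral summer peak)
  expect_gt(mean(s$tmax[[1]]$values), mean(s$tmax[[7]]$values))
  # nodata holes punched consistently across layers
  holes <- simulate_climate(10, 10, seed = 2, n_holes = 7)
  na1 <- is.na(holes$stack$tmin[[1]]$values)
  expect_equal(sum(na1), 7)
  expect_identical(na1, is.na(holes$stack$tmax[[6]]$values))
})

test_that("a flat zero-gradient climate yields a single class everywhere", {
  p <- fig5_virulence()
  sim <- simulate_climate(6, 6, seed = 3, t_equator = 28, gradient = 0,
                          noise_sd = 0, params = p)
  # flatten the seasonal cycle too so every midpoint is exactly 28
  flat <- uniform_stack(28, nrows = 6, ncols = 6, diurnal = 8)
  pm <- classify_performance(project_response(flat, p))
  expect_equal(length(unique(as.vector(pm$classes$values))), 1L)
  # and the gradient version agrees with its own analytic truth
  pm2 <- classify_performance(project_response(sim$stack, p))
  expect_true(all(pm2$classes$values == sim$truth_classes))
})
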