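# fixture parameter sets (published fits bundled with the package)
fig5_virulence <- function() cjavanica_params("virulence")
table6_sets <- function() {
  list(growth_exp1 = cjavanica_params("growth_exp1"),
       growth_exp2 = cjavanica_params("growth_exp2"),
       growth_exp3 = cjavanica_params("growth_exp3"))
}
all_fixture_sets <- function() c(list(virulence = fig5_virulence()),
                                 table6_sets())

tc_families <- c("logistic", "log_logistic", "log_normal", "weibull",
                 "gompertz")

# random valid parameter draws for property loops
random_thermal <- function(model_id, n = 1L) {
  lapply(seq_len(n), function(i) {
    T1 <- runif(1, 2, 22)
    T2 <- T1 + runif(1, 6, 25)
    if (model_id == "ratkowsky1")
      thermal_params("ratkowsky1", cc = runif(1, 0.5, 5),
                     k1 = runif(1, 0.02, 0.5), k2 = runif(1, 0.05, 0.6),
                     T1 = T1, T2 = T2)
    else
      thermal_params("ratkowsky2", cc = runif(1, 0.5, 8),
                     k = runif(1, 0.05, 0.6), T1 = T1, T2 = T2)
  })
}

random_time_course <- function(family, d_min = 0) {
  time_course_params(family, b = runif(1, 0.3, 4),
                     d = runif(1, d_min, 1),
                     e = runif(1, 2, 9))
}

# small uniform-temperature monthly stack
uniform_stack <- function(temp, nrows = 5, ncols = 4, diurnal = 0) {
  g <- function(v) climate_grid(matrix(v, nrows, ncols), cellsize = 0.5)
  monthly_stack(replicate(12, g(temp - diurnal / 2), simplify = FALSE),
                replicate(12, g(temp + diurnal / 2), simplify = FALSE))
}
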