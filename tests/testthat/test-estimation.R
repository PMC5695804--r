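test_that("min-max scaling maps extremes to 0/1 and ignores affine units", {
  expect_equal(scale_measurements(c(1, 3, 5)), c(0, 0.5, 1))
  expect_equal(scale_measurements(c(0, 10)), c(0, 1))
  x <- c(2, 9, 4, 7)
  expect_equal(scale_measurements(3.6 * x + 12), scale_measurements(x))
  expect_error(scale_measurements(c(4, 4, 4)),
               class = "complementr_degenerate_scaling")
})

test_that("the objective vanishes for a perfect fit and isolates scale errors", {
  m <- default_model_fx()
  data <- noiseless_data_fx()
  o1 <- measurement_objective(m, data, conditions = "zymosan_0")
  o2 <- measurement_objective(m, data, conditions = "zymosan_1")
  expect_lt(o1, 1e-8)
  # the C3a peak falls between sampling times, leaving a tiny residual scale
  # term even for a perfect fit
  expect_lt(o2, 1e-3)
  # halving the measured values keeps the shape term at zero but makes the
  # scale term ((M' - max y)/M')^2 ~ 1 per series (2 species)
  half <- data[data$condition == "zymosan_1", ]
  half$value <- half$value / 2
  o_half <- measurement_objective(m, half, conditions = "zymosan_1")
  expect_equal(o_half, 2, tolerance = 0.05)
})

test_that("the objective matches a hand-assembled evaluation on 3 points", {
  m <- default_model_fx()
  meas <- tibble::tibble(
    condition = "zymosan_1", dose_mg_ml = 1, species = "C3a",
    time = c(2, 4, 6), value = c(150, 1100, 3200), units = "nM",
    split = "train")
  got <- measurement_objective(m, meas, conditions = "zymosan_1",
                               species = "C3a")
  # independent arithmetic on the simulated curve
  tr <- simulate_model(m, dose = 1, t_span = c(0, 6), n_out = 200)
  y <- approx(tr$time, tr$C3a, xout = c(2, 4, 6))$y
  m_hat <- (meas$value - min(meas$value)) / diff(range(meas$value))
  y_hat <- (y - min(y)) / diff(range(y))
  expected <- sum((m_hat - y_hat)^2) +
    ((max(meas$value) - max(tr$C3a)) / max(meas$value))^2
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("simulation failure turns the objective into Inf with a warning", {
  m <- default_model_fx()
  data <- noiseless_data_fx()
  p <- model_parameter_values(m)
  p[grep("_kcat$|_kmax$|assembly", names(p))] <- 1e300
  expect_warning(
    val <- measurement_objective(m, data, params = p,
                                 conditions = "zymosan_1"),
    "objective set to Inf")
  expect_identical(val, Inf)
})

test_that("the warm-start optimizer solves a smooth benchmark and is seeded", {
  sphere <- function(x) sum(x^2)
  lo <- rep(-5, 5); hi <- rep(5, 5)
  r1 <- dops_warm_start(sphere, lo, hi, budget = 2000, seed = 3)
  expect_lt(r1$value, 1e-2)
  expect_true(all(r1$par >= lo & r1$par <= hi))
  r2 <- dops_warm_start(sphere, lo, hi, budget = 2000, seed = 3)
  expect_identical(r1, r2)
  # budget 1 returns the single evaluated point
  r3 <- dops_warm_start(sphere, lo, hi, budget = 1, seed = 1)
  expect_identical(r3$evals, 1L)
  expect_equal(r3$par, (lo + hi) / 2)
})

test_that("Pareto ranking reproduces strict domination and trade-offs", {
  expect_identical(pareto_rank(rbind(c(1, 2), c(2, 3))), c(0L, 1L))
  expect_identical(pareto_rank(rbind(c(1, 3), c(3, 1))), c(0L, 0L))
  set.seed(99)
  m <- matrix(runif(40), ncol = 2)
  expect_identical(pareto_rank(m), brute_force_ranks(m))
})

test_that("the annealing ensemble spans the toy bi-objective trade-off", {
  # two quadratic bowls with minima at -1 and +1
  fn <- function(x) c((x[1] - 1)^2, (x[1] + 1)^2)
  e1 <- poets_ensemble(fn, start = c(x = 0), lower = -3, upper = 3,
                       iterations = 400, target_size = 200, seed = 5,
                       step = 0.2)
  e2 <- poets_ensemble(fn, start = c(x = 0), lower = -3, upper = 3,
                       iterations = 400, target_size = 200, seed = 5,
                       step = 0.2)
  expect_identical(e1, e2)
  front <- e1[e1$rank == 0, ]
  expect_gt(nrow(front), 5)
  # the rank-0 front lives between the two single-objective optima and
  # reaches toward both ends
  expect_true(all(front$x >= -1 - 1e-6 & front$x <= 1 + 1e-6))
  expect_lt(min(front$x), -0.5)
  expect_gt(max(front$x), 0.5)
  # archive ranks satisfy the layered non-domination definition
  expect_identical(e1$rank,
                   brute_force_ranks(as.matrix(e1[, c("o1", "o2")])))
})

test_that("AIC obeys its penalty and log identities and floors zero residuals", {
  a <- aic_value(28, 40, rss = 2.5, m_norm = 100)
  expect_equal(as.numeric(aic_value(56, 40, 2.5, 100)) - as.numeric(a),
               2 * 28)
  expect_equal(as.numeric(aic_value(28, 40, 2.5 * exp(1), 100)) -
                 as.numeric(a), 40)
  z <- aic_value(28, 40, 0, 100)
  expect_true(attr(z, "floored"))
  expect_lt(as.numeric(z), as.numeric(a))
})

test_that("model AIC is computed from the normalized residual", {
  m <- default_model_fx()
  data <- noiseless_data_fx()
  train <- data[data$split == "train", ]
  a <- aic_score(m, train)
  # perfect simulation: residual ~ 0 against noiseless data
  expect_lt(as.numeric(a), 2 * 28 + nrow(train) * log(1e-10))
})

test_that("random parameter controls respect bounds and the seed", {
  m <- default_model_fx()
  d1 <- random_parameter_control(m$parameters, 50, seed = 4)
  d2 <- random_parameter_control(m$parameters, 50, seed = 4)
  expect_identical(d1, d2)
  for (p in m$parameters$name) {
    lo <- m$parameters$lower[m$parameters$name == p]
    hi <- m$parameters$upper[m$parameters$name == p]
    expect_true(all(d1[[p]] >= lo & d1[[p]] <= hi))
  }
  # log-uniform: median of log10 draws near the log-midpoint
  b <- tibble::tibble(name = "k", lower = 0.1, upper = 1)
  d <- random_parameter_control(b, 1000, seed = 8)
  expect_lt(abs(median(log10(d$k)) - (-0.5)), 0.2 / 2)
})
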