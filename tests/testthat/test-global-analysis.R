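# closed-form total-order indices of the Ishigami benchmark (a = 7, b = 0.1)
ishigami <- function(x, a = 7, b = 0.1) {
  sin(x[, 1]) + a * sin(x[, 2])^2 + b * x[, 3]^4 * sin(x[, 1])
}
ishigami_total <- function(a = 7, b = 0.1) {
  v1 <- 0.5 * (1 + b * pi^4 / 5)^2
  v2 <- a^2 / 8
  v13 <- 8 * b^2 * pi^8 / 225
  v <- v1 + v2 + v13
  c((v1 + v13) / v, v2 / v, v13 / v)
}

test_that("Saltelli samples have exactly N(2d+2) rows inside the bounds", {
  lo <- c(a = 0, b = -1, c = 10)
  hi <- c(a = 1, b = 1, c = 20)
  s <- saltelli_sample(lo, hi, N = 5, seed = 2)
  expect_identical(nrow(s), 5L * (2L * 3L + 2L))
  expect_true(all(sweep(s, 2, lo, `>=`)) && all(sweep(s, 2, hi, `<=`)))
  expect_identical(nrow(saltelli_sample(c(x = 0), c(x = 1), N = 2)), 8L)
  # property over random (N, d)
  set.seed(3)
  for (i in 1:5) {
    N <- sample(2:20, 1); d <- sample(1:10, 1)
    s <- saltelli_sample(rep(0, d), rep(1, d), N = N)
    expect_identical(nrow(s), as.integer(N * (2 * d + 2)))
  }
})

test_that("total-order estimates recover the Ishigami closed form", {
  lo <- rep(-pi, 3); hi <- rep(pi, 3)
  s <- saltelli_sample(lo, hi, N = 1024, seed = 7)
  st <- sobol_total_indices(ishigami(s), sample = s)
  expect_true(all(abs(st$total_order - ishigami_total()) < 0.05))
  expect_true(all(st$ci_lower <= st$total_order &
                    st$total_order <= st$ci_upper))
})

test_that("inert inputs earn a zero total index and active ones earn 1", {
  s <- saltelli_sample(c(x1 = 0, x2 = 0), c(x1 = 1, x2 = 1), N = 1024,
                       seed = 11)
  st <- sobol_total_indices(s[, 1], sample = s)  # y = x1, x2 inert
  expect_lt(abs(st$total_order[1] - 1), 0.05)
  expect_lt(abs(st$total_order[2]), 0.05)
  # the inert parameter's CI covers 0
  expect_lte(st$ci_lower[2], 1e-10)
})

test_that("a constant response makes total indices undefined", {
  s <- saltelli_sample(c(x = 0), c(x = 1), N = 16, seed = 1)
  expect_error(sobol_total_indices(rep(3, nrow(s)), sample = s),
               class = "complementr_zero_variance")
})

test_that("the model-level sensitivity wrapper runs at desk scale", {
  m <- default_model_fx()
  data <- noiseless_data_fx()
  st <- sobol_sensitivity(m, data, conditions = "zymosan_1", N = 4, seed = 2,
                          n_boot = 20)
  expect_identical(nrow(st), 28L)
  expect_identical(attr(st, "n_evaluations"), 4L * (2L * 28L + 2L))
  expect_true(all(is.finite(st$total_order)))
})

test_that("robustness coefficients are log ratios of marker AUCs", {
  m <- default_model_fx()
  tr <- simulate_model(m, dose = 1, t_span = c(0, 6), n_out = 60)
  expect_equal(robustness_coefficient(tr, tr, "C3a"), 0)
  tr10 <- tr
  tr10$C3a <- tr$C3a * 10
  expect_equal(robustness_coefficient(tr, tr10, "C3a"), 1)
  # unit changes cancel in the ratio
  trk <- tr; trk$C3a <- tr$C3a * 1000
  trk10 <- tr10; trk10$C3a <- tr10$C3a * 1000
  expect_equal(robustness_coefficient(trk, trk10, "C3a"), 1)
  zero <- tr; zero$C5b <- 0
  expect_error(robustness_coefficient(zero, tr, "C5b"),
               class = "complementr_undefined_coefficient")
})

test_that("C3a is exactly insensitive to C5 knockdowns", {
  m <- default_model_fx()
  for (dz in c(0, 1)) {
    nominal <- simulate_model(m, dose = dz)
    kd <- simulate_model(m, ic = knockdown(model_initial_conditions(m),
                                           "C5", 99)["C5"], dose = dz)
    expect_lt(abs(robustness_coefficient(nominal, kd, "C3a")), 1e-8)
  }
})

test_that("the robustness study reports the expected factorial structure", {
  m <- default_model_fx()
  rt <- robustness_study(m, levels = c(0, 90), doses = c(0, 1),
                         t_span = c(0, 6))
  expect_identical(nrow(rt), 2L * 3L * 2L * 2L)  # markers x targets x levels x doses
  # 0% knockdown leaves every marker unchanged
  expect_true(all(abs(rt$alpha[rt$level == 0]) < 1e-10))
  # C5-only knockdown never moves C3a
  expect_true(all(abs(rt$alpha[rt$marker == "C3a" & rt$target == "C5"]) < 1e-8))
  # knockdowns do not increase marker exposure
  expect_true(all(rt$alpha <= 1e-10))
})

test_that("joint C3+C5 knockdown outranks either single knockdown for C5a", {
  m <- default_model_fx()
  rt <- robustness_study(m, levels = 90, doses = 1, t_span = c(0, 8))
  a <- function(tg) rt$alpha[rt$marker == "C5a" & rt$target == tg]
  expect_lte(a("C3+C5"), a("C3"))
  expect_lte(a("C3+C5"), a("C5"))
})

test_that("C5a is more robust to C3 knockdown when the lectin gate is open", {
  m <- default_model_fx()
  rt <- robustness_study(m, levels = 99, doses = c(0, 1), t_span = c(0, 8))
  a0 <- rt$alpha[rt$marker == "C5a" & rt$target == "C3" & rt$dose == 0]
  a1 <- rt$alpha[rt$marker == "C5a" & rt$target == "C3" & rt$dose == 1]
  expect_lt(abs(a1), abs(a0))
})

test_that("pairwise displacement floors null rows and compounds the diagonal", {
  m <- default_model_fx()
  pars <- c("lectin_c4_kmax", "tickover_k", "cp_c3_kcat")
  # at zero dose the lectin gate is shut: perturbing its rate alone does
  # nothing (off-diagonal cells still move through the partner parameter)
  pw0 <- pairwise_displacement(m, dose = 0, parameters = pars,
                               t_span = c(0, 4), n_out = 12)
  expect_identical(pw0$matrix["lectin_c4_kmax", "lectin_c4_kmax"],
                   log10(1e-12))
  expect_identical(sort(unique(pw0$clusters$label)),
                   sort(unique(c("high", "medium", "low")[
                     seq_len(length(unique(pw0$clusters$cluster)))])))
  # delta = 0 leaves the model at its nominal state everywhere
  pwz <- pairwise_displacement(m, dose = 1, parameters = pars[1:2],
                               delta = 0, t_span = c(0, 4), n_out = 12)
  expect_true(all(pwz$matrix == log10(1e-12)))
  # diagonal cell (p, p) compounds to a (1+delta)^2 single-parameter change
  pw <- pairwise_displacement(m, dose = 1, parameters = "tickover_k",
                              t_span = c(0, 4), n_out = 12)
  times <- seq(0, 4, length.out = 12)
  nominal <- simulate_model(m, dose = 1, times = times)
  pp <- model_parameter_values(m)
  pp["tickover_k"] <- pp[["tickover_k"]] * 1.1^2
  pert <- simulate_model(m, params = pp, dose = 1, times = times)
  sp <- m$species$name
  d_direct <- sqrt(sum((as.matrix(pert[, sp]) - as.matrix(nominal[, sp]))^2))
  expect_equal(pw$matrix["tickover_k", "tickover_k"], log10(d_direct),
               tolerance = 1e-6)
})

test_that("pairwise displacement is symmetric and clusters into three groups", {
  m <- default_model_fx()
  pars <- c("tickover_k", "cp_c3_kcat", "ap_c3_assembly_k", "c3a_deg_k",
            "lectin_c4_kmax", "cp_c5_kcat")
  pw <- pairwise_displacement(m, dose = 1, parameters = pars,
                              t_span = c(0, 6), n_out = 12)
  expect_equal(pw$matrix, t(pw$matrix))
  expect_identical(length(unique(pw$clusters$cluster)), 3L)
  expect_setequal(unique(pw$clusters$label), c("high", "medium", "low"))
})
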