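test_that("Hill transfer hits its landmark values and stays in [0,1]", {
  expect_equal(hill_transfer(2, K = 2, n = 1), 0.5)
  expect_equal(hill_transfer(5, K = 5, n = 3.7), 0.5)
  expect_equal(hill_transfer(0, K = 1, n = 2), 0)
  expect_equal(hill_transfer(0, K = 1, n = 2, "inhibiting"), 1)
  expect_equal(hill_transfer(6, K = 2, n = 2), 9 / 10)
  # property: bounded on random non-negative inputs
  set.seed(11)
  for (i in 1:50) {
    v <- hill_transfer(rexp(1, 0.1), K = rexp(1) + 0.01, n = runif(1, 0.2, 5),
                       sample(c("activating", "inhibiting"), 1))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("Hill transfer rejects non-positive gain or order", {
  expect_error(hill_transfer(1, K = 0, n = 1), class = "complementr_invalid_rule")
  expect_error(hill_transfer(1, K = 1, n = -2), class = "complementr_invalid_rule")
  expect_error(hill_transfer(-1, K = 1, n = 1), class = "complementr_domain_error")
})

test_that("control integration selects min/max and defaults to 1", {
  # factors engineered to produce transfer outputs 0.2 and 0.7
  factors <- list(
    list(actor = "A", direction = "activating", K = 4, n = 1),  # 1/(4+1)=0.2
    list(actor = "B", direction = "activating", K = 3, n = 1)   # 7/10 = 0.7
  )
  state <- c(A = 1, B = 7)
  expect_equal(integrate_control(control_rule("rx", "min", factors), state), 0.2)
  expect_equal(integrate_control(control_rule("rx", "max", factors), state), 0.7)
  expect_identical(integrate_control(NULL, state), 1)
})

test_that("control factors can read external inputs and reject unknown actors", {
  rule <- control_rule("rx", "min", list(
    list(actor = "zymosan", direction = "activating", K = 1, n = 1)))
  expect_equal(integrate_control(rule, c(A = 1), inputs = c(zymosan = 1)), 0.5)
  expect_error(integrate_control(rule, c(A = 1), inputs = c(other = 1)),
               class = "complementr_config_error")
})

test_that("control outputs stay in [0,1] for random rules and states", {
  set.seed(42)
  for (i in 1:40) {
    nf <- sample(1:4, 1)
    factors <- lapply(seq_len(nf), function(j) {
      list(actor = paste0("s", j),
           direction = sample(c("activating", "inhibiting"), 1),
           K = rexp(1) + 0.01, n = runif(1, 0.5, 4))
    })
    rule <- control_rule("rx", sample(c("min", "max"), 1), factors)
    state <- setNames(rexp(nf, 0.2), paste0("s", seq_len(nf)))
    v <- integrate_control(rule, state)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("saturation rate matches closed forms and is bounded/monotone", {
  expect_equal(saturation_rate(1, 2, 5, 5, 1), 1.0)       # half-max
  expect_equal(saturation_rate(3, 0, 5, 5, 1), 0)          # no catalyst
  expect_equal(saturation_rate(2, 1, 9, 3, 2), 2 * 81 / 90) # 1.8
  expect_equal(saturation_rate(2, 1, 0, 3, 2), 0)
  expect_error(saturation_rate(1, 1, -1, 1, 1),
               class = "complementr_domain_error")
  # property: non-decreasing in substrate, bounded by kmax * enzyme
  set.seed(7)
  for (i in 1:20) {
    kmax <- rexp(1); eps <- rexp(1); K <- rexp(1) + 0.05
    eta <- runif(1, 0.5, 3)
    xs <- sort(rexp(10, 0.2))
    r <- vapply(xs, function(x) saturation_rate(kmax, eps, x, K, eta),
                numeric(1))
    expect_true(all(diff(r) >= -1e-12))
    expect_true(all(r <= kmax * eps + 1e-12))
  }
})

test_that("mass-action rate follows the stoichiometric power law", {
  expect_equal(mass_action_rate(2, c(A = 3, B = 4), c(A = -1, B = -1, C = 1)),
               24)
  expect_equal(mass_action_rate(2, c(A = 0, B = 4), c(A = -1, B = -1)), 0)
  expect_equal(mass_action_rate(1, c(A = 2), c(A = -2, B = 1)), 4)
  expect_error(mass_action_rate(1, c(A = 1), c(A = 1)),
               class = "complementr_config_error")
})

test_that("mass-action rates are homogeneous of total reactant order", {
  set.seed(13)
  for (i in 1:20) {
    ns <- sample(1:3, 1)
    sto <- setNames(-sample(1:2, ns, replace = TRUE), paste0("s", 1:ns))
    x <- setNames(rexp(ns) + 0.1, names(sto))
    k <- rexp(1)
    c_scale <- runif(1, 0.5, 3)
    r1 <- mass_action_rate(k, x, sto)
    r2 <- mass_action_rate(k, c_scale * x, sto)
    expect_equal(r2, r1 * c_scale^sum(abs(sto)), tolerance = 1e-10)
  }
})

test_that("RHS assembly equals S diag(v) r with tau scaling on a tiny chain", {
  m <- tiny_model()
  state <- c(A = 6, B = 3, C = 2)
  z <- 0.5
  # hand assembly
  p <- model_parameter_values(m)
  r1 <- p["k1"] * state["A"]
  v2 <- 1 - state["C"] / (p["Kc"] + state["C"])
  r2 <- p["k2"] * state["A"] * state["B"] / (p["K2"] + state["B"])
  S <- matrix(c(-1, 1, 0, 0, -1, 1), nrow = 3,
              dimnames = list(c("A", "B", "C"), NULL))
  expected <- as.vector(S %*% (c(r1, r2) * c(1, v2)))
  expected[3] <- expected[3] * z  # C is initiator-scaled
  got <- evaluate_rhs(m, state, inputs = c(zymosan = z))
  expect_equal(unname(got), expected, tolerance = 1e-12)
  # at the reference dose tau = 1: identical to unscaled assembly
  got_ref <- evaluate_rhs(m, state, inputs = c(zymosan = 1))
  expect_equal(unname(got_ref)[3], as.vector(S %*% (c(r1, r2) * c(1, v2)))[3])
})

test_that("single-reaction mass balance conserves matter and zero rates stall", {
  m <- tiny_model()
  d <- evaluate_rhs(m, c(A = 5, B = 0, C = 0), inputs = c(zymosan = 1))
  expect_equal(unname(d["A"] + d["B"]), 0)  # A -> B conserves A+B
  p0 <- model_parameter_values(m)
  p0[c("k1", "k2")] <- 0
  d0 <- evaluate_rhs(m, c(A = 5, B = 2, C = 1), params = p0,
                     inputs = c(zymosan = 1))
  expect_equal(unname(d0), rep(0, 3))
})

test_that("initiator-scaled species require a dose", {
  m <- tiny_model()
  expect_error(evaluate_rhs(m, c(A = 1, B = 1, C = 1)),
               class = "complementr_input_error")
})
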