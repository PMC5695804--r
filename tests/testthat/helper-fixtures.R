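# Shared fixtures, built lazily and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_model_fx <- function() cached("model", default_complement_model)

## noiseless synthetic panel over the full dose titration
noiseless_data_fx <- function() {
  cached("noiseless", function() {
    generate_measurements(default_model_fx(), synthetic_protocol(sigma = 0))
  })
}

## noisy training data (5% multiplicative noise) and a reduced-budget fit,
## shared by the estimation-quality checks
noisy_train_fx <- function() {
  cached("noisy_train", function() {
    d <- generate_measurements(default_model_fx(),
                               synthetic_protocol(sigma = 0.05, seed = 101))
    train_validate_split(d)$train
  })
}

fitted_fx <- function() {
  cached("fit", function() {
    fit_complement(noisy_train_fx(), default_model_fx(), budget = 150,
                   iterations = 150, ensemble_size = 60, seed = 42)
  })
}

## a tiny 3-species chain A -> B -> C for hand-checkable RHS assembly:
## r1: A -> B (first order, k1); r2: B -> C (saturation, enzyme A,
## inhibited by C)
tiny_model <- function() {
  species <- tibble::tibble(
    name = c("A", "B", "C"),
    initial = c(10, 0, 0),
    tau = c("constant", "constant", "initiator")
  )
  parameters <- tibble::tibble(
    name = c("k1", "k2", "K2", "Kc"),
    value = c(0.5, 2, 4, 1),
    lower = c(0.01, 0.01, 0.1, 0.1),
    upper = c(10, 100, 100, 10)
  )
  reactions <- list(
    reaction("r1", "first_order", c(A = -1, B = 1),
             params = list(kmax = "k1"), substrate = "A"),
    reaction("r2", "saturation", c(B = -1, C = 1),
             params = list(kmax = "k2", K = "K2", eta = 1),
             enzyme = "A", substrate = "B")
  )
  controls <- list(
    control_rule("r2", "min", list(
      list(actor = "C", direction = "inhibiting", K = "Kc", n = 1)
    ))
  )
  complement_model(species, reactions, controls, parameters,
                   initiator = list(name = "zymosan", units = "mg/ml",
                                    reference_dose = 1))
}

## parameter vector with every rate constant zeroed (saturation/Hill shape
## constants left positive)
zero_rate_params <- function(model) {
  p <- model_parameter_values(model)
  rate_names <- grep("(_kmax|_kcat|_k)$", names(p), value = TRUE)
  p[rate_names] <- 0
  p
}

## independent O(n^2) layered non-dominated sort used as a ranking oracle
brute_force_ranks <- function(m) {
  n <- nrow(m)
  dominates <- function(a, b) all(m[a, ] <= m[b, ]) && any(m[a, ] < m[b, ])
  ranks <- rep(NA_integer_, n)
  level <- 0L
  left <- seq_len(n)
  while (length(left) > 0) {
    front <- left[vapply(left, function(i) {
      !any(vapply(setdiff(left, i), function(j) dominates(j, i), logical(1)))
    }, logical(1))]
    ranks[front] <- level
    left <- setdiff(left, front)
    level <- level + 1L
  }
  ranks
}
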