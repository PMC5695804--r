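## Measurement scaling, the two-term shape+scale training objective, a hybrid
## particle-swarm / dynamically-dimensioned-search warm start, a multiobjective
## simulated-annealing Pareto ensemble generator, AIC scoring, and
## random-parameter controls. Optimisation runs in log10 parameter space
## because kinetic constants span decades.

#' Min-max scale a measurement series
#'
#' `(M - min) / (max - min)`: the lowest value maps to 0 and the highest to 1.
#' Invariant under positive affine transforms of the series (unit changes).
#'
#' @param values Numeric series with at least two distinct values.
#' @return Scaled series in `[0, 1]`.
#' @export
scale_measurements <- function(values) {
  rng <- range(values)
  if (!is.finite(diff(rng)) || diff(rng) == 0) {
    abort("Cannot min-max scale a constant series (max equals min).",
          class = "complementr_degenerate_scaling")
  }
  (values - rng[1]) / (rng[2] - rng[1])
}

## Scaled-sim helper tolerating a flat simulated series (maps to zeros)
scale_or_zero <- function(values) {
  rng <- range(values)
  if (diff(rng) <= .Machine$double.eps * max(abs(rng), 1)) {
    rep(0, length(values))
  } else {
    (values - rng[1]) / (rng[2] - rng[1])
  }
}

#' Shape + scale training objective
#'
#' For each (condition, species) series bound to the objective, compares the
#' min-max scaled measurement shape against the min-max scaled simulation
#' (linearly interpolated to the measurement times) and adds a relative scale
#' error comparing the largest measured concentration with the largest
#' simulated value:
#' `sum_i (Mhat_i - yhat_i)^2 + ((M' - max y) / M')^2`.
#' The objective is zero iff shapes match exactly and the simulated maximum
#' equals the measured scale. A failed simulation yields `Inf` with a warning.
#'
#' @param model A `complement_model`.
#' @param data A measurement tibble with columns `condition`, `dose_mg_ml`,
#'   `species`, `time`, `value` (see [generate_measurements()]).
#' @param params Optional named parameter vector (defaults to nominal).
#' @param conditions Condition ids to include (default: all in `data`).
#' @param species Measured species to include (default: all in `data`).
#' @param n_out Simulation output grid size.
#' @return Non-negative scalar.
#' @export
measurement_objective <- function(model, data, params = NULL,
                                  conditions = NULL, species = NULL,
                                  n_out = 200) {
  conditions <- conditions %||% unique(data$condition)
  species <- species %||% unique(data$species)
  d <- data[data$condition %in% conditions & data$species %in% species, ]
  if (nrow(d) == 0) {
    abort("No measurements match the requested conditions/species.",
          class = "complementr_input_error")
  }
  total <- 0
  for (cond in unique(d$condition)) {
    dc <- d[d$condition == cond, ]
    dose <- dc$dose_mg_ml[1]
    t_max <- max(dc$time)
    traj <- tryCatch(
      simulate_model(model, params = params, dose = dose,
                     t_span = c(0, t_max), n_out = n_out),
      error = function(e) {
        warn(paste0("Simulation failed for condition `", cond, "`: ",
                    conditionMessage(e), " — objective set to Inf."))
        NULL
      })
    if (is.null(traj)) return(Inf)
    for (s in unique(dc$species)) {
      ds <- dc[dc$species == s, ]
      ds <- ds[order(ds$time), ]
      y_at <- approx(traj$time, traj[[s]], xout = ds$time, rule = 2)$y
      m_hat <- scale_measurements(ds$value)
      y_hat <- scale_or_zero(y_at)
      shape <- sum((m_hat - y_hat)^2)
      m_prime <- max(ds$value)
      scale_term <- ((m_prime - max(traj[[s]])) / m_prime)^2
      total <- total + shape + scale_term
    }
  }
  total
}

#' Build the default training objective specification
#'
#' Two objectives: `O1`, the total C3a + C5a residual without initiator
#' (dose 0), and `O2`, the residual at the 1 mg/ml reference dose.
#'
#' @param data A measurement tibble.
#' @param species Measured species (default C3a, C5a).
#' @return Named list mapping objective id to a character vector of condition
#'   ids.
#' @export
objective_spec <- function(data, species = c("C3a", "C5a")) {
  conds <- unique(data[, c("condition", "dose_mg_ml")])
  list(
    O1 = conds$condition[conds$dose_mg_ml == 0],
    O2 = conds$condition[conds$dose_mg_ml == 1]
  )
}

## ---- optimizers -----------------------------------------------------------

## Reflect a point into [lower, upper]
reflect_bounds <- function(x, lower, upper) {
  for (i in seq_along(x)) {
    while (x[i] < lower[i] || x[i] > upper[i]) {
      if (x[i] < lower[i]) x[i] <- 2 * lower[i] - x[i]
      if (x[i] > upper[i]) x[i] <- 2 * upper[i] - x[i]
    }
  }
  x
}

#' Hybrid swarm / dynamically-dimensioned-search warm start
#'
#' Minimises `fn` within box bounds using a two-phase heuristic: several
#' independent particle swarms explore for a fraction of the evaluation
#' budget (or until the global best stagnates), then a dynamically
#' dimensioned search refines the incumbent by perturbing a randomly chosen,
#' progressively shrinking subset of dimensions. Deterministic under `seed`;
#' never returns a point outside the bounds.
#'
#' @param fn Objective function over a numeric vector.
#' @param lower,upper Finite bound vectors.
#' @param budget Total number of objective evaluations (>= 1).
#' @param seed Integer RNG seed.
#' @param init Optional start point; defaults to the bound-box centre.
#' @param n_swarms,n_particles Swarm topology (phase 1).
#' @param switch_frac Fraction of budget given to phase 1 (default 0.4).
#' @param stagnation Swarm iterations without improvement before switching
#'   early (default 25).
#' @param dds_r Neighbourhood size of the DDS perturbation as a fraction of
#'   each bound range (default 0.2).
#' @return List with `par`, `value`, and `evals` used.
#' @export
dops_warm_start <- function(fn, lower, upper, budget = 1000, seed = 1,
                            init = NULL, n_swarms = 3, n_particles = 8,
                            switch_frac = 0.4, stagnation = 25,
                            dds_r = 0.2) {
  stopifnot(budget >= 1, all(is.finite(lower)), all(is.finite(upper)),
            all(upper >= lower))
  d <- length(lower)
  set.seed(seed)
  rng <- upper - lower
  evals <- 0L
  eval_fn <- function(x) {
    evals <<- evals + 1L
    val <- suppressWarnings(fn(x))
    if (!is.finite(val)) val <- Inf
    val
  }

  best_x <- init %||% ((lower + upper) / 2)
  best_f <- eval_fn(best_x)
  if (budget == 1) {
    if (is.infinite(best_f)) {
      abort("No feasible point found within the evaluation budget.",
            class = "complementr_no_feasible_point")
    }
    return(list(par = best_x, value = best_f, evals = evals))
  }

  ## phase 1: independent swarms
  pso_budget <- floor(budget * switch_frac)
  n_part <- n_swarms * n_particles
  if (pso_budget > n_part) {
    X <- t(vapply(seq_len(n_part),
                  function(i) lower + runif(d) * rng, numeric(d)))
    X[1, ] <- best_x
    V <- t(vapply(seq_len(n_part),
                  function(i) (runif(d) - 0.5) * 0.2 * rng, numeric(d)))
    pbest <- X
    pf <- apply(X, 1, eval_fn)
    swarm_id <- rep(seq_len(n_swarms), each = n_particles)
    gbest <- t(vapply(seq_len(n_swarms), function(s) {
      rows <- which(swarm_id == s)
      pbest[rows[which.min(pf[rows])], ]
    }, numeric(d)))
    gf <- vapply(seq_len(n_swarms), function(s) min(pf[swarm_id == s]),
                 numeric(1))
    if (min(pf) < best_f) { best_f <- min(pf); best_x <- pbest[which.min(pf), ] }
    stag <- 0L
    w <- 0.7; c1 <- 1.5; c2 <- 1.5
    while (evals + n_part <= pso_budget && stag < stagnation) {
      improved <- FALSE
      for (i in seq_len(n_part)) {
        s <- swarm_id[i]
        V[i, ] <- w * V[i, ] + c1 * runif(d) * (pbest[i, ] - X[i, ]) +
          c2 * runif(d) * (gbest[s, ] - X[i, ])
        X[i, ] <- reflect_bounds(X[i, ] + V[i, ], lower, upper)
        f <- eval_fn(X[i, ])
        if (f < pf[i]) { pf[i] <- f; pbest[i, ] <- X[i, ] }
        if (f < gf[s]) { gf[s] <- f; gbest[s, ] <- X[i, ] }
        if (f < best_f) { best_f <- f; best_x <- X[i, ]; improved <- TRUE }
      }
      stag <- if (improved) 0L else stag + 1L
    }
  }

  ## phase 2: dynamically dimensioned search around the incumbent
  n_dds <- budget - evals
  if (n_dds > 0 && is.finite(best_f)) {
    for (m in seq_len(n_dds)) {
      p_incl <- max(1 - log(m) / log(n_dds), 1 / d)
      incl <- which(runif(d) < p_incl)
      if (length(incl) == 0) incl <- sample.int(d, 1)
      cand <- best_x
      cand[incl] <- cand[incl] + rnorm(length(incl)) * dds_r * rng[incl]
      cand <- reflect_bounds(cand, lower, upper)
      f <- eval_fn(cand)
      if (f < best_f) { best_f <- f; best_x <- cand }
    }
  }
  if (is.infinite(best_f)) {
    abort("No feasible point found within the evaluation budget.",
          class = "complementr_no_feasible_point")
  }
  list(par = best_x, value = best_f, evals = evals)
}

#' Layered non-dominated (Pareto) ranking
#'
#' Rank 0 is the non-dominated set; rank k is the set that becomes
#' non-dominated after removing ranks `< k`. A vector dominates another when
#' it is `<=` in every objective and `<` in at least one.
#'
#' @param objectives Numeric matrix (rows = solutions, columns = objectives)
#'   or a data frame of objective columns.
#' @return Integer vector of ranks (0-based).
#' @export
pareto_rank <- function(objectives) {
  m <- as.matrix(objectives)
  n <- nrow(m)
  if (n == 0) return(integer(0))
  rank_out <- rep(NA_integer_, n)
  remaining <- seq_len(n)
  level <- 0L
  while (length(remaining) > 0) {
    sub <- m[remaining, , drop = FALSE]
    nondom <- vapply(seq_along(remaining), function(i) {
      xi <- sub[i, ]
      !any(vapply(seq_along(remaining), function(j) {
        if (i == j) return(FALSE)
        xj <- sub[j, ]
        all(xj <= xi) && any(xj < xi)
      }, logical(1)))
    }, logical(1))
    rank_out[remaining[nondom]] <- level
    remaining <- remaining[!nondom]
    level <- level + 1L
  }
  rank_out
}

#' Multiobjective simulated-annealing Pareto ensemble
#'
#' Random walk in the (typically log10-transformed) parameter box. A candidate
#' is accepted outright when it is non-dominated with respect to the current
#' archive, and otherwise with Metropolis probability `exp(-dO / T)` on the
#' increase of the summed objectives. All accepted points enter the archive,
#' whose Pareto ranks are refreshed at every insertion. Deterministic under
#' `seed`.
#'
#' @param fn_multi Function returning the objective vector for a parameter
#'   vector.
#' @param start In-bounds start point (e.g. the [dops_warm_start()] result).
#' @param lower,upper Bound vectors.
#' @param iterations Number of proposal steps.
#' @param target_size Maximum archive size returned (worst ranks trimmed).
#' @param t0 Initial temperature; default is the spread of the summed
#'   objective over a handful of probe perturbations.
#' @param cooling Geometric cooling factor applied every `epoch` iterations
#'   (default 0.9).
#' @param epoch Iterations between temperature updates (default 10).
#' @param step Proposal standard deviation as a fraction of each bound range
#'   (default 0.05).
#' @param seed Integer RNG seed.
#' @return Tibble: one row per archive member with parameter columns (in the
#'   search space of `fn_multi`), objective columns `o1..ok`, and `rank`.
#' @export
poets_ensemble <- function(fn_multi, start, lower, upper, iterations = 400,
                           target_size = 100, t0 = NULL, cooling = 0.9,
                           epoch = 10, step = 0.05, seed = 1) {
  d <- length(start)
  stopifnot(length(lower) == d, length(upper) == d,
            all(start >= lower - 1e-12), all(start <= upper + 1e-12))
  set.seed(seed)
  rng <- upper - lower
  o_start <- fn_multi(start)
  k <- length(o_start)
  if (!all(is.finite(o_start))) {
    abort("Objectives at the start point are not finite.",
          class = "complementr_input_error")
  }
  if (is.null(t0)) {
    probes <- replicate(5, {
      x <- reflect_bounds(start + rnorm(d) * step * rng, lower, upper)
      sum(fn_multi(x))
    })
    spread <- stats::sd(c(probes[is.finite(probes)], sum(o_start)))
    t0 <- max(spread, 1e-6)
  }

  arch_x <- matrix(start, nrow = 1)
  arch_o <- matrix(o_start, nrow = 1)
  current <- start
  cur_o <- o_start
  temp <- t0
  accepted <- 0L

  for (it in seq_len(iterations)) {
    cand <- reflect_bounds(current + rnorm(d) * step * rng, lower, upper)
    cand_o <- fn_multi(cand)
    if (all(is.finite(cand_o))) {
      dominated <- any(apply(arch_o, 1, function(a) {
        all(a <= cand_o) && any(a < cand_o)
      }))
      accept <- if (!dominated) {
        TRUE
      } else {
        delta <- sum(cand_o) - sum(cur_o)
        runif(1) < exp(-max(delta, 0) / temp)
      }
      if (accept) {
        current <- cand
        cur_o <- cand_o
        arch_x <- rbind(arch_x, cand)
        arch_o <- rbind(arch_o, cand_o)
        accepted <- accepted + 1L
      }
    }
    if (it %% epoch == 0) temp <- temp * cooling
  }
  if (accepted == 0L) {
    warn("No proposals accepted; archive contains only the start point.")
  }
  ranks <- pareto_rank(arch_o)
  ord <- order(ranks, rowSums(arch_o))
  keep <- head(ord, target_size)
  out <- as_tibble(as.data.frame(arch_x[keep, , drop = FALSE]))
  names(out) <- names(start) %||% paste0("p", seq_len(d))
  oo <- as.data.frame(arch_o[keep, , drop = FALSE])
  names(oo) <- paste0("o", seq_len(k))
  out <- bind_cols(out, as_tibble(oo))
  out$rank <- pareto_rank(arch_o[keep, , drop = FALSE])
  out
}

#' Akaike information criterion for a model fit
#'
#' `AIC = 2 N_p + N_m ln( (1/||M||) sum (x - y)^2 )` where `N_p` is the number
#' of model parameters, `N_m` the number of measurements, and `||M||` the
#' scale of the data, implemented as the sum of squared measurements
#' (`norm = "sumsq"`) or `N_m * max(M)^2` (`norm = "maxsq"`). A zero residual
#' is floored at machine epsilon and flagged via attribute `floored`.
#'
#' @param model A `complement_model`.
#' @param data Measurement tibble.
#' @param params Optional named parameter vector.
#' @param conditions Condition ids to include (default all).
#' @param norm Data-scale normalisation, `"sumsq"` (default) or `"maxsq"`.
#' @return AIC value (scalar).
#' @export
aic_score <- function(model, data, params = NULL, conditions = NULL,
                      norm = c("sumsq", "maxsq")) {
  norm <- match.arg(norm)
  conditions <- conditions %||% unique(data$condition)
  d <- data[data$condition %in% conditions, ]
  if (nrow(d) == 0) {
    abort("No measurements selected.", class = "complementr_input_error")
  }
  rss <- 0
  for (cond in unique(d$condition)) {
    dc <- d[d$condition == cond, ]
    traj <- simulate_model(model, params = params, dose = dc$dose_mg_ml[1],
                           t_span = c(0, max(dc$time)))
    for (s in unique(dc$species)) {
      ds <- dc[dc$species == s, ]
      y_at <- approx(traj$time, traj[[s]], xout = ds$time, rule = 2)$y
      rss <- rss + sum((ds$value - y_at)^2)
    }
  }
  n_m <- nrow(d)
  n_p <- nrow(model$parameters)
  m_norm <- if (norm == "sumsq") sum(d$value^2) else n_m * max(d$value)^2
  aic_value(n_p, n_m, rss, m_norm)
}

#' AIC from a precomputed residual
#'
#' The information criterion `2 n_params + n_meas * ln(rss / m_norm)` used by
#' [aic_score()]; exposed so alternative residual definitions can be scored.
#' A non-positive residual is floored at machine epsilon and flagged via
#' attribute `floored`.
#'
#' @param n_params Number of model parameters.
#' @param n_meas Number of measurements.
#' @param rss Residual sum of squares between simulation and measurements.
#' @param m_norm Scale of the experimental data (e.g. sum of squared
#'   measurements).
#' @return AIC value with attribute `floored`.
#' @export
aic_value <- function(n_params, n_meas, rss, m_norm) {
  stopifnot(n_meas > 0, m_norm > 0)
  floored <- FALSE
  if (rss <= 0) { rss <- .Machine$double.eps; floored <- TRUE }
  out <- 2 * n_params + n_meas * log(rss / m_norm)
  attr(out, "floored") <- floored
  out
}

#' Random-parameter control draws
#'
#' Log-uniform draws within per-parameter bounds, matching the order of
#' magnitude of the nominal values — the null family against which the fitted
#' ensemble's AIC is compared.
#'
#' @param bounds Tibble/data frame with columns `name`, `lower`, `upper`
#'   (e.g. `model$parameters`).
#' @param n Number of draws (>= 1).
#' @param seed Integer RNG seed.
#' @return Tibble with `n` rows and one column per parameter.
#' @export
random_parameter_control <- function(bounds, n, seed = 1) {
  stopifnot(n >= 1)
  set.seed(seed)
  lo <- log10(bounds$lower)
  hi <- log10(bounds$upper)
  draws <- vapply(seq_along(lo), function(i) {
    10^runif(n, lo[i], hi[i])
  }, numeric(n))
  draws <- matrix(draws, nrow = n)
  colnames(draws) <- bounds$name
  as_tibble(as.data.frame(draws))
}

## ---- high-level fitting wrapper ------------------------------------------

#' Fit a complement model to measurement data
#'
#' Full estimation pipeline: log10-transformed bounds, a
#' [dops_warm_start()] on the summed objective, then a [poets_ensemble()]
#' multiobjective refinement. Returns a `complement_fit` with the Pareto
#' archive mapped back to natural parameter units.
#'
#' @param data Measurement tibble (must contain the training conditions).
#' @param model A `complement_model` (default: the shipped network).
#' @param objectives Named list mapping objective id to condition ids
#'   (default: [objective_spec()] — no-initiator vs reference-dose).
#' @param budget Warm-start evaluation budget.
#' @param iterations Annealing proposals for the ensemble stage.
#' @param ensemble_size Target archive size.
#' @param bounds_decades Half-width of the log10 search box around nominal
#'   values, clipped to the declared parameter bounds (default 2).
#' @param seed Integer RNG seed (controls both stages).
#' @param species Measured species used in the objectives.
#' @return A `complement_fit`: list with `ensemble` (tibble of parameter
#'   columns, objectives `o1`, `o2`, and `rank`), `warm_start`, `model`,
#'   `objectives`, `data`.
#' @export
fit_complement <- function(data, model = default_complement_model(),
                           objectives = objective_spec(data, species),
                           budget = 300, iterations = 300,
                           ensemble_size = 100, bounds_decades = 2,
                           seed = 1, species = c("C3a", "C5a")) {
  nominal <- model_parameter_values(model)
  lo <- pmax(log10(nominal) - bounds_decades, log10(model$parameters$lower))
  hi <- pmin(log10(nominal) + bounds_decades, log10(model$parameters$upper))
  names(lo) <- names(hi) <- names(nominal)

  obj_multi <- function(logp) {
    p <- setNames(10^logp, names(nominal))
    vapply(objectives, function(conds) {
      measurement_objective(model, data, params = p, conditions = conds,
                            species = species)
    }, numeric(1))
  }
  obj_sum <- function(logp) sum(obj_multi(logp))

  ws <- dops_warm_start(obj_sum, lo, hi, budget = budget, seed = seed,
                        init = log10(nominal))
  ens <- poets_ensemble(obj_multi, setNames(ws$par, names(nominal)), lo, hi,
                        iterations = iterations, target_size = ensemble_size,
                        seed = seed + 1)
  par_cols <- names(nominal)
  ens[par_cols] <- lapply(ens[par_cols], function(x) 10^x)
  structure(list(ensemble = ens, warm_start = ws, model = model,
                 objectives = objectives, data = data, seed = seed),
            class = "complement_fit")
}

#' @export
print.complement_fit <- function(x, ...) {
  cat("<complement_fit>\n")
  cat("  ensemble size:", nrow(x$ensemble), "\n")
  cat("  rank-0 front :", sum(x$ensemble$rank == 0), "members\n")
  obj_cols <- grep("^o[0-9]+$", names(x$ensemble), value = TRUE)
  best <- min(rowSums(x$ensemble[, obj_cols, drop = FALSE]))
  cat("  best summed objective:", signif(best, 5), "\n")
  invisible(x)
}
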