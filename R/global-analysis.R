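## Sobol total-order sensitivity with Saltelli sampling, pairwise 10%
## perturbation displacement clustering, and log10-AUC knockdown robustness
## coefficients.

#' Saltelli sample for total-order Sobol indices
#'
#' Generates exactly `N * (2d + 2)` parameter vectors inside box bounds,
#' arranged as base matrices A and B (Latin-hypercube within the bounds)
#' followed by the cross matrices `AB_i` (A with column i replaced from B) and
#' `BA_i`, the layout required by the Jansen/Saltelli total-index estimators.
#'
#' @param lower,upper Named bound vectors (length `d`).
#' @param N Number of base samples (>= 2).
#' @param seed Integer RNG seed.
#' @return Numeric matrix of dimension `N*(2d+2) x d`, with attributes `N`,
#'   `d`, and `layout` describing the row blocks.
#' @examples
#' s <- saltelli_sample(c(a = 0, b = 0), c(a = 1, b = 1), N = 2, seed = 1)
#' nrow(s)   # 2 * (2*2 + 2) = 12
#' @export
saltelli_sample <- function(lower, upper, N, seed = 1) {
  d <- length(lower)
  stopifnot(N >= 2, d >= 1, length(upper) == d, all(upper >= lower))
  set.seed(seed)
  U <- lhs::randomLHS(N, 2 * d)
  A <- U[, seq_len(d), drop = FALSE]
  B <- U[, d + seq_len(d), drop = FALSE]
  blocks <- vector("list", 2 * d + 2)
  blocks[[1]] <- A
  blocks[[2]] <- B
  for (i in seq_len(d)) {
    AB <- A; AB[, i] <- B[, i]
    blocks[[2 + i]] <- AB
    BA <- B; BA[, i] <- A[, i]
    blocks[[2 + d + i]] <- BA
  }
  out <- do.call(rbind, blocks)
  out <- sweep(sweep(out, 2, upper - lower, `*`), 2, lower, `+`)
  colnames(out) <- names(lower)
  attr(out, "N") <- N
  attr(out, "d") <- d
  attr(out, "layout") <- c("A", "B", paste0("AB", seq_len(d)),
                           paste0("BA", seq_len(d)))
  out
}

#' Total-order Sobol indices from Saltelli-layout evaluations
#'
#' Jansen estimator of the total-order index
#' `ST_i = (1/2N) sum (f(A) - f(AB_i))^2 / V`, averaged with its mirrored
#' `B`/`BA_i` form, with a bootstrap confidence interval over the base
#' samples. Requires the evaluation vector to follow the row order of
#' [saltelli_sample()].
#'
#' @param y Numeric vector of model evaluations, length `N*(2d+2)`.
#' @param N,d Saltelli layout dimensions (taken from the sample's attributes
#'   if `sample` is given).
#' @param sample Optional: the matrix returned by [saltelli_sample()].
#' @param names Optional parameter names.
#' @param conf Bootstrap confidence level (default 0.95).
#' @param n_boot Bootstrap replicates (default 200).
#' @return A `complement_sensitivity` tibble: `parameter`, `total_order`,
#'   `ci_lower`, `ci_upper`.
#' @export
sobol_total_indices <- function(y, N = NULL, d = NULL, sample = NULL,
                                names = NULL, conf = 0.95, n_boot = 200) {
  if (!is.null(sample)) {
    N <- N %||% attr(sample, "N")
    d <- d %||% attr(sample, "d")
    names <- names %||% colnames(sample)
  }
  stopifnot(!is.null(N), !is.null(d))
  if (length(y) != N * (2 * d + 2)) {
    abort("`y` must have length N*(2d+2) matching the Saltelli layout.",
          class = "complementr_input_error")
  }
  if (!all(is.finite(y))) {
    abort("Evaluations must be finite.", class = "complementr_input_error")
  }
  yA <- y[seq_len(N)]
  yB <- y[N + seq_len(N)]
  yAB <- matrix(y[2 * N + seq_len(N * d)], nrow = N)
  yBA <- matrix(y[2 * N + N * d + seq_len(N * d)], nrow = N)
  V <- var(c(yA, yB))
  if (!is.finite(V) || V <= .Machine$double.eps * max(abs(c(yA, yB)))^2) {
    abort("Model output variance is zero; total indices are undefined.",
          class = "complementr_zero_variance")
  }
  st_from <- function(idx) {
    v <- var(c(yA[idx], yB[idx]))
    st1 <- colMeans((yA[idx] - yAB[idx, , drop = FALSE])^2) / (2 * v)
    st2 <- colMeans((yB[idx] - yBA[idx, , drop = FALSE])^2) / (2 * v)
    (st1 + st2) / 2
  }
  st <- st_from(seq_len(N))
  boot <- vapply(seq_len(n_boot), function(b) {
    st_from(sample.int(N, N, replace = TRUE))
  }, numeric(d))
  boot <- matrix(boot, nrow = d)
  alpha <- 1 - conf
  ci <- apply(boot, 1, quantile, probs = c(alpha / 2, 1 - alpha / 2))
  out <- tibble(
    parameter = names %||% paste0("p", seq_len(d)),
    total_order = unname(st),
    ci_lower = unname(ci[1, ]),
    ci_upper = unname(ci[2, ])
  )
  class(out) <- c("complement_sensitivity", class(out))
  out
}

#' Sobol sensitivity of the training residual
#'
#' Saltelli-samples the parameter space (uniform in log10 by default, since
#' kinetic constants span decades), evaluates the shape+scale training
#' objective for the chosen condition set at every sampled parameter vector,
#' and returns total-order indices. Bounds default to the ensemble range when
#' a fit/ensemble is supplied, else to the model's declared bounds.
#'
#' @param model A `complement_model`.
#' @param data Measurement tibble.
#' @param conditions Condition ids defining the analysed objective.
#' @param N Base sample count (the full study scale is N = 400, d = 28 for
#'   23,200 evaluations; scale N down for desk-scale runs).
#' @param seed Integer RNG seed.
#' @param ensemble Optional fit or parameter tibble whose per-parameter
#'   min/max set the sampling bounds.
#' @param log10_space Sample uniformly in log10 of the bounds (default TRUE).
#' @param n_boot Bootstrap replicates for the CIs.
#' @return A `complement_sensitivity` tibble (see [sobol_total_indices()]),
#'   with attribute `n_evaluations`.
#' @export
sobol_sensitivity <- function(model, data, conditions = NULL, N = 64,
                              seed = 1, ensemble = NULL, log10_space = TRUE,
                              n_boot = 200) {
  if (!is.null(ensemble)) {
    em <- ensemble_parameter_matrix(ensemble, model)
    lower <- apply(em, 2, min)
    upper <- apply(em, 2, max)
    flat <- upper <= lower * (1 + 1e-9)
    if (any(flat)) { # widen degenerate ranges slightly
      lower[flat] <- lower[flat] * 0.9
      upper[flat] <- upper[flat] * 1.1
    }
  } else {
    lower <- setNames(model$parameters$lower, model$parameters$name)
    upper <- setNames(model$parameters$upper, model$parameters$name)
  }
  if (log10_space) {
    samp <- saltelli_sample(log10(lower), log10(upper), N, seed)
    pmat <- 10^samp
  } else {
    samp <- saltelli_sample(lower, upper, N, seed)
    pmat <- samp
  }
  y <- vapply(seq_len(nrow(pmat)), function(i) {
    suppressWarnings(
      measurement_objective(model, data,
                            params = setNames(pmat[i, ], colnames(pmat)),
                            conditions = conditions)
    )
  }, numeric(1))
  if (any(!is.finite(y))) { # failed integrations: pin at the worst observed fit
    worst <- max(y[is.finite(y)])
    y[!is.finite(y)] <- worst
  }
  out <- sobol_total_indices(y, sample = samp, n_boot = n_boot)
  attr(out, "n_evaluations") <- length(y)
  out
}

## ---- pairwise displacement ------------------------------------------------

#' Pairwise parameter perturbation displacement
#'
#' Increases every (ordered) pair of parameters by `delta` (both members of
#' the pair; the diagonal compounds to a `(1+delta)^2` single-parameter
#' change), simulates under physiological conditions (1 mg/ml initiator by
#' default), and measures the euclidean distance between the perturbed and
#' nominal state trajectories. Distances are averaged over ensemble members,
#' log10-transformed (floored at `floor`), and the parameters clustered into
#' three groups (high / medium / low displacement) by Ward hierarchical
#' clustering of the matrix rows.
#'
#' @param model A `complement_model`.
#' @param ensemble Optional fit/parameter tibble; default: nominal parameters
#'   only.
#' @param dose Initiator dose (default 1 mg/ml).
#' @param delta Fractional perturbation (default 0.1 = 10%).
#' @param parameters Optional subset of parameter names to analyse.
#' @param t_span,n_out Simulation window and grid (the trajectory on this grid
#'   is the state vector compared).
#' @param use `"trajectory"` (default) compares the full concatenated
#'   trajectory; `"final"` compares terminal states only.
#' @param n_clusters Number of displacement clusters (default 3).
#' @param floor Floor for zero displacements before log10 (default 1e-12).
#' @return A `complement_pairwise` list: `matrix` (d x d log10 mean
#'   displacement), `clusters` (tibble `parameter`, `cluster`, `label`), and
#'   `n_failed`.
#' @export
pairwise_displacement <- function(model, ensemble = NULL, dose = 1,
                                  delta = 0.1, parameters = NULL,
                                  t_span = c(0, 8), n_out = 40,
                                  use = c("trajectory", "final"),
                                  n_clusters = 3, floor = 1e-12) {
  use <- match.arg(use)
  stopifnot(delta >= 0)
  members <- if (is.null(ensemble)) {
    matrix(model_parameter_values(model), nrow = 1,
           dimnames = list(NULL, model$parameters$name))
  } else {
    ensemble_parameter_matrix(ensemble, model)
  }
  pnames <- parameters %||% model$parameters$name
  d <- length(pnames)
  times <- seq(t_span[1], t_span[2], length.out = n_out)
  state_of <- function(traj) {
    m <- as.matrix(traj[, model$species$name])
    if (use == "final") m[nrow(m), ] else as.vector(m)
  }
  acc <- matrix(0, d, d, dimnames = list(pnames, pnames))
  cnt <- matrix(0L, d, d)
  n_failed <- 0L
  for (m_i in seq_len(nrow(members))) {
    pv <- members[m_i, ]
    nominal <- tryCatch(
      state_of(simulate_model(model, params = pv, dose = dose,
                              times = times)),
      error = function(e) NULL)
    if (is.null(nominal)) { n_failed <- n_failed + 1L; next }
    for (a in seq_len(d)) {
      for (b in a:d) {
        pp <- pv
        pp[pnames[a]] <- pp[pnames[a]] * (1 + delta)
        pp[pnames[b]] <- pp[pnames[b]] * (1 + delta)
        st <- tryCatch(
          state_of(simulate_model(model, params = pp, dose = dose,
                                  times = times)),
          error = function(e) NULL)
        if (is.null(st)) { n_failed <- n_failed + 1L; next }
        dist_ab <- sqrt(sum((st - nominal)^2))
        acc[a, b] <- acc[a, b] + dist_ab
        cnt[a, b] <- cnt[a, b] + 1L
        if (a != b) { acc[b, a] <- acc[a, b]; cnt[b, a] <- cnt[a, b] }
      }
    }
  }
  if (all(cnt == 0)) {
    abort("All pairwise simulations failed.",
          class = "complementr_integration_error")
  }
  mean_disp <- acc / pmax(cnt, 1L)
  logm <- log10(pmax(mean_disp, floor))
  if (d > n_clusters) {
    hc <- hclust(dist(logm), method = "ward.D2")
    cl <- cutree(hc, k = n_clusters)
  } else {
    cl <- seq_len(d)
  }
  ## label clusters by their mean displacement, largest first
  means <- tapply(rowMeans(logm), cl, mean)
  lab_names <- c("high", "medium", "low")[seq_len(min(3, length(means)))]
  ord <- order(means, decreasing = TRUE)
  labels <- setNames(rep("low", length(means)), names(means))
  labels[names(means)[ord[seq_along(lab_names)]]] <- lab_names
  clusters <- tibble(parameter = pnames, cluster = unname(cl),
                     label = unname(labels[as.character(cl)]))
  structure(list(matrix = logm, clusters = clusters, n_failed = n_failed,
                 dose = dose, delta = delta),
            class = "complement_pairwise")
}

## ---- robustness -----------------------------------------------------------

#' Knockdown robustness coefficient
#'
#' `alpha = log10( AUC_perturbed / AUC_nominal )` of a marker species over
#' `[t0, tf]`: 0 means the perturbation left the marker's exposure unchanged,
#' positive values indicate increased abundance, negative decreased.
#'
#' @param nominal,perturbed `complement_trajectory` objects sharing a span
#'   that covers `[t0, tf]`.
#' @param marker Species name (e.g. `"C3a"`, `"C5a"`).
#' @param t0,tf Integration window (defaults: full common span).
#' @return Scalar robustness coefficient.
#' @examples
#' m <- default_complement_model()
#' tr <- simulate_model(m, dose = 1)
#' robustness_coefficient(tr, tr, "C3a")   # identical trajectories -> 0
#' @export
robustness_coefficient <- function(nominal, perturbed, marker,
                                   t0 = NULL, tf = NULL) {
  t0 <- t0 %||% max(nominal$time[1], perturbed$time[1])
  tf <- tf %||% min(max(nominal$time), max(perturbed$time))
  auc_n <- trajectory_auc(nominal, marker, t0, tf)
  if (auc_n <= 0) {
    abort("Nominal AUC is zero; the robustness coefficient is undefined.",
          class = "complementr_undefined_coefficient")
  }
  auc_p <- trajectory_auc(perturbed, marker, t0, tf)
  log10(auc_p / auc_n)
}

#' Knockdown robustness study
#'
#' Full factorial over markers x knockdown targets x knockdown levels x
#' initiator conditions: for each cell, the initial condition of the target
#' species is reduced, the model re-simulated, and the mean robustness
#' coefficient over the ensemble subset reported.
#'
#' @param model A `complement_model`.
#' @param ensemble Optional fit/parameter tibble; when a `complement_fit` is
#'   given, members with Pareto rank below `subset_rank` are used (the
#'   near-front subset); default: nominal parameters only.
#' @param markers Marker species (default C3a, C5a).
#' @param targets Named list of knockdown target sets (default C3, C5, and
#'   C3+C5 jointly).
#' @param levels Knockdown percentages (default 50, 90, 99).
#' @param doses Initiator doses defining the conditions (default 0 and
#'   1 mg/ml).
#' @param t_span Simulation window for the AUCs.
#' @param subset_rank Pareto-rank threshold when `ensemble` is a fit
#'   (default 5, i.e. ranks 0–4).
#' @return A `complement_robustness` tibble: `marker`, `target`, `level`,
#'   `dose`, `alpha` (ensemble mean), `n_members`; failed cells carry `NA`.
#' @export
robustness_study <- function(model, ensemble = NULL,
                             markers = c("C3a", "C5a"),
                             targets = list("C3" = "C3", "C5" = "C5",
                                            "C3+C5" = c("C3", "C5")),
                             levels = c(50, 90, 99), doses = c(0, 1),
                             t_span = c(0, 8), subset_rank = 5) {
  members <- if (is.null(ensemble)) {
    matrix(model_parameter_values(model), nrow = 1,
           dimnames = list(NULL, model$parameters$name))
  } else {
    if (inherits(ensemble, "complement_fit")) {
      sub <- ensemble$ensemble[ensemble$ensemble$rank < subset_rank, ]
      if (nrow(sub) == 0) {
        abort("No ensemble members below the requested Pareto rank.",
              class = "complementr_input_error")
      }
      ensemble_parameter_matrix(sub, model)
    } else {
      ensemble_parameter_matrix(ensemble, model)
    }
  }
  ic0 <- model_initial_conditions(model)
  grid <- expand.grid(marker = markers, target = names(targets),
                      level = levels, dose = doses,
                      stringsAsFactors = FALSE)
  cells <- vector("list", nrow(grid))
  for (m_i in seq_len(nrow(members))) {
    pv <- members[m_i, ]
    for (dz in doses) {
      nominal <- tryCatch(
        simulate_model(model, params = pv, dose = dz, t_span = t_span),
        error = function(e) NULL)
      for (tg in names(targets)) {
        for (lv in levels) {
          rows <- which(grid$target == tg & grid$level == lv &
                          grid$dose == dz)
          perturbed <- if (is.null(nominal)) NULL else tryCatch(
            simulate_model(model, params = pv,
                           ic = knockdown(ic0, targets[[tg]], lv)[targets[[tg]]],
                           dose = dz, t_span = t_span),
            error = function(e) NULL)
          for (r in rows) {
            a <- if (is.null(perturbed)) NA_real_ else tryCatch(
              robustness_coefficient(nominal, perturbed, grid$marker[r]),
              error = function(e) NA_real_)
            cells[[r]] <- c(cells[[r]], a)
          }
        }
      }
    }
  }
  out <- as_tibble(grid)
  out$alpha <- vapply(cells, function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  out$n_members <- vapply(cells, function(v) sum(!is.na(v)), integer(1))
  out <- arrange(out, .data$dose, .data$marker, .data$target, .data$level)
  class(out) <- c("complement_robustness", class(out))
  out
}
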