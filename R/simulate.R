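## Stiff ODE integration of complement models (deSolve::lsoda), ensemble
## summaries with confidence bands, and trapezoidal AUCs.

#' Simulate a complement model
#'
#' Integrates the model balances with a stiff-capable variable-step solver
#' (lsoda) and returns the trajectory on an even output grid (or at
#' caller-supplied times). States are clamped non-negative inside the rate
#' evaluation and on output; integration failures raise an error reporting the
#' failing time.
#'
#' @param model A `complement_model`.
#' @param params Optional named parameter vector (defaults to nominal values).
#' @param ic Optional named initial-condition vector (defaults to the model's).
#' @param dose Initiator (zymosan) dose in mg/ml; 0 means no initiator.
#' @param t_span Length-2 numeric, simulation window in hours.
#' @param n_out Number of evenly spaced output points (default 200).
#' @param times Optional explicit output times (overrides `n_out`).
#' @param rtol,atol Solver tolerances (defaults 1e-6, 1e-9).
#' @param method deSolve method; default `"lsoda"` switches automatically
#'   between stiff and non-stiff regimes.
#' @return A `complement_trajectory`: a tibble with a `time` column and one
#'   column per species; the dose and knockdown metadata are carried in
#'   attributes `dose` and `condition`.
#' @examples
#' traj <- simulate_model(default_complement_model(), dose = 1)
#' tail(traj[, c("time", "C3a", "C5a")], 2)
#' @export
simulate_model <- function(model, params = NULL, ic = NULL, dose = 0,
                           t_span = c(0, 8), n_out = 200, times = NULL,
                           rtol = 1e-6, atol = 1e-9, method = "lsoda") {
  if (is.null(times)) {
    if (t_span[2] <= t_span[1]) {
      abort("`t_span` must be increasing.", class = "complementr_input_error")
    }
    times <- seq(t_span[1], t_span[2], length.out = n_out)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    abort("Output times must be strictly increasing.",
          class = "complementr_input_error")
  }
  sp <- model$species$name
  x0 <- model_initial_conditions(model)
  if (!is.null(ic)) {
    unknown <- setdiff(names(ic), sp)
    if (length(unknown) > 0) {
      abort(paste0("Unknown species in `ic`: ",
                   paste(unknown, collapse = ", ")),
            class = "complementr_input_error")
    }
    x0[names(ic)] <- ic
  }
  cm <- compile_model(model, values = params, dose = dose)
  out <- suppressWarnings(
    deSolve::ode(y = setNames(as.numeric(x0), sp), times = times,
                 func = cm$rhs, parms = NULL, method = method,
                 rtol = rtol, atol = atol)
  )
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0) {
    t_fail <- out[nrow(out), 1]
    abort(paste0("Integration failed at t = ", signif(t_fail, 6),
                 "; last state: ",
                 paste(signif(out[nrow(out), -1], 4), collapse = ", ")),
          class = "complementr_integration_error")
  }
  if (nrow(out) < length(times)) {
    abort(paste0("Integration stopped early at t = ", out[nrow(out), 1]),
          class = "complementr_integration_error")
  }
  tb <- as_tibble(as.data.frame(unclass(out)))
  names(tb)[1] <- "time"
  tb[sp] <- lapply(tb[sp], function(col) pmax(col, 0))
  attr(tb, "dose") <- dose
  attr(tb, "condition") <- list(dose = dose, knockdowns = ic)
  class(tb) <- c("complement_trajectory", class(tb))
  tb
}

#' Area under a species curve
#'
#' Trapezoidal integral of one species over `[t0, tf]` on the trajectory's
#' output grid (endpoints interpolated linearly when they fall between grid
#' points).
#'
#' @param traj A `complement_trajectory` (or any data frame with a `time`
#'   column and species columns).
#' @param species Species column to integrate.
#' @param t0,tf Integration window; defaults to the full trajectory span. Must
#'   lie within the trajectory span.
#' @return Non-negative scalar, concentration x time.
#' @export
trajectory_auc <- function(traj, species, t0 = NULL, tf = NULL) {
  if (!species %in% names(traj)) {
    abort(paste0("Unknown species `", species, "`."),
          class = "complementr_input_error")
  }
  tt <- traj$time
  t0 <- t0 %||% tt[1]
  tf <- tf %||% tt[length(tt)]
  if (t0 < tt[1] - 1e-12 || tf > tt[length(tt)] + 1e-12 || tf <= t0) {
    abort("[t0, tf] must be an increasing window inside the trajectory span.",
          class = "complementr_input_error")
  }
  y <- traj[[species]]
  keep <- tt > t0 & tt < tf
  ts <- c(t0, tt[keep], tf)
  ys <- c(approx(tt, y, xout = t0)$y, y[keep], approx(tt, y, xout = tf)$y)
  pracma::trapz(ts, ys)
}

#' Simulate a parameter ensemble
#'
#' Runs one simulation per ensemble member and summarises each species over
#' time: ensemble mean, t-based confidence interval of the mean, and the
#' empirical interval of the simulated values (0.5/99.5 percentiles at the
#' default 99% level). Members whose integration fails are skipped and
#' counted.
#'
#' @param model A `complement_model`.
#' @param ensemble A data frame with one column per model parameter (extra
#'   columns such as objectives or ranks are ignored), or a
#'   `complement_fit`.
#' @param ic,dose,t_span,n_out Passed to [simulate_model()].
#' @param level Band coverage (default 0.99).
#' @return A `complement_ensemble_summary` tibble with columns `time`,
#'   `species`, `mean`, `ci_lower`, `ci_upper` (CI of the mean), `lower`,
#'   `upper` (interval of simulated values); attribute `n_failed` counts
#'   skipped members.
#' @export
simulate_ensemble <- function(model, ensemble, ic = NULL, dose = 0,
                              t_span = c(0, 8), n_out = 200, level = 0.99) {
  ens <- ensemble_parameter_matrix(ensemble, model)
  if (nrow(ens) == 0) {
    abort("Ensemble is empty.", class = "complementr_input_error")
  }
  sp <- model$species$name
  times <- seq(t_span[1], t_span[2], length.out = n_out)
  runs <- vector("list", nrow(ens))
  failed <- 0L
  for (i in seq_len(nrow(ens))) {
    res <- tryCatch(
      simulate_model(model, params = ens[i, ], ic = ic, dose = dose,
                     times = times),
      error = function(e) {
        warn(paste0("Ensemble member ", i, " skipped: ",
                    conditionMessage(e)))
        NULL
      })
    runs[i] <- list(res)
    if (is.null(res)) failed <- failed + 1L
  }
  runs <- runs[!vapply(runs, is.null, logical(1))]
  if (length(runs) == 0) {
    abort("All ensemble members failed to integrate.",
          class = "complementr_integration_error")
  }
  n <- length(runs)
  alpha <- 1 - level
  out <- purrr::map_dfr(sp, function(s) {
    mat <- vapply(runs, function(r) r[[s]], numeric(length(times)))
    mat <- matrix(mat, nrow = length(times))
    mu <- rowMeans(mat)
    if (n > 1) {
      se <- apply(mat, 1, sd) / sqrt(n)
      tq <- qt(1 - alpha / 2, df = n - 1)
      ci_lo <- mu - tq * se
      ci_hi <- mu + tq * se
      lo <- apply(mat, 1, quantile, probs = alpha / 2)
      hi <- apply(mat, 1, quantile, probs = 1 - alpha / 2)
    } else {
      ci_lo <- ci_hi <- lo <- hi <- mu
    }
    tibble(time = times, species = s, mean = mu,
           ci_lower = ci_lo, ci_upper = ci_hi, lower = lo, upper = hi)
  })
  attr(out, "n_members") <- n
  attr(out, "n_failed") <- failed
  attr(out, "dose") <- dose
  class(out) <- c("complement_ensemble_summary", class(out))
  out
}

## Accepts a complement_fit, a data frame with parameter columns (+ extras),
## or a plain matrix; returns a numeric matrix with named parameter columns.
ensemble_parameter_matrix <- function(ensemble, model) {
  if (inherits(ensemble, "complement_fit")) ensemble <- ensemble$ensemble
  par_names <- model$parameters$name
  df <- as.data.frame(ensemble)
  missing_p <- setdiff(par_names, names(df))
  if (length(missing_p) > 0) {
    abort(paste0("Ensemble is missing parameter column(s): ",
                 paste(missing_p, collapse = ", ")),
          class = "complementr_input_error")
  }
  as.matrix(df[, par_names, drop = FALSE])
}
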