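## broom-style accessors for fitted objects.

#' Tidy a complement fit
#'
#' One row per model parameter summarising the Pareto ensemble: the best
#' (lowest summed objective) member's value, and the ensemble spread.
#'
#' @param x A `complement_fit`.
#' @param rank_max Include members with Pareto rank below this (default:
#'   rank-0 front only, `rank_max = 1`).
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `ensemble_median`,
#'   `ensemble_min`, `ensemble_max`.
#' @export
tidy.complement_fit <- function(x, rank_max = 1, ...) {
  ens <- x$ensemble[x$ensemble$rank < rank_max, ]
  if (nrow(ens) == 0) ens <- x$ensemble
  par_names <- x$model$parameters$name
  obj_cols <- grep("^o[0-9]+$", names(ens), value = TRUE)
  best <- ens[which.min(rowSums(ens[, obj_cols, drop = FALSE])), ]
  tibble(
    term = par_names,
    estimate = as.numeric(best[1, par_names]),
    ensemble_median = vapply(par_names, function(p) median(ens[[p]]),
                             numeric(1)),
    ensemble_min = vapply(par_names, function(p) min(ens[[p]]), numeric(1)),
    ensemble_max = vapply(par_names, function(p) max(ens[[p]]), numeric(1))
  )
}

#' Glance at a complement fit
#'
#' @param x A `complement_fit`.
#' @param ... Unused.
#' @return One-row tibble: ensemble size, rank-0 front size, best per-objective
#'   and summed objective values, and the training AIC of the best member.
#' @export
glance.complement_fit <- function(x, ...) {
  ens <- x$ensemble
  obj_cols <- grep("^o[0-9]+$", names(ens), value = TRUE)
  sums <- rowSums(ens[, obj_cols, drop = FALSE])
  best <- ens[which.min(sums), ]
  par_names <- x$model$parameters$name
  train <- x$data[x$data$condition %in% unlist(x$objectives), ]
  aic <- tryCatch(
    as.numeric(aic_score(x$model, train,
                         params = setNames(as.numeric(best[1, par_names]),
                                           par_names))),
    error = function(e) NA_real_)
  out <- tibble(
    n_ensemble = nrow(ens),
    n_front = sum(ens$rank == 0),
    objective_sum = min(sums),
    aic = aic
  )
  for (oc in obj_cols) out[[paste0("best_", oc)]] <- min(ens[[oc]])
  out
}

#' @importFrom stats median
NULL
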