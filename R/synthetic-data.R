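## Synthetic immunoassay-style C3a/C5a time courses generated from the model
## itself, so training, validation, sensitivity and robustness stages run
## without any external download. The dose panel mirrors the in vitro zymosan
## titration convention: train on the extremes (no initiator, 1 mg/ml),
## validate on the intermediate doses.

#' Define a synthetic measurement protocol
#'
#' @param doses Initiator doses in mg/ml (default 0, 0.001, 0.01, 0.1, 1).
#' @param n_times Sample times per condition (default 8, evenly spaced over
#'   `(0, horizon]`).
#' @param horizon Sampling horizon in hours (default 8, by which nominal C3a
#'   has reached >= 90% of its plateau at the highest dose).
#' @param sigma Multiplicative log-normal noise scale (immunoassay-like CV;
#'   default 0.05). `sigma = 0` gives noiseless tables.
#' @param seed Integer RNG seed.
#' @param species Measured species (default C3a and C5a).
#' @param train_doses Doses tagged `train` (default 0 and 1 mg/ml); all other
#'   doses are tagged `validate`.
#' @return A `synthetic_protocol` list.
#' @export
synthetic_protocol <- function(doses = c(0, 0.001, 0.01, 0.1, 1),
                               n_times = 8, horizon = 8, sigma = 0.05,
                               seed = 1, species = c("C3a", "C5a"),
                               train_doses = c(0, 1)) {
  if (sigma < 0 || any(doses < 0) || n_times < 2) {
    abort("Protocol invalid: need sigma >= 0, doses >= 0, >= 2 time points.",
          class = "complementr_input_error")
  }
  structure(list(doses = doses, n_times = n_times, horizon = horizon,
                 sigma = sigma, seed = seed, species = species,
                 train_doses = train_doses),
            class = "synthetic_protocol")
}

#' Generate a synthetic measurement table
#'
#' Simulates each dose of the protocol with the supplied (default nominal)
#' parameters, samples the measured species at the protocol time points, and
#' applies multiplicative noise `value * exp(sigma * xi)` with standard-normal
#' `xi`. Deterministic under the protocol seed.
#'
#' @param model A `complement_model`.
#' @param protocol A [synthetic_protocol()].
#' @param params Optional named parameter vector.
#' @return Measurement tibble with columns `condition`, `dose_mg_ml`,
#'   `species`, `time`, `value`, `units`, `split` (`train`/`validate`).
#' @examples
#' tbl <- generate_measurements(default_complement_model(),
#'                              synthetic_protocol(sigma = 0))
#' dplyr::count(tbl, condition, split)
#' @export
generate_measurements <- function(model, protocol = synthetic_protocol(),
                                  params = NULL) {
  stopifnot(inherits(protocol, "synthetic_protocol"))
  set.seed(protocol$seed)
  times <- seq(protocol$horizon / protocol$n_times, protocol$horizon,
               length.out = protocol$n_times)
  rows <- list()
  for (dz in protocol$doses) {
    traj <- tryCatch(
      simulate_model(model, params = params, dose = dz,
                     t_span = c(0, protocol$horizon)),
      error = function(e) {
        abort(paste0("Simulation failed for dose ", dz, " mg/ml: ",
                     conditionMessage(e)),
              class = "complementr_integration_error")
      })
    for (s in protocol$species) {
      y <- approx(traj$time, traj[[s]], xout = times)$y
      noise <- if (protocol$sigma > 0) {
        exp(protocol$sigma * rnorm(length(y)))
      } else {
        rep(1, length(y))
      }
      rows[[length(rows) + 1]] <- tibble(
        condition = sprintf("zymosan_%g", dz),
        dose_mg_ml = dz, species = s, time = times,
        value = y * noise, units = "nM",
        split = if (dz %in% protocol$train_doses) "train" else "validate"
      )
    }
  }
  bind_rows(rows)
}

#' Split a measurement table into training and validation tables
#'
#' Disjoint partition by the `split` tag; the union of the outputs is the
#' input.
#'
#' @param table Measurement tibble carrying a `split` column with values
#'   `train` / `validate`.
#' @return Named list with elements `train` and `validate`.
#' @export
train_validate_split <- function(table) {
  if (!"split" %in% names(table) || any(is.na(table$split)) ||
      !all(table$split %in% c("train", "validate"))) {
    abort("Measurement table rows must be tagged `train` or `validate`.",
          class = "complementr_input_error")
  }
  out <- list(train = table[table$split == "train", ],
              validate = table[table$split == "validate", ])
  if (nrow(out$validate) == 0) {
    abort("No rows tagged `validate`.", class = "complementr_input_error")
  }
  out
}

#' Read / write measurement tables
#'
#' CSV with columns `condition`, `dose_mg_ml`, `species`, `time`, `value`,
#' `units` and optionally `split`.
#'
#' @param path File path.
#' @return A measurement tibble ([read_measurements()]); `path` invisibly
#'   ([write_measurements()]).
#' @export
read_measurements <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "dose_mg_ml", "species", "time", "value")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0) {
    abort(paste0("Measurement file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "complementr_input_error")
  }
  as_tibble(d)
}

#' @rdname read_measurements
#' @param table Measurement tibble.
#' @export
write_measurements <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
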