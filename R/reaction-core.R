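## Rate laws and rule-based control algebra shared by every network built on
## this framework. Concentrations are non-negative reals; rates carry the units
## of the rate constants (default model: nM and hours).

#' Hill regulatory transfer function
#'
#' Maps an actor concentration onto the unit interval. Activating factors
#' return `x^n / (K^n + x^n)`; inhibiting factors return the complement
#' `1 - x^n / (K^n + x^n)`, so an absent inhibitor leaves a rate untouched.
#'
#' @param x Non-negative actor concentration (vectorised).
#' @param K Half-saturation gain, same units as `x`; must be positive.
#' @param n Hill order (cooperativity); must be positive.
#' @param direction `"activating"` or `"inhibiting"`.
#' @return Numeric in `[0, 1]`, same length as `x`.
#' @examples
#' hill_transfer(2, K = 2, n = 1)              # half-saturation -> 0.5
#' hill_transfer(6, K = 2, n = 2)              # 9/10
#' hill_transfer(0, K = 1, n = 1, "inhibiting") # no inhibitor -> 1
#' @export
hill_transfer <- function(x, K, n, direction = c("activating", "inhibiting")) {
  direction <- match.arg(direction)
  if (!is.numeric(K) || any(K <= 0) || !is.numeric(n) || any(n <= 0)) {
    abort("Invalid control rule: Hill gain `K` and order `n` must be positive.",
          class = "complementr_invalid_rule")
  }
  if (any(x < 0)) {
    abort("Actor concentration must be non-negative.",
          class = "complementr_domain_error")
  }
  xn <- x^n
  f <- xn / (K^n + xn)
  f[x == 0] <- 0 # guard 0^n/K^n when n underflows
  if (direction == "inhibiting") 1 - f else f
}

#' Evaluate a control rule
#'
#' Combines the Hill transfer outputs of every factor of a rule through its
#' integration rule (`min` or `max`). A reaction without a rule has control
#' value 1 (no modifying factors).
#'
#' @param rule A control rule as built by [control_rule()], or `NULL`.
#' @param state Named numeric vector of species concentrations.
#' @param inputs Named numeric vector of external inputs (e.g. the initiator
#'   dose), consulted when a factor's actor is not a species.
#' @return A scalar in `[0, 1]`.
#' @export
integrate_control <- function(rule, state, inputs = numeric()) {
  if (is.null(rule)) return(1)
  outs <- vapply(rule$factors, function(f) {
    if (!is.null(names(state)) && f$actor %in% names(state)) {
      x <- state[[f$actor]]
    } else if (f$actor %in% names(inputs)) {
      x <- inputs[[f$actor]]
    } else {
      abort(paste0("Control factor actor `", f$actor,
                   "` is neither a species nor an input."),
            class = "complementr_config_error")
    }
    hill_transfer(max(x, 0), f$K, f$n, f$direction)
  }, numeric(1))
  if (identical(rule$integration, "max")) max(outs) else min(outs)
}

#' Saturation (Michaelis/Hill) kinetic rate
#'
#' `k_max * enzyme * x^eta / (K^eta + x^eta)` — used for lectin-pathway
#' activation and convertase-catalysed cleavage.
#'
#' @param k_max Maximum rate constant (>= 0).
#' @param enzyme_level Catalyst abundance (species concentration or external
#'   input level; >= 0).
#' @param x_s Substrate concentration (>= 0).
#' @param K Saturation constant (> 0).
#' @param eta Hill/cooperativity order (> 0), default 1.
#' @return Non-negative rate, bounded above by `k_max * enzyme_level`.
#' @export
saturation_rate <- function(k_max, enzyme_level, x_s, K, eta = 1) {
  if (any(c(k_max, enzyme_level, x_s) < 0) || K <= 0 || eta <= 0) {
    abort("saturation_rate: concentrations must be non-negative, K and eta positive.",
          class = "complementr_domain_error")
  }
  if (x_s == 0) return(0)
  k_max * enzyme_level * x_s^eta / (K^eta + x_s^eta)
}

#' Irreversible mass-action rate
#'
#' `k_max * prod(x_s^(-sigma_s))` over the reactant set (species with negative
#' stoichiometric coefficient). Binding is treated as irreversible: there is no
#' reverse term.
#'
#' @param k_max Rate constant (>= 0).
#' @param reactant_levels Named non-negative concentrations of the reactants.
#' @param stoichiometry Named signed integer coefficients; reactants must have
#'   negative entries. Only the reactant entries are consulted.
#' @return Non-negative rate.
#' @export
mass_action_rate <- function(k_max, reactant_levels, stoichiometry) {
  reac <- names(stoichiometry)[stoichiometry < 0]
  if (length(reac) == 0) {
    abort("mass_action_rate: reaction has no reactants (no negative stoichiometry).",
          class = "complementr_config_error")
  }
  if (!all(reac %in% names(reactant_levels))) {
    abort("mass_action_rate: reactant levels missing for some reactants.",
          class = "complementr_config_error")
  }
  x <- reactant_levels[reac]
  if (any(x < 0)) {
    abort("mass_action_rate: concentrations must be non-negative.",
          class = "complementr_domain_error")
  }
  k_max * prod(x^(-stoichiometry[reac]))
}

## ---- constructors for network pieces -------------------------------------

#' Define a reaction
#'
#' @param id Reaction identifier (unique within a model).
#' @param law One of `"saturation"`, `"mass_action"`, `"first_order"`.
#' @param stoichiometry Named numeric vector of signed coefficients.
#' @param params Named list mapping rate-law roles to parameter names (strings,
#'   resolved in the model's parameter table) or fixed numeric constants.
#'   Saturation: `kmax`, `K`, `eta`; mass action / first order: `kmax`.
#' @param enzyme For saturation laws: the catalysing species name, or `NULL`
#'   when the catalyst is an external unit input.
#' @param substrate For saturation and first-order laws: the substrate species.
#' @export
reaction <- function(id, law = c("saturation", "mass_action", "first_order"),
                     stoichiometry, params, enzyme = NULL, substrate = NULL) {
  law <- match.arg(law)
  if (law == "saturation" && (is.null(substrate) ||
                              !all(c("kmax", "K") %in% names(params)))) {
    abort("Saturation reactions need a substrate and kmax/K parameters.",
          class = "complementr_config_error")
  }
  if (law == "mass_action" && !any(stoichiometry < 0)) {
    abort("Mass-action reactions need at least one reactant (sigma < 0).",
          class = "complementr_config_error")
  }
  if (law == "first_order" && is.null(substrate)) {
    abort("First-order reactions need a substrate.",
          class = "complementr_config_error")
  }
  if (law == "saturation" && is.null(params$eta)) params$eta <- 1
  structure(list(id = id, law = law, stoichiometry = stoichiometry,
                 params = params, enzyme = enzyme, substrate = substrate),
            class = "complement_reaction")
}

#' Define a control rule
#'
#' @param target Reaction id the rule multiplies.
#' @param integration `"min"` or `"max"` over the factor transfer outputs.
#' @param factors List of factors, each a list with `actor` (species or input
#'   name), `direction` (`"activating"`/`"inhibiting"`), `K` and `n` (parameter
#'   names or fixed numbers).
#' @export
control_rule <- function(target, integration = c("min", "max"), factors) {
  integration <- match.arg(integration)
  structure(list(target = target, integration = integration, factors = factors),
            class = "complement_control")
}

## Resolve a parameter reference (name or fixed numeric) against a named vector
resolve_param <- function(ref, values) {
  if (is.character(ref)) {
    if (!ref %in% names(values)) {
      abort(paste0("Parameter `", ref, "` is referenced but not declared."),
            class = "complementr_config_error")
    }
    unname(values[[ref]])
  } else {
    as.numeric(ref)
  }
}

## ---- model compilation ----------------------------------------------------

## Turn a model + parameter values + initiator dose into fast closures for the
## integrator: a stoichiometric matrix, one rate closure per reaction (control
## folded in; initiator-dependent factors are constant within a simulation),
## and the time-scale multipliers tau.
compile_model <- function(model, values = NULL, dose = NULL) {
  sp <- model$species$name
  M <- length(sp)
  if (is.null(values)) values <- model_parameter_values(model)
  init_name <- model$initiator$name
  needs_dose <- any(model$species$tau == "initiator")
  if (is.null(dose)) {
    if (needs_dose) {
      abort("Initiator-scaled species present but no initiator dose supplied.",
            class = "complementr_input_error")
    }
    dose <- 0
  }
  inputs <- setNames(dose, init_name)

  nr <- length(model$reactions)
  S <- matrix(0, M, nr, dimnames = list(sp, vapply(model$reactions, `[[`,
                                                  "", "id")))
  controls_by_target <- setNames(
    model$controls,
    vapply(model$controls, `[[`, "", "target")
  )

  rate_fns <- vector("list", nr)
  for (j in seq_len(nr)) {
    rx <- model$reactions[[j]]
    st <- rx$stoichiometry
    bad <- setdiff(names(st), sp)
    if (length(bad) > 0) {
      abort(paste0("Reaction `", rx$id, "` names undeclared species: ",
                   paste(bad, collapse = ", ")),
            class = "complementr_config_error")
    }
    S[names(st), j] <- st

    ## control: species-dependent factors evaluated per step; input factors
    ## (the initiator gate) are constant for a fixed dose
    ctrl <- controls_by_target[[rx$id]]
    const_ctrl <- 1
    dyn_factors <- list()
    if (!is.null(ctrl)) {
      for (f in ctrl$factors) {
        K <- resolve_param(f$K, values)
        n <- resolve_param(f$n, values)
        if (f$actor %in% sp) {
          dyn_factors[[length(dyn_factors) + 1]] <-
            list(idx = match(f$actor, sp), K = K, n = n,
                 direction = f$direction)
        } else if (f$actor %in% names(inputs)) {
          out <- hill_transfer(max(inputs[[f$actor]], 0), K, n, f$direction)
          const_ctrl <- c(const_ctrl, out)
        } else {
          abort(paste0("Control factor actor `", f$actor, "` unknown."),
                class = "complementr_config_error")
        }
      }
      agg <- if (identical(ctrl$integration, "max")) max else min
      has_const <- length(const_ctrl) > 1
      ## with no dynamic factors the control collapses to a constant
      const_only <- length(dyn_factors) == 0
      const_val <- if (has_const) agg(const_ctrl[-1]) else 1
    } else {
      agg <- min
      has_const <- FALSE
      const_only <- TRUE
      const_val <- 1
    }

    kmax <- resolve_param(rx$params$kmax, values)
    if (rx$law == "saturation") {
      K <- resolve_param(rx$params$K, values)
      eta <- resolve_param(rx$params$eta %||% 1, values)
      s_idx <- match(rx$substrate, sp)
      e_idx <- if (is.null(rx$enzyme)) 0L else match(rx$enzyme, sp)
      Keta <- K^eta
      rate_fns[[j]] <- local({
        kmax <- kmax; Keta <- Keta; eta <- eta; s_idx <- s_idx; e_idx <- e_idx
        dyn <- dyn_factors; agg_f <- agg; cv <- const_val
        co <- const_only; hc <- has_const
        function(x) {
          xs <- x[s_idx]
          eps <- if (e_idx > 0L) x[e_idx] else 1
          if (xs <= 0 || eps <= 0) return(0)
          xe <- xs^eta
          r <- kmax * eps * xe / (Keta + xe)
          v <- if (co) cv else {
            outs <- vapply(dyn, function(f) {
              xa <- x[f$idx]
              h <- if (xa <= 0) 0 else xa^f$n / (f$K^f$n + xa^f$n)
              if (f$direction == "inhibiting") 1 - h else h
            }, numeric(1))
            agg_f(c(outs, if (hc) cv))
          }
          r * v
        }
      })
    } else if (rx$law == "mass_action") {
      reac_idx <- match(names(st)[st < 0], sp)
      pow <- -st[st < 0]
      rate_fns[[j]] <- local({
        kmax <- kmax; reac_idx <- reac_idx; pow <- pow
        dyn <- dyn_factors; agg_f <- agg; cv <- const_val
        co <- const_only; hc <- has_const
        function(x) {
          r <- kmax * prod(x[reac_idx]^pow)
          if (co) return(r * cv)
          outs <- vapply(dyn, function(f) {
            xa <- x[f$idx]
            h <- if (xa <= 0) 0 else xa^f$n / (f$K^f$n + xa^f$n)
            if (f$direction == "inhibiting") 1 - h else h
          }, numeric(1))
          r * agg_f(c(outs, if (hc) cv))
        }
      })
    } else { # first_order
      s_idx <- match(rx$substrate, sp)
      rate_fns[[j]] <- local({
        kmax <- kmax; s_idx <- s_idx
        dyn <- dyn_factors; agg_f <- agg; cv <- const_val
        co <- const_only; hc <- has_const
        function(x) {
          r <- kmax * x[s_idx]
          if (co) return(r * cv)
          outs <- vapply(dyn, function(f) {
            xa <- x[f$idx]
            h <- if (xa <= 0) 0 else xa^f$n / (f$K^f$n + xa^f$n)
            if (f$direction == "inhibiting") 1 - h else h
          }, numeric(1))
          r * agg_f(c(outs, if (hc) cv))
        }
      })
    }
  }

  ## time-scale multipliers: tau = z/z* for initiator-scaled species at z > 0;
  ## without initiator the correction does not apply (tau = 1)
  tau <- rep(1, M)
  if (needs_dose && dose > 0) {
    tau[model$species$tau == "initiator"] <- dose / model$initiator$reference_dose
  }
  tau_scaled <- any(tau != 1)

  rhs <- function(t, x, parms) {
    x <- pmax(x, 0)
    r <- numeric(nr)
    for (j in seq_len(nr)) r[j] <- rate_fns[[j]](x)
    dx <- as.vector(S %*% r)
    if (tau_scaled) dx <- dx * tau
    list(dx)
  }

  list(rhs = rhs, S = S, species = sp, tau = tau, rate_fns = rate_fns,
       dose = dose)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate the ODE right-hand side
#'
#' Assembles `dx_i/dt = tau_i * sum_j sigma_ij * r_j * v_j` for a model at one
#' state. The time-scale multiplier `tau_i = z / z*` applies to the
#' initiator-scaled species (C5a and C5b in the default network) when an
#' initiator dose `z > 0` is supplied; all other species have `tau_i = 1`.
#'
#' @param model A `complement_model`.
#' @param state Named (or model-ordered) numeric state vector; values are
#'   clamped at zero for rate evaluation.
#' @param params Optional named parameter vector; defaults to the model's
#'   nominal values.
#' @param inputs Named numeric vector of external inputs; must carry the
#'   initiator dose when the model contains initiator-scaled species.
#' @return Named derivative vector (one entry per species).
#' @export
evaluate_rhs <- function(model, state, params = NULL, inputs = NULL) {
  sp <- model$species$name
  if (!is.null(names(state))) {
    missing_sp <- setdiff(sp, names(state))
    if (length(missing_sp) > 0) {
      abort(paste0("State is missing species: ",
                   paste(missing_sp, collapse = ", ")),
            class = "complementr_input_error")
    }
    state <- state[sp]
  } else if (length(state) != length(sp)) {
    abort("State length does not match the number of species.",
          class = "complementr_input_error")
  }
  dose <- NULL
  if (!is.null(inputs) && model$initiator$name %in% names(inputs)) {
    dose <- inputs[[model$initiator$name]]
  }
  cm <- compile_model(model, values = params, dose = dose)
  setNames(cm$rhs(0, as.numeric(state), NULL)[[1]], sp)
}
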