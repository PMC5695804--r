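## The shipped reduced-order lectin + alternative pathway network:
## 18 state variables, 13 reactions, 28 free kinetic parameters.
## Concentrations in nM, time in hours, initiator (zymosan) dose in mg/ml.

#' Construct a complement model
#'
#' Low-level constructor; most users want [default_complement_model()] or
#' [read_model()]. Validates the structure and errors listing every violated
#' invariant.
#'
#' @param species Tibble/data frame with columns `name`, `initial` (nM) and
#'   `tau` (`"constant"` or `"initiator"`).
#' @param reactions List of [reaction()] objects.
#' @param controls List of [control_rule()] objects.
#' @param parameters Tibble with columns `name`, `value`, `lower`, `upper`.
#' @param initiator List with `name`, `units`, `reference_dose`.
#' @return A `complement_model`.
#' @export
complement_model <- function(species, reactions, controls, parameters,
                             initiator = list(name = "zymosan",
                                              units = "mg/ml",
                                              reference_dose = 1)) {
  species <- as_tibble(species)
  parameters <- as_tibble(parameters)
  model <- structure(
    list(species = species, reactions = reactions, controls = controls,
         parameters = parameters, initiator = initiator),
    class = "complement_model")
  problems <- validate_model(model)
  if (length(problems) > 0) {
    abort(paste0("Invalid model definition:\n",
                 paste0("- ", problems, collapse = "\n")),
          class = "complementr_config_error")
  }
  model
}

## Returns a character vector of invariant violations (empty when valid)
validate_model <- function(model) {
  p <- character()
  sp <- model$species$name
  if (anyDuplicated(sp)) p <- c(p, "duplicated species names")
  if (any(model$species$initial < 0)) {
    p <- c(p, paste("negative initial condition for:",
                    paste(sp[model$species$initial < 0], collapse = ", ")))
  }
  if (!all(model$species$tau %in% c("constant", "initiator"))) {
    p <- c(p, "species `tau` must be \"constant\" or \"initiator\"")
  }
  par_names <- model$parameters$name
  if (anyDuplicated(par_names)) p <- c(p, "duplicated parameter names")
  pt <- model$parameters
  oob <- pt$value < pt$lower | pt$value > pt$upper
  if (any(oob)) {
    p <- c(p, paste("parameter value outside bounds for:",
                    paste(pt$name[oob], collapse = ", ")))
  }
  if (any(pt$lower <= 0)) {
    p <- c(p, paste("non-positive lower bound for:",
                    paste(pt$name[pt$lower <= 0], collapse = ", ")))
  }
  rx_ids <- vapply(model$reactions, `[[`, "", "id")
  if (anyDuplicated(rx_ids)) p <- c(p, "duplicated reaction ids")
  for (rx in model$reactions) {
    bad <- setdiff(names(rx$stoichiometry), sp)
    if (length(bad) > 0) {
      p <- c(p, paste0("reaction `", rx$id, "` names undeclared species: ",
                       paste(bad, collapse = ", ")))
    }
    if (!is.null(rx$enzyme) && !rx$enzyme %in% sp) {
      p <- c(p, paste0("reaction `", rx$id, "` enzyme `", rx$enzyme,
                       "` is not a species"))
    }
    if (!is.null(rx$substrate) && !rx$substrate %in% sp) {
      p <- c(p, paste0("reaction `", rx$id, "` substrate `", rx$substrate,
                       "` is not a species"))
    }
    for (ref in rx$params) {
      if (is.character(ref) && !ref %in% par_names) {
        p <- c(p, paste0("reaction `", rx$id, "` references undeclared ",
                         "parameter `", ref, "`"))
      }
    }
  }
  ctrl_targets <- vapply(model$controls, `[[`, "", "target")
  if (anyDuplicated(ctrl_targets)) {
    p <- c(p, "a reaction may carry at most one control rule")
  }
  for (ct in model$controls) {
    if (!ct$target %in% rx_ids) {
      p <- c(p, paste0("control rule targets unknown reaction `",
                       ct$target, "`"))
    }
    for (f in ct$factors) {
      if (!f$actor %in% c(sp, model$initiator$name)) {
        p <- c(p, paste0("control factor actor `", f$actor,
                         "` is neither a species nor the initiator"))
      }
      for (ref in list(f$K, f$n)) {
        if (is.character(ref) && !ref %in% par_names) {
          p <- c(p, paste0("control factor references undeclared parameter `",
                           ref, "`"))
        }
      }
    }
  }
  p
}

#' Nominal parameter values of a model
#'
#' @param model A `complement_model`.
#' @return Named numeric vector of the nominal parameter values.
#' @export
model_parameter_values <- function(model) {
  setNames(model$parameters$value, model$parameters$name)
}

#' Initial conditions of a model
#'
#' @param model A `complement_model`.
#' @return Named numeric vector (nM), in species order.
#' @export
model_initial_conditions <- function(model) {
  setNames(model$species$initial, model$species$name)
}

#' The default reduced-order complement network
#'
#' Builds the shipped lectin + alternative pathway model: 18 species and 28
#' free parameters across 13 reactions. Lectin initiation cleaves C4 and C2
#' behind a zymosan-gated Hill rule; classical-pathway (CP) and alternative
#' pathway (AP) C3 convertases cleave C3 under C4BP and factor H inhibitory
#' control respectively; tickover seeds the AP; C3b recruitment converts C3
#' convertases into C5 convertases; both C5 convertases cleave C5; C3a and C5a
#' are cleared first order. Factor B and D are assumed in excess (lumped into
#' the AP convertase assembly step); factor H and C4BP act purely as control
#' factors, so their own balances are constant.
#'
#' Initial conditions are physiological serum levels converted to nM
#' (C3 1.2 mg/ml, C4 0.4, C2 0.025, C5 0.075, factor H 0.5, C4BP 0.25);
#' fragments and complexes start at zero. C5a and C5b carry the
#' initiator-scaled time-scale rule `tau = z / z*` (`z*` = 1 mg/ml).
#'
#' @return A `complement_model`.
#' @examples
#' m <- default_complement_model()
#' nrow(m$species)      # 18
#' nrow(m$parameters)   # 28
#' @export
default_complement_model <- function() {
  species <- tibble::tribble(
    ~name,          ~initial, ~tau,
    "C4",             1950,   "constant",
    "C4a",               0,   "constant",
    "C4b",               0,   "constant",
    "C2",              245,   "constant",
    "C2a",               0,   "constant",
    "C2b",               0,   "constant",
    "C3",             6500,   "constant",
    "C3a",               0,   "constant",
    "C3b",               0,   "constant",
    "C5",              395,   "constant",
    "C5a",               0,   "initiator",
    "C5b",               0,   "initiator",
    "CP_C3_convertase",  0,   "constant",
    "AP_C3_convertase",  0,   "constant",
    "CP_C5_convertase",  0,   "constant",
    "AP_C5_convertase",  0,   "constant",
    "FactorH",        3200,   "constant",
    "C4BP",            440,   "constant"
  )

  ## 28 free parameters; declaration order fixes the 1..28 index map
  parameters <- tibble::tribble(
    ~name,               ~value, ~lower,  ~upper,
    "lectin_c4_kmax",      400,   4,      4e4,    #  1 C4 -> C4a + C4b rate
    "lectin_c4_Km",       1000,  10,      1e5,    #  2
    "lectin_c2_kmax",      100,   1,      1e4,    #  3 C2 -> C2a + C2b rate
    "lectin_c2_Km",        500,   5,      5e4,    #  4
    "lectin_gate_K",       0.1,   1e-3,   10,     #  5 zymosan gate gain
    "cp_c3_assembly_k",   1e-3,   1e-5,   0.1,    #  6 C4b + C2a binding
    "cp_c3_kcat",           20,   0.2,    2000,   #  7 CP C3 convertase activity
    "cp_c3_Km",           2000,  20,      2e5,    #  8
    "cp_c3_eta",             1,   1,      4,      #  9
    "c4bp_K",             1000,  10,      1e5,    # 10 C4BP inhibition gain
    "c4bp_n",                1,   1,      4,      # 11
    "tickover_k",        0.003,   3e-5,   0.3,    # 12 basal C3 hydrolysis
    "ap_c3_assembly_k",    0.1,   1e-3,   10,     # 13 C3b -> AP C3 convertase
    "ap_c3_kcat",           10,   0.1,    1000,   # 14 AP C3 convertase activity
    "ap_c3_Km",           3000,  30,      3e5,    # 15
    "ap_c3_eta",             1,   1,      4,      # 16
    "fh_K",               3000,  30,      3e5,    # 17 factor H inhibition gain
    "fh_n",                  1,   1,      4,      # 18
    "cp_c5_assembly_k",   3e-5,   3e-7,   3e-3,   # 19 CP C3 conv + C3b binding
    "ap_c5_assembly_k",   3e-5,   3e-7,   3e-3,   # 20 AP C3 conv + C3b binding
    "cp_c5_kcat",          0.2,   2e-3,   20,     # 21 CP C5 convertase activity
    "cp_c5_Km",           1000,  10,      1e5,    # 22
    "cp_c5_eta",             1,   1,      4,      # 23
    "ap_c5_kcat",          0.2,   2e-3,   20,     # 24 AP C5 convertase activity
    "ap_c5_Km",           1000,  10,      1e5,    # 25
    "ap_c5_eta",             1,   1,      4,      # 26
    "c3a_deg_k",           0.1,   1e-3,   10,     # 27 C3a clearance
    "c5a_deg_k",          0.01,   1e-4,   1       # 28 C5a clearance
  )

  reactions <- list(
    reaction("lectin_C4_cleavage", "saturation",
             c(C4 = -1, C4a = 1, C4b = 1),
             params = list(kmax = "lectin_c4_kmax", K = "lectin_c4_Km",
                           eta = 1),
             substrate = "C4"),
    reaction("lectin_C2_cleavage", "saturation",
             c(C2 = -1, C2a = 1, C2b = 1),
             params = list(kmax = "lectin_c2_kmax", K = "lectin_c2_Km",
                           eta = 1),
             substrate = "C2"),
    reaction("cp_c3_convertase_assembly", "mass_action",
             c(C4b = -1, C2a = -1, CP_C3_convertase = 1),
             params = list(kmax = "cp_c3_assembly_k")),
    reaction("cp_c3_convertase_activity", "saturation",
             c(C3 = -1, C3a = 1, C3b = 1),
             params = list(kmax = "cp_c3_kcat", K = "cp_c3_Km",
                           eta = "cp_c3_eta"),
             enzyme = "CP_C3_convertase", substrate = "C3"),
    reaction("tickover", "first_order",
             c(C3 = -1, C3a = 1, C3b = 1),
             params = list(kmax = "tickover_k"),
             substrate = "C3"),
    reaction("ap_c3_convertase_assembly", "first_order",
             c(C3b = -1, AP_C3_convertase = 1),
             params = list(kmax = "ap_c3_assembly_k"),
             substrate = "C3b"),
    reaction("ap_c3_convertase_activity", "saturation",
             c(C3 = -1, C3a = 1, C3b = 1),
             params = list(kmax = "ap_c3_kcat", K = "ap_c3_Km",
                           eta = "ap_c3_eta"),
             enzyme = "AP_C3_convertase", substrate = "C3"),
    reaction("cp_c5_convertase_assembly", "mass_action",
             c(CP_C3_convertase = -1, C3b = -1, CP_C5_convertase = 1),
             params = list(kmax = "cp_c5_assembly_k")),
    reaction("ap_c5_convertase_assembly", "mass_action",
             c(AP_C3_convertase = -1, C3b = -1, AP_C5_convertase = 1),
             params = list(kmax = "ap_c5_assembly_k")),
    reaction("cp_c5_convertase_activity", "saturation",
             c(C5 = -1, C5a = 1, C5b = 1),
             params = list(kmax = "cp_c5_kcat", K = "cp_c5_Km",
                           eta = "cp_c5_eta"),
             enzyme = "CP_C5_convertase", substrate = "C5"),
    reaction("ap_c5_convertase_activity", "saturation",
             c(C5 = -1, C5a = 1, C5b = 1),
             params = list(kmax = "ap_c5_kcat", K = "ap_c5_Km",
                           eta = "ap_c5_eta"),
             enzyme = "AP_C5_convertase", substrate = "C5"),
    reaction("c3a_clearance", "first_order", c(C3a = -1),
             params = list(kmax = "c3a_deg_k"), substrate = "C3a"),
    reaction("c5a_clearance", "first_order", c(C5a = -1),
             params = list(kmax = "c5a_deg_k"), substrate = "C5a")
  )

  controls <- list(
    control_rule("lectin_C4_cleavage", "min", list(
      list(actor = "zymosan", direction = "activating",
           K = "lectin_gate_K", n = 2))),
    control_rule("lectin_C2_cleavage", "min", list(
      list(actor = "zymosan", direction = "activating",
           K = "lectin_gate_K", n = 2))),
    control_rule("cp_c3_convertase_activity", "min", list(
      list(actor = "C4BP", direction = "inhibiting",
           K = "c4bp_K", n = "c4bp_n"))),
    control_rule("ap_c3_convertase_activity", "min", list(
      list(actor = "FactorH", direction = "inhibiting",
           K = "fh_K", n = "fh_n")))
  )

  complement_model(species, reactions, controls, parameters)
}

#' @export
print.complement_model <- function(x, ...) {
  cat("<complement_model>\n")
  cat("  species:    ", nrow(x$species), "\n")
  cat("  reactions:  ", length(x$reactions), "\n")
  cat("  parameters: ", nrow(x$parameters), "\n")
  cat("  initiator:  ", x$initiator$name, " (", x$initiator$units, ")\n",
      sep = "")
  invisible(x)
}

## ---- model file i/o -------------------------------------------------------

#' Write a model definition to a YAML file
#'
#' The file has sections `species`, `reactions`, `controls`, `parameters` and
#' `initiator`, and round-trips bit-exactly through [read_model()].
#'
#' @param model A `complement_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  doc <- list(
    initiator = model$initiator,
    species = purrr::pmap(model$species, function(name, initial, tau) {
      list(name = name, initial = initial, tau = tau)
    }),
    parameters = purrr::pmap(model$parameters,
                             function(name, value, lower, upper) {
      list(name = name, value = value, lower = lower, upper = upper)
    }),
    reactions = lapply(model$reactions, function(rx) {
      list(id = rx$id, law = rx$law,
           stoichiometry = as.list(rx$stoichiometry),
           params = rx$params, enzyme = rx$enzyme, substrate = rx$substrate)
    }),
    controls = lapply(model$controls, function(ct) {
      list(target = ct$target, integration = ct$integration,
           factors = ct$factors)
    })
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Read a model definition from a YAML file
#'
#' Species listed without an `initial` entry default to zero. Initial
#' conditions may be given in nM directly, or as mass concentrations with an
#' explicit molecular weight (`initial_mg_ml` together with `mw_kda`), in which
#' case they are converted to nM.
#'
#' @param path Path to a model YAML file as written by [write_model()].
#' @return A validated `complement_model`; validation failures list every
#'   violated invariant.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Model file not found: ", path),
          class = "complementr_input_error")
  }
  doc <- yaml::read_yaml(path)
  species <- purrr::map_dfr(doc$species, function(s) {
    init <- s[["initial"]]
    if (is.null(init) && !is.null(s$initial_mg_ml)) {
      if (is.null(s$mw_kda)) {
        abort(paste0("Species `", s$name,
                     "`: initial_mg_ml requires mw_kda for nM conversion."),
              class = "complementr_config_error")
      }
      ## mg/ml = g/l; nM = 1e6 * (g/l) / (kDa)
      init <- 1e6 * s$initial_mg_ml / s$mw_kda
    }
    tibble(name = s$name, initial = init %||% 0,
           tau = s$tau %||% "constant")
  })
  parameters <- purrr::map_dfr(doc$parameters, function(p) {
    tibble(name = p$name, value = p$value,
           lower = p$lower %||% p$value, upper = p$upper %||% p$value)
  })
  reactions <- lapply(doc$reactions, function(rx) {
    reaction(rx$id, rx$law, unlist(rx$stoichiometry),
             params = rx$params, enzyme = rx$enzyme,
             substrate = rx$substrate)
  })
  controls <- lapply(doc$controls, function(ct) {
    control_rule(ct$target, ct$integration, ct$factors)
  })
  complement_model(species, reactions, controls, parameters,
                   initiator = doc$initiator)
}

## ---- knockdowns -----------------------------------------------------------

#' Knock down initial conditions
#'
#' Multiplies the initial abundance of each target species by
#' `1 - fraction / 100`, emulating an anti-complement intervention (e.g. a C3
#' and/or C5 inhibitor). All other entries are unchanged.
#'
#' @param x A named initial-condition vector or a `complement_model`.
#' @param targets Character vector of species to perturb.
#' @param fraction Knockdown percentage in `[0, 100]`.
#' @return Same type as `x` with the targets reduced.
#' @examples
#' ic <- model_initial_conditions(default_complement_model())
#' knockdown(ic, "C3", 90)[["C3"]]   # 10% of nominal
#' @export
knockdown <- function(x, targets, fraction) {
  if (fraction < 0 || fraction > 100) {
    abort("`fraction` must be a percentage in [0, 100].",
          class = "complementr_input_error")
  }
  if (inherits(x, "complement_model")) {
    ic <- knockdown(model_initial_conditions(x), targets, fraction)
    x$species$initial <- unname(ic[x$species$name])
    return(x)
  }
  unknown <- setdiff(targets, names(x))
  if (length(unknown) > 0) {
    abort(paste0("Unknown knockdown target(s): ",
                 paste(unknown, collapse = ", ")),
          class = "complementr_input_error")
  }
  x[targets] <- x[targets] * (1 - fraction / 100)
  x
}
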