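#' Default parameter bundle
#'
#' Returns the full set of model parameters: the four genetic-scaling
#' parameters, the fixed model parameters, the constant nutritional
#' environment and the simulation settings.  The bundle is the single
#' source of truth for every symbol used by the simulator; every value can
#' be overridden through [load_config()] or by editing the returned list.
#'
#' The genetic-scaling parameters are the model's representation of a
#' genotype: `g2s_gen` and `pc2s_gen` are per-day rates of priority
#' transfer (growth to survival, and current progeny back to survival)
#' that set the lifetime allocation trajectories, while `acqb_gen` and
#' `acql_gen` (kg DM/day) are the mature asymptotes of the basal and
#' lactation-induced intake curves.  Their default values are the "medium"
#' genotype used as the centre of the factorial sensitivity design; they
#' were calibrated so that the medium cow expresses typical Holstein-scale
#' lifetime trajectories (see the methods vignette for the calibration
#' account and for the meaning, units and provenance of every fixed
#' parameter).
#'
#' @return A named list of class `cow_params` with components `genetics`,
#'   `fixed`, `env` and `sim`, each a named list of scalars.
#' @examples
#' p <- default_params()
#' p$genetics$acqb_gen
#' @export
default_params <- function() {
  params <- list(
    genetics = list(
      # per-day priority transfer rates
      g2s_gen  = 0.00285,
      pc2s_gen = 0.042,
      # kg DM/day intake asymptotes at maturity
      acqb_gen = 10.6,
      acql_gen = 8.0
    ),
    fixed = list(
      ## allocation sub-model
      alloc_g_birth   = 0.62,   # growth priority at birth; remainder to survival
      s2pc            = 0.050,  # survival -> current progeny rate (no genetic variance)
      kh_pf0          = 0.0,    # gestation sigmoid baseline (per day)
      kh_pf1          = 0.0020, # gestation sigmoid amplitude (per day)
      kh_pf2          = 0.030,  # gestation sigmoid steepness (per day of gestation)
      kh_pf3          = 200,    # gestation sigmoid midpoint (day of gestation)
      c_growth_gest   = 0.01,   # gestation acceleration of growth decline
      c_lact_gest     = 0.06,   # gestation depression of lactation
      s2pc_quadratic  = FALSE,  # alternative AllocS^2 reading of the S->Pc flow
      ## acquisition sub-model
      k_acqb_mat        = 0.0020, # per-day maturation rate of basal intake
      acqb_immature_frac = 0.8,   # fraction of asymptote missing at birth
      k_acql_mat        = 0.0020, # per-day maturation rate of lactation intake
      acql_immature_frac = 0.6,
      acql_dyn_a        = 0.060,  # within-lactation rise rate (per day in milk)
      acql_dyn_b        = 0.0020, # within-lactation decline rate (per day in milk)
      q0                = 0.60,   # baseline metabolizability (ME/GE) at maintenance
      q_co              = 0.05,   # metabolizability gain per unit concentrate fraction
      q_fl              = 0.02,   # metabolizability loss per unit feeding level above 1
      q_min             = 0.35,
      q_max             = 0.75,
      ## utilization sub-model
      maint_coeff        = 0.2325, # MJ ME per kg^maint_exp per day
      maint_exp          = 0.92,
      k_growth           = 0.70,  # ME -> structural tissue efficiency
      growth_tissue_energy = 18.6, # MJ per kg structural tissue
      k_gest             = 0.14,  # ME -> gravid uterus efficiency
      gest_tissue_energy = 6.0,   # MJ per kg gravid uterus
      k_lact             = 0.62,  # ME allocated to lactation -> milk energy
      milk_energy_density = 3.1,  # MJ per kg milk
      k_repletion        = 0.35,  # ME surplus -> labile tissue efficiency
      labile_tissue_energy = 30,  # MJ per kg labile tissue
      k_mobilization     = 0.84,  # labile tissue -> ME efficiency
      mobilization_cap   = 2.0,   # kg labile mobilizable per day
      structural_mass_birth = 40,
      labile_mass_birth  = 15,
      bcs_ref_ratio      = 0.30,  # labile/structural ratio scored as BCS 3.0
      conc_b0            = -0.20, # conception logit intercept
      conc_b_milk        = -0.046, # per kg/day milk yield
      conc_b_bcs         = 0.15,  # per BCS unit above 3
      conc_b_eb          = 0.004, # per MJ/day smoothed energy balance
      eb_window          = 7,     # trailing days for smoothed energy balance
      ## physiological events (days)
      gestation_length   = 282,
      dry_period         = 70,
      voluntary_waiting  = 65,
      cycle_length       = 21,
      first_breeding_age = 425,
      max_lactation_length = 420,
      culling_days_open  = 200,
      death_deficit_days = 15
    ),
    env = list(
      ge_res  = 4.4,  # Mcal gross energy per kg DM
      ndf_res = 0.35, # resource fibre fraction (carried, inert by default)
      co_res  = 0.30  # concentrate proportion of the diet
    ),
    sim = list(
      dt = 1,            # model is defined at daily resolution
      max_horizon = 7300, # hard stop (20 years)
      n_replicates = 20,
      seed = 1L
    )
  )
  structure(params, class = "cow_params")
}

# bounds used by validate_params(): list(lower, upper, strict_lower)
.param_bounds <- function() {
  list(
    genetics = list(
      g2s_gen = c(0, Inf), pc2s_gen = c(0, Inf),
      acqb_gen = c(0, Inf), acql_gen = c(0, Inf)
    ),
    fixed = list(
      alloc_g_birth = c(0, 1), s2pc = c(0, Inf),
      kh_pf0 = c(0, Inf), kh_pf1 = c(0, Inf), kh_pf2 = c(0, Inf), kh_pf3 = c(0, Inf),
      c_growth_gest = c(0, 1), c_lact_gest = c(0, 1),
      k_acqb_mat = c(0, Inf), acqb_immature_frac = c(0, 1),
      k_acql_mat = c(0, Inf), acql_immature_frac = c(0, 1),
      acql_dyn_a = c(0, Inf), acql_dyn_b = c(0, Inf),
      q0 = c(0, 1), q_co = c(0, 1), q_fl = c(0, 1), q_min = c(0, 1), q_max = c(0, 1),
      maint_coeff = c(0, Inf), maint_exp = c(0, 2),
      k_growth = c(0, 1), growth_tissue_energy = c(0, Inf),
      k_gest = c(0, 1), gest_tissue_energy = c(0, Inf),
      k_lact = c(0, 1), milk_energy_density = c(0, Inf),
      k_repletion = c(0, 1), labile_tissue_energy = c(0, Inf),
      k_mobilization = c(0, 1), mobilization_cap = c(0, Inf),
      structural_mass_birth = c(0, Inf), labile_mass_birth = c(0, Inf),
      bcs_ref_ratio = c(0, Inf),
      conc_b0 = c(-Inf, Inf), conc_b_milk = c(-Inf, Inf),
      conc_b_bcs = c(-Inf, Inf), conc_b_eb = c(-Inf, Inf),
      eb_window = c(1, Inf),
      gestation_length = c(1, Inf), dry_period = c(1, Inf),
      voluntary_waiting = c(1, Inf), cycle_length = c(1, Inf),
      first_breeding_age = c(1, Inf), max_lactation_length = c(1, Inf),
      culling_days_open = c(1, Inf), death_deficit_days = c(1, Inf)
    ),
    env = list(
      ge_res = c(0, Inf), ndf_res = c(0, 1), co_res = c(0, 1)
    ),
    sim = list(
      dt = c(1, 1), max_horizon = c(1, Inf), n_replicates = c(1, Inf),
      seed = c(-Inf, Inf)
    )
  )
}

# genetic-scaling parameters and asymptotes must be strictly positive
.strictly_positive <- c(
  "g2s_gen", "pc2s_gen", "acqb_gen", "acql_gen",
  "ge_res", "maint_coeff", "milk_energy_density",
  "growth_tissue_energy", "gest_tissue_energy", "labile_tissue_energy"
)

#' Validate a parameter bundle
#'
#' Checks every parameter against its documented bound (rates and
#' efficiencies non-negative, fractions in \[0, 1\], genetic-scaling
#' parameters strictly positive, threshold days at least 1, daily time
#' step fixed at 1).  Errors name the offending key and the violated
#' bound.
#'
#' @param params A `cow_params` bundle, e.g. from [default_params()].
#' @return `params`, invisibly, if valid.
#' @examples
#' validate_params(default_params())
#' @export
validate_params <- function(params) {
  if (!is.list(params)) abort("`params` must be a list (see `default_params()`).")
  bounds <- .param_bounds()
  defaults <- unclass(default_params())
  for (grp in names(bounds)) {
    if (is.null(params[[grp]])) {
      abort(sprintf("configuration error: missing required group '%s'", grp))
    }
    missing_keys <- setdiff(names(defaults[[grp]]), names(params[[grp]]))
    if (length(missing_keys) > 0) {
      abort(sprintf(
        "configuration error: missing required key(s): %s",
        paste0(grp, ".", missing_keys, collapse = ", ")
      ))
    }
    for (key in names(bounds[[grp]])) {
      val <- params[[grp]][[key]]
      if (!is.numeric(val) && !is.logical(val) || length(val) != 1 || is.na(val)) {
        abort(sprintf("validation error: '%s.%s' must be a single finite value", grp, key))
      }
      if (is.logical(val)) next
      b <- bounds[[grp]][[key]]
      if (key %in% .strictly_positive) {
        if (val <= 0) {
          abort(sprintf("validation error: '%s.%s' must be > 0 (got %g)", grp, key, val))
        }
      } else if (val < b[1] || val > b[2]) {
        abort(sprintf(
          "validation error: '%s.%s' must be in [%g, %g] (got %g)",
          grp, key, b[1], b[2], val
        ))
      }
    }
  }
  if (params$fixed$q_min > params$fixed$q_max) {
    abort("validation error: 'fixed.q_min' must not exceed 'fixed.q_max'")
  }
  if (params$fixed$dry_period >= params$fixed$gestation_length) {
    abort("validation error: 'fixed.dry_period' must be shorter than 'fixed.gestation_length'")
  }
  invisible(params)
}

#' Read a configuration file into a parameter bundle
#'
#' Reads a flat or nested YAML document and merges it over
#' [default_params()].  Keys may be given nested under `genetics`,
#' `fixed`, `env` and `sim`, or flat (e.g. `acqb_gen: 14`), in which case
#' they are matched to their group by name.  Unknown keys raise an error;
#' the merged bundle is validated before being returned.
#'
#' @param path Path to a YAML configuration file, or `NULL` for defaults.
#' @param overrides Optional named list (flat or nested) applied after the
#'   file, useful for programmatic `key = value` overrides.
#' @return A validated `cow_params` bundle.
#' @examples
#' load_config(overrides = list(acql_gen = 8))$genetics$acql_gen
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  params <- default_params()
  apply_doc <- function(params, doc, origin) {
    if (is.null(doc)) return(params)
    if (!is.list(doc)) abort(sprintf("configuration error: %s does not parse to a mapping", origin))
    grouped <- names(doc) %in% names(params)
    for (grp in names(doc)[grouped]) {
      unknown <- setdiff(names(doc[[grp]]), names(params[[grp]]))
      if (length(unknown) > 0) {
        abort(sprintf("configuration error: unknown key(s) %s in group '%s'",
                      paste0("'", unknown, "'", collapse = ", "), grp))
      }
      params[[grp]] <- modifyList(params[[grp]], doc[[grp]])
    }
    for (key in names(doc)[!grouped]) {
      grp <- .find_group(params, key)
      if (is.null(grp)) abort(sprintf("configuration error: unknown key '%s'", key))
      params[[grp]][[key]] <- doc[[key]]
    }
    params
  }
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("configuration error: file '%s' not found", path))
    params <- apply_doc(params, yaml::read_yaml(path), sprintf("file '%s'", path))
  }
  params <- apply_doc(params, overrides, "`overrides`")
  validate_params(params)
  params
}

.find_group <- function(params, key) {
  for (grp in names(params)) if (key %in% names(params[[grp]])) return(grp)
  NULL
}

#' Write a parameter bundle to a YAML configuration file
#'
#' The written file round-trips through [load_config()] to an identical
#' bundle, so a run can be reproduced from its configuration snapshot.
#'
#' @param params A validated `cow_params` bundle.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  validate_params(params)
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @export
print.cow_params <- function(x, ...) {
  cat("<cow_params>\n")
  g <- x$genetics
  cat(sprintf("  genotype: g2s_gen=%g  pc2s_gen=%g  acqb_gen=%g  acql_gen=%g\n",
              g$g2s_gen, g$pc2s_gen, g$acqb_gen, g$acql_gen))
  cat(sprintf("  environment: ge_res=%g Mcal/kg, ndf_res=%g, co_res=%g\n",
              x$env$ge_res, x$env$ndf_res, x$env$co_res))
  cat(sprintf("  %d fixed parameters; horizon %d d, %d replicates\n",
              length(x$fixed), x$sim$max_horizon, x$sim$n_replicates))
  invisible(x)
}
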