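#' Partition acquired energy among life functions
#'
#' Multiplies the day's ME by the four partition coefficients.  The
#' partition is exactly conservative: the four energies sum to the energy
#' acquired (neutral balance between acquisition and allocation).
#'
#' @param me ME acquired (MJ/day).
#' @param alloc Named vector `c(alloc_g, alloc_s, alloc_pf, alloc_pc)`.
#' @return Named vector `c(e_growth, e_somatic, e_gest, e_lact)` (MJ/day).
#' @export
partition_energy <- function(me, alloc) {
  c(
    e_growth  = me * alloc[["alloc_g"]],
    e_somatic = me * alloc[["alloc_s"]],
    e_gest    = me * alloc[["alloc_pf"]],
    e_lact    = me * alloc[["alloc_pc"]]
  )
}

#' Maintenance energy requirement
#'
#' Metabolic-mass scaling of maintenance: `coeff * mass^exponent`, with
#' the gravid uterus included in the mass.
#'
#' @param mass Total body mass (kg): structural + labile + gravid uterus.
#' @param coeff MJ per kg^`exponent` per day.
#' @param exponent Metabolic mass exponent (default 0.75).
#' @return Requirement (MJ/day).
#' @export
maintenance_requirement <- function(mass, coeff = 0.60, exponent = 0.75) {
  coeff * mass^exponent
}

#' Somatic energy bookkeeping for one day
#'
#' Somatic energy first pays maintenance; any surplus is deposited as
#' labile mass (body reserves) at the repletion efficiency, and any
#' deficit is covered by mobilizing labile mass at the mobilization
#' efficiency, limited by the available reserves and a daily cap.  The
#' day is flagged as a deficit day when maintenance remains uncovered
#' after mobilization.
#'
#' @param e_somatic Somatic energy for the day (MJ).
#' @param maint Maintenance requirement (MJ).
#' @param labile_mass Current labile mass (kg).
#' @param fixed Fixed-parameter list (uses `k_repletion`,
#'   `labile_tissue_energy`, `k_mobilization`, `mobilization_cap`).
#' @return List with `labile_mass` (updated, kg), `e_repletion` (MJ
#'   deposited), `e_mobilized` (MJ of ME-equivalent supplied by
#'   mobilization) and `deficit` (logical flag).
#' @export
somatic_update <- function(e_somatic, maint, labile_mass, fixed) {
  surplus <- e_somatic - maint
  e_repletion <- 0
  e_mobilized <- 0
  deficit <- FALSE
  if (surplus >= 0) {
    e_repletion <- surplus
    labile_mass <- labile_mass +
      surplus * fixed$k_repletion / fixed$labile_tissue_energy
  } else {
    yield <- fixed$labile_tissue_energy * fixed$k_mobilization # MJ per kg
    avail <- min(labile_mass, fixed$mobilization_cap) * yield
    e_mobilized <- min(-surplus, avail)
    labile_mass <- labile_mass - e_mobilized / yield
    deficit <- (e_mobilized < -surplus - 1e-9)
  }
  list(labile_mass = labile_mass, e_repletion = e_repletion,
       e_mobilized = e_mobilized, deficit = deficit)
}

#' Convert growth energy to structural mass
#'
#' @param e_growth Growth energy (MJ/day).
#' @param structural_mass Current structural mass (kg).
#' @param k_growth Conversion efficiency.
#' @param tissue_energy Energy content of structural tissue (MJ/kg).
#' @return Updated structural mass (kg); never decreases.
#' @export
grow_structural <- function(e_growth, structural_mass, k_growth = 0.70,
                            tissue_energy = 15.5) {
  structural_mass + e_growth * k_growth / tissue_energy
}

#' Convert gestation energy to gravid uterus mass
#'
#' @param e_gest Gestation energy (MJ/day).
#' @param uterus_mass Current gravid uterus mass (kg).
#' @param k_gest Conversion efficiency.
#' @param tissue_energy Energy content of gravid uterus tissue (MJ/kg).
#' @return Updated gravid uterus mass (kg); reset to 0 by the engine at
#'   parturition.
#' @export
gestation_update <- function(e_gest, uterus_mass, k_gest = 0.14,
                             tissue_energy = 6.0) {
  uterus_mass + e_gest * k_gest / tissue_energy
}

#' Convert lactation energy to milk
#'
#' @param e_lact ME allocated to lactation (MJ/day).
#' @param k_lact Conversion efficiency of that energy to milk energy.
#' @param milk_energy_density Energy content of milk (MJ/kg).
#' @return Named vector `c(milk_energy, milk_yield)` (MJ/day, kg/day).
#' @export
milk_from_energy <- function(e_lact, k_lact = 0.62, milk_energy_density = 3.1) {
  milk_energy <- e_lact * k_lact
  c(milk_energy = milk_energy, milk_yield = milk_energy / milk_energy_density)
}

#' Body condition score
#'
#' Monotone mapping of the reserve ratio (labile over structural mass)
#' onto the 0-5 body condition scale, anchored so that the reference
#' ratio scores 3.0, and clamped to the scale.
#'
#' @param labile_mass,structural_mass Body masses (kg).
#' @param ref_ratio Labile/structural ratio scored as 3.0.
#' @return Score in \[0, 5\].
#' @export
body_condition <- function(labile_mass, structural_mass, ref_ratio = 0.30) {
  ratio <- ifelse(structural_mass > 0, labile_mass / structural_mass, 0)
  pmin(5, pmax(0, 3 * ratio / ref_ratio))
}

#' Daily probability of conception
#'
#' Logistic model of the probability that an insemination results in
#' conception, decreasing in milk yield and increasing in body condition
#' and in the smoothed energy balance.
#'
#' @param milk_yield Milk yield (kg/day).
#' @param bcs Body condition score (0-5).
#' @param energy_balance Smoothed energy balance (MJ/day).
#' @param b0 Logit intercept (probability at zero milk, BCS 3, balance 0).
#' @param b_milk,b_bcs,b_eb Logit slopes.
#' @return Probability in \[0, 1\].
#' @export
conception_probability <- function(milk_yield, bcs, energy_balance,
                                   b0 = -0.20, b_milk = -0.035,
                                   b_bcs = 0.15, b_eb = 0.004) {
  plogis(b0 + b_milk * milk_yield + b_bcs * (bcs - 3) + b_eb * energy_balance)
}

#' Survival check against the consecutive-deficit rule
#'
#' Survival probability becomes null when the animal has been unable to
#' cover its maintenance requirement for `threshold_days` consecutive
#' days; survival is deterministic given the deficit counter.
#'
#' @param consecutive_deficit_days Current run length of deficit days.
#' @param threshold_days Lethal run length (default 15).
#' @return `TRUE` if alive.
#' @export
survival_check <- function(consecutive_deficit_days, threshold_days = 15) {
  consecutive_deficit_days < threshold_days
}
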