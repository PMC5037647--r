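#' Basal dry-matter acquisition
#'
#' Maturation curve of basal intake: a monotone rise from a fixed
#' immature fraction of the genetic asymptote at birth towards the
#' asymptote `acqb_gen`, the maximum intake of a mature non-lactating
#' animal.  Intake is deliberately not scaled by body weight, so that
#' acquisition and growth allocation remain genetically independent.
#'
#' @param age Age in days.
#' @param acqb_gen Asymptotic basal intake at maturity (kg DM/day).
#' @param k_acqb_mat Maturation rate (per day).
#' @param immature_frac Fraction of the asymptote missing at birth
#'   (default 0.8, i.e. a newborn acquires 20% of the mature level).
#' @return Basal intake (kg DM/day).
#' @export
basal_acquisition <- function(age, acqb_gen, k_acqb_mat, immature_frac = 0.8) {
  acqb_gen * (1 - immature_frac * exp(-k_acqb_mat * age))
}

#' Mature ceiling of lactation-induced acquisition
#'
#' Maximum extra intake inducible by lactation at a given age; matures
#' with age towards the genetic asymptote `acql_gen` in the same
#' exponential form as basal intake.
#'
#' @param age Age in days.
#' @param acql_gen Asymptotic lactation intake increment at maturity
#'   (kg DM/day).
#' @param k_acql_mat Maturation rate (per day).
#' @param immature_frac Fraction of the asymptote missing at birth.
#' @return Ceiling of the lactation intake increment (kg DM/day).
#' @export
lactation_max <- function(age, acql_gen, k_acql_mat, immature_frac = 0.6) {
  acql_gen * (1 - immature_frac * exp(-k_acql_mat * age))
}

#' Within-lactation intake dynamics
#'
#' Dimensionless shape of the lactation-induced intake over days in milk:
#' `(1 - exp(-a d)) * exp(-b d)` normalized to a unit maximum, i.e. a
#' rapid rise from zero at calving to a peak (near eight weeks under the
#' default rates) followed by a slow decline.  The peak location has the
#' closed form `log((a + b) / b) / a`.
#'
#' @param dim Days in milk (0 at calving).
#' @param a Rise rate (per day).
#' @param b Decline rate (per day).
#' @return Value in \[0, 1\].
#' @export
lactation_dyn <- function(dim, a = 0.060, b = 0.0020) {
  peak <- log((a + b) / b) / a
  norm <- (1 - exp(-a * peak)) * exp(-b * peak)
  (1 - exp(-a * dim)) * exp(-b * dim) / norm
}

#' Total daily dry-matter intake
#'
#' Basal component plus the lactation component, the latter gated by
#' lactating status.
#'
#' @param acq_b Basal intake (kg DM/day).
#' @param acql_max Mature ceiling of the lactation increment (kg DM/day).
#' @param acql_dyn Within-lactation dynamics in \[0, 1\].
#' @param lac_stat Logical lactating status.
#' @return Total intake (kg DM/day).
#' @export
total_intake <- function(acq_b, acql_max, acql_dyn, lac_stat) {
  acq_b + as.numeric(lac_stat) * acql_max * acql_dyn
}

#' Diet metabolizability (ME as a fraction of GE)
#'
#' Linear adjustment of a baseline metabolizability for the proportion of
#' concentrate in the diet (raising it) and for the feeding level above
#' maintenance (depressing it, reflecting faster passage at high intake),
#' clamped to a plausible range.  Captures the energy losses in faeces,
#' urine and enteric methane during digestion.
#'
#' @param feeding_level Ratio of ME intake to maintenance ME requirement
#'   (1 = fed at maintenance).
#' @param co_res Concentrate proportion of the diet in \[0, 1\].
#' @param q0 Baseline metabolizability at maintenance with no concentrate.
#' @param q_co Gain per unit concentrate proportion.
#' @param q_fl Depression per unit feeding level above 1.
#' @param q_min,q_max Clamp bounds.
#' @return Metabolizability fraction.
#' @export
metabolizability <- function(feeding_level, co_res, q0 = 0.60, q_co = 0.05,
                             q_fl = 0.02, q_min = 0.35, q_max = 0.75) {
  pmin(q_max, pmax(q_min, q0 + q_co * co_res - q_fl * (feeding_level - 1)))
}

#' Metabolizable energy acquired
#'
#' Converts total dry-matter intake to ME given the gross energy density
#' of the resource (in Mcal/kg DM, converted at 4.184 MJ/Mcal) and the
#' diet metabolizability.
#'
#' @param acq_t Total intake (kg DM/day).
#' @param ge_res Resource gross energy density (Mcal/kg DM).
#' @param q Metabolizability (ME/GE fraction).
#' @return ME acquired (MJ/day).
#' @export
me_acquired <- function(acq_t, ge_res, q) {
  acq_t * ge_res * MCAL_TO_MJ * q
}
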