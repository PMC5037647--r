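#' Feed efficiency
#'
#' Ratio of cumulative energy for milk production to cumulative energy
#' acquired, as a percentage.  Defined as 0 when no energy was acquired.
#'
#' @param e_milk Cumulative energy for milk production (MJ).
#' @param e_acq Cumulative ME acquired (MJ).
#' @return Feed efficiency (%).
#' @export
feed_efficiency <- function(e_milk, e_acq) {
  if (any(e_milk < 0) || any(e_acq < 0)) {
    abort("feed_efficiency: energies must be non-negative")
  }
  ifelse(e_acq > 0, 100 * e_milk / e_acq, 0)
}

#' Window of one lactation
#'
#' Closed-open day interval from the parturition of the given parity to
#' the following drying-off.  A female that terminated mid-lactation gets
#' a window ending at her terminal day, flagged incomplete (such cows are
#' excluded from lactation-level marginal statistics); a female that
#' never reached the parity is flagged missing.
#'
#' @param events Event log tibble (columns `day`, `event`, `parity`).
#' @param parity Which lactation (default 2, the reference lactation).
#' @return List with `start`, `end` (days), `complete` and `missing`
#'   logicals.
#' @export
lactation_window <- function(events, parity = 2) {
  part <- events$day[events$event == "PARTURITION" & events$parity == parity]
  if (length(part) == 0) {
    return(list(start = NA_real_, end = NA_real_, complete = FALSE, missing = TRUE))
  }
  start <- part[[1]]
  dries <- events$day[events$event == "DRYING_OFF" & events$day > start]
  if (length(dries) > 0) {
    list(start = start, end = dries[[1]], complete = TRUE, missing = FALSE)
  } else {
    list(start = start, end = max(events$day) + 1, complete = FALSE, missing = FALSE)
  }
}

#' Summarize a lifetime trajectory
#'
#' Computes the life-summary battery from a daily trajectory and its
#' event log: lifetime and second-lactation feed efficiencies, cumulative
#' energies, lifetime energy balance, maintenance and mobilization shares,
#' longevity, productive longevity, lactation count, final structural
#' mass, labile mass at drying, and reproductive timings.
#'
#' Conventions: the energy for milk production is the ME allocated to the
#' lactation function; the lifetime energy balance is cumulative reserve
#' repletion minus cumulative mobilization; total energy use is ME
#' acquired plus energy supplied by mobilization; productive longevity is
#' the productive (lactating) time of the life, i.e. cumulative days in
#' milk.  Second-lactation
#' quantities are `NA` unless the second lactation ended in a drying-off.
#'
#' @param trajectory Daily trajectory tibble from [simulate_cow()].
#' @param events Event log tibble.
#' @param terminal Terminal cause (`"DIED"`, `"CULLED"` or `"HORIZON"`).
#' @param censored Logical: lifetime truncated by the simulation horizon.
#' @return A one-row tibble.
#' @export
summarize_life <- function(trajectory, events, terminal = "HORIZON",
                           censored = FALSE) {
  tr <- trajectory
  n_days <- nrow(tr)
  e_acq_life <- sum(tr$me_acquired)
  e_milk_life <- sum(tr$e_lact)
  e_grow_life <- sum(tr$e_growth)
  e_repl_life <- sum(tr$e_repletion)
  e_mob_life <- sum(tr$e_mobilized)
  # maintenance actually paid: somatic energy not banked, plus mobilization
  e_maint_life <- sum(tr$e_somatic) - e_repl_life + e_mob_life
  e_use_life <- e_acq_life + e_mob_life

  parts <- events[events$event == "PARTURITION", ]
  dries <- events[events$event == "DRYING_OFF", ]
  n_lact <- nrow(parts)
  first_part <- if (n_lact >= 1) parts$day[[1]] else NA_real_

  w2 <- lactation_window(events, parity = 2)
  if (isTRUE(w2$complete)) {
    in2 <- tr$day >= w2$start & tr$day < w2$end
    e_acq_lac2 <- sum(tr$me_acquired[in2])
    e_milk_lac2 <- sum(tr$e_lact[in2])
    e_grow_lac2 <- sum(tr$e_growth[in2])
    e_mob_lac2 <- sum(tr$e_mobilized[in2])
    e_use_lac2 <- e_acq_lac2 + e_mob_lac2
    fe_lac2 <- feed_efficiency(e_milk_lac2, e_acq_lac2)
    e_mob_pct_lac2 <- 100 * e_mob_lac2 / e_use_lac2
    labile_drying2 <- tr$labile_mass[tr$day == w2$end]
  } else {
    e_acq_lac2 <- e_milk_lac2 <- e_grow_lac2 <- NA_real_
    fe_lac2 <- e_mob_pct_lac2 <- labile_drying2 <- NA_real_
  }

  labile_at_drying <- tr$labile_mass[match(dries$day, tr$day)]
  age_part2 <- if (n_lact >= 2) parts$day[[2]] else NA_real_
  interval_23 <- if (n_lact >= 3) parts$day[[3]] - parts$day[[2]] else NA_real_

  tibble(
    fe_life = feed_efficiency(e_milk_life, e_acq_life),
    fe_lac2 = fe_lac2,
    e_acq_life = e_acq_life,
    e_milk_life = e_milk_life,
    e_acq_lac2 = e_acq_lac2,
    e_milk_lac2 = e_milk_lac2,
    e_grow_life = e_grow_life,
    e_grow_lac2 = e_grow_lac2,
    e_balance_life = e_repl_life - e_mob_life,
    e_maintenance_pct = 100 * e_maint_life / e_use_life,
    e_mobilized_pct_life = 100 * e_mob_life / e_use_life,
    e_mobilized_pct_lac2 = e_mob_pct_lac2,
    longevity = n_days / 365,
    productive_longevity = sum(tr$lac_stat) / 365,
    n_lactations = n_lact,
    structural_mass_final = tr$structural_mass[[n_days]],
    labile_mass_at_drying2 = labile_drying2,
    mean_labile_mass_at_drying =
      if (nrow(dries) > 0) mean(labile_at_drying) else NA_real_,
    age_at_parturition2 = age_part2,
    interval_part2_part3 = interval_23,
    e_milk_per_lactation = ifelse(n_lact > 0, e_milk_life / n_lact, 0),
    terminal = terminal,
    censored = censored
  )
}
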