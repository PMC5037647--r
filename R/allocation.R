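#' Priority flow from growth to survival
#'
#' Daily rate at which priority leaves the growth compartment for the
#' survival (somatic) compartment.  The rate is mass-action in the growth
#' coefficient, scaled by the genetic parameter, plus an acceleration
#' proportional to the gestation coefficient: once gestation builds up,
#' the decline of growth priority speeds up (gestation slows growth).
#' The gestation term is smoothly tapered as the growth compartment
#' empties so that the flow cannot drive the coefficient negative.
#'
#' @param alloc_g,alloc_pf Partition coefficients for growth and gestation.
#' @param g2s_gen Genetic-scaling rate (per day) of the growth-to-survival
#'   transfer.
#' @param c_growth_gest Gestation acceleration coefficient (default 0.01).
#' @return Transfer rate (per day).
#' @export
flow_g2s <- function(alloc_g, alloc_pf, g2s_gen, c_growth_gest = 0.01) {
  alloc_g * g2s_gen + c_growth_gest * alloc_pf * (alloc_g / (alloc_g + 1e-3))
}

#' Priority flow from survival to future progeny (gestation)
#'
#' A rising four-parameter logistic in days of gestation,
#' `kh_pf0 + kh_pf1 / (1 + exp(-kh_pf2 * (t_gest - kh_pf3)))`, gated to
#' zero outside gestation.  There is no genetic variance in this flow.
#'
#' @param t_gest Days since conception.
#' @param gest_stat Logical gestation status.
#' @param kh_pf0,kh_pf1,kh_pf2,kh_pf3 Sigmoid baseline, amplitude,
#'   steepness and midpoint.
#' @return Transfer rate (per day).
#' @export
flow_s2pf <- function(t_gest, gest_stat, kh_pf0, kh_pf1, kh_pf2, kh_pf3) {
  ifelse(gest_stat, kh_pf0 + kh_pf1 / (1 + exp(-kh_pf2 * (t_gest - kh_pf3))), 0)
}

#' Priority flow from survival to current progeny (lactation build-up)
#'
#' Mass-action transfer from the survival compartment into the lactation
#' compartment at the fixed rate `s2pc`, gated by lactating status.  The
#' default reading is linear in the survival coefficient; setting
#' `quadratic = TRUE` uses the squared coefficient instead.
#'
#' @param alloc_s Survival partition coefficient.
#' @param s2pc Fixed transfer rate (per day).
#' @param lac_stat Logical lactating status.
#' @param quadratic Use the `alloc_s^2` form.
#' @return Transfer rate (per day).
#' @export
flow_s2pc <- function(alloc_s, s2pc, lac_stat, quadratic = FALSE) {
  src <- if (quadratic) alloc_s^2 else alloc_s
  ifelse(lac_stat, src * s2pc, 0)
}

#' Priority flow from current progeny back to survival (lactation decline)
#'
#' Mass-action decay of the lactation coefficient at the genetic rate
#' `pc2s_gen`, accelerated during concurrent gestation in proportion to
#' the gestation coefficient (the depressive effect of gestation on
#' lactation).  Gated by lactating status.
#'
#' @param alloc_pc,alloc_pf Partition coefficients for lactation and
#'   gestation.
#' @param pc2s_gen Genetic-scaling rate (per day).
#' @param lac_stat,gest_stat Logical statuses.
#' @param c_lact_gest Gestation depression coefficient (default 0.06).
#' @return Transfer rate (per day).
#' @export
flow_pc2s <- function(alloc_pc, alloc_pf, pc2s_gen, lac_stat, gest_stat,
                      c_lact_gest = 0.06) {
  ifelse(lac_stat, alloc_pc * (pc2s_gen + alloc_pf * as.numeric(gest_stat) * c_lact_gest), 0)
}

#' Derivatives of the four allocation compartments
#'
#' Assembles the compartment derivatives from the four priority flows.
#' The flows move a conserved dimensionless quantity of one around the
#' compartment network, so the four derivatives sum to zero exactly.
#'
#' @param flows Named numeric vector or list with elements `f_g2s`,
#'   `f_s2pf`, `f_s2pc`, `f_pc2s` (per day).
#' @return Named numeric vector `c(alloc_g, alloc_s, alloc_pf, alloc_pc)`
#'   of derivatives.
#' @export
allocation_derivatives <- function(flows) {
  f_g2s <- flows[["f_g2s"]]; f_s2pf <- flows[["f_s2pf"]]
  f_s2pc <- flows[["f_s2pc"]]; f_pc2s <- flows[["f_pc2s"]]
  c(
    alloc_g  = -f_g2s,
    alloc_s  = f_g2s - f_s2pf - f_s2pc + f_pc2s,
    alloc_pf = f_s2pf,
    alloc_pc = f_s2pc - f_pc2s
  )
}

# Derivative of the allocation state at intra-day offset tau (days).
# Statuses are frozen over the day; gestation time advances with tau.
# Used by both the RK4 stepper and the reference fine-step integrators.
.alloc_deriv <- function(y, tau, t_gest, lac_stat, gest_stat, genetics, fixed) {
  f <- c(
    f_g2s = flow_g2s(y[[1]], y[[3]], genetics$g2s_gen, fixed$c_growth_gest),
    f_s2pf = flow_s2pf(t_gest + tau, gest_stat, fixed$kh_pf0, fixed$kh_pf1,
                       fixed$kh_pf2, fixed$kh_pf3),
    f_s2pc = flow_s2pc(y[[2]], fixed$s2pc, lac_stat, fixed$s2pc_quadratic),
    f_pc2s = flow_pc2s(y[[4]], y[[3]], genetics$pc2s_gen, lac_stat, gest_stat,
                       fixed$c_lact_gest)
  )
  allocation_derivatives(f)
}

#' One fixed-step fourth-order Runge-Kutta step
#'
#' Advances a state vector by one step of size `dt` under a derivative
#' function `deriv(y, tau)` evaluated at intra-step offsets 0, dt/2 and
#' dt.  Components that undershoot zero by less than `1e-9` (a numerical
#' artefact of gated flows) are clamped to zero; a larger undershoot
#' raises an error carrying the offending state.
#'
#' @param y Numeric state vector.
#' @param deriv Function of `(y, tau)` returning the derivative vector.
#' @param dt Step size in days (default 1).
#' @return Updated state vector.
#' @export
rk4_step <- function(y, deriv, dt = 1) {
  k1 <- deriv(y, 0)
  k2 <- deriv(y + dt / 2 * k1, dt / 2)
  k3 <- deriv(y + dt / 2 * k2, dt / 2)
  k4 <- deriv(y + dt * k3, dt)
  if (!all(is.finite(k1)) || !all(is.finite(k4))) {
    abort("numerical error: non-finite derivative in rk4_step")
  }
  out <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  neg <- out < 0
  if (any(neg)) {
    if (any(out < -1e-9)) {
      abort(sprintf(
        "numerical error: allocation coefficient undershoot beyond tolerance (state: %s)",
        paste(signif(out, 6), collapse = ", ")
      ))
    }
    out[neg] <- 0
  }
  out
}

#' Discrete priority shift at a physiological event
#'
#' At parturition the female's priority switches from future progeny to
#' current progeny: the whole gestation priority is transferred into the
#' lactation compartment, from which lactation further builds through the
#' survival-to-current-progeny flow.  At drying-off the whole lactation
#' priority is returned to survival (no more energy invested in
#' lactation).  The coefficient sum is preserved exactly.
#'
#' @param alloc Named numeric vector `c(alloc_g, alloc_s, alloc_pf,
#'   alloc_pc)`.
#' @param event One of `"PARTURITION"`, `"DRYING_OFF"`.
#' @return Shifted allocation vector.
#' @export
apply_event_shift <- function(alloc, event) {
  if (event == "PARTURITION") {
    alloc[["alloc_pc"]] <- alloc[["alloc_pc"]] + alloc[["alloc_pf"]]
    alloc[["alloc_pf"]] <- 0
  } else if (event == "DRYING_OFF") {
    alloc[["alloc_s"]] <- alloc[["alloc_s"]] + alloc[["alloc_pc"]]
    alloc[["alloc_pc"]] <- 0
  } else {
    abort(sprintf("unknown event tag '%s'", event))
  }
  alloc
}

#' Integrate the allocation system alone over a status schedule
#'
#' Utility integrator for studying the allocation sub-model in isolation:
#' advances the four partition coefficients day by day under externally
#' prescribed lactation/gestation schedules, without the rest of the
#' energy budget.  Mainly used for property checks and illustration.
#'
#' @param days Number of daily steps.
#' @param params A `cow_params` bundle.
#' @param lac_stat,gest_stat Logical vectors of length `days` (recycled)
#'   giving the prescribed statuses for each day.
#' @param t_gest0 Gestation day at the start of the first gestating day.
#' @param method `"rk4"` (daily step) or `"euler"` with sub-step `dt`.
#' @param dt Sub-step for the Euler reference integrator.
#' @return A tibble with one row per day (day 0 = initial state).
#' @export
integrate_allocation <- function(days, params = default_params(),
                                 lac_stat = FALSE, gest_stat = FALSE,
                                 t_gest0 = 0, method = c("rk4", "euler"),
                                 dt = 0.01) {
  method <- match.arg(method)
  lac_stat <- rep_len(lac_stat, days)
  gest_stat <- rep_len(gest_stat, days)
  fixed <- params$fixed
  genetics <- params$genetics
  y <- c(alloc_g = fixed$alloc_g_birth, alloc_s = 1 - fixed$alloc_g_birth,
         alloc_pf = 0, alloc_pc = 0)
  out <- matrix(NA_real_, nrow = days + 1, ncol = 4,
                dimnames = list(NULL, names(y)))
  out[1, ] <- y
  t_gest <- t_gest0
  for (i in seq_len(days)) {
    deriv <- function(yy, tau) {
      .alloc_deriv(yy, tau, t_gest, lac_stat[i], gest_stat[i], genetics, fixed)
    }
    if (method == "rk4") {
      y <- rk4_step(y, deriv, dt = 1)
    } else {
      nsub <- round(1 / dt)
      for (s in seq_len(nsub)) y <- y + dt * deriv(y, (s - 1) * dt)
      y[y < 0 & y > -1e-9] <- 0
    }
    if (gest_stat[i]) t_gest <- t_gest + 1
    out[i + 1, ] <- y
  }
  out <- as_tibble(out)
  out$day <- 0:days
  out[, c("day", names(y))]
}
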