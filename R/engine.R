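#' Simulate one cow from birth to death, culling or the horizon
#'
#' Runs the daily loop wiring the four sub-models: (1) dry-matter
#' acquisition and its conversion to ME, (2) allocation coefficients
#' advanced by a daily fourth-order Runge-Kutta step under the start-of-day
#' physiological statuses, (3) partition of ME and its utilization into
#' body masses and milk, (4) phenotypes (body condition, energy balance,
#' conception probability), (5) discrete events (insemination, conception,
#' parturition, drying-off, culling, death).  Status changes triggered by
#' an event become effective at the next time step; discrete priority
#' shifts are applied at the end of the day the event fires.  A female
#' eligible for culling (parity at least 2, days open past the threshold,
#' not pregnant) finishes her running lactation and is culled once dry,
#' so lactation-level metrics remain defined for culled cows.
#'
#' Conception is the only stochastic element: each insemination is a
#' Bernoulli draw from R's random stream, seeded by `seed`, so a given
#' `(params, seed)` pair reproduces the trajectory and event log exactly.
#'
#' @param params A validated `cow_params` bundle (see [default_params()]).
#' @param seed Integer seed for the conception draws.
#' @param record Keep the daily trajectory (set `FALSE` in large
#'   experiments to return the life summary only).
#' @return An object of class `cow_life`: a list with `summary` (one-row
#'   tibble, see [summarize_life()]), `events` (tibble: day, event,
#'   parity, days_open), `trajectory` (tibble with one row per day, or
#'   `NULL`), and `seed`.
#' @examples
#' life <- simulate_cow(seed = 42)
#' glance(life)$n_lactations
#' @export
simulate_cow <- function(params = default_params(), seed = 1L, record = TRUE) {
  validate_params(params)
  set.seed(seed)
  fx <- params$fixed
  gn <- params$genetics
  ev <- params$env

  ## unpack scalars for the inner loop
  g2s <- gn$g2s_gen; pc2s <- gn$pc2s_gen
  acqb_gen <- gn$acqb_gen; acql_gen <- gn$acql_gen
  c_gg <- fx$c_growth_gest; c_lg <- fx$c_lact_gest
  s2pc <- fx$s2pc; s2pc_quad <- isTRUE(fx$s2pc_quadratic)
  kh0 <- fx$kh_pf0; kh1 <- fx$kh_pf1; kh2 <- fx$kh_pf2; kh3 <- fx$kh_pf3
  k_bmat <- fx$k_acqb_mat; bfrac <- fx$acqb_immature_frac
  k_lmat <- fx$k_acql_mat; lfrac <- fx$acql_immature_frac
  dyn_a <- fx$acql_dyn_a; dyn_b <- fx$acql_dyn_b
  dyn_peak <- log((dyn_a + dyn_b) / dyn_b) / dyn_a
  dyn_norm <- (1 - exp(-dyn_a * dyn_peak)) * exp(-dyn_b * dyn_peak)
  q0 <- fx$q0; q_co <- fx$q_co; q_fl <- fx$q_fl
  q_min <- fx$q_min; q_max <- fx$q_max
  ge_mj <- ev$ge_res * MCAL_TO_MJ; co_res <- ev$co_res
  m_coeff <- fx$maint_coeff; m_exp <- fx$maint_exp
  k_gro <- fx$k_growth / fx$growth_tissue_energy       # kg per MJ
  k_ute <- fx$k_gest / fx$gest_tissue_energy           # kg per MJ
  k_lac <- fx$k_lact; rho_milk <- fx$milk_energy_density
  k_rep <- fx$k_repletion / fx$labile_tissue_energy    # kg per MJ
  mob_yield <- fx$labile_tissue_energy * fx$k_mobilization # MJ per kg
  mob_cap <- fx$mobilization_cap
  ref_ratio <- fx$bcs_ref_ratio
  b0 <- fx$conc_b0; b_milk <- fx$conc_b_milk
  b_bcs <- fx$conc_b_bcs; b_eb <- fx$conc_b_eb
  ebw <- as.integer(fx$eb_window)
  gest_len <- fx$gestation_length; dry_len <- fx$dry_period
  vwp <- fx$voluntary_waiting; cyc <- fx$cycle_length
  fba <- fx$first_breeding_age; max_dim <- fx$max_lactation_length
  cull_open <- fx$culling_days_open; death_run <- fx$death_deficit_days
  horizon <- params$sim$max_horizon

  ## state at birth
  alloc <- c(fx$alloc_g_birth, 1 - fx$alloc_g_birth, 0, 0) # G, S, Pf, Pc
  structural <- fx$structural_mass_birth
  labile <- fx$labile_mass_birth
  uterus <- 0
  lac <- FALSE; gest <- FALSE
  lac_next <- FALSE; gest_next <- FALSE
  parity <- 0L; dog <- 0L; dim <- 0L; dsc <- 0L
  deficit_run <- 0L
  fl_prev <- 1
  eb_buf <- numeric(ebw); eb_n <- 0L; eb_i <- 0L

  cols <- c("day", "alloc_g", "alloc_s", "alloc_pf", "alloc_pc",
            "acq_b", "acq_l", "acq_t", "q_me", "me_acquired",
            "e_growth", "e_somatic", "e_gest", "e_lact",
            "maintenance", "e_repletion", "e_mobilized", "deficit",
            "structural_mass", "labile_mass", "uterus_mass",
            "milk_energy", "milk_yield", "bcs", "energy_balance", "p_conc",
            "lac_stat", "gest_stat", "parity", "days_in_milk", "days_open")
  traj <- matrix(0, nrow = horizon + 1L, ncol = length(cols),
                 dimnames = list(NULL, cols))
  ev_day <- integer(0); ev_tag <- character(0)
  ev_parity <- integer(0); ev_open <- integer(0)
  log_event <- function(day, tag) {
    ev_day[[length(ev_day) + 1L]] <<- day
    ev_tag[[length(ev_tag) + 1L]] <<- tag
    ev_parity[[length(ev_parity) + 1L]] <<- parity
    ev_open[[length(ev_open) + 1L]] <<- if (parity > 0L && !gest) dsc else 0L
  }

  terminal <- "HORIZON"
  t_end <- horizon

  for (t in 0:horizon) {
    if (t > 0L) {
      ## status changes from yesterday's events take effect now
      lac <- lac_next; gest <- gest_next
      if (gest) dog <- dog + 1L
      if (lac) dim <- dim + 1L
      if (parity > 0L) dsc <- dsc + 1L
    }

    ## (1) acquisition and ME
    acq_b <- acqb_gen * (1 - bfrac * exp(-k_bmat * t))
    if (lac) {
      acql_max <- acql_gen * (1 - lfrac * exp(-k_lmat * t))
      acq_l <- acql_max * (1 - exp(-dyn_a * dim)) * exp(-dyn_b * dim) / dyn_norm
    } else {
      acq_l <- 0
    }
    acq_t <- acq_b + acq_l
    q <- q0 + q_co * co_res - q_fl * (fl_prev - 1)
    q <- if (q < q_min) q_min else if (q > q_max) q_max else q
    me <- acq_t * ge_mj * q

    ## (2) allocation advanced by RK4 (statuses frozen over the day)
    lacn <- as.numeric(lac); gestn <- as.numeric(gest)
    drv <- function(y, tau) {
      f1 <- y[1L] * g2s + c_gg * y[3L] * (y[1L] / (y[1L] + 1e-3))
      f2 <- gestn * (kh0 + kh1 / (1 + exp(-kh2 * (dog + tau - kh3))))
      f3 <- lacn * s2pc * (if (s2pc_quad) y[2L]^2 else y[2L])
      f4 <- lacn * y[4L] * (pc2s + y[3L] * gestn * c_lg)
      c(-f1, f1 - f2 - f3 + f4, f2, f3 - f4)
    }
    k1 <- drv(alloc, 0)
    k2 <- drv(alloc + 0.5 * k1, 0.5)
    k3 <- drv(alloc + 0.5 * k2, 0.5)
    k4 <- drv(alloc + k3, 1)
    alloc <- alloc + (k1 + 2 * k2 + 2 * k3 + k4) / 6
    if (any(alloc < 0)) {
      if (any(alloc < -1e-9)) {
        abort(sprintf("simulation error at day %d: allocation undershoot (%s)",
                      t, paste(signif(alloc, 6), collapse = ", ")))
      }
      alloc[alloc < 0] <- 0
    }

    ## (3) energy partition and utilization
    e_growth <- me * alloc[1L]; e_somatic <- me * alloc[2L]
    e_gest <- me * alloc[3L]; e_lact <- me * alloc[4L]
    mass <- structural + labile + uterus
    maint <- m_coeff * mass^m_exp
    surplus <- e_somatic - maint
    if (surplus >= 0) {
      e_repletion <- surplus; e_mobilized <- 0
      labile <- labile + surplus * k_rep
      deficit <- FALSE
      deficit_run <- 0L
    } else {
      e_repletion <- 0
      avail <- (if (labile < mob_cap) labile else mob_cap) * mob_yield
      e_mobilized <- if (-surplus < avail) -surplus else avail
      labile <- labile - e_mobilized / mob_yield
      deficit <- e_mobilized < -surplus - 1e-9
      deficit_run <- if (deficit) deficit_run + 1L else 0L
    }
    structural <- structural + e_growth * k_gro
    if (gest) uterus <- uterus + e_gest * k_ute
    milk_energy <- e_lact * k_lac
    milk_yield <- milk_energy / rho_milk

    ## (4) phenotypes
    bcs <- 3 * (labile / structural) / ref_ratio
    bcs <- if (bcs < 0) 0 else if (bcs > 5) 5 else bcs
    eb_i <- eb_i %% ebw + 1L
    eb_buf[eb_i] <- e_repletion - e_mobilized
    if (eb_n < ebw) eb_n <- eb_n + 1L
    ebal <- sum(eb_buf[seq_len(eb_n)]) / eb_n
    p_conc <- plogis(b0 + b_milk * milk_yield + b_bcs * (bcs - 3) + b_eb * ebal)
    fl_prev <- me / maint

    traj[t + 1L, ] <- c(t, alloc, acq_b, acq_l, acq_t, q, me,
                        e_growth, e_somatic, e_gest, e_lact,
                        maint, e_repletion, e_mobilized, as.numeric(deficit),
                        structural, labile, uterus, milk_energy, milk_yield,
                        bcs, ebal, p_conc, lacn, gestn, parity, dim, dsc)

    ## (5) events; statuses flip at the next time step
    conceived_today <- FALSE
    if (!gest) {
      service <- if (parity == 0L) {
        t >= fba && (t - fba) %% cyc == 0
      } else {
        # the conception window closes at the culling threshold for
        # females in parity >= 2: conceiving later would not avert culling
        dsc >= vwp && (dsc - vwp) %% cyc == 0 &&
          (parity < 2L || dsc < cull_open)
      }
      if (service) {
        if (parity == 0L && t == fba) log_event(t, "FIRST_BREEDING_ELIGIBLE")
        log_event(t, "INSEMINATION")
        if (runif(1) < p_conc) {
          conceived_today <- TRUE
          gest_next <- TRUE
          dog <- 0L
          log_event(t, "CONCEPTION")
        }
      }
    }
    if (gest && dog == gest_len) {
      parity <- parity + 1L
      uterus <- 0
      alloc[4L] <- alloc[4L] + alloc[3L]; alloc[3L] <- 0
      gest_next <- FALSE; lac_next <- TRUE
      dog <- 0L; dim <- -1L; dsc <- 0L
      log_event(t, "PARTURITION")
    }
    if (lac && ((gest && gest_len - dog == dry_len && !conceived_today) ||
                (!gest && !conceived_today && dim >= max_dim))) {
      alloc[2L] <- alloc[2L] + alloc[4L]; alloc[4L] <- 0
      lac_next <- FALSE
      log_event(t, "DRYING_OFF")
    }
    if (deficit_run >= death_run) {
      log_event(t, "DIED")
      terminal <- "DIED"; t_end <- t
      break
    }
    if (!gest && !lac && !conceived_today && parity >= 2L && dsc >= cull_open) {
      log_event(t, "CULLED")
      terminal <- "CULLED"; t_end <- t
      break
    }
  }

  traj <- as_tibble(traj[seq_len(t_end + 1L), , drop = FALSE])
  events <- tibble(
    day = ev_day, event = ev_tag, parity = ev_parity, days_open = ev_open
  )
  summary <- summarize_life(traj, events, terminal = terminal,
                            censored = terminal == "HORIZON")
  structure(
    list(
      summary = summary,
      events = events,
      trajectory = if (record) traj else NULL,
      seed = seed,
      params = params
    ),
    class = "cow_life"
  )
}

#' Run replicate lifetimes of one genotype
#'
#' Repeats [simulate_cow()] under distinct recorded seeds derived from a
#' base seed, returning one life-summary row per replicate.  Replicates
#' differ only through the stochastic conception draws.
#'
#' @param params A validated `cow_params` bundle.
#' @param n Number of replicates (the study condition is 20).
#' @param base_seed Base integer seed.
#' @param point_id Integer tag mixed into the per-replicate seed (used by
#'   [run_design()] to give every design point its own stream).
#' @return A tibble with `n` rows: `replicate`, `seed`, then the
#'   [summarize_life()] columns.
#' @export
run_replicates <- function(params = default_params(), n = 20, base_seed = 1L,
                           point_id = 0L) {
  stopifnot(n >= 1)
  purrr::map_dfr(seq_len(n), function(r) {
    seed <- replicate_seed(base_seed, point_id, r)
    life <- simulate_cow(params, seed = seed, record = FALSE)
    dplyr::bind_cols(tibble(replicate = r, seed = seed), life$summary)
  })
}

#' Deterministic per-replicate seed
#'
#' Mixes a base seed with a design-point id and replicate index into a
#' distinct 31-bit seed, so that every (design point, replicate) pair has
#' its own reproducible conception stream.
#'
#' @param base_seed,point_id,replicate Integers.
#' @return An integer seed in `[1, 2^31 - 1]`.
#' @export
replicate_seed <- function(base_seed, point_id, replicate) {
  as.integer((base_seed + 1000003 * point_id + 7919 * replicate) %% 2147483647 + 1)
}

#' @export
print.cow_life <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<cow_life> %s at %.1f years; %d lactation(s); FE_life %.1f%%, FE_lac2 %s\n",
    s$terminal, s$longevity, s$n_lactations, s$fe_life,
    ifelse(is.na(s$fe_lac2), "NA", sprintf("%.1f%%", s$fe_lac2))
  ))
  invisible(x)
}
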