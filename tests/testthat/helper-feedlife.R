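# shared fixtures: one recorded medium lifetime, reused across test files
medium_life <- simulate_cow(default_params(), seed = 101, record = TRUE)

# tiny hand-checkable trajectory + event log for metric oracles
toy_trajectory <- function() {
  tibble::tibble(
    day = 0:9,
    me_acquired = c(10, 10, 20, 20, 20, 20, 20, 20, 10, 10),
    e_growth    = c(2, 2, 1, 1, 1, 1, 1, 1, 0, 0),
    e_somatic   = c(8, 8, 9, 9, 9, 9, 9, 9, 10, 10),
    e_gest      = 0,
    e_lact      = c(0, 0, 10, 10, 10, 10, 10, 10, 0, 0),
    e_repletion = c(1, 1, 0, 0, 0, 0, 0, 0, 2, 2),
    e_mobilized = c(0, 0, 1, 1, 1, 1, 0, 0, 0, 0),
    structural_mass = seq(100, 109, 1),
    labile_mass = c(20, 21, 20, 19, 18, 17, 17, 17, 19, 21),
    lac_stat = c(0, 0, 1, 1, 1, 1, 1, 1, 0, 0),
    days_in_milk = c(0, 0, 0, 1, 2, 3, 4, 5, 0, 0)
  )
}

toy_events <- function() {
  tibble::tibble(
    day = c(1, 2, 8),
    event = c("PARTURITION", "PARTURITION", "DRYING_OFF"),
    parity = c(1L, 2L, 2L),
    days_open = 0L
  )
}
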