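#' Is an insemination scheduled today?
#'
#' Services start on the first eligible day (for a heifer, the first
#' breeding age; for a cow, the voluntary waiting period after calving)
#' and recur every oestrous cycle while the female is not pregnant.
#'
#' @param age Age (days).
#' @param parity Number of parturitions so far.
#' @param days_since_calving Days since the last parturition (ignored for
#'   heifers).
#' @param gest_stat Logical gestating status.
#' @param first_breeding_age,voluntary_waiting,cycle_length Schedule
#'   parameters (days).
#' @return Logical: insemination today.
#' @export
insemination_due <- function(age, parity, days_since_calving, gest_stat,
                             first_breeding_age = 450, voluntary_waiting = 50,
                             cycle_length = 21) {
  if (gest_stat) return(FALSE)
  if (parity == 0) {
    age >= first_breeding_age && (age - first_breeding_age) %% cycle_length == 0
  } else {
    days_since_calving >= voluntary_waiting &&
      (days_since_calving - voluntary_waiting) %% cycle_length == 0
  }
}

#' Stochastic conception at an insemination
#'
#' A single Bernoulli draw from R's seeded random stream.
#'
#' @param p_conc Conception probability in \[0, 1\].
#' @return Logical: conception occurred.
#' @export
conception_event <- function(p_conc) {
  stopifnot(p_conc >= 0, p_conc <= 1)
  runif(1) < p_conc
}

#' Culling rule on days open
#'
#' From the second lactation onwards, a female that has not conceived
#' within the threshold number of days after calving is culled.
#'
#' @param parity Number of parturitions.
#' @param days_open Days since calving without an established conception.
#' @param gest_stat Logical gestating status.
#' @param threshold Days-open threshold (default 200).
#' @return Logical: cull today.
#' @export
culling_check <- function(parity, days_open, gest_stat, threshold = 200) {
  !gest_stat && parity >= 2 && days_open >= threshold
}
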