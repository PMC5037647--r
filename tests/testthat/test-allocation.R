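test_that("priority flows reproduce their defining forms", {
  # growth -> survival: mass action plus gestation acceleration
  expect_equal(flow_g2s(1, 0, 0.005), 0.005)
  expect_equal(flow_g2s(0.5, 0.2, 0.004), 0.002 + 0.01 * 0.2 * (0.5 / 0.501))
  expect_equal(flow_g2s(0, 0.3, 0.01), 0) # tapered: empty compartment, no flow
  # survival -> current progeny, gated by lactation
  expect_equal(flow_s2pc(0.8, 0.1, lac_stat = TRUE), 0.08)
  expect_equal(flow_s2pc(0.8, 0.1, lac_stat = FALSE), 0)
  expect_equal(flow_s2pc(0, 0.1, lac_stat = TRUE), 0)
  expect_equal(flow_s2pc(0.8, 0.1, lac_stat = TRUE, quadratic = TRUE), 0.064)
  # current progeny -> survival with gestation depression
  expect_equal(flow_pc2s(0.6, 0, 0.01, lac_stat = FALSE, gest_stat = FALSE), 0)
  expect_equal(flow_pc2s(0.6, 0, 0.01, lac_stat = TRUE, gest_stat = FALSE), 0.006)
  expect_equal(flow_pc2s(0.6, 0.5, 0.01, lac_stat = TRUE, gest_stat = TRUE),
               0.6 * (0.01 + 0.5 * 0.06))
})

test_that("gestation flow is a gated rising sigmoid with closed-form midpoint", {
  expect_equal(flow_s2pf(150, FALSE, 0, 0.002, 0.03, 200), 0)
  tg <- seq(0, 282, by = 1)
  f <- flow_s2pf(tg, TRUE, 0, 0.002, 0.03, 200)
  expect_true(all(diff(f) >= 0))
  expect_lt(max(f), 0.002)
  expect_equal(flow_s2pf(1e6, TRUE, 0, 0.002, 0.03, 200), 0.002)
  # midpoint of the four-parameter logistic: baseline + half the amplitude
  expect_equal(flow_s2pf(200, TRUE, 0.0005, 0.002, 0.03, 200), 0.0005 + 0.001)
})

test_that("allocation derivatives conserve the priority quantity", {
  f0 <- c(f_g2s = 0, f_s2pf = 0, f_s2pc = 0, f_pc2s = 0)
  expect_equal(unname(allocation_derivatives(f0)), rep(0, 4))
  f1 <- c(f_g2s = 0.004, f_s2pf = 0, f_s2pc = 0, f_pc2s = 0)
  d1 <- allocation_derivatives(f1)
  expect_equal(d1[["alloc_g"]], -0.004)
  expect_equal(d1[["alloc_s"]], 0.004)
  expect_equal(d1[["alloc_pf"]], 0)
  expect_equal(d1[["alloc_pc"]], 0)
  for (i in 1:25) {
    f <- setNames(runif(4, 0, 0.1), names(f0))
    expect_equal(sum(allocation_derivatives(f)), 0)
  }
})

test_that("rk4 matches the closed-form exponential decay", {
  k <- 0.01
  deriv <- function(y, tau) -k * y
  y <- 1
  for (i in 1:100) y <- rk4_step(y, deriv, dt = 1)
  expect_equal(y, exp(-k * 100), tolerance = 1e-8)
  # zero derivative leaves the state untouched
  expect_identical(rk4_step(c(0.5, 0.5), function(y, tau) c(0, 0)), c(0.5, 0.5))
  expect_error(rk4_step(1, function(y, tau) NaN), "non-finite")
})

test_that("rk4 conserves the coefficient sum step by step", {
  p <- default_params()
  alloc_deriv <- getFromNamespace(".alloc_deriv", "feedlife")
  y <- c(0.4, 0.3, 0.1, 0.2)
  for (i in 1:50) {
    y <- rk4_step(y, function(yy, tau) {
      alloc_deriv(yy, tau, t_gest = 100 + i, lac_stat = TRUE, gest_stat = TRUE,
                  p$genetics, p$fixed)
    })
    expect_equal(sum(y), 1, tolerance = 1e-9)
  }
})

test_that("event shifts move whole compartments and conserve the sum", {
  a <- c(alloc_g = 0.1, alloc_s = 0.5, alloc_pf = 0.0, alloc_pc = 0.3)
  d <- apply_event_shift(a, "DRYING_OFF")
  expect_equal(d[["alloc_pc"]], 0)
  expect_equal(d[["alloc_s"]], 0.8)
  expect_equal(sum(d), sum(a))
  b <- c(alloc_g = 0.05, alloc_s = 0.45, alloc_pf = 0.25, alloc_pc = 0.25)
  pb <- apply_event_shift(b, "PARTURITION")
  expect_equal(pb[["alloc_pf"]], 0)
  expect_equal(pb[["alloc_pc"]], 0.5)
  expect_equal(sum(pb), sum(b))
  # shifting an empty source compartment is a no-op
  expect_equal(apply_event_shift(d, "DRYING_OFF"), d)
  expect_error(apply_event_shift(a, "WEANING"), "unknown event")
})

test_that("without lactation the current-progeny compartment never drains by flow", {
  out <- integrate_allocation(200, lac_stat = FALSE, gest_stat = FALSE)
  expect_true(all(out$alloc_pc == 0))
  # growth declines monotonically towards survival
  expect_true(all(diff(out$alloc_g) <= 0))
  expect_true(all(abs(rowSums(out[, 2:5]) - 1) < 1e-9))
})

test_that("a larger growth-to-survival rate lowers the whole growth trajectory", {
  p_lo <- load_config(overrides = list(g2s_gen = 0.002))
  p_hi <- load_config(overrides = list(g2s_gen = 0.004))
  sched_lac <- rep(c(FALSE, TRUE), c(300, 700))
  g_lo <- integrate_allocation(1000, p_lo, lac_stat = sched_lac)$alloc_g
  g_hi <- integrate_allocation(1000, p_hi, lac_stat = sched_lac)$alloc_g
  expect_true(all(g_hi <= g_lo + 1e-12))
})

test_that("daily rk4 agrees with a fine-step Euler reference over 3000 days", {
  sched_lac <- rep(c(FALSE, TRUE, FALSE, TRUE), c(700, 400, 100, 1800))
  sched_gest <- rep(c(FALSE, TRUE, FALSE), c(500, 282, 2218))
  rk <- integrate_allocation(3000, lac_stat = sched_lac, gest_stat = sched_gest,
                             method = "rk4")
  eu <- integrate_allocation(3000, lac_stat = sched_lac, gest_stat = sched_gest,
                             method = "euler", dt = 0.01)
  expect_lt(max(abs(as.matrix(rk[, 2:5]) - as.matrix(eu[, 2:5]))), 1e-4)
})
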