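test_that("factor levels are equidistant on the trait scale with inverted rates", {
  lv <- factor_levels(deviation = 0.15)
  expect_equal(nrow(lv), 12)
  g <- lv[lv$parameter == "g2s_gen", ]
  # high growth-allocation trait = low transfer rate
  expect_equal(g$value[g$level == "H"], 0.00285 * 0.85)
  expect_equal(g$value[g$level == "L"], 0.00285 * 1.15)
  a <- lv[lv$parameter == "acqb_gen", ]
  expect_equal(a$value[a$level == "H"], 10.6 * 1.15)
  expect_equal(a$value[a$level == "L"], 10.6 * 0.85)
  # symmetric deviations around the medium
  dev <- tapply(lv$value, lv$parameter, function(v) diff(range(v)) / mean(v[2]))
  expect_true(all(abs(unlist(dev)) > 0))
})

test_that("the complete factorial has 81 points including all-medium once", {
  d <- build_factorial()
  expect_equal(nrow(d), 81)
  expect_equal(length(unique(d$point_id)), 81)
  all_m <- d[d$growth_allocation == "M" & d$lactation_allocation == "M" &
               d$basal_acquisition == "M" & d$lactation_acquisition == "M", ]
  expect_equal(nrow(all_m), 1)
  expect_equal(all_m$g2s_gen, default_params()$genetics$g2s_gen)
  expect_equal(all_m$acql_gen, default_params()$genetics$acql_gen)
})

test_that("a design subset runs deterministically with one row per replicate", {
  d <- build_factorial()[c(1, 41), ]
  r1 <- run_design(d, n_reps = 2, base_seed = 17)
  r2 <- run_design(d, n_reps = 2, base_seed = 17)
  expect_equal(nrow(r1), 4)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  expect_equal(length(unique(r1$seed)), 4)
})

test_that("marginal means agree with a brute-force group-by on a toy table", {
  toy <- tibble::tibble(
    growth_allocation = factor(rep(c("L", "M", "H"), c(4, 3, 3)),
                               levels = c("L", "M", "H")),
    lactation_allocation = factor("M", levels = c("L", "M", "H")),
    basal_acquisition = factor("M", levels = c("L", "M", "H")),
    lactation_acquisition = factor("M", levels = c("L", "M", "H")),
    y = c(1, 2, 3, 4, 10, 11, 12, 20, 21, 22)
  )
  mm <- marginal_means(toy, "y", factors = "growth_allocation")
  expect_equal(mm$mean, c(mean(1:4), 11, 21))
  expect_equal(mm$deviation_from_m, 100 * (c(2.5, 11, 21) - 11) / 11)
  expect_equal(mm$se[2], stats::sd(10:12) / sqrt(3))
  # a constant response has zero deviation everywhere
  toy$y <- 5
  mm5 <- marginal_means(toy, "y", factors = "growth_allocation")
  expect_equal(mm5$mean, rep(5, 3))
  expect_equal(mm5$deviation_from_m, rep(0, 3))
})

test_that("marginal means over factor codes recover the codes", {
  d <- build_factorial()
  d$y <- as.numeric(d$basal_acquisition)
  mm <- marginal_means(d, "y", factors = "basal_acquisition")
  expect_equal(mm$mean, c(1, 2, 3))
})

test_that("anova indices match a hand-computed cell-mean decomposition", {
  # 2x2 single-replicate table: SS worked out from cell and marginal means
  toy <- tibble::tibble(
    f1 = factor(c("L", "L", "H", "H")),
    f2 = factor(c("L", "H", "L", "H")),
    y = c(1, 2, 4, 7)
  )
  sens <- anova_sensitivity(toy, "y", max_order = 2, factors = c("f1", "f2"))
  idx <- tidy(sens)
  expect_equal(idx$ss[idx$term == "f1"], 16)
  expect_equal(idx$ss[idx$term == "f2"], 4)
  expect_equal(idx$ss[idx$term == "f1:f2"], 1)
  expect_equal(sens$ss_total, 21)
  expect_equal(sum(idx$index), 1, tolerance = 1e-9)
})

test_that("a pure main effect captures all variance; pure noise goes to residual", {
  d <- build_factorial()
  d2 <- dplyr::bind_rows(d, d)
  d2$y <- as.numeric(d2$lactation_allocation)
  sens <- anova_sensitivity(d2, "y")
  idx <- tidy(sens)
  expect_equal(idx$index[idx$term == "lactation_allocation"], 1, tolerance = 1e-9)
  expect_equal(idx$index[idx$term == "residual"], 0, tolerance = 1e-9)
  set.seed(8)
  d2$y <- rnorm(nrow(d2))
  noise <- tidy(anova_sensitivity(d2, "y"))
  expect_gt(noise$index[noise$term == "residual"], 0.7)
  expect_true(all(noise$index[noise$order %in% 1] < 0.1))
  g <- glance(anova_sensitivity(d2, "y"))
  expect_equal(g$main_effect_share + g$interaction_share + g$residual_share, 1,
               tolerance = 1e-9)
})
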