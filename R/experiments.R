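#' Factor levels for the factorial sensitivity design
#'
#' Builds the low/medium/high values of the four genetic-scaling
#' parameters.  Levels are labelled on the trait scale: the factors are
#' the level of allocation to growth, the level of allocation to
#' lactation, basal acquisition and lactation acquisition.  Because
#' raising the transfer rates `g2s_gen` and `pc2s_gen` *lowers* the
#' allocation to growth and to lactation respectively, the high trait
#' level of the two allocation factors maps to the low rate-parameter
#' value; the two acquisition factors map directly.  Low and high are
#' equidistant percentage deviations from the medium (calibrated default)
#' value.
#'
#' @param params A `cow_params` bundle supplying the medium values.
#' @param deviation Fractional deviation of L and H from M (default 0.15).
#' @return A tibble with columns `factor`, `parameter`, `level` (ordered
#'   L/M/H on the trait scale) and `value` (parameter value).
#' @export
factor_levels <- function(params = default_params(), deviation = 0.15) {
  g <- params$genetics
  spec <- tibble(
    factor = c("growth_allocation", "lactation_allocation",
               "basal_acquisition", "lactation_acquisition"),
    parameter = c("g2s_gen", "pc2s_gen", "acqb_gen", "acql_gen"),
    medium = c(g$g2s_gen, g$pc2s_gen, g$acqb_gen, g$acql_gen),
    inverted = c(TRUE, TRUE, FALSE, FALSE)
  )
  tidyr::crossing(spec, tibble(level = c("L", "M", "H"))) %>%
    mutate(
      level = factor(.data$level, levels = c("L", "M", "H")),
      sign = dplyr::case_when(
        .data$level == "M" ~ 0,
        (.data$level == "H") != .data$inverted ~ 1,
        TRUE ~ -1
      ),
      value = .data$medium * (1 + .data$sign * deviation)
    ) %>%
    dplyr::select("factor", "parameter", "level", "value") %>%
    arrange(.data$factor, .data$level)
}

#' Build the complete 3^4 factorial design
#'
#' Cartesian product of the three levels of the four genetic-scaling
#' factors: 81 design points, including the all-medium point.
#'
#' @param levels Level table from [factor_levels()].
#' @return A tibble with 81 rows: `point_id`, one L/M/H column per
#'   factor, and the four parameter-value columns.
#' @export
build_factorial <- function(levels = factor_levels()) {
  wide_levels <- split(levels, levels$factor)
  grid <- tidyr::crossing(
    growth_allocation = c("L", "M", "H"),
    lactation_allocation = c("L", "M", "H"),
    basal_acquisition = c("L", "M", "H"),
    lactation_acquisition = c("L", "M", "H")
  )
  lookup <- function(fac, lev) {
    tab <- wide_levels[[fac]]
    tab$value[match(lev, as.character(tab$level))]
  }
  grid %>%
    mutate(
      across(all_of(names(wide_levels)), ~ factor(.x, levels = c("L", "M", "H"))),
      g2s_gen = lookup("growth_allocation", .data$growth_allocation),
      pc2s_gen = lookup("lactation_allocation", .data$lactation_allocation),
      acqb_gen = lookup("basal_acquisition", .data$basal_acquisition),
      acql_gen = lookup("lactation_acquisition", .data$lactation_acquisition)
    ) %>%
    arrange(.data$growth_allocation, .data$lactation_allocation,
            .data$basal_acquisition, .data$lactation_acquisition) %>%
    mutate(point_id = dplyr::row_number(), .before = 1)
}

#' Run the factorial sensitivity experiment
#'
#' Simulates every design point with `n_reps` replicate lifetimes each,
#' seeding replicate `r` of point `d` deterministically from the base
#' seed, so a run is exactly reproducible.  Individual simulation
#' failures are recorded and skipped rather than aborting the run.
#'
#' @param design Design tibble from [build_factorial()] (or a subset of
#'   its rows).
#' @param params Baseline `cow_params` bundle for all non-genetic
#'   parameters.
#' @param n_reps Replicates per design point (the study condition is 20).
#' @param base_seed Base integer seed.
#' @return A tibble of class `fe_experiment`: the design columns plus
#'   `replicate`, `seed` and the [summarize_life()] columns, one row per
#'   (point, replicate).
#' @export
run_design <- function(design = build_factorial(), params = default_params(),
                       n_reps = 20, base_seed = 1L) {
  validate_params(params)
  rows <- purrr::map_dfr(seq_len(nrow(design)), function(i) {
    pt <- design[i, ]
    p <- params
    p$genetics$g2s_gen <- pt$g2s_gen
    p$genetics$pc2s_gen <- pt$pc2s_gen
    p$genetics$acqb_gen <- pt$acqb_gen
    p$genetics$acql_gen <- pt$acql_gen
    out <- tryCatch(
      run_replicates(p, n = n_reps, base_seed = base_seed,
                     point_id = pt$point_id),
      error = function(e) {
        warn(sprintf("design point %d failed: %s", pt$point_id,
                     conditionMessage(e)))
        NULL
      }
    )
    if (is.null(out)) return(NULL)
    dplyr::bind_cols(pt[rep(1, nrow(out)), ], out)
  })
  structure(rows, class = c("fe_experiment", class(rows)),
            base_seed = base_seed, n_reps = n_reps)
}

.design_factors <- c("growth_allocation", "lactation_allocation",
                     "basal_acquisition", "lactation_acquisition")

#' Marginal means of a response over the factorial design
#'
#' For each factor and level, the mean of the response over all runs with
#' that factor held at that level (27 design points times the
#' replicates), with its standard error and the percentage deviation from
#' the factor's medium level.  Statistics average per-cow values (mean of
#' ratios); rows with a missing response (e.g. lactation-level metrics of
#' cows that terminated mid-lactation) are dropped with a count kept in
#' the `n_missing` column.
#'
#' @param results An `fe_experiment` tibble from [run_design()].
#' @param response Name of a summary column, e.g. `"fe_life"`.
#' @param factors Factor columns to marginalise over.
#' @return A tibble: `factor`, `level`, `n`, `n_missing`, `mean`, `se`,
#'   `deviation_from_m` (%).
#' @export
marginal_means <- function(results, response = "fe_life",
                           factors = .design_factors) {
  if (!response %in% names(results)) {
    abort(sprintf("unknown response column '%s'", response))
  }
  purrr::map_dfr(factors, function(fac) {
    out <- results %>%
      group_by(level = .data[[fac]]) %>%
      summarise(
        n = sum(!is.na(.data[[response]])),
        n_missing = sum(is.na(.data[[response]])),
        mean = mean(.data[[response]], na.rm = TRUE),
        se = stats::sd(.data[[response]], na.rm = TRUE) / sqrt(.data$n),
        .groups = "drop"
      )
    if (any(out$n == 0)) abort(sprintf("empty cell for factor '%s'", fac))
    m <- out$mean[out$level == "M"]
    out %>%
      mutate(factor = fac, response = response,
             deviation_from_m = 100 * (mean - m) / m, .before = 1)
  })
}

#' ANOVA variance-decomposition sensitivity indices
#'
#' Fits the factorial linear model of the response on the design factors
#' up to the given interaction order and decomposes the output
#' variability into per-term sums of squares.  The sensitivity index of a
#' term is its share of the total sum of squares; the residual share
#' collects replicate stochasticity and unmodelled higher-order
#' interactions.  For the complete balanced design the sequential sums of
#' squares are orthogonal; with imbalance (dropped missing responses)
#' they depend on term order and are flagged.
#'
#' @param results An `fe_experiment` tibble from [run_design()].
#' @param response Name of a summary column.
#' @param max_order Highest interaction order to include (default 2).
#' @param factors Factor columns.
#' @return An object of class `fe_sensitivity` with a tidy index table
#'   (see [tidy.fe_sensitivity()]).
#' @export
anova_sensitivity <- function(results, response = "fe_life", max_order = 2,
                              factors = .design_factors) {
  dat <- results[!is.na(results[[response]]), c(factors, response)]
  n_dropped <- nrow(results) - nrow(dat)
  dat <- as.data.frame(dat)
  dat[factors] <- lapply(dat[factors], function(x) factor(as.character(x)))
  form <- stats::as.formula(paste0(
    "`", response, "` ~ (", paste(factors, collapse = " + "), ")^", max_order
  ))
  fit <- lm(form, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    abort(sprintf("rank deficiency in sensitivity ANOVA (term(s): %s)",
                  paste(unique(bad), collapse = ", ")))
  }
  # only the sums of squares are used, so the F-test warning emitted for a
  # perfect (saturated) fit is irrelevant here
  aov_tab <- suppressWarnings(anova(fit))
  ss <- aov_tab[["Sum Sq"]]
  terms <- rownames(aov_tab)
  terms[terms == "Residuals"] <- "residual"
  indices <- tibble(
    term = terms,
    order = ifelse(terms == "residual", NA_integer_,
                   lengths(strsplit(terms, ":", fixed = TRUE))),
    ss = ss,
    index = ss / sum(ss)
  )
  structure(
    list(indices = indices, response = response, fit = fit,
         ss_total = sum(ss), n = nrow(dat), n_dropped = n_dropped,
         balanced = n_dropped == 0),
    class = "fe_sensitivity"
  )
}

#' @export
print.fe_sensitivity <- function(x, ...) {
  cat(sprintf("<fe_sensitivity> response: %s (n = %d%s)\n", x$response, x$n,
              if (x$balanced) "" else sprintf(", %d rows dropped", x$n_dropped)))
  main <- x$indices %>% filter(!is.na(.data$order), .data$order == 1) %>%
    arrange(dplyr::desc(.data$index))
  for (i in seq_len(nrow(main))) {
    cat(sprintf("  %-22s %6.1f%%\n", main$term[[i]], 100 * main$index[[i]]))
  }
  resid <- x$indices$index[x$indices$term == "residual"]
  cat(sprintf("  %-22s %6.1f%%\n", "residual", 100 * resid))
  invisible(x)
}
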