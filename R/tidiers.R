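#' Tidy a simulated lifetime
#'
#' Returns the daily trajectory as a tibble (one row per simulated day).
#'
#' @param x A `cow_life` object from [simulate_cow()].
#' @param ... Unused.
#' @return A tibble, or an error if the run was made with `record = FALSE`.
#' @method tidy cow_life
#' @export
tidy.cow_life <- function(x, ...) {
  if (is.null(x$trajectory)) {
    abort("trajectory was not recorded; rerun simulate_cow() with record = TRUE")
  }
  x$trajectory
}

#' One-row summary of a simulated lifetime
#'
#' @param x A `cow_life` object.
#' @param ... Unused.
#' @return The [summarize_life()] row with the seed prepended.
#' @method glance cow_life
#' @export
glance.cow_life <- function(x, ...) {
  dplyr::bind_cols(tibble(seed = x$seed), x$summary)
}

#' Tidy sensitivity indices
#'
#' @param x An `fe_sensitivity` object from [anova_sensitivity()].
#' @param ... Unused.
#' @return A tibble with `term`, `order`, `ss` and `index` (share of the
#'   total sum of squares; sums to 1 over all terms plus the residual).
#' @method tidy fe_sensitivity
#' @export
tidy.fe_sensitivity <- function(x, ...) {
  x$indices
}

#' One-row summary of a sensitivity decomposition
#'
#' @param x An `fe_sensitivity` object.
#' @param ... Unused.
#' @return A tibble with the response name, total sum of squares, the
#'   share explained by main effects, by interactions, and the residual
#'   share.
#' @method glance fe_sensitivity
#' @export
glance.fe_sensitivity <- function(x, ...) {
  idx <- x$indices
  tibble(
    response = x$response,
    n = x$n,
    ss_total = x$ss_total,
    main_effect_share = sum(idx$index[!is.na(idx$order) & idx$order == 1]),
    interaction_share = sum(idx$index[!is.na(idx$order) & idx$order > 1]),
    residual_share = idx$index[idx$term == "residual"],
    balanced = x$balanced
  )
}
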