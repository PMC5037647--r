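#' Canned scenario fixtures
#'
#' Parameter bundles for documented scenarios, used in examples and
#' tests: `"all-medium"` is the default calibrated genotype;
#' `"never-conceives"` forces the conception probability to (numerically)
#' zero, producing a milkless life ending at the horizon;
#' `"high-lactation"` lowers the lactation-to-survival transfer rate by
#' 15%, i.e. the high-lactation-allocation genotype of the factorial
#' design.
#'
#' @param name Scenario name.
#' @param params Baseline bundle to modify.
#' @return A validated `cow_params` bundle.
#' @examples
#' make_fixture("never-conceives")$fixed$conc_b0
#' @export
make_fixture <- function(name = c("all-medium", "never-conceives",
                                  "high-lactation"),
                         params = default_params()) {
  name <- match.arg(name)
  if (name == "never-conceives") {
    params$fixed$conc_b0 <- -745 # plogis(-745) underflows to exactly 0
  } else if (name == "high-lactation") {
    params$genetics$pc2s_gen <- params$genetics$pc2s_gen * 0.85
  }
  validate_params(params)
  params
}

#' Write run outputs to CSV files
#'
#' Writes the trajectory, event log, life summary and a reproduction
#' manifest (configuration snapshot and seed) for one simulated life.
#'
#' @param life A `cow_life` object.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_life_csv <- function(life, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(life$trajectory)) {
    utils::write.csv(life$trajectory, file.path(dir, "trajectory.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(life$events, file.path(dir, "events.csv"), row.names = FALSE)
  utils::write.csv(life$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  write_config(life$params, file.path(dir, "config.yaml"))
  yaml::write_yaml(list(seed = life$seed, package = "feedlife",
                        version = as.character(utils::packageVersion("feedlife"))),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}
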