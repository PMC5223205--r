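#' Run configuration
#'
#' Bundles the tunable parameters shared across the pipeline: the seasonal
#' stage thresholds that define the flood-pulse seasons, the STARS settings,
#' the common-species CPUE filter, the missing-value sweep increment and the
#' random seed. Values can be layered from a YAML file via
#' [read_run_config()]; arguments given here always win.
#'
#' @param season_low_threshold Stage level (m) below which a day is dry and at
#'   whose upward crossing a flood-pulse cycle starts. Default 20.
#' @param season_high_threshold Stage level (m) above which a day is in the
#'   flood season. Default 26.
#' @param stars_significance Two-sided significance level of the sequential
#'   t-test. Default 0.05 (hydrological series); 0.01 is conventional for the
#'   noisier biological series.
#' @param stars_window Cut-off length `l` (years) of the STARS test window.
#'   Default 10; 7 is the common short alternative.
#' @param prewhiten Logical; remove lag-1 autocorrelation before STARS.
#' @param common_species_cpue_threshold CPUE (individuals per m2 of gillnet)
#'   above which a species counts as common. Default 0.01.
#' @param sweep_increment Grid step of the missing-value sweep, in the units
#'   of the swept series. Default 0.001.
#' @param max_gap_fraction Largest tolerated fraction of missing days inside
#'   a flood-pulse cycle before its metrics are flagged unusable.
#' @param random_seed Integer seed used by the synthetic generators.
#'
#' @return An object of class `"run_config"` (a named list).
#' @examples
#' cfg <- run_config(stars_window = 7)
#' cfg$stars_window
#' @export
run_config <- function(season_low_threshold = 20,
                       season_high_threshold = 26,
                       stars_significance = 0.05,
                       stars_window = 10,
                       prewhiten = TRUE,
                       common_species_cpue_threshold = 0.01,
                       sweep_increment = 0.001,
                       max_gap_fraction = 0.05,
                       random_seed = 20170110L) {
  cfg <- list(
    season_low_threshold = as.numeric(season_low_threshold),
    season_high_threshold = as.numeric(season_high_threshold),
    stars_significance = as.numeric(stars_significance),
    stars_window = as.integer(stars_window),
    prewhiten = isTRUE(prewhiten),
    common_species_cpue_threshold = as.numeric(common_species_cpue_threshold),
    sweep_increment = as.numeric(sweep_increment),
    max_gap_fraction = as.numeric(max_gap_fraction),
    random_seed = as.integer(random_seed)
  )
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(cfg) {
  if (!(cfg$season_low_threshold < cfg$season_high_threshold))
    stop("season thresholds must satisfy low < high", call. = FALSE)
  if (!(cfg$stars_significance > 0 && cfg$stars_significance < 1))
    stop("stars_significance must lie in (0, 1)", call. = FALSE)
  if (cfg$stars_window < 3)
    stop("stars_window must be at least 3 years", call. = FALSE)
  if (cfg$sweep_increment <= 0)
    stop("sweep_increment must be positive", call. = FALSE)
  if (cfg$max_gap_fraction < 0 || cfg$max_gap_fraction >= 1)
    stop("max_gap_fraction must lie in [0, 1)", call. = FALSE)
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' Keys in the file mirror the arguments of [run_config()]. Values supplied
#' through `...` override the file (command line wins over configuration).
#'
#' @param path Path to a YAML file; `NULL` gives pure defaults.
#' @param ... Overrides passed on to [run_config()].
#' @return A `"run_config"` object.
#' @export
read_run_config <- function(path = NULL, ...) {
  file_args <- list()
  if (!is.null(path)) {
    file_args <- yaml::read_yaml(path)
    known <- names(formals(run_config))
    unknown <- setdiff(names(file_args), known)
    if (length(unknown)) {
      warning("ignoring unknown config keys: ",
              paste(unknown, collapse = ", "), call. = FALSE)
      file_args <- file_args[intersect(names(file_args), known)]
    }
  }
  overrides <- list(...)
  file_args[names(overrides)] <- overrides
  do.call(run_config, file_args)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration\n")
  for (nm in names(x)) cat(sprintf("  %-30s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
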