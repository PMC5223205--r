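#' Classify a day of the flood pulse into a season
#'
#' Seasons follow the classical four-phase description of the central-Amazon
#' flood pulse: \emph{dry} while the stage is strictly below the low
#' threshold (20 m by default), \emph{flood} while strictly above the high
#' threshold (26 m), and within the closed band between the thresholds
#' \emph{rising} when the stage is moving up and \emph{receding} when it is
#' moving down. The band is split by direction so no level is ever left
#' unlabelled.
#'
#' @param level Stage level(s) in metres.
#' @param direction Character vector, one of `"ascending"`, `"descending"`;
#'   flat days must be resolved to a direction by the caller (see
#'   [segment_cycles()] for the carry-forward rule).
#' @param config A [run_config()] providing the two thresholds.
#' @return Character vector of season labels among
#'   `"dry", "rising", "flood", "receding"`.
#' @examples
#' classify_day(c(19, 27.2, 23), c("ascending", "descending", "descending"))
#' @export
classify_day <- function(level, direction, config = run_config()) {
  stopifnot(length(level) == length(direction))
  if (!all(direction %in% c("ascending", "descending")))
    stop("direction must be 'ascending' or 'descending'", call. = FALSE)
  lo <- config$season_low_threshold
  hi <- config$season_high_threshold
  out <- ifelse(level < lo, "dry",
         ifelse(level > hi, "flood",
         ifelse(direction == "ascending", "rising", "receding")))
  out
}

# direction of each day: sign of the first difference; flat days inherit the
# previous day's direction, the first day takes the next day's sign
day_directions <- function(levels) {
  n <- length(levels)
  d <- sign(diff(levels))       # d[i] applies to day i+1
  dir <- c(NA_real_, d)
  nz <- which(d != 0)
  if (length(nz) == 0L) dir[] <- 1 else dir[1L] <- d[nz[1L]]
  # carry-forward for flat days
  for (i in seq_len(n)[-1L]) if (dir[i] == 0) dir[i] <- dir[i - 1L]
  ifelse(dir >= 0, "ascending", "descending")
}

#' Segment a stage series into annual flood-pulse cycles
#'
#' A flood-pulse cycle runs from one upward crossing of the low threshold to
#' the day before the next one, so each cycle contains exactly one rising
#' limb, one flood peak, one receding limb and the dry season that follows
#' (attached to the ending cycle). An upward crossing is the first day at or
#' above the low threshold after at least one day below it; to keep daily
#' gauge noise jittering around the threshold from splitting a pulse in two,
#' a crossing only starts a new cycle once the stage has receded at least
#' `hysteresis_m` below the threshold since the previous crossing. Partial
#' cycles before the first and after the last crossing are dropped and
#' reported in the `dropped_days` attribute. Missing calendar days between
#' a cycle's first and the next cycle's first day count against the cycle's
#' gap budget.
#'
#' @param series A `"stage_series"` from [read_stage_series()] or
#'   [gen_hydrograph()].
#' @param config A [run_config()].
#' @param hysteresis_m Recession (m) below the low threshold required
#'   before the next upward crossing opens a new cycle (default 0.5).
#' @return A list of `"flood_pulse_cycle"` objects, each a data frame with
#'   columns `date`, `level_m`, `season`, and attributes `cycle_id`
#'   (label `"YYYY-YYYY"`), `start_date`, `end_date`, `n_missing_days`,
#'   `usable`.
#' @export
segment_cycles <- function(series, config = run_config(),
                           hysteresis_m = 0.5) {
  lo <- config$season_low_threshold
  lev <- series$level_m
  n <- length(lev)
  below <- lev < lo
  # upward crossings: at/above low, previous observed day below
  cross <- which(!below & c(FALSE, below[-n]))
  # hysteresis: drop crossings not preceded by a recession below lo - hyst
  if (length(cross)) {
    kept <- cross[1L]
    if (length(cross) > 1L) for (k in cross[-1L]) {
      prev <- kept[length(kept)]
      if (min(lev[prev:k]) < lo - hysteresis_m) kept <- c(kept, k)
    }
    cross <- kept
  }
  if (length(cross) == 0L)
    stop("series never crosses the low threshold upward; no cycles",
         call. = FALSE)
  if (length(cross) < 2L) {
    warning("fewer than two upward crossings; no complete cycle",
            call. = FALSE)
    return(structure(list(), dropped_days = n))
  }
  dirs <- day_directions(lev)
  seasons <- classify_day(lev, dirs, config)
  cycles <- vector("list", length(cross) - 1L)
  for (k in seq_len(length(cross) - 1L)) {
    idx <- cross[k]:(cross[k + 1L] - 1L)
    cyc <- data.frame(date = series$date[idx],
                      level_m = lev[idx],
                      season = seasons[idx])
    span <- as.integer(series$date[cross[k + 1L]] -
                         series$date[cross[k]])
    n_missing <- span - length(idx)
    y0 <- as.integer(format(cyc$date[1L], "%Y"))
    y1 <- as.integer(format(cyc$date[nrow(cyc)], "%Y"))
    attr(cyc, "cycle_id") <- paste0(y0, "-", y1)
    attr(cyc, "start_date") <- cyc$date[1L]
    attr(cyc, "end_date") <- cyc$date[nrow(cyc)]
    attr(cyc, "n_missing_days") <- n_missing
    attr(cyc, "usable") <- n_missing / span <= config$max_gap_fraction
    class(cyc) <- c("flood_pulse_cycle", "data.frame")
    cycles[[k]] <- cyc
  }
  dropped <- (cross[1L] - 1L) + (n - cross[length(cross)] + 1L)
  structure(cycles, dropped_days = dropped)
}

#' Seven hydrological metrics of one flood-pulse cycle
#'
#' Computes the amplitude of the pulse (within-cycle maximum minus minimum
#' stage), the annual lowest and highest stage, and the number of days spent
#' in each of the four seasons. A cycle flagged unusable (too many missing
#' days) yields a record of `NA`s.
#'
#' @param cycle A `"flood_pulse_cycle"` from [segment_cycles()].
#' @return A one-row data frame with columns `cycle_id`, `amplitude_m`,
#'   `min_m`, `max_m`, `days_dry`, `days_rising`, `days_flood`,
#'   `days_receding`, `n_missing_days`.
#' @export
cycle_metrics <- function(cycle) {
  stopifnot(inherits(cycle, "flood_pulse_cycle"))
  id <- attr(cycle, "cycle_id")
  if (!isTRUE(attr(cycle, "usable"))) {
    return(data.frame(cycle_id = id, amplitude_m = NA_real_, min_m = NA_real_,
                      max_m = NA_real_, days_dry = NA_integer_,
                      days_rising = NA_integer_, days_flood = NA_integer_,
                      days_receding = NA_integer_,
                      n_missing_days = attr(cycle, "n_missing_days")))
  }
  tab <- table(factor(cycle$season,
                      levels = c("dry", "rising", "flood", "receding")))
  data.frame(cycle_id = id,
             amplitude_m = max(cycle$level_m) - min(cycle$level_m),
             min_m = min(cycle$level_m),
             max_m = max(cycle$level_m),
             days_dry = as.integer(tab[["dry"]]),
             days_rising = as.integer(tab[["rising"]]),
             days_flood = as.integer(tab[["flood"]]),
             days_receding = as.integer(tab[["receding"]]),
             n_missing_days = attr(cycle, "n_missing_days"))
}

#' Cycle-by-metric feature matrix, standardised
#'
#' Segments the series, computes the seven metrics per complete usable cycle
#' and z-scores each metric column (mean 0, unit standard deviation across
#' cycles), the usual preparation before ordination. Zero-variance columns
#' are left at zero with a warning.
#'
#' @param series A `"stage_series"`.
#' @param config A [run_config()].
#' @return A list with `raw` (data frame, one row per usable cycle) and
#'   `standardized` (numeric matrix, row names = cycle ids).
#' @export
hydro_feature_matrix <- function(series, config = run_config()) {
  cycles <- segment_cycles(series, config)
  met <- do.call(rbind, lapply(cycles, cycle_metrics))
  usable <- stats::complete.cases(met)
  if (sum(usable) < 3L)
    stop("need at least 3 complete usable cycles, got ", sum(usable),
         call. = FALSE)
  met_u <- met[usable, , drop = FALSE]
  m <- as.matrix(met_u[, c("amplitude_m", "min_m", "max_m", "days_dry",
                           "days_rising", "days_flood", "days_receding")])
  rownames(m) <- met_u$cycle_id
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    warning("zero-variance metric column(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  z <- scale(m, center = TRUE, scale = ifelse(sds == 0, 1, sds))
  z[, sds == 0] <- 0
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  list(raw = met, standardized = z)
}
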