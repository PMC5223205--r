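#' Synthetic daily hydrograph with a known regime change
#'
#' Generates a quasi-sinusoidal annual flood pulse: within each 365-day year
#' the stage runs from the year's minimum up to its maximum and back
#' (`min + amp (1 - cos(2 pi d / 365)) / 2`), plus Gaussian daily noise.
#' From `change_year` onward the amplitude and the dry-season minimum are
#' shifted by the scenario deltas, emulating a hydrological regime with
#' higher flood peaks and drier dry seasons. The new regime takes effect
#' with the flood pulse of `change_year`; year-start minima follow from
#' `change_year + 1`, so that each flood-pulse cycle (a pulse plus the dry
#' season that follows it) is entirely in one regime and cycle-level
#' metrics change at a single cycle. Defaults mimic the Negro River
#' at Manaus: minima around 18 m, amplitude around 10 m, so every annual
#' pulse crosses both the 20 m and 26 m season thresholds; after the change
#' the amplitude grows by 2 m and the minimum drops by 1.5 m.
#'
#' @param n_years Number of simulated years (default 16).
#' @param base_min_m Dry-season minimum stage before the change (m).
#' @param base_amplitude_m Pulse amplitude before the change (m).
#' @param change_year Year index (1-based) at which the new regime starts;
#'   `NULL` for no change.
#' @param amplitude_delta_m Added to the amplitude from `change_year` on.
#' @param min_delta_m Added to the minimum from `change_year` on.
#' @param noise_sd_m Daily Gaussian noise standard deviation (m).
#' @param min_year_sd_m,amplitude_year_sd_m Interannual standard deviation
#'   of the dry-season minimum and of the amplitude (m). Annual flood
#'   pulses vary appreciably between years even within a stable regime;
#'   the defaults (0.3 and 0.5 m) keep the default regime contrast at
#'   roughly four interannual standard deviations, an abrupt but not
#'   caricatural change.
#' @param start_year Calendar year of the first day.
#' @param seed Optional integer seed.
#' @return A `"stage_series"` with attribute `truth`: a list with the
#'   per-year minima, maxima, amplitudes and the change year.
#' @export
gen_hydrograph <- function(n_years = 16, base_min_m = 18,
                           base_amplitude_m = 10, change_year = NULL,
                           amplitude_delta_m = 2, min_delta_m = -1.5,
                           noise_sd_m = 0.05, min_year_sd_m = 0.3,
                           amplitude_year_sd_m = 0.5, start_year = 2000,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  yr <- seq_len(n_years)
  after <- if (is.null(change_year)) rep(FALSE, n_years) else yr >= change_year
  # the pulse of change_year opens the new regime; year-start minima (the
  # dry season that closes each cycle) follow one year later
  after_min <- if (is.null(change_year)) rep(FALSE, n_years) else
    yr >= change_year + 1L
  reg_min <- base_min_m + min_delta_m * after_min
  reg_max <- reg_min + base_amplitude_m + amplitude_delta_m * after
  if (any(reg_min >= 20) || any(reg_max <= 26))
    stop("scenario pulses must cross both season thresholds ",
         "(regime minima < 20 m, regime maxima > 26 m); got minima in [",
         min(reg_min), ", ", max(reg_min), "], maxima in [",
         min(reg_max), ", ", max(reg_max), "]", call. = FALSE)
  mins <- reg_min + stats::rnorm(n_years, 0, min_year_sd_m)
  mins <- pmin(mins, 19.5)  # every year must still open with a dry season
  amps <- base_amplitude_m + amplitude_delta_m * after +
    stats::rnorm(n_years, 0, amplitude_year_sd_m)
  # peaks are tied to the regime's own minimum so the post-change maxima do
  # not overshoot in the hand-over year
  maxs <- base_min_m + min_delta_m * after + amps
  d <- 0:364
  shape <- (1 - cos(2 * pi * d / 365)) / 2
  levels <- unlist(lapply(yr, function(y)
    mins[y] + (maxs[y] - mins[y]) * shape))
  levels <- levels + stats::rnorm(length(levels), 0, noise_sd_m)
  dates <- as.Date(paste0(start_year, "-01-01")) + seq_along(levels) - 1L
  out <- data.frame(date = dates, level_m = levels)
  attr(out, "n_gap_days") <- 0L
  attr(out, "truth") <- list(year = yr, min_m = mins, max_m = maxs,
                             amplitude_m = amps, change_year = change_year,
                             start_year = start_year)
  class(out) <- c("stage_series", "data.frame")
  out
}

#' Synthetic annual series from a response-family mean
#'
#' Mean from [model_mean()] plus stationary AR(1) Gaussian noise with
#' marginal standard deviation `noise_sd`.
#'
#' @param family,params,tau Passed to [model_mean()].
#' @param n Series length.
#' @param noise_sd Marginal noise standard deviation.
#' @param phi AR(1) coefficient of the noise.
#' @param seed Optional integer seed.
#' @param start_label Label of the first point (default 1).
#' @return An `"annual_series"` with attribute `truth` (family, params,
#'   tau, noise_sd, phi).
#' @export
gen_annual_series <- function(family, params, n, tau = NULL, noise_sd = 0,
                              phi = 0, seed = NULL, start_label = 1) {
  if (!is.null(seed)) set.seed(seed)
  labs <- start_label + seq_len(n) - 1
  mu <- model_mean(family, params, labs, tau)
  e <- numeric(n)
  if (noise_sd > 0) {
    z <- stats::rnorm(n)
    e[1L] <- noise_sd * z[1L]
    for (i in seq_len(n)[-1L])
      e[i] <- phi * e[i - 1L] + noise_sd * sqrt(1 - phi^2) * z[i]
  }
  out <- annual_series(labs, mu + e)
  attr(out, "truth") <- list(family = family, params = params, tau = tau,
                             noise_sd = noise_sd, phi = phi)
  out
}

# trait archetypes of the five life-history strategies: rows are
# (max SL mm, maturation SL mm, fecundity, oocyte diameter mm, care score)
lh_archetypes <- function() {
  rbind(ES = c(130, 80, 800, 2.2, 4.0),
        EL = c(550, 350, 4000, 2.8, 3.5),
        IS = c(150, 90, 15000, 1.4, 2.0),
        PL = c(500, 320, 250000, 1.0, 1.0),
        PS = c(140, 85, 40000, 0.9, 1.0))
}

# diet archetypes of the four trophic levels (proportions by category)
trophic_archetypes <- function() {
  cats <- diet_categories
  m <- matrix(0, 4L, length(cats), dimnames = list(c("1", "1.5", "2", "3"),
                                                   cats))
  m["1", c("detritus", "algae", "plant", "invertebrate")] <-
    c(0.45, 0.30, 0.20, 0.05)
  m["1.5", c("plant", "detritus", "invertebrate", "fish", "other")] <-
    c(0.30, 0.15, 0.30, 0.15, 0.10)
  m["2", c("invertebrate", "plankton", "plant", "other")] <-
    c(0.55, 0.30, 0.10, 0.05)
  m["3", c("fish", "invertebrate", "other")] <- c(0.75, 0.20, 0.05)
  m
}

#' Synthetic species trait table from strategy archetypes
#'
#' Draws each species' five life-history traits around its strategy's
#' archetype with multiplicative lognormal within-cluster noise
#' (`within_sd` on the log scale), giving well-separated clusters along
#' the fecundity/parental-care and body-size gradients.
#'
#' @param life_history Character vector of strategy labels (ES, EL, IS,
#'   PL, PS), one per species.
#' @param species_id Species identifiers (default `sp001`...).
#' @param within_sd Within-cluster log-scale standard deviation.
#' @param seed Optional integer seed.
#' @return A trait table as from [read_trait_table()].
#' @export
gen_traits <- function(life_history, species_id = NULL, within_sd = 0.12,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(life_history)
  if (is.null(species_id))
    species_id <- sprintf("sp%03d", seq_len(n))
  arch <- lh_archetypes()
  stopifnot(all(life_history %in% rownames(arch)))
  draw <- function(j) {
    arch[life_history, j] * exp(stats::rnorm(n, 0, within_sd))
  }
  max_sl <- draw(1L)
  data.frame(species_id = species_id,
             max_sl_mm = max_sl,
             maturation_sl_mm = pmin(draw(2L), 0.95 * max_sl),
             fecundity = draw(3L),
             oocyte_diam_mm = draw(4L),
             parental_care_score = draw(5L))
}

#' Synthetic diet table from trophic archetypes
#'
#' @param trophic_level Numeric vector of levels (1, 1.5, 2, 3) per species.
#' @param species_id Species identifiers.
#' @param jitter_sd Lognormal jitter applied to archetype proportions
#'   before renormalisation.
#' @param seed Optional integer seed.
#' @return A diet table as from [read_diet_table()].
#' @export
gen_diet <- function(trophic_level, species_id = NULL, jitter_sd = 0.15,
                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(trophic_level)
  if (is.null(species_id))
    species_id <- sprintf("sp%03d", seq_len(n))
  arch <- trophic_archetypes()
  rows <- lapply(seq_len(n), function(i) {
    p <- arch[as.character(trophic_level[i]), ]
    p <- p * exp(stats::rnorm(length(p), 0, jitter_sd))
    p <- p / sum(p)
    keep <- p > 0
    data.frame(species_id = species_id[i],
               item_category = colnames(arch)[keep],
               volume_prop = unname(p[keep]))
  })
  do.call(rbind, rows)
}

#' Default community scenario
#'
#' Group composition mirrors the surveyed assemblage: 97 common species
#' split into the five life-history strategies (ES 12, EL 3, IS 18, PL 29,
#' PS 35) plus `n_rare` rare species seeded below the common-CPUE
#' threshold, and trophic levels assigned across the common species in the
#' proportions 26 : 21 : 26 : 24. Group response functions default to the
#' step/segmented shapes typical of an abrupt disturbance at `tau`: abrupt
#' CPUE drops for ES, EL and IS, a decline-then-stable trajectory for PL
#' and a stable-then-decline trajectory for PS.
#'
#' @param tau Change-point cycle label (index into the cycles).
#' @param n_rare Number of rare species (default 99, for 196 in total).
#' @param baseline_common,baseline_rare Per-species baseline CPUE
#'   (individuals per m2).
#' @param noise_sd Log-scale standard deviation of the shared group-year
#'   effects.
#' @param phi AR(1) coefficient of the group-year effects.
#' @param effort_m2 Gillnet area fished per cycle.
#' @return A list scenario consumed by [gen_community()].
#' @export
community_scenario <- function(tau, n_rare = 99, baseline_common = 0.02,
                               baseline_rare = 0.002, noise_sd = 0.15,
                               phi = 0.2, effort_m2 = 1000) {
  counts <- c(ES = 12, EL = 3, IS = 18, PL = 29, PS = 35)
  responses <- list(
    ES = list(family = "step_mean", params = list(a = 1, c = -0.4)),
    EL = list(family = "step_mean", params = list(a = 1, c = -0.45)),
    IS = list(family = "step_mean", params = list(a = 1, c = -0.4)),
    PL = list(family = "linear_stable",
              params = list(a = 1, b = 0, m = 0.6)),
    PS = list(family = "stable_linear",
              params = list(m = 1, a = 1, b = 0)))
  # PL declines linearly to its stable level before tau; PS declines after.
  # Slopes are filled in by gen_community once the cycle labels are known.
  list(counts = counts, responses = responses, tau = tau, n_rare = n_rare,
       baseline_common = baseline_common, baseline_rare = baseline_rare,
       noise_sd = noise_sd, phi = phi, effort_m2 = effort_m2)
}

#' Synthetic fish community over a set of flood-pulse cycles
#'
#' Per-species expected CPUE is the species baseline times its group's
#' response function evaluated at the cycle label, times a shared lognormal
#' group-year effect with AR(1) structure; realised counts are Poisson with
#' mean expected CPUE times effort, so CPUE re-estimation by
#' [cpue_matrix()] is exactly the inverse of generation in expectation.
#'
#' @param scenario A scenario list from [community_scenario()], optionally
#'   with modified fields.
#' @param cycles Cycle spans: a data frame `cycle_id,start_date,end_date`,
#'   a list of `"flood_pulse_cycle"` objects, or an integer number of
#'   cycles (spans are then invented, one per year from 2000).
#' @param seed Optional integer seed.
#' @return A list: `catch`, `effort`, `traits`, `diet`, `labels` (tables
#'   passing the package readers' schemas) and `truth` (group responses,
#'   baselines, species group membership, `tau`).
#' @export
gen_community <- function(scenario, cycles, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.numeric(cycles) && length(cycles) == 1L) {
    n_cyc <- as.integer(cycles)
    starts <- as.Date(paste0(2000 + seq_len(n_cyc) - 1L, "-06-01"))
    cycles <- data.frame(
      cycle_id = paste0(2000 + seq_len(n_cyc) - 1L, "-",
                        2000 + seq_len(n_cyc)),
      start_date = starts, end_date = starts + 364)
  } else if (!is.data.frame(cycles)) {
    cycles <- data.frame(
      cycle_id = vapply(cycles, attr, character(1), "cycle_id"),
      start_date = as.Date(vapply(cycles, function(c)
        as.character(attr(c, "start_date")), character(1))),
      end_date = as.Date(vapply(cycles, function(c)
        as.character(attr(c, "end_date")), character(1))))
  }
  n_cyc <- nrow(cycles)
  labs <- seq_len(n_cyc)
  tau <- scenario$tau

  counts <- scenario$counts
  groups <- rep(names(counts), counts)
  n_common <- length(groups)
  n_rare <- scenario$n_rare
  n_sp <- n_common + n_rare
  sp <- sprintf("sp%03d", seq_len(n_sp))
  common <- seq_len(n_common)

  # default slopes for the decline legs once cycle labels are known
  responses <- scenario$responses
  for (g in names(responses)) {
    r <- responses[[g]]
    if (r$family == "linear_stable" && r$params$b == 0) {
      r$params$b <- (r$params$m - 1) / (tau - 1)
      r$params$a <- 1 - r$params$b
    }
    if (r$family == "stable_linear" && r$params$b == 0) {
      r$params$b <- -0.4 / (n_cyc - tau + 1)
      r$params$a <- r$params$m - r$params$b * (tau - 1)
    }
    responses[[g]] <- r
  }

  g_of <- function(g, t) model_mean(responses[[g]]$family,
                                    responses[[g]]$params, t, tau)
  # shared lognormal group-year effects with AR(1) structure
  eff <- sapply(names(counts), function(g) {
    e <- numeric(n_cyc)
    z <- stats::rnorm(n_cyc)
    e[1L] <- scenario$noise_sd * z[1L]
    for (i in labs[-1L])
      e[i] <- scenario$phi * e[i - 1L] +
        scenario$noise_sd * sqrt(1 - scenario$phi^2) * z[i]
    exp(e)
  })

  baseline <- c(rep(scenario$baseline_common, n_common),
                rep(scenario$baseline_rare, n_rare))
  expected <- matrix(0, n_cyc, n_sp)
  for (i in seq_len(n_sp)) {
    if (i <= n_common) {
      g <- groups[i]
      expected[, i] <- baseline[i] * g_of(g, labs) * eff[, g]
    } else {
      expected[, i] <- baseline[i]
    }
  }
  if (any(expected < 0))
    stop("negative expected CPUE; response parameters too extreme",
         call. = FALSE)
  lambda <- expected * scenario$effort_m2
  if (any(lambda > 1e9)) stop("expected count overflow", call. = FALSE)
  cnt <- matrix(stats::rpois(length(lambda), lambda), n_cyc, n_sp)

  mid <- cycles$start_date + floor((cycles$end_date - cycles$start_date) / 2)
  nz <- which(cnt > 0, arr.ind = TRUE)
  catch <- data.frame(date = mid[nz[, 1L]],
                      species_id = sp[nz[, 2L]],
                      count = cnt[nz])
  catch <- catch[order(catch$date, catch$species_id), ]
  rownames(catch) <- NULL
  effort <- data.frame(cycle_id = cycles$cycle_id,
                       effort_m2 = scenario$effort_m2)

  # functional labels: strategies per group; trophic levels spread over the
  # common species in the surveyed proportions 26:21:26:24
  trophic_pool <- rep(c(1, 1.5, 2, 3), times = c(26, 21, 26, 24))
  trophic <- rep(trophic_pool, length.out = n_common)
  labels <- data.frame(species_id = sp[common],
                       life_history = groups,
                       trophic_level = trophic)
  traits <- gen_traits(groups, species_id = sp[common])
  diet <- gen_diet(trophic, species_id = sp[common])

  truth <- list(responses = responses, tau = tau, baseline = baseline,
                species_id = sp, common_species = sp[common],
                groups = stats::setNames(groups, sp[common]),
                expected_cpue = expected, cycle_id = cycles$cycle_id)
  list(catch = catch, effort = effort, traits = traits, diet = diet,
       labels = labels, cycles = cycles, truth = truth)
}
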