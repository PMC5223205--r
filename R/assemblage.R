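#' Catch-per-unit-effort matrix
#'
#' Aggregates raw catches into a cycle-by-species CPUE matrix: each entry is
#' the total count of a species over all sampling dates falling inside a
#' flood-pulse cycle, divided by the total gillnet area fished in that
#' cycle. CPUE removes the bias from inter-annual differences in sampling
#' effort (cycles differ in length and number of completed surveys).
#'
#' @param catch Catch table (`date,species_id,count`), see
#'   [read_catch_table()].
#' @param effort Effort table (`cycle_id,effort_m2`).
#' @param cycles List of `"flood_pulse_cycle"` objects from
#'   [segment_cycles()], or a data frame with columns `cycle_id`,
#'   `start_date`, `end_date`.
#' @return A numeric matrix (individuals per m2), rows = cycle ids,
#'   columns = species ids. Catch dates outside all cycles are excluded;
#'   their total count is reported in the `n_excluded` attribute.
#' @export
cpue_matrix <- function(catch, effort, cycles) {
  if (is.data.frame(cycles)) {
    spans <- cycles
  } else {
    spans <- data.frame(
      cycle_id = vapply(cycles, attr, character(1), "cycle_id"),
      start_date = as.Date(vapply(cycles, function(c)
        as.character(attr(c, "start_date")), character(1))),
      end_date = as.Date(vapply(cycles, function(c)
        as.character(attr(c, "end_date")), character(1))))
  }
  idx <- rep(NA_integer_, nrow(catch))
  for (k in seq_len(nrow(spans))) {
    inside <- catch$date >= spans$start_date[k] &
      catch$date <= spans$end_date[k]
    idx[inside] <- k
  }
  excluded <- sum(catch$count[is.na(idx)])
  if (excluded > 0)
    message(excluded, " individuals on dates outside all cycles excluded")
  keep <- !is.na(idx)
  species <- sort(unique(catch$species_id))
  counts <- tapply(catch$count[keep],
                   list(factor(spans$cycle_id[idx[keep]],
                               levels = spans$cycle_id),
                        factor(catch$species_id[keep], levels = species)),
                   sum, default = 0)
  eff <- effort$effort_m2[match(spans$cycle_id, effort$cycle_id)]
  if (anyNA(eff))
    stop("no effort recorded for cycle(s): ",
         paste(spans$cycle_id[is.na(eff)], collapse = ", "), call. = FALSE)
  if (any(eff <= 0)) stop("effort must be positive", call. = FALSE)
  m <- sweep(unclass(counts), 1L, eff, "/")
  attr(m, "n_excluded") <- excluded
  m
}

#' Filter to common species
#'
#' Keeps the species whose CPUE exceeds the threshold in at least one cycle
#' (the aggregation rule is the maximum over cycles).
#'
#' @param cpue Cycle-by-species CPUE matrix.
#' @param threshold CPUE threshold (default 0.01 individuals per m2).
#' @return The column subset of `cpue`.
#' @export
filter_common <- function(cpue, threshold = 0.01) {
  keep <- apply(cpue, 2L, max) > threshold
  if (!any(keep))
    stop("no species exceeds the CPUE threshold ", threshold, call. = FALSE)
  cpue[, keep, drop = FALSE]
}

#' Diversity, Shannon entropy and Pielou evenness per cycle
#'
#' Richness S counts positive entries; Shannon H = -sum p log p over
#' relative CPUE (natural log); Pielou J = H / log S, reported missing when
#' S = 1 (evenness undefined for a single species).
#'
#' @param cpue CPUE matrix (rows = cycles) or a single row.
#' @return Data frame with columns `cycle_id`, `richness`, `shannon`,
#'   `evenness`.
#' @export
diversity_indices <- function(cpue) {
  if (is.null(dim(cpue))) cpue <- matrix(cpue, nrow = 1L,
                                         dimnames = list("row1", NULL))
  if (any(rowSums(cpue) == 0))
    stop("all-zero cycle row(s); diversity undefined", call. = FALSE)
  res <- t(apply(cpue, 1L, function(x) {
    p <- x[x > 0] / sum(x)
    S <- length(p)
    H <- -sum(p * log(p))
    J <- if (S > 1L) H / log(S) else NA_real_
    c(S, H, J)
  }))
  data.frame(cycle_id = rownames(cpue), richness = as.integer(res[, 1L]),
             shannon = res[, 2L], evenness = res[, 3L],
             row.names = NULL)
}

#' Relative-abundance anomaly
#'
#' Each value minus the mean over the baseline cycles (the pre-disturbance
#' reference period), so anomalies over the baseline itself sum to zero.
#'
#' @param series An `"annual_series"` (or named numeric vector) of relative
#'   abundances.
#' @param baseline_labels Labels of the baseline cycles.
#' @return An `"annual_series"` of anomalies.
#' @export
abundance_anomaly <- function(series, baseline_labels) {
  s <- as_annual_series(series)
  if (length(baseline_labels) == 0L)
    stop("baseline set must be non-empty", call. = FALSE)
  if (is.character(baseline_labels))
    baseline_labels <- as.numeric(sub("-.*$", "", baseline_labels))
  miss <- setdiff(baseline_labels, s$label)
  if (length(miss))
    stop("baseline label(s) absent from series: ",
         paste(miss, collapse = ", "), call. = FALSE)
  base <- mean(s$value[s$label %in% baseline_labels])
  annual_series(s$label, s$value - base)
}

#' Taxonomic assemblage structure
#'
#' The composition ordination of the common-species CPUE matrix: square
#' root transform, Bray-Curtis dissimilarity, principal coordinates.
#'
#' @param cpue Common-species CPUE matrix (rows = cycles).
#' @return An `"ordination"` with one score row per cycle.
#' @export
taxonomic_structure <- function(cpue) {
  pcoa(bray_curtis(sqrt_transform(cpue)))
}

#' Functional assemblage structure
#'
#' Aggregates species CPUE into functional groups (life-history strategies
#' or trophic levels), Hellinger-transforms the group-by-cycle matrix and
#' ordinates it by centred, unscaled PCA.
#'
#' @param cpue CPUE matrix (rows = cycles, columns = species).
#' @param labels Label table (`species_id,life_history,trophic_level`), see
#'   [read_label_table()].
#' @param scheme `"life_history"` or `"trophic"`.
#' @return An `"ordination"`; the aggregated group matrix is attached as
#'   attribute `"group_cpue"`.
#' @export
functional_structure <- function(cpue, labels,
                                 scheme = c("life_history", "trophic")) {
  scheme <- match.arg(scheme)
  col <- if (scheme == "life_history") "life_history" else "trophic_level"
  grp <- labels[[col]][match(colnames(cpue), labels$species_id)]
  if (anyNA(grp))
    stop("species lacking a ", scheme, " label: ",
         paste(colnames(cpue)[is.na(grp)], collapse = ", "), call. = FALSE)
  agg <- t(rowsum(t(cpue), group = as.character(grp)))
  ord <- pca(hellinger_transform(agg), center = TRUE, scale = FALSE)
  attr(ord, "group_cpue") <- agg
  ord
}

#' Life-history trait ordination and suggested strategy labels
#'
#' Ordinates species along the classical life-history continuum: size and
#' fecundity traits are log-transformed, all five traits are z-scored and a
#' PCA is run. For convenience the function also suggests the five strategy
#' labels. Because the raw PCA axes rotate with species composition, the
#' suggestions are built on the two gradients that define the strategies
#' directly: the fecundity-versus-parental-care contrast (z(log fecundity)
#' minus z(care score); periodic positive, equilibrium negative) and body
#' size (z(log maximum SL)). Species are split into five groups by Ward
#' clustering on that plane (deterministic); the groups, ordered along the
#' fecundity-care contrast, are named equilibrium, equilibrium,
#' intermediate, periodic, periodic, and within each strategy pair the
#' group whose median maximum standard length exceeds `sl_cut_mm` (or
#' failing that, the larger-bodied of the pair) is the "large" form. The
#' suggested labels are a starting point — expert labels from a label
#' table remain the canonical path.
#'
#' @param traits Trait table, see [read_trait_table()].
#' @param sl_cut_mm Standard-length cut separating large from small species
#'   (default 250 mm).
#' @return A list: `ordination` (an `"ordination"`, one score row per
#'   species) and `labels` (data frame `species_id,life_history`; all `NA`
#'   with a message when fewer than six species are available to cluster).
#' @export
life_history_pca <- function(traits, sl_cut_mm = 250) {
  if (any(as.matrix(traits[, -1L]) <= 0))
    stop("trait values must be positive", call. = FALSE)
  z <- cbind(log_max_sl = log(traits$max_sl_mm),
             log_maturation_sl = log(traits$maturation_sl_mm),
             log_fecundity = log(traits$fecundity),
             oocyte_diam = traits$oocyte_diam_mm,
             parental_care = traits$parental_care_score)
  mu <- colMeans(z); sds <- apply(z, 2L, stats::sd)
  sds[sds == 0] <- 1
  z <- scale(z, center = mu, scale = sds)
  rownames(z) <- traits$species_id
  ord <- pca(z, center = TRUE, scale = FALSE)

  n <- nrow(z)
  if (n < 6L) {
    message("fewer than 6 species; no strategy labels suggested")
    lab <- rep(NA_character_, n)
  } else {
    g1 <- z[, "log_fecundity"] - z[, "parental_care"]
    g2 <- z[, "log_max_sl"]
    cl <- stats::cutree(stats::hclust(stats::dist(cbind(g1, g2)),
                                      method = "ward.D2"), k = 5L)
    side <- c("E", "E", "I", "P", "P")[
      rank(tapply(g1, cl, mean))]          # strategy by contrast order
    med_sl <- tapply(traits$max_sl_mm, cl, stats::median)
    lab_of <- character(5L)
    for (s in c("E", "P")) {
      pair <- which(side == s)
      big <- med_sl[pair] > sl_cut_mm
      if (sum(big) != 1L) big <- med_sl[pair] == max(med_sl[pair])
      lab_of[pair] <- paste0(s, ifelse(big, "L", "S"))
    }
    lab_of[side == "I"] <- "IS"
    lab <- lab_of[cl]
  }
  list(ordination = ord,
       labels = data.frame(species_id = traits$species_id,
                           life_history = lab))
}

#' Trophic-level assignment from diet composition
#'
#' Assigns each species to one of four consumer trophic levels from its
#' volumetric diet proportions: level 1 (herbivores and detritivores) when
#' plant + detritus + algae dominate, level 3 (piscivores) when fish
#' dominates, level 2 (invertivores and planktivores) when invertebrates +
#' plankton dominate, and level 1.5 (omnivores, mixed plant and animal)
#' otherwise. Dominance means the combined share reaches `dominance`
#' (default 0.6).
#'
#' @param diet Diet table, see [read_diet_table()].
#' @param dominance Share above which a diet block dominates.
#' @return Data frame `species_id,trophic_level`.
#' @export
assign_trophic <- function(diet, dominance = 0.6) {
  share <- function(cats) {
    tapply(ifelse(diet$item_category %in% cats, diet$volume_prop, 0),
           diet$species_id, sum)
  }
  tot <- tapply(diet$volume_prop, diet$species_id, sum)
  if (any(tot == 0)) stop("empty diet for some species", call. = FALSE)
  plant <- share(c("plant", "detritus", "algae")) / tot
  fish <- share("fish") / tot
  invert <- share(c("invertebrate", "plankton")) / tot
  lvl <- ifelse(plant >= dominance, 1,
         ifelse(fish >= dominance, 3,
         ifelse(invert >= dominance, 2, 1.5)))
  data.frame(species_id = names(tot), trophic_level = as.numeric(lvl),
             row.names = NULL)
}

#' Repeated-measures ANOVA of functional-group abundance
#'
#' Tests the before/after effect of a disturbance on group abundance. Each
#' flood-pulse cycle is a subject measured once per functional group;
#' period (before vs after the split) is a between-subject factor and group
#' a within-subject factor. The analysis is a mixed two-factor ANOVA
#' (`stats::aov` with a cycle error stratum) and the quantity of interest
#' is the period-by-group interaction. Per-group before/after Welch
#' contrasts are reported alongside.
#'
#' @param group_cpue Matrix of CPUE, rows = cycles (rownames = cycle ids or
#'   starting years), columns = functional groups.
#' @param split_label Year label: cycles with starting year `>= split_label`
#'   form the after period.
#' @return List with `anova` (data frame of F, dfs and p for period, group
#'   and their interaction) and `contrasts` (per-group data frame with
#'   means and Welch p-values).
#' @export
rm_anova <- function(group_cpue, split_label) {
  yrs <- as.numeric(sub("-.*$", "", rownames(group_cpue)))
  period <- factor(ifelse(yrs >= split_label, "after", "before"),
                   levels = c("before", "after"))
  if (any(table(period) < 2L))
    stop("each period needs at least 2 cycles", call. = FALSE)
  long <- data.frame(
    value = as.vector(group_cpue),
    cycle = factor(rep(rownames(group_cpue), ncol(group_cpue))),
    group = factor(rep(colnames(group_cpue), each = nrow(group_cpue))),
    period = rep(period, ncol(group_cpue)))
  fit <- stats::aov(value ~ period * group + Error(cycle), data = long)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: cycle"]][[1L]])
  within <- as.data.frame(sm[["Error: Within"]][[1L]])
  pick <- function(tab, term) {
    i <- which(trimws(rownames(tab)) == term)
    data.frame(term = term, df1 = tab$Df[i],
               df2 = tab$Df[nrow(tab)],
               F = tab$`F value`[i], p = tab$`Pr(>F)`[i])
  }
  anova_tab <- rbind(pick(between, "period"),
                     pick(within, "group"),
                     pick(within, "period:group"))
  contrasts <- do.call(rbind, lapply(colnames(group_cpue), function(g) {
    x <- group_cpue[period == "before", g]
    y <- group_cpue[period == "after", g]
    tt <- stats::t.test(x, y)
    data.frame(group = g, mean_before = mean(x), mean_after = mean(y),
               t = unname(tt$statistic), p = tt$p.value)
  }))
  list(anova = anova_tab, contrasts = contrasts)
}
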