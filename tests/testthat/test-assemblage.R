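make_cycles <- function(n, start_year = 2000) {
  starts <- as.Date(paste0(start_year + seq_len(n) - 1L, "-06-01"))
  data.frame(cycle_id = paste0(start_year + seq_len(n) - 1L, "-",
                               start_year + seq_len(n)),
             start_date = starts, end_date = starts + 364)
}

test_that("cpue is counts over effort, with scaling and exclusion rules", {
  cyc <- make_cycles(2)
  catch <- data.frame(
    date = as.Date(c("2000-08-01", "2000-08-01", "2001-08-01",
                     "1990-01-01")),
    species_id = c("sp1", "sp2", "sp1", "sp1"),
    count = c(30, 10, 15, 99))
  effort <- data.frame(cycle_id = cyc$cycle_id, effort_m2 = c(1000, 500))
  expect_message(m <- cpue_matrix(catch, effort, cyc), "99")
  expect_equal(m["2000-2001", "sp1"], 0.03)
  expect_equal(m["2001-2002", "sp2"], 0)      # unobserved -> 0
  expect_equal(attr(m, "n_excluded"), 99)
  # doubling effort halves CPUE
  effort2 <- effort; effort2$effort_m2 <- effort2$effort_m2 * 2
  m2 <- suppressMessages(cpue_matrix(catch, effort2, cyc))
  expect_equal(unclass(m2), unclass(m) / 2, ignore_attr = TRUE)
  # zero / missing effort
  expect_error(cpue_matrix(catch, effort[1, , drop = FALSE], cyc),
               "no effort")
})

test_that("common-species filter uses the max-over-cycles rule", {
  m <- rbind(c(0.005, 0.2, 0.009), c(0.002, 0.1, 0.011))
  colnames(m) <- c("rare", "abundant", "border")
  f <- filter_common(m, threshold = 0.01)
  expect_equal(colnames(f), c("abundant", "border"))
  expect_equal(filter_common(m, threshold = 0.001), m)
  expect_error(filter_common(m, threshold = 1), "no species")
})

test_that("diversity indices match their identities", {
  even <- matrix(rep(0.1, 4), 1, dimnames = list("c1", NULL))
  d <- diversity_indices(even)
  expect_equal(d$richness, 4L)
  expect_equal(d$shannon, log(4))
  expect_equal(d$evenness, 1)
  single <- matrix(c(0.5, 0, 0), 1, dimnames = list("c1", NULL))
  d1 <- diversity_indices(single)
  expect_equal(d1$richness, 1L)
  expect_true(is.na(d1$evenness))
  dp <- diversity_indices(matrix(c(0.5, 0.25, 0.25), 1,
                                 dimnames = list("c1", NULL)))
  expect_equal(dp$shannon, 1.5 * log(2))
  expect_equal(dp$evenness, 1.5 * log(2) / log(3))
  expect_error(diversity_indices(matrix(0, 1, 3)), "all-zero")
  # filtering never increases richness
  set.seed(1)
  m <- matrix(rexp(30, 50), 3, 10, dimnames = list(paste0("c", 1:3), NULL))
  rich_all <- diversity_indices(m)$richness
  rich_f <- diversity_indices(filter_common(m, 0.005))$richness
  expect_true(all(rich_f <= rich_all))
})

test_that("anomalies are deviations from the baseline mean", {
  s <- annual_series(2000:2007, c(0.1, 0.1, 0.1, 0.1, 0.3, 0.3, 0.3, 0.3))
  a <- abundance_anomaly(s, 2000:2003)
  expect_equal(a$value, c(rep(0, 4), rep(0.2, 4)))
  expect_equal(sum(a$value[1:4]), 0)  # centering identity
  flat <- annual_series(1:5, rep(0.2, 5))
  expect_equal(abundance_anomaly(flat, 1:3)$value, rep(0, 5))
  expect_error(abundance_anomaly(s, 1999), "absent")
  expect_error(abundance_anomaly(s, numeric(0)), "non-empty")
})

test_that("taxonomic structure is invariant to species order and detects
          a composition step", {
  set.seed(2)
  m <- matrix(rexp(80, 10), 8, 10,
              dimnames = list(paste0("c", 1:8), paste0("sp", 1:10)))
  o1 <- taxonomic_structure(m)
  o2 <- taxonomic_structure(m[, sample(10)])
  expect_equal(abs(o1$scores[, 1]), abs(o2$scores[, 1]), tolerance = 1e-8)
  # identical composition -> identical scores
  m2 <- rbind(m, m[8, , drop = FALSE])
  rownames(m2)[9] <- "c9"
  o3 <- taxonomic_structure(m2)
  expect_equal(o3$scores[8, ], o3$scores[9, ], tolerance = 1e-8)
  # step change separates the two periods on axis 1
  comm <- rbind(matrix(rep(c(10, 1), each = 24), 6, 8, byrow = FALSE),
                matrix(rep(c(1, 10), each = 24), 6, 8, byrow = FALSE))
  comm <- comm + matrix(rexp(96, 5), 12, 8)
  rownames(comm) <- paste0("c", 1:12)
  os <- taxonomic_structure(comm)
  pre <- os$scores[1:6, 1]; post <- os$scores[7:12, 1]
  expect_true(max(pre) < min(post) || min(pre) > max(post))
})

test_that("functional structure aggregates by group and is label-name
          invariant", {
  set.seed(3)
  m <- matrix(rexp(60, 10), 6, 10,
              dimnames = list(paste0("c", 1:6), paste0("sp", 1:10)))
  lab <- data.frame(species_id = paste0("sp", 1:10),
                    life_history = rep(c("ES", "PL"), 5),
                    trophic_level = rep(c(1, 2), 5))
  o <- functional_structure(m, lab, "life_history")
  agg <- attr(o, "group_cpue")
  expect_equal(dim(agg), c(6L, 2L))
  expect_equal(agg[, "ES"],
               rowSums(m[, lab$life_history == "ES"]))
  # renaming groups changes nothing but names
  lab2 <- lab
  lab2$life_history <- ifelse(lab$life_history == "ES", "PS", "EL")
  o2 <- functional_structure(m, lab2, "life_history")
  expect_equal(o$eigenvalues, o2$eigenvalues, tolerance = 1e-12)
  # unlabeled species is an error listing the offender
  expect_error(functional_structure(m, lab[-3, ], "life_history"), "sp3")
  # all-identical cycles: scores all zero after centering
  mc <- matrix(rep(m[1, ], each = 6), 6, 10,
               dimnames = dimnames(m))
  oc <- functional_structure(mc, lab, "life_history")
  expect_equal(max(abs(oc$scores)), 0, tolerance = 1e-12)
})

test_that("life-history PCA separates archetypes and suggests labels", {
  # two-species contrast: high fecundity/no care vs low fecundity/high care
  tr <- data.frame(species_id = c("per", "eq"),
                   max_sl_mm = c(300, 300),
                   maturation_sl_mm = c(200, 200),
                   fecundity = c(2e5, 500),
                   oocyte_diam_mm = c(1, 2.5),
                   parental_care_score = c(1, 4))
  r <- life_history_pca(tr)
  expect_lt(r$ordination$scores[1, 1] * r$ordination$scores[2, 1], 0)
  # duplicated rows score identically
  tr2 <- rbind(tr, tr)
  tr2$species_id <- c("a", "b", "c", "d")
  r2 <- life_history_pca(tr2)
  expect_equal(r2$ordination$scores[1, ], r2$ordination$scores[3, ],
               tolerance = 1e-10)
  expect_error(life_history_pca(transform(tr, fecundity = -1)), "positive")
})

test_that("suggested strategies recover generated clusters and are
          unit invariant", {
  set.seed(4)
  lh <- sample(rep(c("ES", "EL", "IS", "PL", "PS"), each = 40))
  tr <- gen_traits(lh, seed = 5)
  r <- life_history_pca(tr)
  agree <- mean(r$labels$life_history == lh)
  expect_gte(agree, 0.90)
  # mm -> cm leaves suggestions unchanged (log + z-score scale invariance)
  tr_cm <- tr
  tr_cm$max_sl_mm <- tr$max_sl_mm / 10
  tr_cm$maturation_sl_mm <- tr$maturation_sl_mm / 10
  r_cm <- life_history_pca(tr_cm, sl_cut_mm = 25)
  expect_equal(r_cm$labels$life_history, r$labels$life_history)
})

test_that("trophic assignment follows the dominance rule", {
  diet <- data.frame(
    species_id = rep(c("herb", "omni", "pisc", "invert"), each = 2),
    item_category = c("detritus", "algae", "plant", "invertebrate",
                      "fish", "invertebrate", "invertebrate", "plankton"),
    volume_prop = c(0.7, 0.3, 0.5, 0.5, 0.7, 0.3, 0.6, 0.4))
  lv <- assign_trophic(diet)
  expect_equal(lv$trophic_level[match(c("herb", "omni", "pisc", "invert"),
                                      lv$species_id)],
               c(1, 1.5, 3, 2))
})

test_that("rm-anova matches hand-worked sums of squares on a balanced
          toy design", {
  # 2 groups x 2 periods x 3 cycles per period (irregular, non-degenerate)
  m <- rbind(c(10, 20), c(11.5, 22), c(12, 20.5),   # before
             c(15, 19), c(16, 21.5), c(17.5, 20))   # after
  colnames(m) <- c("g1", "g2")
  rownames(m) <- paste0(c(2000, 2001, 2002, 2005, 2006, 2007))
  res <- rm_anova(m, split_label = 2005)
  # hand-worked two-factor mixed ANOVA with cycles as subjects
  long <- data.frame(v = as.vector(m),
                     g = rep(c("g1", "g2"), each = 6),
                     p = rep(rep(c("b", "a"), each = 3), 2),
                     s = rep(1:6, 2))
  gm <- mean(long$v)
  ss_p <- 6 * sum((tapply(long$v, long$p, mean) - gm)^2)
  ss_g <- 6 * sum((tapply(long$v, long$g, mean) - gm)^2)
  cell <- tapply(long$v, list(long$p, long$g), mean)
  ss_pg <- 3 * sum((cell - outer(rowMeans(cell), colMeans(cell), "+") +
                      gm)^2)
  ss_s <- 2 * sum((tapply(long$v, long$s, mean) - gm)^2)
  ss_tot <- sum((long$v - gm)^2)
  ss_err <- ss_tot - ss_g - ss_pg - ss_s
  df_err <- 4   # (n_cycles - 2) * (n_groups - 1)
  f_int <- (ss_pg / 1) / (ss_err / df_err)
  got <- res$anova[res$anova$term == "period:group", ]
  expect_equal(got$F, f_int, tolerance = 1e-10)
  expect_equal(got$df1, 1)
  expect_equal(got$df2, df_err)
})

test_that("rm-anova finds an injected group step and not a flat group", {
  set.seed(6)
  hits_step <- hits_flat <- 0
  for (r in 1:100) {
    n <- 10
    m <- cbind(stepg = c(rnorm(5, 10, 0.2), rnorm(5, 9, 0.2)),  # 5 sd step
               flat1 = rnorm(n, 5, 0.2),
               flat2 = rnorm(n, 3, 0.2))
    rownames(m) <- 2000:2009
    res <- rm_anova(m, split_label = 2005)
    ct <- res$contrasts
    if (ct$p[ct$group == "stepg"] < 0.05) hits_step <- hits_step + 1
    if (ct$p[ct$group == "flat1"] < 0.05) hits_flat <- hits_flat + 1
  }
  expect_gte(hits_step / 100, 0.95)
  expect_lte(hits_flat / 100, 0.15)
  # identical cell means in both periods: interaction F exactly 0
  g1 <- c(4.2, 3.9, 4.0, 4.3, 3.6)
  g2 <- c(2.1, 2.4, 1.8, 2.2, 2.5)
  m0 <- cbind(g1 = c(g1, rev(g1)), g2 = c(g2, g2[c(3, 1, 2, 5, 4)]))
  rownames(m0) <- 2000:2009
  res0 <- rm_anova(m0, split_label = 2005)
  f0 <- res0$anova$F[res0$anova$term == "period:group"]
  expect_lt(f0, 1e-10)
  expect_error(rm_anova(m0[1:3, ], split_label = 2002), "at least 2")
})
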