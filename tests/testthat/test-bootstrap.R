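strata5 <- c("East" = 26, "South-West" = 64, "North-Parisian-basin" = 41,
             "West" = 26, "South-East" = 17)

test_that("stratified resampling conserves stratum sizes and determinism", {
  s <- sim_survey(survey_sim_config(n_species = 15, seed = 4))
  p2 <- s[s$period == "P2000s", ]
  set.seed(1)
  rs <- stratified_resample(p2, strata5)
  fields <- unique(rs[, c("field_id", "region")])
  expect_equal(as.integer(table(fields$region)[names(strata5)]),
               as.integer(strata5))
  expect_equal(nrow(fields), sum(strata5))
  set.seed(99); a <- stratified_resample(p2, strata5)
  set.seed(99); b <- stratified_resample(p2, strata5)
  expect_identical(a, b)
  expect_error(stratified_resample(p2, c(Atlantis = 3)), "absent")
  # single-field stratum: resample is a multiset of the original fields
  one <- p2[p2$region == "East", ]
  set.seed(2)
  rs1 <- stratified_resample(one, c(East = 5))
  expect_true(all(sort(unique(rs1$species)) %in% unique(one$species)))
})

test_that("bootstrap intervals are percentile intervals of the replicates", {
  s <- presence_survey(30, 12, score = "3")
  set.seed(8)
  bc <- bootstrap_commonness(s, c(East = 30), B = 400,
                             keep_replicates = TRUE)
  fr <- attr(bc, "freq_replicates")
  row <- bc[bc$metric == "frequency" & bc$species == "focal", ]
  expect_equal(row$mean, mean(fr[, "focal"]))
  expect_equal(row$ci_low,
               unname(quantile(fr[, "focal"], 0.025)))
  expect_equal(row$ci_high,
               unname(quantile(fr[, "focal"], 0.975)))
  # constant data: species in every field -> zero-width frequency CI
  const <- bc[bc$metric == "frequency" & bc$species == "filler", ]
  expect_equal(const$ci_low, 100)
  expect_equal(const$ci_high, 100)
  # absent-from-replicate convention: abundance over presence fields only
  ab <- bc[bc$metric == "abundance" & bc$species == "focal", ]
  expect_gte(ab$ci_low, 1.5)
  expect_error(bootstrap_commonness(s, c(East = 30), B = 1), "B must")
})

test_that("status calls follow the interval rule and the detection floor", {
  expect_equal(classify_status(26.5, 33.1, 45.1), "+")
  expect_equal(classify_status(38.0, 29.7, 41.1), "=")
  expect_equal(classify_status(40.2, 15.4, 24.6), "-")
  expect_equal(classify_status(NA, 8.0, 16.6), "N")   # clearly above floor
  expect_equal(classify_status(NA, 1.7, 7.4), "?")    # floor inside CI
  expect_equal(classify_status(NA, 2.3, 8.0), "N")    # bound at the floor
  # monotone in the old value: + -> = -> -
  st <- classify_status(c(1, 10, 25), 5, 20)
  expect_equal(st, c("+", "=", "-"))
  expect_error(classify_status(1, 10, 5), "invalid interval")
})

test_that("published-style calls are reproduced from the printed columns", {
  pub <- published_survey_summary()
  recomputed <- classify_status(pub$freq_p1, pub$freq_lo, pub$freq_hi,
                                detection_threshold = 2.3)
  expect_equal(recomputed, pub$freq_status)
  recomputed_ab <- classify_status(pub$abund_p1, pub$abund_lo, pub$abund_hi,
                                   detection_threshold = 0.5)
  expect_equal(recomputed_ab, pub$abund_status)
})

test_that("spearman trend calls use the exact small-sample null", {
  # strictly increasing series
  up <- yearly_trend(2002:2008, 1:7)
  expect_equal(up$rho, 1)
  expect_equal(up$trend, "+")
  # sum(d^2) = 6 over 7 years: rho = 0.893, exact two-sided p = 0.012
  tr1 <- yearly_trend(2002:2008, c(2, 1, 4, 3, 6, 5, 7))
  expect_equal(tr1$rho, 1 - 6 * 6 / (7 * 48))
  ref1 <- cor.test(2002:2008, c(2, 1, 4, 3, 6, 5, 7),
                   method = "spearman", exact = TRUE)
  expect_equal(tr1$p, ref1$p.value, tolerance = 1e-8)
  expect_equal(tr1$trend, "+")
  # sum(d^2) = 14: rho = 0.75, p ~ 0.066 -> marginal call
  tr2 <- yearly_trend(2002:2008, c(1, 4, 2, 6, 3, 5, 7))
  expect_equal(tr2$rho, 0.75)
  expect_gt(tr2$p, 0.05)
  expect_lt(tr2$p, 0.10)
  expect_equal(tr2$trend, "(+)")
  expect_error(yearly_trend(2002:2004, 1:3), "4 years")
  # t-approximation branch agrees with cor.test for larger n
  set.seed(3)
  y <- rnorm(20)
  mine <- yearly_trend(1991:2010, y)
  ref <- suppressWarnings(cor.test(1991:2010, y, method = "spearman"))
  expect_equal(mine$rho, unname(ref$estimate))
})

test_that("status tables merge bootstrap calls with reference values", {
  cfg <- survey_sim_config(n_species = 12, seed = 31,
                           occupancy = seq(0.15, 0.9, length.out = 12))
  s <- sim_survey(cfg)
  p2 <- s[s$period == "P2000s", ]
  s1 <- species_summary(s[s$period == "P1970s", ])
  ref <- data.frame(species = s1$species, freq_p1 = 100 * s1$F,
                    abund_p1 = s1$A)
  st <- status_table(p2, ref, strata5, B = 200, seed = 5)
  expect_true(all(st$freq_lo <= st$freq_p2 + 1e-9))
  expect_true(all(st$freq_hi >= st$freq_p2 - 1e-9))
  expect_true(all(st$freq_status %in% c("+", "-", "=", "N", "?")))
  expect_true(all(st$trend %in% c("+", "-", "=", "(+)", "(-)")))
  # same seed, same table
  expect_identical(st, status_table(p2, ref, strata5, B = 200, seed = 5))
})
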