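test_that("odds ratios match closed-form arithmetic and invert under row swap", {
  bal <- odds_ratio_woolf(50, 50, 50, 50)
  expect_equal(bal$or, 1)
  expect_equal(log(bal$ci_low), -log(bal$ci_high), tolerance = 1e-12)
  tab <- odds_ratio_woolf(30, 70, 60, 40)
  expect_equal(tab$or, (30 * 40) / (70 * 60), tolerance = 1e-12)
  se <- sqrt(1 / 30 + 1 / 70 + 1 / 60 + 1 / 40)
  expect_equal(tab$ci_low, exp(log(tab$or) - qnorm(0.975) * se),
               tolerance = 1e-12)
  # OR(swapped rows) = 1/OR, exactly
  swap <- odds_ratio_woolf(60, 40, 30, 70)
  expect_equal(swap$or, 1 / tab$or, tolerance = 1e-14)
  expect_warning(odds_ratio_woolf(0, 10, 5, 5), "continuity")
})

test_that("hypertension OR: adjusted and unadjusted paths agree with constant covariates", {
  set.seed(40)
  n <- 600
  cohort <- data.frame(
    daily_sodium = rnorm(n, 165, 38),
    hypertension = runif(n) < 0.4,
    age = rep(60, n), sex = rep("female", n), bmi = rep(23, n))
  carrier <- runif(n) < 0.5
  un <- hypertension_or(cohort, carrier, "all", adjusted = FALSE)
  ad <- hypertension_or(cohort, carrier, "all", adjusted = TRUE)
  expect_equal(ad$or, un$or, tolerance = 1e-6)
  expect_equal(ad$ci_low, un$ci_low, tolerance = 1e-4)
  # strata partition the cohort at the median split
  lo <- hypertension_or(cohort, carrier, "low")
  hi <- hypertension_or(cohort, carrier, "high")
  expect_equal(lo$n + hi$n, n)
})

test_that("subgroup slopes recover exact and generated signals", {
  # exact linear signal: trait = 2 * sodium, constant covariates
  n <- 80
  cohort <- data.frame(daily_sodium = seq(100, 250, length.out = n),
                       age = rep(60, n), sex = rep("female", n),
                       bmi = rep(23, n))
  cohort$sbp <- 2 * cohort$daily_sodium
  sl <- subgroup_slopes(cohort, rep(TRUE, n), trait = "sbp")
  car <- sl[sl$group == "carrier", ]
  expect_equal(car$beta, 2, tolerance = 1e-10)
  expect_lt(car$p, 1e-12)
  expect_true(sl$untestable[sl$group == "non_carrier"])  # empty subgroup

  # generative recovery of a carrier slope of 0.093 at replication scale
  cfg <- sim_config(n_subjects = 4241, n_variants = 1, causal_index = 1,
                    maf = sqrt(0.55), coding_model = "recessive",
                    beta_E = 0.042, beta_GE = 0.093 - 0.042, seed = 41)
  cc <- gen_cohort(cfg, site = "replication")
  prep <- prepare_cohort(cc$cohort)$cohort
  G <- code_genotype(cc$genotypes$hard[1, ], model = "recessive")
  G <- G[match(prep$subject_id, cc$genotypes$samples)]
  sl <- subgroup_slopes(prep, G == 1, trait = "sbp")
  car <- sl[sl$group == "carrier", ]
  expect_lt(abs(car$beta - 0.093), 2 * car$se)
  non <- sl[sl$group == "non_carrier", ]
  expect_lt(abs(non$beta - 0.042), 2 * non$se)
})

test_that("sodium permuted within subgroup gives uniform slope p-values", {
  set.seed(42)
  n <- 150
  base <- data.frame(age = rnorm(n, 60, 10), sex = rep("female", n),
                     bmi = rnorm(n, 23, 3), sbp = rnorm(n, 128, 18))
  sodium <- rnorm(n, 165, 38)
  ps <- vapply(1:200, function(i) {
    base$daily_sodium <- sample(sodium)
    sl <- subgroup_slopes(base, rep(TRUE, n), trait = "sbp")
    sl$p[sl$group == "carrier"]
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("tertile table partitions the cohort and handles boundary ties", {
  sodium <- c(rep(100, 4), rep(150, 4), rep(200, 4))
  cohort <- data.frame(daily_sodium = sodium, sbp = rnorm(12, 128, 5),
                       age = rnorm(12, 60, 5), sex = "female", bmi = 23)
  tab <- tertile_table(cohort, trait = "sbp")
  expect_equal(sum(tab$n), 12)
  # duplicated boundary values all land in the lower tertile
  b <- attr(tab, "boundaries")
  expect_equal(tab$n[tab$tertile == "T1"], sum(sodium <= b$mEq_day[1]))
  expect_error(tertile_table(data.frame(daily_sodium = c(1, 1, 2),
                                        sbp = 1:3), trait = "sbp"),
               "distinct")
  # boundary mg/day uses the clinical conversion: 147.5 -> 3,393
  expect_equal(round_half_up(convert_sodium_units(147.5, "mEq/day",
                                                  "mg/day")), 3393)
})

test_that("tertile differences are null when trait is independent of sodium, and shift-invariant", {
  set.seed(43)
  n <- 900
  cohort <- data.frame(daily_sodium = rnorm(n, 165, 38),
                       sbp = rnorm(n, 128, 18), age = rnorm(n, 60, 10),
                       sex = sample(c("female", "male"), n, TRUE),
                       bmi = rnorm(n, 23, 3))
  tab <- tertile_table(cohort, trait = "sbp")
  hi <- tab[tab$tertile == "T3", ]
  expect_lt(abs(hi$mean_diff), 3 * hi$sd * sqrt(2 / hi$n))
  expect_equal(tab$mean_diff[tab$tertile == "T1"], 0)
  # adding a constant shifts means, leaves differences and p identical
  c2 <- cohort; c2$sbp <- c2$sbp + 100
  t2 <- tertile_table(c2, trait = "sbp")
  expect_equal(t2$mean_diff, tab$mean_diff, tolerance = 1e-10)
  expect_equal(t2$p, tab$p, tolerance = 1e-10)
  expect_equal(t2$mean, tab$mean + 100, tolerance = 1e-10)
})

test_that("a generated carrier high-low contrast of ~5.9 mm Hg is recovered", {
  # slope chosen so the expected T3-T1 adjusted difference is 5.9 mm Hg:
  # for Normal sodium the outer-tertile mean gap is about 2.18 sigma
  slope <- 5.9 / (2.18 * 37.9)
  cfg <- sim_config(n_subjects = 2173, n_variants = 1, causal_index = 1,
                    maf = sqrt(0.999), coding_model = "recessive",
                    beta_E = 0, beta_GE = slope, seed = 44)
  cc <- gen_cohort(cfg)   # ~everyone a "carrier" with slope `slope`
  prep <- prepare_cohort(cc$cohort)$cohort
  tab <- tertile_table(prep, trait = "sbp")
  hi <- tab[tab$group == "all" & tab$tertile == "T3", ]
  se_approx <- sqrt(2) * 17.5 / sqrt(hi$n)
  expect_lt(abs(hi$mean_diff - 5.9), 2.5 * se_approx)
})

test_that("sensitivity modes are no-ops or exact count reductions as appropriate", {
  cc <- gen_cohort(sim_config(n_subjects = 800, n_variants = 1, seed = 45,
                              med_prop = 0))
  prep <- prepare_cohort(cc$cohort)$cohort
  flag <- runif(nrow(prep)) < 0.5
  primary <- subgroup_slopes(prep, flag, "sbp")
  # no medicated subjects: measured-BP mode identical to primary
  sens <- sensitivity_rerun(prep, flag, "sbp", mode = "measured_bp")
  expect_equal(sens$slopes, primary)
  expect_equal(sens$n, nrow(prep))

  cc2 <- gen_cohort(sim_config(n_subjects = 800, n_variants = 1, seed = 46))
  prep2 <- prepare_cohort(cc2$cohort)$cohort
  flag2 <- runif(nrow(prep2)) < 0.5
  sens2 <- sensitivity_rerun(prep2, flag2, "sbp", mode = "drop_medicated")
  expect_equal(sens2$n, sum(!prep2$on_antihypertensive))
  sens3 <- sensitivity_rerun(prep2, flag2, "sbp", mode = "drop_hypertensive")
  expect_equal(sens3$n, sum(!prep2$hypertension))
})

test_that("sensitivity modes recover the same interaction when it is independent of medication", {
  cfg <- sim_config(n_subjects = 3000, n_variants = 1, causal_index = 1,
                    maf = sqrt(0.5), coding_model = "recessive",
                    beta_GE = 0.12, seed = 47)
  cc <- gen_cohort(cfg)
  prep <- prepare_cohort(cc$cohort)$cohort
  G <- code_genotype(cc$genotypes$hard[1, ], model = "recessive")
  G <- G[match(prep$subject_id, cc$genotypes$samples)]
  primary <- subgroup_slopes(prep, G == 1, "sbp")
  pc <- primary[primary$group == "carrier", ]
  for (mode in c("measured_bp", "drop_medicated")) {
    sens <- sensitivity_rerun(prep, G == 1, "sbp", mode = mode)
    sc <- sens$slopes[sens$slopes$group == "carrier", ]
    expect_lt(abs(sc$beta - pc$beta), 2 * sqrt(sc$se^2 + pc$se^2) + 1e-9)
  }
})
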