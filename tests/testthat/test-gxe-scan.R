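test_that("genotype coding matches expectation and argmax rules", {
  post <- rbind(c(0.1, 0.7, 0.2))
  expect_equal(code_genotype(posteriors = post, model = "dosage"), 1.1)
  expect_equal(code_genotype(posteriors = post, model = "additive"), 1)
  # recessive coding of the reference-homozygote class (e.g. GG vs AG/AA)
  hard <- c(0, 1, 2)  # 0 = ref hom
  expect_equal(code_genotype(hard, model = "recessive",
                             coded_allele = "ref"), c(1, 0, 0))
  expect_equal(code_genotype(hard, model = "dominant"), c(0, 1, 1))
  expect_equal(code_genotype(hard, model = "recessive"), c(0, 0, 1))
  # dominant and recessive coincide when no heterozygotes exist
  hh <- c(0, 2, 2, 0)
  expect_equal(code_genotype(hh, model = "dominant"),
               code_genotype(hh, model = "recessive"))
  # posterior tie broken toward the lower genotype class, flagged
  tie <- rbind(c(0.4, 0.4, 0.2))
  coded <- code_genotype(posteriors = tie, model = "additive")
  expect_equal(as.numeric(coded), 0)
  expect_true(attr(coded, "ties"))
  expect_error(code_genotype(posteriors = rbind(c(0.5, 0.2, 0.2)),
                             model = "additive"), "sum to 1")
})

test_that("interaction LRT matches the closed-form OLS oracle on a worked dataset", {
  G <- c(0, 1, 2, 0, 1, 2, 1, 0)
  E <- c(120, 150, 180, 200, 140, 160, 130, 170)
  BP <- c(118, 125, 141, 132, 122, 150, 119, 128)
  rec <- fit_interaction_lrt(G, E, BP)
  X1 <- cbind(1, G, E)
  X2 <- cbind(X1, G * E)
  o1 <- ols_oracle(X1, BP)
  o2 <- ols_oracle(X2, BP)
  expect_equal(rec$lrt_stat, 8 * log(o1$rss / o2$rss), tolerance = 1e-10)
  expect_equal(rec$beta_GE, unname(o2$beta[4]), tolerance = 1e-10)
  expect_equal(rec$se_GE, unname(o2$se[4]), tolerance = 1e-10)
  expect_equal(rec$p_raw, pchisq(rec$lrt_stat, 1, lower.tail = FALSE))
  expect_equal(rec$n_used, 8)
  # optional 2-df joint test nests the 1-df one
  rj <- fit_interaction_lrt(G, E, BP, joint = TRUE)
  o0 <- ols_oracle(cbind(1, E), BP)
  expect_equal(rj$lrt_joint, 8 * log(o0$rss / o2$rss), tolerance = 1e-10)
  expect_gte(rj$lrt_joint, rj$lrt_stat - 1e-12)
  expect_equal(rj$p_joint, pchisq(rj$lrt_joint, 2, lower.tail = FALSE))
})

test_that("degenerate designs are flagged untestable, not errors", {
  set.seed(20)
  n <- 50
  G <- rbinom(n, 2, 0.4); BP <- rnorm(n, 120, 10)
  # constant exposure makes G x E collinear with G
  rec <- fit_interaction_lrt(G, rep(150, n), BP)
  expect_true(rec$untestable)
  # constant genotype
  rec <- fit_interaction_lrt(rep(1, n), rnorm(n, 160, 30), BP)
  expect_true(rec$untestable)
  # too few observations
  rec <- fit_interaction_lrt(c(0, 1, 2), c(1, 2, 3), c(1, 2, 3))
  expect_true(rec$untestable)
})

test_that("LRT is invariant to affine rescaling of exposure and covariates", {
  set.seed(21)
  n <- 500
  G <- rbinom(n, 2, 0.3)
  E <- rnorm(n, 165, 38)
  Z <- cbind(age = rnorm(n, 59, 12), bmi = rnorm(n, 23.6, 3.6))
  BP <- 120 + 0.05 * E + 0.04 * G * E + 0.3 * Z[, 1] + rnorm(n, 0, 15)
  a <- fit_interaction_lrt(G, E, BP, Z)
  b <- fit_interaction_lrt(G, (E - 164.8) / 37.9, BP,
                           cbind(10 * Z[, 1] - 3, Z[, 2] / 5))
  expect_equal(a$lrt_stat, b$lrt_stat, tolerance = 1e-10)
  expect_equal(a$p_raw, b$p_raw, tolerance = 1e-10)
  expect_equal(b$beta_GE, a$beta_GE * 37.9, tolerance = 1e-8)
})

test_that("Wald and LRT statistics agree asymptotically", {
  set.seed(22)
  n <- 2000
  G <- rbinom(n, 2, 0.3)
  E <- rnorm(n, 165, 38)
  BP <- 120 + 0.04 * E + 0.06 * G * E + rnorm(n, 0, 17)
  rec <- fit_interaction_lrt(G, E, BP)
  wald <- (rec$beta_GE / rec$se_GE)^2
  expect_lt(abs(wald - rec$lrt_stat) / rec$lrt_stat, 0.1)
})

test_that("permuted genotypes reject at the nominal rate", {
  set.seed(23)
  n <- 500
  G0 <- rbinom(n, 2, 0.3)
  # fresh null outcome per refit so the binomial envelope is valid
  hits <- vapply(1:1000, function(i) {
    E <- rnorm(n, 165, 38)
    BP <- 120 + 0.04 * E + rnorm(n, 0, 17)
    fit_interaction_lrt(sample(G0), E, BP)$p_raw < 0.05
  }, logical(1))
  envelope <- 1.96 * sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(mean(hits) - 0.05), envelope + 1e-9)
})

test_that("genome scan applies per-model frequency filters and finds planted signals", {
  cc <- make_test_cohort(n = 800, n_variants = 40, seed = 24,
                         maf = c(rep(0.05, 20), rep(0.4, 20)))
  # hom-alt frequency ~0.0025 for the first 20 variants: recessive filter drops them
  dos <- genome_scan(cc$cohort, cc$genotypes, model = "dosage",
                     trait = "sbp")
  rec <- genome_scan(cc$cohort, cc$genotypes, model = "recessive",
                     trait = "sbp")
  expect_true(all(cc$genotypes$variants$id[1:20] %in% dos$variant_id))
  expect_false(any(cc$genotypes$variants$id[1:20] %in% rec$variant_id))
  expect_error(genome_scan(cc$cohort, cc$genotypes, trait = "nope"),
               "nope")

  # planted interaction ranks first
  top <- vapply(1:20, function(s) {
    sim <- make_test_cohort(n = 500, n_variants = 25, seed = 100 + s,
                            causal_index = 13, coding_model = "additive",
                            beta_GE = 0.2)
    sc <- genome_scan(sim$cohort, sim$genotypes, model = "additive",
                      trait = "sbp")
    sc$variant_id[which.max(sc$lrt_stat)] == "var0013"
  }, logical(1))
  expect_gte(mean(top), 0.95)
})

test_that("genomic control matches direct quantile arithmetic and floors lambda", {
  recs <- data.frame(variant_id = c("a", "b", "c"),
                     lrt_stat = c(1, 2, 3), p_raw = NA, p_gc = NA,
                     untestable = FALSE)
  suppressWarnings(g <- genomic_control(recs))
  expect_equal(g$lambda, 2 / 0.4549364, tolerance = 1e-6)
  expect_equal(g$records$p_gc,
               pchisq(c(1, 2, 3) / g$lambda, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # calibrated null: statistics at the chi-square median -> lambda 1, p unchanged
  null <- data.frame(variant_id = "x", lrt_stat = 0.45493642311957283031,
                     p_raw = 0.5, p_gc = NA, untestable = FALSE)
  suppressWarnings(g0 <- genomic_control(null))
  expect_equal(g0$lambda, 1, tolerance = 1e-12)
  expect_equal(g0$records$p_gc, g0$records$p_raw, tolerance = 1e-12)
  # deflation is floored: lambda < 1 leaves statistics unchanged
  defl <- data.frame(variant_id = letters[1:3], lrt_stat = c(0.1, 0.2, 0.3),
                     p_raw = pchisq(c(0.1, 0.2, 0.3), 1, lower.tail = FALSE),
                     p_gc = NA, untestable = FALSE)
  suppressWarnings(gd <- genomic_control(defl))
  expect_lt(gd$lambda, 1)
  expect_equal(gd$records$p_gc, gd$records$p_raw, tolerance = 1e-12)
  expect_error(genomic_control(data.frame(lrt_stat = 1, untestable = TRUE)),
               "no testable")
})

test_that("two-stage evaluation applies the staged gates in order", {
  mk <- function(p, b, id = "rs1", model = "recessive")
    data.frame(variant_id = id, coding_model = model, beta_GE = b,
               p_raw = p, p_gc = p, stringsAsFactors = FALSE)
  # strong three-stage signal with consistent negative betas
  d <- two_stage_evaluate(mk(4.7e-6, -0.064), mk(4.1e-4, -0.049),
                          mk(4.3e-9, -0.056))
  expect_equal(d$status, "genome_wide")
  expect_true(d$direction_consistent)
  # flipped replication sign: suggestive only
  d <- two_stage_evaluate(mk(2e-6, -0.064), mk(4.1e-4, 0.049),
                          mk(4.3e-9, -0.056))
  expect_equal(d$status, "suggestive")
  # discovery above the suggestive gate: none, regardless of replication
  d <- two_stage_evaluate(mk(2e-5, -0.064), mk(1e-6, -0.049),
                          mk(1e-12, -0.056))
  expect_equal(d$status, "none")
  # replication above 0.05: suggestive only
  d <- two_stage_evaluate(mk(2e-6, -0.064), mk(0.06, -0.049),
                          mk(1e-12, -0.056))
  expect_equal(d$status, "suggestive")
  # combined above 5e-8: replicated only
  d <- two_stage_evaluate(mk(2e-6, -0.064), mk(0.01, -0.049),
                          mk(1e-7, -0.056))
  expect_equal(d$status, "replicated")
  expect_error(two_stage_evaluate(mk(1e-6, 1), mk(0.01, 1, id = "rs2"),
                                  mk(1e-9, 1)), "variant ids")
})
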