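# Independent oracles used across tests.

# Direct enumeration oracle for the HWE exact test: log-factorial formula for
# the conditional probability of each heterozygote count given allele counts,
# normalised by direct summation (no recurrence).
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  na <- 2 * n_hom_ref + n_het
  nb <- 2 * n_hom_alt + n_het
  n <- n_hom_ref + n_het + n_hom_alt
  hs <- seq(min(na, nb) %% 2, min(na, nb), by = 2)
  lp <- vapply(hs, function(k) {
    a <- (na - k) / 2
    b <- (nb - k) / 2
    k * log(2) + lgamma(n + 1) - lgamma(a + 1) - lgamma(k + 1) - lgamma(b + 1)
  }, numeric(1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  min(sum(p[p <= p[match(n_het, hs)] * (1 + 1e-12)]), 1)
}

# Closed-form OLS oracle: solves the normal equations explicitly and returns
# RSS, coefficients and coefficient SEs.
ols_oracle <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  rss <- sum(res^2)
  sigma2 <- rss / (length(y) - ncol(X))
  list(beta = drop(beta), rss = rss,
       se = sqrt(diag(solve(XtX)) * sigma2))
}

# small analysis-ready cohort for scan tests
make_test_cohort <- function(n = 400, n_variants = 30, seed = 42, ...) {
  cc <- gen_cohort(sim_config(n_subjects = n, n_variants = n_variants,
                              seed = seed, ...))
  prep <- prepare_cohort(cc$cohort)
  list(cohort = prep$cohort,
       genotypes = subset_genotypes(
         cc$genotypes, samples = match(prep$cohort$subject_id,
                                       cc$genotypes$samples)))
}
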