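#' Simulation configuration for synthetic cohorts
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults emulate a
#' population-based Japanese cohort: daily sodium ~ Normal(164.8, 37.9)
#' mEq/day, age ~ Normal(59.0, 11.8) years, BMI ~ Normal(23.6, 3.6) kg/m2,
#' 66.4% female, 23.7% on antihypertensive medication, SBP marginal mean
#' 128.2 mm Hg. \code{resid_sd} is the residual SD of covariate-adjusted
#' blood pressure (default 17.2 mm Hg for SBP, 10.9 for DBP; see the
#' methods vignette for the derivation); an age effect on the modelled
#' trait brings the marginal SD to the observed ~19.2 mm Hg.
#'
#' @param n_subjects,n_variants counts.
#' @param maf per-variant alternate-allele frequency in (0,1); scalar
#'   recycled to \code{n_variants}.
#' @param causal_index index of the causal variant, or NULL for a pure null.
#' @param beta0 intercept, mm Hg; NULL = chosen so the marginal trait mean
#'   matches \code{trait_mean}.
#' @param beta_G mm Hg per coded genotype unit.
#' @param beta_E mm Hg per mEq/day of sodium.
#' @param beta_GE interaction, mm Hg per (coded unit x mEq/day).
#' @param mu_Na,sigma_Na sodium mean and SD, mEq/day.
#' @param resid_sd residual SD of the modelled trait, mm Hg.
#' @param coding_model coding of the causal genotype: dosage, additive,
#'   dominant or recessive.
#' @param coded_allele which allele the causal coding counts.
#' @param imputation_quality target dosage-vs-truth R-squared in (0, 1].
#' @param trait which trait carries the genetic model ("sbp" or "dbp").
#' @param trait_mean marginal mean of the modelled trait, mm Hg.
#' @param beta_age,beta_sex,beta_bmi covariate effects on the modelled trait
#'   (age default 0.71 mm Hg/year for SBP so the marginal SD matches the
#'   observed one; sex and BMI default 0).
#' @param site_offsets named list of replication-site mean shifts
#'   (\code{age}, \code{sodium}, \code{bp}), defaults matching the observed
#'   discovery/replication contrasts.
#' @param age_mean,age_sd,bmi_mean,bmi_sd,female_prop,med_prop covariate
#'   distributions.
#' @param n_pcs number of principal-component covariates (iid standard
#'   normal, no effect on BP).
#' @param measurement_sd SD of the per-measurement device noise, mm Hg.
#' @param seed integer RNG seed.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_subjects = 4527, n_variants = 100, maf = 0.2,
                       causal_index = NULL, beta0 = NULL, beta_G = 0,
                       beta_E = 0.041426, beta_GE = 0,
                       mu_Na = 164.8, sigma_Na = 37.9, resid_sd = NULL,
                       coding_model = c("additive", "dosage", "dominant",
                                        "recessive"),
                       coded_allele = c("alt", "ref"),
                       imputation_quality = 1.0,
                       trait = c("sbp", "dbp"), trait_mean = NULL,
                       beta_age = NULL, beta_sex = 0, beta_bmi = 0,
                       site_offsets = list(age = 3.6, sodium = 11.8,
                                           bp = 3.3),
                       age_mean = 59.0, age_sd = 11.8,
                       bmi_mean = 23.6, bmi_sd = 3.6,
                       female_prop = 0.664, med_prop = 0.237,
                       n_pcs = 20, measurement_sd = 2, seed = 1) {
  coding_model <- match.arg(coding_model)
  coded_allele <- match.arg(coded_allele)
  trait <- match.arg(trait)
  if (is.null(resid_sd)) resid_sd <- if (trait == "sbp") 17.2 else 10.9
  if (is.null(trait_mean)) trait_mean <- if (trait == "sbp") 128.2 else 76.7
  if (is.null(beta_age)) beta_age <- if (trait == "sbp") 0.71 else 0.40
  maf <- rep_len(maf, n_variants)
  stopifnot(n_subjects >= 1, n_variants >= 0,
            sigma_Na > 0, resid_sd > 0,
            imputation_quality > 0, imputation_quality <= 1)
  if (!is.null(causal_index) &&
      (causal_index < 1 || causal_index > n_variants))
    stop("causal_index out of range [1, ", n_variants, "]")
  structure(list(
    n_subjects = as.integer(n_subjects), n_variants = as.integer(n_variants),
    maf = maf, causal_index = causal_index, beta0 = beta0, beta_G = beta_G,
    beta_E = beta_E, beta_GE = beta_GE, mu_Na = mu_Na, sigma_Na = sigma_Na,
    resid_sd = resid_sd, coding_model = coding_model,
    coded_allele = coded_allele, imputation_quality = imputation_quality,
    trait = trait, trait_mean = trait_mean, beta_age = beta_age,
    beta_sex = beta_sex, beta_bmi = beta_bmi, site_offsets = site_offsets,
    age_mean = age_mean, age_sd = age_sd, bmi_mean = bmi_mean,
    bmi_sd = bmi_sd, female_prop = female_prop, med_prop = med_prop,
    n_pcs = as.integer(n_pcs), measurement_sd = measurement_sd,
    seed = as.integer(seed)), class = "sim_config")
}

#' Container for per-variant genotype data
#'
#' Variants in rows, subjects in columns. \code{dosage} is the posterior
#' expected alternate-allele count, \code{p0}/\code{p1}/\code{p2} the
#' genotype posteriors, \code{hard} the best-guess genotype (0/1/2 alternate
#' alleles, NA allowed), \code{variants} the metadata table (id, chrom, pos,
#' ref, alt, r2).
#'
#' @param dosage,p0,p1,p2,hard matrices of identical dimension.
#' @param variants data.frame with one row per variant.
#' @param samples character vector of subject ids.
#' @return object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(dosage, p0, p1, p2, hard, variants, samples) {
  dims <- dim(dosage)
  for (m in list(p0, p1, p2, hard))
    stopifnot(identical(dim(m), dims))
  stopifnot(nrow(variants) == dims[1], length(samples) == dims[2])
  structure(list(dosage = dosage, p0 = p0, p1 = p1, p2 = p2, hard = hard,
                 variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$variants), "variants x",
      length(x$samples), "subjects\n")
  invisible(x)
}

#' Generate genotypes under Hardy-Weinberg equilibrium with imputation noise
#'
#' True genotypes are Binomial(2, maf) per variant. When
#' \code{imputation_quality < 1}, a per-subject leak probability moves the
#' observed genotype class to an adjacent class and spreads posterior mass
#' symmetrically around it; the leak is calibrated per variant by bisection
#' (with common random numbers) so the realised dosage-vs-truth R-squared
#' matches the target. Dosage is always the posterior expectation.
#'
#' @param config a [sim_config]. Identical config (incl. seed) gives
#'   bit-identical output.
#' @return a [genotype_matrix]; \code{variants$r2} records the realised
#'   dosage-vs-truth R-squared and \code{variants$true_geno} holds the
#'   underlying truth for validation.
#' @export
gen_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gen_genotypes_stream(config)
}

# draws from the current RNG stream (callable mid-stream from gen_cohort)
gen_genotypes_stream <- function(config) {
  n <- config$n_subjects
  v <- config$n_variants
  bad <- which(!is.finite(config$maf) | config$maf <= 0 | config$maf >= 1)
  if (length(bad))
    stop("maf out of (0,1) for variant(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  dosage <- p0 <- p1 <- p2 <- hard <- matrix(NA_real_, v, n)
  truth <- matrix(NA_integer_, v, n)
  r2_real <- numeric(v)
  for (i in seq_len(v)) {
    g <- stats::rbinom(n, 2, config$maf[i])
    truth[i, ] <- g
    if (config$imputation_quality >= 1 || stats::var(g) == 0) {
      p0[i, ] <- as.numeric(g == 0)
      p1[i, ] <- as.numeric(g == 1)
      p2[i, ] <- as.numeric(g == 2)
      dosage[i, ] <- g
      hard[i, ] <- g
      r2_real[i] <- if (stats::var(g) == 0) NA_real_ else 1
    } else {
      u_leak <- stats::runif(n)
      u_side <- stats::runif(n)
      noisy <- function(lam) {
        gs <- g
        leak <- u_leak < lam
        gs[leak & g == 0] <- 1L
        gs[leak & g == 2] <- 1L
        het <- leak & g == 1
        gs[het] <- ifelse(u_side[het] < 0.5, 0L, 2L)
        gs
      }
      dos_of <- function(lam) {
        gs <- noisy(lam)
        ifelse(gs == 1, 1, ifelse(gs == 0, lam, 2 - lam))
      }
      r2_of <- function(lam) {
        d <- dos_of(lam)
        if (stats::var(d) == 0) 0 else stats::cor(d, g)^2
      }
      lo <- 0; hi <- 0.999
      for (k in 1:40) {
        mid <- (lo + hi) / 2
        if (r2_of(mid) > config$imputation_quality) lo <- mid else hi <- mid
      }
      lam <- (lo + hi) / 2
      gs <- noisy(lam)
      p0[i, ] <- ifelse(gs == 0, 1 - lam, ifelse(gs == 1, lam / 2, 0))
      p1[i, ] <- ifelse(gs == 1, 1 - lam, lam)
      p2[i, ] <- ifelse(gs == 2, 1 - lam, ifelse(gs == 1, lam / 2, 0))
      dosage[i, ] <- p1[i, ] + 2 * p2[i, ]
      hard[i, ] <- gs
      r2_real[i] <- r2_of(lam)
    }
  }
  ids <- sprintf("var%04d", seq_len(max(v, 1))[seq_len(v)])
  samples <- sprintf("S%05d", seq_len(n))
  variants <- data.frame(
    id = ids, chrom = rep(1L, v), pos = seq_len(v) * 1000L,
    ref = rep("A", v), alt = rep("G", v),
    maf_target = config$maf, r2 = r2_real,
    stringsAsFactors = FALSE)
  variants$true_geno <- I(lapply(seq_len(v), function(i) truth[i, ]))
  dimnames(dosage) <- dimnames(p0) <- dimnames(p1) <- dimnames(p2) <-
    dimnames(hard) <- list(ids, samples)
  genotype_matrix(dosage, p0, p1, p2, hard, variants, samples)
}

#' Generate a full synthetic cohort
#'
#' Draws genotypes (see [gen_genotypes]), covariates and sodium exposure,
#' and builds blood pressure from the linear interaction model
#' \deqn{BP = \beta_0 + \beta_G G + \beta_E E + \beta_{GE} G E +
#'   covariates + \epsilon,\ \epsilon \sim N(0, resid\_sd^2)}
#' with G the coded genotype at the causal variant (0 everywhere when
#' \code{causal_index} is NULL). Two raw measurements per trait are emitted;
#' medicated subjects' measured BP is lowered by 10/5 mm Hg (SBP/DBP), the
#' treatment effect that [prepare_bp] re-imputes. The non-modelled trait is
#' drawn from its marginal null distribution.
#'
#' @param config a [sim_config].
#' @param site "discovery" or "replication"; the replication site applies
#'   \code{config$site_offsets} to the age, sodium and BP means.
#' @return list with \code{cohort} (data.frame) and \code{genotypes}
#'   (a [genotype_matrix]).
#' @export
gen_cohort <- function(config, site = c("discovery", "replication")) {
  stopifnot(inherits(config, "sim_config"))
  site <- match.arg(site)
  set.seed(config$seed)
  genotypes <- gen_genotypes_stream(config)
  n <- config$n_subjects

  off <- if (site == "replication") config$site_offsets
         else list(age = 0, sodium = 0, bp = 0)
  age <- stats::rnorm(n, config$age_mean + off$age, config$age_sd)
  sex <- ifelse(stats::runif(n) < config$female_prop, "female", "male")
  bmi <- stats::rnorm(n, config$bmi_mean, config$bmi_sd)
  height <- stats::rnorm(n, 158, 8)
  weight <- bmi * (height / 100)^2
  E <- stats::rnorm(n, config$mu_Na + off$sodium, config$sigma_Na)
  med <- stats::runif(n) < config$med_prop
  pcs <- matrix(stats::rnorm(n * config$n_pcs), n, config$n_pcs)
  if (config$n_pcs > 0) colnames(pcs) <- paste0("pc", seq_len(config$n_pcs))

  G <- rep(0, n)
  if (!is.null(config$causal_index)) {
    ci <- config$causal_index
    G <- code_genotype(genotypes$hard[ci, ],
                       posteriors = cbind(genotypes$p0[ci, ],
                                          genotypes$p1[ci, ],
                                          genotypes$p2[ci, ]),
                       model = config$coding_model,
                       coded_allele = config$coded_allele)
  }
  beta0 <- config$beta0
  if (is.null(beta0))
    beta0 <- config$trait_mean + off$bp -
      config$beta_E * (config$mu_Na + off$sodium) -
      config$beta_age * (config$age_mean + off$age) -
      config$beta_bmi * config$bmi_mean -
      config$beta_sex * (1 - config$female_prop)
  bp_true <- beta0 + config$beta_G * G + config$beta_E * E +
    config$beta_GE * G * E +
    config$beta_age * age + config$beta_bmi * bmi +
    config$beta_sex * (sex == "male") +
    stats::rnorm(n, 0, config$resid_sd)

  other_mean <- if (config$trait == "sbp") 76.7 else 128.2
  other_sd <- if (config$trait == "sbp") 11.9 else 19.2
  other_true <- stats::rnorm(n, other_mean + if (config$trait == "dbp")
    off$bp else 0, other_sd)
  sbp_true <- if (config$trait == "sbp") bp_true else other_true
  dbp_true <- if (config$trait == "sbp") other_true else bp_true

  meas <- function(x, drop) {
    cbind(x - drop + stats::rnorm(n, 0, config$measurement_sd),
          x - drop + stats::rnorm(n, 0, config$measurement_sd))
  }
  sbp_m <- meas(sbp_true, ifelse(med, 10, 0))
  dbp_m <- meas(dbp_true, ifelse(med, 5, 0))

  cohort <- data.frame(
    subject_id = genotypes$samples,
    age = age, sex = sex, bmi = bmi,
    height = height, weight = weight,
    sbp_raw_1 = sbp_m[, 1], sbp_raw_2 = sbp_m[, 2],
    dbp_raw_1 = dbp_m[, 1], dbp_raw_2 = dbp_m[, 2],
    on_antihypertensive = med,
    daily_sodium = E,
    site = site,
    stringsAsFactors = FALSE)
  cohort <- cbind(cohort, pcs)
  list(cohort = cohort, genotypes = genotypes)
}

#' Emit spot-urine analytes consistent with a daily sodium target
#'
#' Inverts the spot-urine estimator: given each subject's daily sodium (and
#' age/height/weight for the predicted creatinine), draws a plausible spot
#' creatinine and solves for the spot sodium such that
#' [estimate_daily_sodium] recovers the (optionally noise-perturbed) target.
#' \code{noise_sd} is the log-scale SD of multiplicative noise applied to
#' the target before inversion, so the estimator's output is
#' \code{daily_sodium * exp(N(0, noise_sd^2))}.
#'
#' @param cohort data.frame with \code{daily_sodium}, \code{age},
#'   \code{height}, \code{weight}.
#' @param formula a [sodium_formula]; defaults to [tanaka_coefficients()].
#' @param noise_sd log-scale noise SD (0 = exact round trip).
#' @param seed RNG seed for creatinine and noise draws.
#' @return the cohort with \code{spot_urine_na} and \code{spot_urine_cr}
#'   columns added.
#' @export
gen_spot_urine <- function(cohort, formula = tanaka_coefficients(),
                           noise_sd = 0, seed = 1) {
  stopifnot(inherits(formula, "sodium_formula"))
  req <- c("daily_sodium", "age", "height", "weight")
  if (!all(req %in% names(cohort)))
    stop("cohort lacks column(s): ",
         paste(setdiff(req, names(cohort)), collapse = ", "))
  if (any(!is.finite(cohort$daily_sodium)))
    stop("daily_sodium must be present and finite for all subjects")
  pr_cr <- predicted_creatinine(formula, cohort$age, cohort$weight,
                                cohort$height)
  if (any(!is.finite(pr_cr) | pr_cr <= 0))
    stop("formula coefficients give non-positive predicted creatinine; ",
         "inversion is not monotone")
  set.seed(seed)
  n <- nrow(cohort)
  target <- cohort$daily_sodium
  if (noise_sd > 0) target <- target * exp(stats::rnorm(n, 0, noise_sd))
  spot_cr <- exp(stats::rnorm(n, log(100), 0.4))  # ~ typical spot creatinine
  ratio <- (target / formula$scale)^(1 / formula$exponent) / pr_cr
  cohort$spot_urine_cr <- spot_cr
  cohort$spot_urine_na <- ratio * spot_cr * formula$cr_unit_factor
  cohort
}
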