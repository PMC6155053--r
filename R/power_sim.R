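#' Specification of one power-simulation cell
#'
#' Parameters of the Monte-Carlo power calculation for the 1-df
#' interaction likelihood-ratio test. The generative model is
#' \eqn{BP = \beta_E E + \beta_{GE} G E + N(0, resid\_sd^2)} with
#' \eqn{E \sim N(\mu_{Na}, \sigma_{Na}^2)} and G drawn Binomial(2, freq)
#' under the additive model or Bernoulli(freq) under the dominant/recessive
#' (carrier/homozygote) coding. Trait defaults: \code{beta_E} 0.041426
#' (SBP) / 0.019897 (DBP) mm Hg per mEq/day; \code{resid_sd} is the SD of
#' age-, sex-, BMI-adjusted BP, default 17.2 (SBP) / 10.9 (DBP) mm Hg (see
#' the methods vignette for how these are reconstructed).
#'
#' @param n subjects per simulated cohort (default 4,527).
#' @param trait "sbp" or "dbp" (sets \code{beta_E}/\code{resid_sd} defaults).
#' @param mu_Na,sigma_Na sodium mean/SD, mEq/day (defaults 164.8 / 37.9).
#' @param beta_E main sodium effect, mm Hg per mEq/day.
#' @param beta_GE_ratio interaction effect as a multiple of \code{beta_E}.
#' @param model genetic model ("additive", "dominant" or "recessive").
#' @param freq effect allele frequency (additive) or effect genotype
#'   frequency (dominant/recessive).
#' @param resid_sd residual SD, mm Hg.
#' @param alpha significance threshold (default suggestive, 1e-5).
#' @param iterations Monte-Carlo iterations (default 1,000).
#' @param seed RNG seed.
#' @return object of class \code{power_spec}.
#' @export
power_spec <- function(n = 4527, trait = c("sbp", "dbp"),
                       mu_Na = 164.8, sigma_Na = 37.9, beta_E = NULL,
                       beta_GE_ratio = 2.0,
                       model = c("additive", "dominant", "recessive"),
                       freq = 0.2, resid_sd = NULL, alpha = 1e-5,
                       iterations = 1000, seed = 1) {
  trait <- match.arg(trait)
  model <- match.arg(model)
  if (is.null(beta_E)) beta_E <- if (trait == "sbp") 0.041426 else 0.019897
  if (is.null(resid_sd)) resid_sd <- if (trait == "sbp") 17.2 else 10.9
  stopifnot(alpha > 0, alpha < 1, iterations >= 1, freq > 0, freq < 1,
            sigma_Na > 0, resid_sd > 0, n > 10)
  structure(list(n = as.integer(n), trait = trait, mu_Na = mu_Na,
                 sigma_Na = sigma_Na, beta_E = beta_E,
                 beta_GE_ratio = beta_GE_ratio, model = model, freq = freq,
                 resid_sd = resid_sd, alpha = alpha,
                 iterations = as.integer(iterations),
                 seed = as.integer(seed)),
            class = "power_spec")
}

#' Simulate one cohort and test the interaction once
#'
#' Draws one cohort under the spec's generative model, fits the nested
#' interaction models of [fit_interaction_lrt], and reports whether the
#' interaction term reached \code{spec$alpha}. Draws from the current RNG
#' stream; seed the stream for reproducibility.
#'
#' @param spec a [power_spec].
#' @return logical: was the null of no interaction rejected?
#' @export
simulate_once <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  E <- stats::rnorm(spec$n, spec$mu_Na, spec$sigma_Na)
  G <- if (spec$model == "additive") stats::rbinom(spec$n, 2, spec$freq)
       else stats::rbinom(spec$n, 1, spec$freq)
  beta_GE <- spec$beta_GE_ratio * spec$beta_E
  BP <- spec$beta_E * E + beta_GE * G * E +
    stats::rnorm(spec$n, 0, spec$resid_sd)
  rec <- fit_interaction_lrt(G, E, BP, model = spec$model)
  if (rec$untestable) return(FALSE)
  rec$p_raw < spec$alpha
}

#' Monte-Carlo power with analytic cross-check
#'
#' Power is the fraction of \code{iterations} simulated cohorts whose
#' interaction term is significant at \code{spec$alpha}. The analytic
#' cross-check uses the non-central chi-square 1-df approximation with
#' \eqn{NCP = n \beta_{GE}^2 Var(G) \sigma_{Na}^2 / resid\_sd^2}, where
#' Var(G) is 2f(1-f) for the additive coding and f(1-f) for the Bernoulli
#' codings.
#'
#' @param spec a [power_spec].
#' @return one-row data.frame: the spec fields plus \code{power},
#'   \code{mc_se} and \code{analytic_power}.
#' @export
estimate_power <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  set.seed(spec$seed)
  hits <- vapply(seq_len(spec$iterations), function(i) simulate_once(spec),
                 logical(1))
  p <- mean(hits)
  cbind(as.data.frame(spec[c("n", "trait", "model", "freq", "beta_E",
                             "beta_GE_ratio", "resid_sd", "alpha",
                             "iterations", "seed")]),
        data.frame(power = p,
                   mc_se = sqrt(p * (1 - p) / spec$iterations),
                   analytic_power = analytic_power(spec)))
}

#' @rdname estimate_power
#' @export
analytic_power <- function(spec) {
  var_g <- if (spec$model == "additive") 2 * spec$freq * (1 - spec$freq)
           else spec$freq * (1 - spec$freq)
  beta_GE <- spec$beta_GE_ratio * spec$beta_E
  ncp <- spec$n * beta_GE^2 * var_g * spec$sigma_Na^2 / spec$resid_sd^2
  if (ncp == 0) return(spec$alpha)  # central case: power is alpha exactly
  crit <- stats::qchisq(spec$alpha, df = 1, lower.tail = FALSE)
  stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
}

#' Power over the full parameter grid
#'
#' Cartesian product of trait x model x frequency x effect-size ratio, one
#' [estimate_power] call per cell with a deterministic per-cell seed
#' derived from \code{seed}.
#'
#' @param traits,models,freqs,ratios grid axes (defaults give the standard
#'   2 x 3 x 2 x 4 = 48 cells).
#' @param n,alpha,iterations,seed shared settings (see [power_spec]).
#' @return data.frame with one row per cell.
#' @export
power_grid <- function(traits = c("sbp", "dbp"),
                       models = c("additive", "dominant", "recessive"),
                       freqs = c(0.2, 0.5), ratios = c(0.5, 1.0, 1.5, 2.0),
                       n = 4527, alpha = 1e-5, iterations = 1000, seed = 1) {
  grid <- expand.grid(trait = traits, model = models, freq = freqs,
                      ratio = ratios, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    estimate_power(power_spec(
      n = n, trait = grid$trait[i], model = grid$model[i],
      freq = grid$freq[i], beta_GE_ratio = grid$ratio[i],
      alpha = alpha, iterations = iterations,
      seed = (seed + 977L * i) %% .Machine$integer.max))
  })
  do.call(rbind, res)
}
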