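# covariate design shared by the post-hoc fits: age, sex, BMI by default
posthoc_covariates <- function(cohort, covariates = c("age", "sex", "bmi")) {
  covariates <- intersect(covariates, names(cohort))
  if (!length(covariates)) return(NULL)
  m <- lapply(covariates, function(v) {
    x <- cohort[[v]]
    if (v == "sex") as.numeric(x == "male") else as.numeric(x)
  })
  m <- do.call(cbind, m)
  colnames(m) <- covariates
  m
}

#' Sodium slope within genotype subgroups
#'
#' Within each genotype subgroup (carriers vs non-carriers), regresses the
#' trait on daily sodium with age, sex and BMI adjustment and reports the
#' sodium slope, its standard error and P-value.
#'
#' @param cohort data.frame with the trait, \code{daily_sodium} and the
#'   covariate columns.
#' @param carrier_flag logical vector (TRUE = carrier) aligned with the
#'   cohort, or the name of a logical cohort column.
#' @param trait trait column name.
#' @param covariates adjustment covariate names.
#' @return data.frame with one row per subgroup: \code{group}, \code{n},
#'   \code{beta} (mm Hg per mEq/day), \code{se}, \code{p},
#'   \code{untestable}.
#' @export
subgroup_slopes <- function(cohort, carrier_flag, trait = "sbp",
                            covariates = c("age", "sex", "bmi")) {
  if (is.character(carrier_flag) && length(carrier_flag) == 1L)
    carrier_flag <- cohort[[carrier_flag]]
  stopifnot(length(carrier_flag) == nrow(cohort))
  cov_m <- posthoc_covariates(cohort, covariates)
  out <- lapply(c(FALSE, TRUE), function(g) {
    idx <- which(carrier_flag %in% g)
    sub <- cohort[idx, , drop = FALSE]
    cm <- if (is.null(cov_m)) NULL else cov_m[idx, , drop = FALSE]
    y <- sub[[trait]]
    E <- sub$daily_sodium
    keep <- is.finite(y) & is.finite(E)
    if (!is.null(cm)) keep <- keep & rowSums(!is.finite(cm)) == 0
    n <- sum(keep)
    p_design <- 2L + if (is.null(cm)) 0L else ncol(cm)
    lab <- if (g) "carrier" else "non_carrier"
    if (n <= p_design || stats::var(E[keep]) == 0)
      return(data.frame(group = lab, n = n, beta = NA_real_, se = NA_real_,
                        p = NA_real_, untestable = TRUE))
    X <- cbind(1, E = E[keep], cm[keep, , drop = FALSE])
    fit <- stats::lm.fit(X, y[keep])
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / (n - fit$rank)
    R <- qr.R(fit$qr)
    cu <- matrix(NA_real_, ncol(X), ncol(X))
    piv <- fit$qr$pivot[seq_len(fit$rank)]
    cu[piv, piv] <- chol2inv(R[seq_len(fit$rank), seq_len(fit$rank)])
    se <- sqrt(sigma2 * cu[2, 2])
    beta <- unname(fit$coefficients[2])
    tval <- beta / se
    data.frame(group = lab, n = n, beta = beta, se = se,
               p = 2 * stats::pt(abs(tval), n - fit$rank,
                                 lower.tail = FALSE),
               untestable = FALSE)
  })
  do.call(rbind, out)
}

#' Sodium-tertile summary table
#'
#' Tertile boundaries are computed on the whole cohort (not per genotype
#' subgroup); boundary ties go to the lower tertile. For each subgroup
#' ("all" plus carriers/non-carriers when a flag is given) and tertile the
#' table reports the raw trait mean and SD, and the covariate-adjusted mean
#' difference versus the low tertile with its P-value (from a linear model
#' with tertile indicators plus age, sex, BMI).
#'
#' @inheritParams subgroup_slopes
#' @param carrier_flag optional; NULL gives the whole-cohort table only.
#' @return data.frame with columns \code{group}, \code{tertile}, \code{n},
#'   \code{mean}, \code{sd}, \code{mean_diff}, \code{p}; tertile boundaries
#'   (mEq/day and mg/day) in the \code{"boundaries"} attribute.
#' @export
tertile_table <- function(cohort, carrier_flag = NULL, trait = "sbp",
                          covariates = c("age", "sex", "bmi")) {
  E <- cohort$daily_sodium
  if (length(unique(E[is.finite(E)])) < 3)
    stop("fewer than 3 distinct daily sodium values; cannot form tertiles")
  q <- stats::quantile(E, c(1 / 3, 2 / 3), na.rm = TRUE, names = FALSE)
  tert <- cut(E, breaks = c(-Inf, q, Inf), labels = c("T1", "T2", "T3"),
              right = TRUE)
  if (is.character(carrier_flag) && length(carrier_flag) == 1L)
    carrier_flag <- cohort[[carrier_flag]]

  groups <- list(all = rep(TRUE, nrow(cohort)))
  if (!is.null(carrier_flag)) {
    groups$non_carrier <- carrier_flag %in% FALSE
    groups$carrier <- carrier_flag %in% TRUE
  }
  cov_m <- posthoc_covariates(cohort, covariates)

  rows <- lapply(names(groups), function(gname) {
    idx <- which(groups[[gname]])
    y <- cohort[[trait]][idx]
    tt <- tert[idx]
    cm <- if (is.null(cov_m)) NULL else cov_m[idx, , drop = FALSE]
    keep <- is.finite(y) & !is.na(tt)
    if (!is.null(cm)) keep <- keep & rowSums(!is.finite(cm)) == 0
    y <- y[keep]; tt <- droplevels(tt[keep])
    cm <- if (is.null(cm)) NULL else cm[keep, , drop = FALSE]
    base <- data.frame(group = gname, tertile = c("T1", "T2", "T3"),
                       n = as.integer(table(factor(tt, c("T1", "T2", "T3")))),
                       mean = tapply(y, factor(tt, c("T1", "T2", "T3")),
                                     mean)[c("T1", "T2", "T3")],
                       sd = tapply(y, factor(tt, c("T1", "T2", "T3")),
                                   stats::sd)[c("T1", "T2", "T3")],
                       mean_diff = c(0, NA_real_, NA_real_),
                       p = c(NA_real_, NA_real_, NA_real_),
                       stringsAsFactors = FALSE)
    if (nlevels(tt) == 3L) {
      X <- cbind(1, T2 = as.numeric(tt == "T2"), T3 = as.numeric(tt == "T3"),
                 cm)
      fit <- stats::lm.fit(X, y)
      n <- length(y)
      sigma2 <- sum(fit$residuals^2) / (n - fit$rank)
      R <- qr.R(fit$qr)
      cu <- matrix(NA_real_, ncol(X), ncol(X))
      piv <- fit$qr$pivot[seq_len(fit$rank)]
      cu[piv, piv] <- chol2inv(R[seq_len(fit$rank), seq_len(fit$rank)])
      for (j in 2:3) {
        b <- unname(fit$coefficients[j])
        se <- sqrt(sigma2 * cu[j, j])
        base$mean_diff[j] <- b
        base$p[j] <- 2 * stats::pt(abs(b / se), n - fit$rank,
                                   lower.tail = FALSE)
      }
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "boundaries") <- data.frame(
    boundary = c("T1/T2", "T2/T3"),
    mEq_day = q,
    mg_day = round_half_up(convert_sodium_units(q, "mEq/day", "mg/day")))
  out
}

#' Odds ratio from a 2x2 table (Woolf confidence interval)
#'
#' OR = (a d)/(b c) with the Woolf log-scale standard error
#' sqrt(1/a + 1/b + 1/c + 1/d). A zero cell triggers the Haldane continuity
#' correction (+0.5 to every cell) with a warning.
#'
#' @param a,b,c_,d_ cell counts: a = exposed cases, b = exposed non-cases,
#'   c_ = unexposed cases, d_ = unexposed non-cases.
#' @param conf confidence level.
#' @return data.frame with \code{or}, \code{ci_low}, \code{ci_high},
#'   \code{p} (two-sided normal on the log scale).
#' @export
odds_ratio_woolf <- function(a, b, c_, d_, conf = 0.95) {
  cells <- c(a, b, c_, d_)
  stopifnot(all(is.finite(cells)), all(cells >= 0))
  if (any(cells == 0)) {
    warning("zero cell; applying Haldane continuity correction (+0.5)")
    cells <- cells + 0.5
  }
  a <- cells[1]; b <- cells[2]; c_ <- cells[3]; d_ <- cells[4]
  or <- (a * d_) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d_)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  data.frame(or = or,
             ci_low = exp(log(or) - z * se),
             ci_high = exp(log(or) + z * se),
             p = 2 * stats::pnorm(abs(log(or)) / se, lower.tail = FALSE))
}

#' Hypertension odds ratio for carriers within a sodium stratum
#'
#' Within the requested sodium consumption stratum, compares the odds of
#' hypertension between genotype carriers and non-carriers. The default is
#' the unadjusted 2x2 odds ratio with Woolf CI; \code{adjusted = TRUE}
#' fits a logistic regression with age, sex and BMI and returns the
#' exponentiated carrier coefficient with its Wald CI.
#'
#' @inheritParams subgroup_slopes
#' @param sodium_stratum "low", "high" or "all"; low/high halves are split
#'   at the cohort median (ties to the low stratum) or at the outer
#'   tertiles when \code{split = "tertile"}.
#' @param split "median" or "tertile".
#' @param adjusted use the covariate-adjusted logistic path.
#' @param hypertension_col name of the logical hypertension column.
#' @return data.frame with \code{or}, \code{ci_low}, \code{ci_high},
#'   \code{p}, \code{n}.
#' @export
hypertension_or <- function(cohort, carrier_flag,
                            sodium_stratum = c("low", "high", "all"),
                            split = c("median", "tertile"),
                            adjusted = FALSE,
                            covariates = c("age", "sex", "bmi"),
                            hypertension_col = "hypertension") {
  sodium_stratum <- match.arg(sodium_stratum)
  split <- match.arg(split)
  if (is.character(carrier_flag) && length(carrier_flag) == 1L)
    carrier_flag <- cohort[[carrier_flag]]
  hyp <- cohort[[hypertension_col]]
  if (is.null(hyp)) stop("hypertension column '", hypertension_col,
                         "' not found")
  E <- cohort$daily_sodium
  idx <- switch(sodium_stratum,
    all = rep(TRUE, nrow(cohort)),
    low = if (split == "median") E <= stats::median(E, na.rm = TRUE)
          else E <= stats::quantile(E, 1 / 3, na.rm = TRUE, names = FALSE),
    high = if (split == "median") E > stats::median(E, na.rm = TRUE)
           else E > stats::quantile(E, 2 / 3, na.rm = TRUE, names = FALSE))
  idx <- idx & !is.na(carrier_flag) & !is.na(hyp)
  carrier <- carrier_flag[idx]
  hyp <- hyp[idx]
  n <- sum(idx)

  if (!adjusted) {
    a <- sum(carrier & hyp); b <- sum(carrier & !hyp)
    c_ <- sum(!carrier & hyp); d_ <- sum(!carrier & !hyp)
    res <- odds_ratio_woolf(a, b, c_, d_)
  } else {
    cm <- posthoc_covariates(cohort[idx, , drop = FALSE], covariates)
    dat <- data.frame(hyp = hyp, carrier = as.numeric(carrier))
    if (!is.null(cm)) dat <- cbind(dat, as.data.frame(cm))
    fit <- stats::glm(hyp ~ ., data = dat, family = stats::binomial())
    co <- summary(fit)$coefficients["carrier", ]
    z <- stats::qnorm(0.975)
    res <- data.frame(or = exp(co[1]),
                      ci_low = exp(co[1] - z * co[2]),
                      ci_high = exp(co[1] + z * co[2]),
                      p = unname(co[4]))
  }
  res$n <- n
  rownames(res) <- NULL
  res
}

#' Sensitivity re-run of the stratified analyses
#'
#' Re-derives the analysis blood pressure under one of three sensitivity
#' modes and recomputes the subgroup slopes and tertile table with the same
#' schema as the primary analysis:
#' \itemize{
#'   \item \code{measured_bp}: use measured (non-imputed) BP values;
#'   \item \code{drop_medicated}: exclude subjects on antihypertensive
#'     medication;
#'   \item \code{drop_hypertensive}: exclude hypertensive subjects.
#' }
#'
#' @inheritParams subgroup_slopes
#' @param mode sensitivity mode.
#' @return list with \code{mode}, \code{n}, \code{slopes} (see
#'   [subgroup_slopes]) and \code{tertiles} (see [tertile_table]).
#' @export
sensitivity_rerun <- function(cohort, carrier_flag, trait = "sbp",
                              mode = c("measured_bp", "drop_medicated",
                                       "drop_hypertensive"),
                              covariates = c("age", "sex", "bmi")) {
  mode <- match.arg(mode)
  if (is.character(carrier_flag) && length(carrier_flag) == 1L)
    carrier_flag <- cohort[[carrier_flag]]
  stopifnot(length(carrier_flag) == nrow(cohort))

  has_raw <- all(c("sbp_raw_1", "dbp_raw_1", "on_antihypertensive") %in%
                 names(cohort))
  reprep <- function(use_imputed) {
    if (!has_raw) return(cohort)   # already-prepared cohort: nothing to redo
    m2 <- function(p) if (paste0(p, "_2") %in% names(cohort))
      cohort[[paste0(p, "_2")]] else NA_real_
    bp <- prepare_bp(
      Map(c, cohort$sbp_raw_1, m2("sbp_raw")),
      Map(c, cohort$dbp_raw_1, m2("dbp_raw")),
      cohort$on_antihypertensive, use_imputed = use_imputed)
    cohort$sbp <- bp$sbp
    cohort$dbp <- bp$dbp
    cohort
  }

  if (mode == "measured_bp") {
    cc <- reprep(use_imputed = FALSE)
    keep <- rep(TRUE, nrow(cc))
  } else {
    cc <- reprep(use_imputed = TRUE)
    keep <- if (mode == "drop_medicated") !(cc$on_antihypertensive %in% TRUE)
            else !classify_hypertension(cc$sbp, cc$dbp,
                                        cc$on_antihypertensive)
  }
  cc <- cc[keep, , drop = FALSE]
  cf <- carrier_flag[keep]
  list(mode = mode, n = nrow(cc),
       slopes = subgroup_slopes(cc, cf, trait, covariates),
       tertiles = tertile_table(cc, cf, trait, covariates))
}
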