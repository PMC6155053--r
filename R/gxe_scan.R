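#' Code a genotype under a genetic model
#'
#' Dosage coding returns the posterior-expected coded-allele count; the
#' additive, dominant and recessive codings use the best-guess genotype
#' (posterior argmax when posteriors are given, otherwise the supplied hard
#' call). Dominant codes carriers of at least one coded allele as 1;
#' recessive codes the coded-allele homozygote as 1 (so a contrast such as
#' "GG vs AG/AA" is recessive coding of the G allele). Posterior argmax ties
#' are broken toward the lower genotype class and flagged in the
#' \code{"ties"} attribute.
#'
#' @param hard integer vector of hard-call alternate-allele counts (0/1/2,
#'   NA allowed); may be NULL if posteriors are given.
#' @param posteriors optional n x 3 matrix of genotype posteriors
#'   (P(0 alt), P(1 alt), P(2 alt)); rows must sum to 1 within 1e-3.
#' @param model "dosage", "additive", "dominant" or "recessive".
#' @param coded_allele count the "alt" (default) or "ref" allele.
#' @return numeric vector of coded genotypes (NA propagated), with attribute
#'   \code{ties} when posterior argmax ties were broken.
#' @export
code_genotype <- function(hard = NULL, posteriors = NULL,
                          model = c("dosage", "additive", "dominant",
                                    "recessive"),
                          coded_allele = c("alt", "ref")) {
  model <- match.arg(model)
  coded_allele <- match.arg(coded_allele)
  if (is.null(hard) && is.null(posteriors))
    stop("either hard calls or posteriors must be supplied")
  ties <- NULL
  if (!is.null(posteriors)) {
    posteriors <- as.matrix(posteriors)
    stopifnot(ncol(posteriors) == 3)
    rs <- rowSums(posteriors)
    ok <- is.finite(rs)
    if (any(abs(rs[ok] - 1) > 1e-3))
      stop("genotype posteriors must sum to 1 (tolerance 1e-3)")
    alt_dosage <- posteriors[, 2] + 2 * posteriors[, 3]
    pm <- pmax(posteriors[, 1], posteriors[, 2], posteriors[, 3])
    # argmax with ties toward the lower genotype class
    bg <- ifelse(posteriors[, 1] >= pm - 1e-12, 0L,
                 ifelse(posteriors[, 2] >= pm - 1e-12, 1L, 2L))
    ties <- rowSums(abs(posteriors - pm) < 1e-12) > 1
    bg[!ok] <- NA_integer_
    alt_dosage[!ok] <- NA_real_
  } else {
    alt_dosage <- as.numeric(hard)
    bg <- as.integer(hard)
  }
  if (model == "dosage") {
    out <- if (coded_allele == "alt") alt_dosage else 2 - alt_dosage
  } else {
    cnt <- if (coded_allele == "alt") bg else 2L - bg
    out <- switch(model,
      additive = as.numeric(cnt),
      dominant = as.numeric(cnt >= 1L),
      recessive = as.numeric(cnt == 2L))
  }
  if (!is.null(ties) && any(ties, na.rm = TRUE))
    attr(out, "ties") <- ties
  out
}

# one untestable scan record
untestable_record <- function(model, reason, n_used = NA_integer_) {
  data.frame(variant_id = NA_character_, coding_model = model,
             coded_genotype_freq = NA_real_,
             beta_G = NA_real_, beta_E = NA_real_, beta_GE = NA_real_,
             se_GE = NA_real_, lrt_stat = NA_real_, p_raw = NA_real_,
             p_gc = NA_real_, n_used = n_used, untestable = TRUE,
             reason = reason, stringsAsFactors = FALSE)
}

#' Fit the nested interaction models and the 1-df likelihood-ratio test
#'
#' Fits, by ordinary least squares on complete cases,
#' model 1: \eqn{BP = \beta_0 + \beta_G G + \beta_E E + covariates} and
#' model 2: model 1 \eqn{+ \beta_{GE} G \times E}. The likelihood-ratio
#' statistic uses the Gaussian maximum-likelihood variance profile,
#' \eqn{LRT = n \log(RSS_1 / RSS_2)}, referred to chi-square with 1 df.
#' The interaction coefficient and its standard error come from model 2.
#'
#' @param G coded genotype vector (see [code_genotype]).
#' @param E exposure vector (daily sodium, mEq/day).
#' @param BP trait vector (mm Hg).
#' @param covariates optional numeric matrix/data.frame of adjustment
#'   covariates (e.g. 20 PCs, age, sex, BMI).
#' @param model label stored in the record.
#' @param joint also test the genetic main effect jointly with the
#'   interaction (2-df test of \eqn{\beta_G = \beta_{GE} = 0}); off by
#'   default — the pipeline's aim is the interaction term itself.
#' @return one-row data.frame (a scan record); with \code{joint = TRUE} it
#'   gains \code{lrt_joint} and \code{p_joint} columns. Degenerate designs
#'   (constant G, interaction collinear with the main effects, too few
#'   observations) yield a record flagged \code{untestable} rather than an
#'   error.
#' @export
fit_interaction_lrt <- function(G, E, BP, covariates = NULL,
                                model = "dosage", joint = FALSE) {
  n_all <- length(BP)
  cov_m <- NULL
  if (!is.null(covariates)) {
    cov_m <- as.matrix(as.data.frame(covariates))
    storage.mode(cov_m) <- "double"
  }
  keep <- is.finite(G) & is.finite(E) & is.finite(BP)
  if (!is.null(cov_m)) keep <- keep & rowSums(!is.finite(cov_m)) == 0
  G <- G[keep]; E <- E[keep]; BP <- BP[keep]
  if (!is.null(cov_m)) cov_m <- cov_m[keep, , drop = FALSE]
  n <- length(BP)

  p2 <- 4L + if (is.null(cov_m)) 0L else ncol(cov_m)
  if (n <= p2)
    return(untestable_record(model, "too few complete observations", n))
  if (stats::var(G) == 0)
    return(untestable_record(model, "constant coded genotype", n))

  X1 <- cbind(`(Intercept)` = 1, G = G, E = E, cov_m)
  X2 <- cbind(X1, `G:E` = G * E)
  f1 <- stats::lm.fit(X1, BP)
  f2 <- stats::lm.fit(X2, BP)
  if (f2$rank <= f1$rank || is.na(f2$coefficients["G:E"]))
    return(untestable_record(model, "interaction collinear with design", n))
  rss1 <- sum(f1$residuals^2)
  rss2 <- sum(f2$residuals^2)
  lrt <- max(n * log(rss1 / rss2), 0)
  p_raw <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)

  # unscaled covariance from the pivoted QR of model 2
  R <- qr.R(f2$qr)
  piv <- f2$qr$pivot[seq_len(f2$rank)]
  cov_unscaled <- matrix(NA_real_, ncol(X2), ncol(X2))
  cov_unscaled[piv, piv] <- chol2inv(R[seq_len(f2$rank), seq_len(f2$rank)])
  sigma2 <- rss2 / (n - f2$rank)
  idx <- match("G:E", colnames(X2))
  se_ge <- sqrt(sigma2 * cov_unscaled[idx, idx])

  rec <- data.frame(variant_id = NA_character_, coding_model = model,
                    coded_genotype_freq = NA_real_,
                    beta_G = unname(f2$coefficients["G"]),
                    beta_E = unname(f2$coefficients["E"]),
                    beta_GE = unname(f2$coefficients["G:E"]),
                    se_GE = se_ge, lrt_stat = lrt, p_raw = p_raw,
                    p_gc = NA_real_, n_used = n, untestable = FALSE,
                    reason = NA_character_, stringsAsFactors = FALSE)
  if (joint) {
    X0 <- X1[, setdiff(colnames(X1), "G"), drop = FALSE]
    f0 <- stats::lm.fit(X0, BP)
    lrt_j <- max(n * log(sum(f0$residuals^2) / rss2), 0)
    rec$lrt_joint <- lrt_j
    rec$p_joint <- stats::pchisq(lrt_j, df = 2, lower.tail = FALSE)
  }
  rec
}

#' Genome-wide interaction scan
#'
#' Runs [fit_interaction_lrt] for every variant passing the
#' model-appropriate frequency filter: minor allele frequency >= `maf_min`
#' for the dosage and additive models, coded-genotype frequency >=
#' `coded_freq_min` for the dominant and recessive models. Upstream QC
#' (call rate, HWE, imputation R-squared) can be applied by passing a
#' [compute_variant_qc] report. Output order follows input order.
#'
#' @param cohort data.frame holding the trait, \code{daily_sodium} and the
#'   covariate columns.
#' @param genotypes a [genotype_matrix] (subjects must align with
#'   \code{cohort} rows).
#' @param model coding model for the scan.
#' @param trait name of the trait column (e.g. "sbp").
#' @param covariates character vector of covariate column names; default
#'   age, sex, BMI and every \code{pc*} column present. \code{sex} and
#'   \code{site} columns are converted to 0/1 indicators.
#' @param coded_allele allele counted by the coding.
#' @param qc_report optional [compute_variant_qc] output; variants failing
#'   call rate, HWE or imputation R-squared are dropped before the scan.
#' @param maf_min,coded_freq_min frequency filters (defaults 0.01).
#' @return data.frame of scan records, one row per scanned variant.
#' @export
genome_scan <- function(cohort, genotypes, model = c("dosage", "additive",
                                                     "dominant", "recessive"),
                        trait = "sbp", covariates = NULL,
                        coded_allele = c("alt", "ref"), qc_report = NULL,
                        maf_min = 0.01, coded_freq_min = 0.01) {
  model <- match.arg(model)
  coded_allele <- match.arg(coded_allele)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!trait %in% names(cohort))
    stop("trait column '", trait, "' not found in cohort")
  if (nrow(cohort) != length(genotypes$samples))
    stop("cohort rows and genotype samples differ in length")

  if (is.null(covariates))
    covariates <- intersect(c("age", "sex", "bmi",
                              grep("^pc[0-9]+$", names(cohort), value = TRUE),
                              NULL), names(cohort))
  cov_m <- NULL
  if (length(covariates)) {
    cov_l <- lapply(covariates, function(v) {
      x <- cohort[[v]]
      if (v == "sex") as.numeric(x == "male")
      else if (v == "site") as.numeric(x == "replication")
      else as.numeric(x)
    })
    cov_m <- do.call(cbind, cov_l)
    colnames(cov_m) <- covariates
  }
  y <- cohort[[trait]]
  E <- cohort$daily_sodium

  keep_variants <- rep(TRUE, nrow(genotypes$variants))
  if (!is.null(qc_report)) {
    m <- match(genotypes$variants$id, qc_report$variant_id)
    up <- qc_report$pass_call_rate & qc_report$pass_hwe & qc_report$pass_r2
    keep_variants <- !is.na(m) & up[m] %in% TRUE
  }

  recs <- vector("list", nrow(genotypes$variants))
  for (i in seq_len(nrow(genotypes$variants))) {
    if (!keep_variants[i]) next
    post <- cbind(genotypes$p0[i, ], genotypes$p1[i, ], genotypes$p2[i, ])
    G <- code_genotype(hard = genotypes$hard[i, ], posteriors = post,
                       model = model, coded_allele = coded_allele)
    ok <- !is.na(G)
    if (!any(ok)) next
    if (model %in% c("dosage", "additive")) {
      af <- mean(G[ok]) / 2
      freq <- min(af, 1 - af)
      if (freq < maf_min) next
      cgf <- af
    } else {
      cgf <- mean(G[ok] == 1)
      if (cgf < coded_freq_min) next
    }
    rec <- fit_interaction_lrt(G, E, y, cov_m, model = model)
    rec$variant_id <- genotypes$variants$id[i]
    rec$coded_genotype_freq <- cgf
    recs[[i]] <- rec
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs))
    return(untestable_record(model, "no variants passed filters")[0, ])
  do.call(rbind, recs)
}

# median of the chi-square 1-df distribution
CHISQ1_MEDIAN <- 0.45493642311957283031

#' Genomic-control correction
#'
#' Computes the inflation factor \eqn{\lambda} = median(LRT) / 0.4549364
#' (the chi-square 1-df median) over testable records, divides every
#' statistic by \eqn{\max(\lambda, 1)} (no deflation) and refers the
#' corrected statistic to chi-square 1 df. Ranking by P-value is preserved.
#'
#' @param records scan-record data.frame from [genome_scan].
#' @return list with \code{lambda} and \code{records} (the input with
#'   \code{p_gc} filled).
#' @export
genomic_control <- function(records) {
  testable <- !records$untestable
  if (!any(testable)) stop("no testable records for genomic control")
  if (sum(testable) < 100)
    warning("fewer than 100 testable records; lambda estimate is noisy")
  lambda <- stats::median(records$lrt_stat[testable]) / CHISQ1_MEDIAN
  corrected <- records$lrt_stat / max(lambda, 1)
  records$p_gc <- stats::pchisq(corrected, df = 1, lower.tail = FALSE)
  records$p_gc[records$untestable] <- NA_real_
  list(lambda = lambda, records = records)
}

#' Two-stage discovery/replication/combined significance evaluation
#'
#' Applies the staged criteria: suggestive if the genomic-control-corrected
#' discovery P < \code{suggestive}; replicated if additionally the
#' replication P < \code{replication} with the same interaction-effect sign
#' as the discovery estimate; genome-wide significant if additionally the
#' combined (site-adjusted) P < \code{genome_wide}. Replication and
#' combined stages use raw P-values; the discovery stage uses the
#' GC-corrected one (falling back to raw when no correction is present).
#'
#' @param discovery,replication,combined aligned scan-record data.frames
#'   (same variants, same coding model, one row per variant).
#' @param suggestive,replication_alpha,genome_wide stage thresholds.
#' @return data.frame with per-variant stage P-values,
#'   \code{direction_consistent} and \code{status} in
#'   \{none, suggestive, replicated, genome_wide\}.
#' @export
two_stage_evaluate <- function(discovery, replication, combined,
                               suggestive = 1e-5, replication_alpha = 0.05,
                               genome_wide = 5e-8) {
  if (!identical(discovery$variant_id, replication$variant_id) ||
      !identical(discovery$variant_id, combined$variant_id))
    stop("variant ids differ across stages")
  if (!identical(discovery$coding_model, replication$coding_model) ||
      !identical(discovery$coding_model, combined$coding_model))
    stop("coding models differ across stages")
  p_disc <- ifelse(is.na(discovery$p_gc), discovery$p_raw, discovery$p_gc)
  p_repl <- replication$p_raw
  p_comb <- combined$p_raw
  dir_ok <- sign(discovery$beta_GE) == sign(replication$beta_GE) &
    sign(discovery$beta_GE) != 0
  dir_ok[is.na(dir_ok)] <- FALSE

  status <- rep("none", nrow(discovery))
  sug <- !is.na(p_disc) & p_disc < suggestive
  status[sug] <- "suggestive"
  repl <- sug & !is.na(p_repl) & p_repl < replication_alpha & dir_ok
  status[repl] <- "replicated"
  gw <- repl & !is.na(p_comb) & p_comb < genome_wide
  status[gw] <- "genome_wide"
  data.frame(variant_id = discovery$variant_id,
             coding_model = discovery$coding_model,
             p_discovery = p_disc, p_replication = p_repl,
             p_combined = p_comb, direction_consistent = dir_ok,
             status = status, stringsAsFactors = FALSE)
}

#' QQ-plot data for a scan
#'
#' Expected vs observed -log10 P for testable records, suitable for a
#' quantile-quantile plot.
#'
#' @param records scan-record data.frame.
#' @param use_gc use GC-corrected P-values when available.
#' @return data.frame with \code{expected} and \code{observed} columns,
#'   sorted by significance.
#' @export
qq_data <- function(records, use_gc = FALSE) {
  p <- if (use_gc && !all(is.na(records$p_gc))) records$p_gc
       else records$p_raw
  p <- sort(p[!is.na(p)])
  n <- length(p)
  data.frame(expected = -log10(stats::ppoints(n)), observed = -log10(p))
}
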