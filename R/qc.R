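#' Hardy-Weinberg equilibrium exact test
#'
#' Exact conditional test of Hardy-Weinberg genotype proportions given the
#' allele counts. The conditional distribution of the heterozygote count is
#' built by the standard two-step recurrence in log space (safe for large
#' samples), and the two-sided P-value sums the probabilities of all
#' heterozygote counts whose conditional probability does not exceed that of
#' the observed count.
#'
#' @param n_hom_ref,n_het,n_hom_alt non-negative integer genotype counts.
#' @return exact two-sided P-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8))
    stop("genotype counts must be non-negative integers")
  counts <- round(counts)
  n <- sum(counts)
  if (n == 0L) stop("total genotype count must be positive")
  n_a <- 2L * counts[1] + counts[2]       # ref allele count
  n_b <- 2L * counts[3] + counts[2]
  h_obs <- counts[2]

  dist <- hwe_het_distribution(n_a, n_b)
  p_obs <- dist$prob[match(h_obs, dist$het)]
  # include outcomes with probability <= observed, with a relative tolerance
  # so analytically tied outcomes are not dropped by rounding
  pval <- sum(dist$prob[dist$prob <= p_obs * (1 + 1e-12)])
  min(pval, 1)
}

# Conditional distribution of the heterozygote count given allele counts
# (n_a ref alleles, n_b alt alleles). Unnormalised log-probabilities follow
# lp(h + 2) = lp(h) + log(4 a b / ((h + 1)(h + 2))), where a and b are the
# homozygote counts at h; normalised by log-sum-exp.
hwe_het_distribution <- function(n_a, n_b) {
  n_rare <- min(n_a, n_b)
  h_min <- n_rare %% 2L
  hets <- seq.int(h_min, n_rare, by = 2L)
  lp <- numeric(length(hets))
  if (length(hets) > 1L) {
    for (i in seq_len(length(hets) - 1L)) {
      h <- hets[i]
      a <- (n_a - h) / 2
      b <- (n_b - h) / 2
      lp[i + 1L] <- lp[i] + log(4 * a * b) - log((h + 1) * (h + 2))
    }
  }
  m <- max(lp)
  prob <- exp(lp - (m + log(sum(exp(lp - m)))))
  list(het = hets, prob = prob)
}

#' Per-variant quality-control report
#'
#' Computes call rate, minor allele frequency, HWE exact-test P-value,
#' coded-genotype frequencies for the dominant (carrier) and recessive
#' (homozygote) codings of the alternate allele, and pass flags for the
#' standard filters. Thresholds are printed as "fail if below", so equality
#' passes. MAF and HWE use hard calls; the imputation R-squared comes from
#' the variant metadata.
#'
#' @param genotypes a [genotype_matrix] or an integer matrix of hard calls
#'   (variants x subjects, values 0/1/2, NA allowed).
#' @param r2 optional numeric vector of per-variant imputation R-squared;
#'   taken from \code{genotypes$variants$r2} for a genotype_matrix.
#' @param thresholds named list overriding any of \code{call_rate} (0.95),
#'   \code{hwe_p} (1e-6), \code{maf} (0.01), \code{r2} (0.8),
#'   \code{coded_freq} (0.01).
#' @return data.frame with one row per variant: metrics and logical pass
#'   flags (\code{pass_call_rate}, \code{pass_hwe}, \code{pass_maf},
#'   \code{pass_r2}, \code{pass_cgf_dominant}, \code{pass_cgf_recessive})
#'   plus per-model composite flags \code{pass_dosage}, \code{pass_additive},
#'   \code{pass_dominant}, \code{pass_recessive}. An all-missing variant
#'   yields an all-fail row, not an error.
#' @export
compute_variant_qc <- function(genotypes, r2 = NULL, thresholds = list()) {
  if (inherits(genotypes, "genotype_matrix")) {
    hard <- genotypes$hard
    if (is.null(r2)) r2 <- genotypes$variants$r2
    ids <- genotypes$variants$id
  } else {
    hard <- as.matrix(genotypes)
    ids <- rownames(hard)
    if (is.null(ids)) ids <- paste0("var", seq_len(nrow(hard)))
  }
  if (is.null(r2)) r2 <- rep(NA_real_, nrow(hard))
  thr <- utils::modifyList(
    list(call_rate = 0.95, hwe_p = 1e-6, maf = 0.01, r2 = 0.8,
         coded_freq = 0.01),
    thresholds)

  n_sub <- ncol(hard)
  nonmiss <- rowSums(!is.na(hard))
  call_rate <- nonmiss / n_sub
  n0 <- rowSums(hard == 0, na.rm = TRUE)
  n1 <- rowSums(hard == 1, na.rm = TRUE)
  n2 <- rowSums(hard == 2, na.rm = TRUE)
  alt_freq <- ifelse(nonmiss > 0, (n1 + 2 * n2) / (2 * nonmiss), NA_real_)
  maf <- pmin(alt_freq, 1 - alt_freq)
  cgf_dom <- ifelse(nonmiss > 0, (n1 + n2) / nonmiss, NA_real_)
  cgf_rec <- ifelse(nonmiss > 0, n2 / nonmiss, NA_real_)
  hwe_p <- vapply(seq_len(nrow(hard)), function(i) {
    if (nonmiss[i] == 0) NA_real_
    else hwe_exact_test(n0[i], n1[i], n2[i])
  }, numeric(1))

  ge <- function(x, t) !is.na(x) & x >= t
  rep <- data.frame(
    variant_id = ids,
    call_rate = call_rate, maf = maf, hwe_p = hwe_p,
    imputation_r2 = r2,
    cgf_dominant = cgf_dom, cgf_recessive = cgf_rec,
    pass_call_rate = ge(call_rate, thr$call_rate),
    pass_hwe = ge(hwe_p, thr$hwe_p),
    pass_maf = ge(maf, thr$maf),
    pass_r2 = ge(r2, thr$r2),
    pass_cgf_dominant = ge(cgf_dom, thr$coded_freq),
    pass_cgf_recessive = ge(cgf_rec, thr$coded_freq),
    stringsAsFactors = FALSE)
  rep[nonmiss == 0, grep("^pass_", names(rep))] <- FALSE
  base <- rep$pass_call_rate & rep$pass_hwe & rep$pass_r2
  rep$pass_dosage <- base & rep$pass_maf
  rep$pass_additive <- base & rep$pass_maf
  rep$pass_dominant <- base & rep$pass_cgf_dominant
  rep$pass_recessive <- base & rep$pass_cgf_recessive
  rep
}

#' Write a QC report as TSV
#' @param report data.frame from [compute_variant_qc].
#' @param path output file.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
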