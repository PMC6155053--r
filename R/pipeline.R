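#' Subset a genotype matrix
#'
#' @param genotypes a [genotype_matrix].
#' @param variants,samples index vectors (integer, logical or character);
#'   NULL keeps everything.
#' @return a [genotype_matrix].
#' @export
subset_genotypes <- function(genotypes, variants = NULL, samples = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  vi <- if (is.null(variants)) seq_len(nrow(genotypes$variants)) else variants
  if (is.character(vi)) vi <- match(vi, genotypes$variants$id)
  si <- if (is.null(samples)) seq_along(genotypes$samples) else samples
  if (is.character(si)) si <- match(si, genotypes$samples)
  genotype_matrix(
    genotypes$dosage[vi, si, drop = FALSE],
    genotypes$p0[vi, si, drop = FALSE], genotypes$p1[vi, si, drop = FALSE],
    genotypes$p2[vi, si, drop = FALSE], genotypes$hard[vi, si, drop = FALSE],
    genotypes$variants[vi, , drop = FALSE], genotypes$samples[si])
}

# column-bind two genotype matrices over the same variants
bind_genotype_samples <- function(g1, g2) {
  stopifnot(identical(g1$variants$id, g2$variants$id))
  genotype_matrix(cbind(g1$dosage, g2$dosage), cbind(g1$p0, g2$p0),
                  cbind(g1$p1, g2$p1), cbind(g1$p2, g2$p2),
                  cbind(g1$hard, g2$hard), g1$variants,
                  c(g1$samples, g2$samples))
}

#' Prepare a raw cohort table for analysis
#'
#' Applies [prepare_bp] to the raw measurement columns
#' (\code{sbp_raw_1/2}, \code{dbp_raw_1/2}), derives daily sodium from spot
#' urine via [estimate_daily_sodium] when no \code{daily_sodium} column is
#' present, classifies hypertension, and drops subjects missing BMI, SBP,
#' DBP or daily sodium.
#'
#' @param cohort raw cohort data.frame.
#' @param use_imputed impute the antihypertensive treatment effect
#'   (+10/+5 mm Hg); FALSE is the measured-BP sensitivity mode.
#' @return list with \code{cohort} (analysis-ready, with \code{sbp},
#'   \code{dbp}, \code{hypertension} columns) and \code{exclusion_log}.
#' @export
prepare_cohort <- function(cohort, use_imputed = TRUE) {
  if (all(c("sbp_raw_1", "dbp_raw_1") %in% names(cohort))) {
    m2 <- function(p) if (paste0(p, "_2") %in% names(cohort))
      cohort[[paste0(p, "_2")]] else rep(NA_real_, nrow(cohort))
    bp <- prepare_bp(Map(c, cohort$sbp_raw_1, m2("sbp_raw")),
                     Map(c, cohort$dbp_raw_1, m2("dbp_raw")),
                     cohort$on_antihypertensive, use_imputed = use_imputed)
    cohort$sbp <- bp$sbp
    cohort$dbp <- bp$dbp
  }
  if (!"daily_sodium" %in% names(cohort) ||
      all(!is.finite(cohort$daily_sodium))) {
    if (!all(c("spot_urine_na", "spot_urine_cr") %in% names(cohort)))
      stop("prep stage: neither daily_sodium nor spot urine analytes present")
    cohort$daily_sodium <- estimate_daily_sodium(
      cohort$spot_urine_na, cohort$spot_urine_cr, cohort$age,
      cohort$height, cohort$weight)
  }
  cohort$hypertension <- classify_hypertension(
    cohort$sbp, cohort$dbp, cohort$on_antihypertensive)
  exclude_incomplete(cohort)
}

#' Run the full interaction-scan pipeline
#'
#' Executes the stage sequence: phenotype preparation, variant QC,
#' per-model discovery scans with genomic control, replication scans of
#' suggestive variants, combined (pooled, site-adjusted) scans, two-stage
#' significance decisions, and stratified post-hoc analyses for loci
#' reaching genome-wide significance. Inputs are either files
#' (\code{genotype_vcf} with a \code{phenotype_tsv} carrying a \code{site}
#' column) or simulated from \code{config$simulate}. A fixed seed gives an
#' identical run report and identical output tables.
#'
#' @param config a [run_config].
#' @return list with \code{report} (counts, lambdas, seed), \code{qc},
#'   \code{scans} (per model: discovery/replication/combined records and
#'   lambda), \code{decisions}, and \code{posthoc} (per genome-wide locus).
#'   When \code{config$output_dir} is set, result TSVs and a JSON run
#'   report are also written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$genotype_vcf)) {
    genotypes_all <- read_genotypes(config$genotype_vcf)
    pheno <- read_cohort_tsv(config$phenotype_tsv)
    if (!"site" %in% names(pheno))
      stop("input stage: phenotype table lacks a 'site' column")
    is_disc <- pheno$site == "discovery"
    cohorts <- list(discovery = pheno[is_disc, , drop = FALSE],
                    replication = pheno[!is_disc, , drop = FALSE])
    genos <- list(
      discovery = subset_genotypes(genotypes_all, samples = which(is_disc)),
      replication = subset_genotypes(genotypes_all,
                                     samples = which(!is_disc)))
  } else if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    n_repl <- sim_args$n_replication
    sim_args$n_replication <- NULL
    sim_args$seed <- config$seed
    cfg_d <- do.call(sim_config, sim_args)
    sim_args$seed <- config$seed + 1L
    if (!is.null(n_repl)) sim_args$n_subjects <- n_repl
    cfg_r <- do.call(sim_config, sim_args)
    d <- gen_cohort(cfg_d, site = "discovery")
    r <- gen_cohort(cfg_r, site = "replication")
    cohorts <- list(discovery = d$cohort, replication = r$cohort)
    genos <- list(discovery = d$genotypes, replication = r$genotypes)
  } else {
    stop("input stage: no genotype input and no simulate block")
  }

  # --- phenotype preparation ---------------------------------------------
  prep <- lapply(cohorts, prepare_cohort)
  excl <- lapply(prep, `[[`, "exclusion_log")
  n_input <- vapply(cohorts, nrow, integer(1))
  cohorts <- lapply(prep, `[[`, "cohort")
  genos <- Map(function(g, cc)
    subset_genotypes(g, samples = match(cc$subject_id, g$samples)),
    genos, cohorts)

  # --- variant QC (discovery cohort) -------------------------------------
  qc <- compute_variant_qc(genos$discovery,
                           thresholds = config$qc_thresholds)
  any_pass <- qc$pass_dosage | qc$pass_additive | qc$pass_dominant |
    qc$pass_recessive
  if (!any(any_pass, na.rm = TRUE))
    stop("qc stage: no variants passed quality control")

  pooled_cohort <- rbind(cohorts$discovery, cohorts$replication)
  pooled_genos <- bind_genotype_samples(genos$discovery, genos$replication)
  covars <- intersect(
    c("age", "sex", "bmi",
      paste0("pc", seq_len(config$n_pcs))), names(pooled_cohort))

  scans <- list()
  decisions <- list()
  for (model in config$models) {
    disc <- genome_scan(cohorts$discovery, genos$discovery, model = model,
                        trait = config$trait, covariates = covars,
                        qc_report = qc)
    gc <- genomic_control(disc)
    disc <- gc$records
    sug_ids <- disc$variant_id[!disc$untestable &
                                 !is.na(disc$p_gc) &
                                 disc$p_gc < config$suggestive]
    dec <- NULL
    repl <- comb <- NULL
    if (length(sug_ids)) {
      repl <- genome_scan(cohorts$replication,
                          subset_genotypes(genos$replication, sug_ids),
                          model = model, trait = config$trait,
                          covariates = covars,
                          maf_min = 0, coded_freq_min = 0)
      comb <- genome_scan(pooled_cohort,
                          subset_genotypes(pooled_genos, sug_ids),
                          model = model, trait = config$trait,
                          covariates = c(covars, "site"),
                          maf_min = 0, coded_freq_min = 0)
      keep <- intersect(intersect(repl$variant_id, comb$variant_id),
                        sug_ids)
      if (length(keep)) {
        dsub <- disc[match(keep, disc$variant_id), , drop = FALSE]
        rsub <- repl[match(keep, repl$variant_id), , drop = FALSE]
        csub <- comb[match(keep, comb$variant_id), , drop = FALSE]
        dec <- two_stage_evaluate(dsub, rsub, csub,
                                  suggestive = config$suggestive,
                                  replication_alpha =
                                    config$replication_alpha,
                                  genome_wide = config$genome_wide)
      }
    }
    scans[[model]] <- list(discovery = disc, replication = repl,
                           combined = comb, lambda = gc$lambda)
    decisions[[model]] <- dec
  }
  decisions <- do.call(rbind, decisions[!vapply(decisions, is.null,
                                                logical(1))])

  # --- post-hoc for genome-wide loci -------------------------------------
  posthoc <- list()
  if (!is.null(decisions) && any(decisions$status == "genome_wide")) {
    hits <- decisions[decisions$status == "genome_wide", , drop = FALSE]
    for (k in seq_len(nrow(hits))) {
      vid <- hits$variant_id[k]
      model <- hits$coding_model[k]
      gsub <- subset_genotypes(genos$discovery, vid)
      post <- cbind(gsub$p0[1, ], gsub$p1[1, ], gsub$p2[1, ])
      if (model %in% c("dominant", "recessive")) {
        G <- code_genotype(gsub$hard[1, ], post, model = model)
        flag <- G == 1
      } else {
        flag <- gsub$hard[1, ] >= 1
      }
      posthoc[[paste(vid, model, sep = ":")]] <- list(
        variant_id = vid, coding_model = model,
        slopes = subgroup_slopes(cohorts$discovery, flag, config$trait),
        tertiles = tertile_table(cohorts$discovery, flag, config$trait))
    }
  }

  report <- list(
    seed = config$seed,
    trait = config$trait,
    n_input = as.list(n_input),
    n_excluded = lapply(excl, as.list),
    n_analysed = lapply(cohorts, nrow),
    n_variants_scanned = lapply(scans, function(s) nrow(s$discovery)),
    lambda = lapply(scans, `[[`, "lambda"),
    n_suggestive = if (is.null(decisions)) 0L else nrow(decisions),
    n_genome_wide = if (is.null(decisions)) 0L
                    else sum(decisions$status == "genome_wide"))

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(...) file.path(config$output_dir, ...)
    write_qc_report(qc, out("qc_report.tsv"))
    for (model in names(scans)) {
      utils::write.table(scans[[model]]$discovery,
                         out(paste0("scan_", model, "_discovery.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(qq_data(scans[[model]]$discovery, use_gc = TRUE),
                         out(paste0("qq_", model, "_discovery.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(decisions))
      utils::write.table(decisions, out("decisions.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, out("run_report.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }

  list(report = report, qc = qc, scans = scans, decisions = decisions,
       posthoc = posthoc)
}
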