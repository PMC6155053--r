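#' Read genotypes from a VCF file
#'
#' Reads a VCF (v4.x) carrying GT and at least one of DS (dosage) or GP
#' (genotype posteriors) FORMAT fields into a [genotype_matrix]. Missing GP
#' is reconstructed as a degenerate mass on GT; missing DS is computed from
#' GP. Per-variant imputation R-squared is taken from the INFO R2 field
#' when present, otherwise estimated empirically as
#' var(dosage) / (2 p (1 - p)). Multiallelic records are skipped with a
#' warning and counted in the \code{"n_skipped_multiallelic"} attribute.
#' Coordinates are 1-based as in the VCF.
#'
#' @param path VCF file path (plain or gzipped).
#' @return a [genotype_matrix].
#' @export
read_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  as_fix_df <- function(v) {
    fm <- vcfR::getFIX(v)
    if (is.null(dim(fm)))   # single record: getFIX returns a named vector
      fm <- matrix(fm, nrow = 1, dimnames = list(NULL, names(fm)))
    as.data.frame(fm, stringsAsFactors = FALSE)
  }
  fix <- as_fix_df(v)
  multi <- grepl(",", fix$ALT)
  n_multi <- sum(multi)
  if (n_multi > 0) {
    warning(n_multi, " multiallelic record(s) skipped")
    v <- v[!multi, ]
    fix <- as_fix_df(v)
  }
  if (nrow(fix) == 0) stop("no biallelic records in ", path)

  fmt <- vcfR::vcf_field_names(v, tag = "FORMAT")$ID
  has <- function(f) f %in% fmt
  if (!any(has("GT"), has("DS"), has("GP")))
    stop("VCF carries none of GT/DS/GP FORMAT fields: ", path)

  samples <- colnames(v@gt)[-1]
  nv <- nrow(fix); ns <- length(samples)

  gt_hard <- NULL
  if (has("GT")) {
    gt <- vcfR::extract.gt(v, element = "GT")
    gt_hard <- matrix(NA_real_, nv, ns)
    clean <- gsub("\\|", "/", gt)
    gt_hard[clean == "0/0"] <- 0
    gt_hard[clean %in% c("0/1", "1/0")] <- 1
    gt_hard[clean == "1/1"] <- 2
  }
  p0 <- p1 <- p2 <- NULL
  if (has("GP")) {
    gp <- vcfR::extract.gt(v, element = "GP")
    split3 <- function(k) {
      out <- matrix(NA_real_, nv, ns)
      parts <- strsplit(as.vector(gp), ",", fixed = TRUE)
      vals <- vapply(parts, function(x)
        if (length(x) == 3) as.numeric(x[k]) else NA_real_, numeric(1))
      matrix(vals, nv, ns)
    }
    p0 <- split3(1); p1 <- split3(2); p2 <- split3(3)
  }
  dosage <- NULL
  if (has("DS")) {
    ds <- vcfR::extract.gt(v, element = "DS")
    dosage <- matrix(as.numeric(as.vector(ds)), nv, ns)
  }
  if (is.null(dosage) && !is.null(p0)) dosage <- p1 + 2 * p2
  if (is.null(p0)) {
    src <- if (!is.null(gt_hard)) gt_hard else round(dosage)
    p0 <- (src == 0) * 1; p1 <- (src == 1) * 1; p2 <- (src == 2) * 1
  }
  if (is.null(dosage)) dosage <- p1 + 2 * p2
  if (is.null(gt_hard)) gt_hard <- ifelse(p0 >= pmax(p1, p2), 0,
                                          ifelse(p1 >= p2, 1, 2))

  info_r2 <- suppressWarnings(
    as.numeric(vcfR::extract.info(v, element = "R2")))
  if (all(is.na(info_r2))) {
    af <- rowMeans(dosage, na.rm = TRUE) / 2
    denom <- 2 * af * (1 - af)
    info_r2 <- ifelse(denom > 0,
                      pmin(apply(dosage, 1, stats::var, na.rm = TRUE) / denom,
                           1), NA_real_)
  }
  variants <- data.frame(
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, r2 = info_r2,
    stringsAsFactors = FALSE)
  rownames(variants) <- NULL
  dimnames(dosage) <- dimnames(p0) <- dimnames(p1) <- dimnames(p2) <-
    dimnames(gt_hard) <- list(variants$id, samples)
  gm <- genotype_matrix(dosage, p0, p1, p2, gt_hard, variants, samples)
  attr(gm, "n_skipped_multiallelic") <- n_multi
  gm
}

#' Write a genotype matrix as a plain-text VCF v4.2
#'
#' Emits GT, DS and GP FORMAT fields and the INFO R2 field with full
#' numeric precision, so a write-then-read round trip reproduces dosages
#' bit-identically.
#'
#' @param genotypes a [genotype_matrix].
#' @param path output file.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  g <- genotypes
  num <- function(x) ifelse(is.na(x), ".", sprintf("%.17g", x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation R-squared\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    "##FORMAT=<ID=GP,Number=G,Type=Float,Description=\"Genotype posteriors\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples), collapse = "\t")), con)
  for (i in seq_len(nrow(g$variants))) {
    hard <- g$hard[i, ]
    gtf <- ifelse(is.na(hard), "./.",
                  c("0/0", "0/1", "1/1")[hard + 1])
    cells <- paste(gtf, num(g$dosage[i, ]),
                   paste(num(g$p0[i, ]), num(g$p1[i, ]), num(g$p2[i, ]),
                         sep = ","), sep = ":")
    info <- if (is.na(g$variants$r2[i])) "." else
      paste0("R2=", sprintf("%.17g", g$variants$r2[i]))
    writeLines(paste(c(g$variants$chrom[i], g$variants$pos[i],
                       g$variants$id[i], g$variants$ref[i],
                       g$variants$alt[i], ".", "PASS", info,
                       "GT:DS:GP", cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read/write a phenotype-covariate table as TSV
#'
#' The TSV has one row per subject and a documented header: subject_id,
#' demographics, raw BP measurements, medication flag, urine analytes or
#' daily sodium, site label and PC columns \code{pc1..pcK}.
#'
#' @param cohort data.frame; \code{path} file path.
#' @return \code{read_cohort_tsv} returns the data.frame.
#' @export
write_cohort_tsv <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (v in intersect(c("on_antihypertensive", "hypertension"), names(df)))
    df[[v]] <- as.logical(df[[v]])
  df
}

#' Pipeline run configuration
#'
#' Assembles, validates and (de)serialises the configuration of a full
#' pipeline run. All significance thresholds must lie in (0,1); the
#' structure round-trips losslessly through YAML.
#'
#' @param genotype_vcf,phenotype_tsv optional input paths (both NULL means
#'   the run simulates its inputs from \code{simulate}).
#' @param simulate optional named list of [sim_config] arguments for
#'   synthetic inputs, plus optional \code{n_replication}.
#' @param trait trait to scan.
#' @param models coding models to run.
#' @param suggestive,replication_alpha,genome_wide stage thresholds.
#' @param qc_thresholds named list passed to [compute_variant_qc].
#' @param n_pcs number of PC covariates to use.
#' @param seed integer seed.
#' @param output_dir optional directory for result TSVs and the run report.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(genotype_vcf = NULL, phenotype_tsv = NULL,
                       simulate = NULL, trait = "sbp",
                       models = c("dosage", "additive", "dominant",
                                  "recessive"),
                       suggestive = 1e-5, replication_alpha = 0.05,
                       genome_wide = 5e-8, qc_thresholds = list(),
                       n_pcs = 20, seed = 1, output_dir = NULL) {
  thr <- c(suggestive, replication_alpha, genome_wide)
  stopifnot(all(thr > 0), all(thr < 1))
  structure(list(genotype_vcf = genotype_vcf, phenotype_tsv = phenotype_tsv,
                 simulate = simulate, trait = trait, models = models,
                 suggestive = suggestive,
                 replication_alpha = replication_alpha,
                 genome_wide = genome_wide, qc_thresholds = qc_thresholds,
                 n_pcs = as.integer(n_pcs), seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path; \code{config} a run_config.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}
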