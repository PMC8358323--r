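#' Pipeline run configuration
#'
#' @param r2_thresholds LD thresholds for haploblock construction
#'   (default the seven levels 0.2..0.8 by 0.1).
#' @param models subset of \code{c("GBLUP", "GBLUP_In_Block", "G_H_BLUP",
#'   "G_H_BLUP+GBLUP")}.
#' @param trait trait column name (default "trait").
#' @param k,repeats cross-validation layout (default 5-fold x 10).
#' @param call_rate_min,maf_min,hwe_p_min,sample_call_rate_min QC
#'   thresholds, see \code{\link{apply_variant_qc}}.
#' @param seed top-level seed; per-stage seeds are derived from it.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(r2_thresholds = seq(0.2, 0.8, by = 0.1),
                       models = c("GBLUP", "GBLUP_In_Block", "G_H_BLUP",
                                  "G_H_BLUP+GBLUP"),
                       trait = "trait", k = 5L, repeats = 10L,
                       call_rate_min = 0.90, maf_min = 0.01,
                       hwe_p_min = 1e-6, sample_call_rate_min = 0.90,
                       seed = 1L) {
  if (any(r2_thresholds <= 0 | r2_thresholds > 1))
    stop("r2_thresholds must lie in (0, 1]")
  if (k < 2L) stop("k must be >= 2")
  if (repeats < 1L) stop("repeats must be >= 1")
  models <- match.arg(models, several.ok = TRUE)
  structure(list(r2_thresholds = r2_thresholds, models = models,
                 trait = trait, k = as.integer(k),
                 repeats = as.integer(repeats),
                 call_rate_min = call_rate_min, maf_min = maf_min,
                 hwe_p_min = hwe_p_min,
                 sample_call_rate_min = sample_call_rate_min,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the haploblock genomic-prediction pipeline
#'
#' Composes the whole analysis in order: QC, whole-panel SNP GRM and
#' heritability, then per LD threshold: haploblock construction, dosage
#' coding, haplotype and in-block/non-blocked SNP GRMs, cross-validated
#' prediction for every requested model, and Hotelling-Williams
#' comparisons of each haplotype model against the in-block SNP model.
#' All models within a run share fold assignments. Identical inputs and
#' config reproduce every number exactly.
#'
#' Model definitions: \code{GBLUP} uses the all-SNP G (threshold
#' independent, computed once); \code{GBLUP_In_Block} uses G built from
#' the SNPs inside blocks at the current threshold; \code{G_H_BLUP} uses
#' G_H from the haplotype-allele dosages; \code{G_H_BLUP+GBLUP} adds a
#' second component with G from the non-blocked SNPs.
#'
#' @param panel a \code{phased_panel} (pre- or post-QC; QC is applied).
#' @param pheno phenotype/covariate table (see
#'   \code{\link{adjust_phenotypes}}).
#' @param config a \code{\link{run_config}}.
#' @param out_dir optional directory; when given, all reports are written
#'   there as delimited text.
#' @return list of class \code{pipeline_result}: \code{qc_report},
#'   \code{h2} (whole-data SNP-GBLUP estimate), \code{whole_fit},
#'   \code{block_summary} (data.frame over thresholds, Table-style),
#'   \code{cv_metrics} (long data.frame), \code{cv_summary},
#'   \code{comparisons} (data.frame of Hotelling p-values),
#'   \code{partitions}, \code{config}.
#' @export
run_pipeline <- function(panel, pheno, config = run_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  qc <- apply_variant_qc(panel, call_rate_min = config$call_rate_min,
                         maf_min = config$maf_min,
                         hwe_p_min = config$hwe_p_min,
                         sample_call_rate_min = config$sample_call_rate_min)
  panel <- qc$panel
  keep <- match(panel$sample_ids, pheno$id)
  if (anyNA(keep)) stop("sample(s) in panel missing from phenotype table")
  pheno <- pheno[keep, , drop = FALSE]

  adj <- adjust_phenotypes(pheno, config$trait)
  y_star <- adj$y_star

  G_all <- snp_grm(panel)
  whole_fit <- fit_single_grm_reml(y_star, G_all)
  h2 <- whole_fit$vc$h2
  if (h2 <= 0) {
    warning("whole-data heritability estimate is 0; accuracies use h2 = 1")
    h2_acc <- 1
  } else h2_acc <- h2

  block_rows <- list(); cv_rows <- list(); cmp_rows <- list()
  partitions <- list(); cv_objects <- list()
  for (t in config$r2_thresholds) {
    part <- build_block_partition(panel, t)
    partitions[[as.character(t)]] <- part
    has_blocks <- length(part$blocks) > 0
    dosage <- if (has_blocks) dosage_matrix(panel, part) else NULL
    block_rows[[length(block_rows) + 1L]] <- data.frame(
      r2_threshold = t,
      haplotype_alleles = if (has_blocks) dosage$Q_H else 0L,
      n_blocks = part$summary$n_blocks,
      n_blocked_snps = part$summary$n_blocked_snps,
      snps_per_block = part$summary$mean_snps_per_block,
      n_non_blocked = part$summary$n_non_blocked)

    models <- list()
    if ("GBLUP" %in% config$models) models$GBLUP <- list(K = G_all)
    if ("GBLUP_In_Block" %in% config$models && has_blocks)
      models$GBLUP_In_Block <- list(K = snp_grm(panel, blocked_indices(part)))
    if ("G_H_BLUP" %in% config$models && has_blocks)
      models$G_H_BLUP <- list(K = haplotype_grm(dosage))
    if ("G_H_BLUP+GBLUP" %in% config$models && has_blocks &&
        length(part$non_blocked))
      models$`G_H_BLUP+GBLUP` <- list(K = haplotype_grm(dosage),
                                      K2 = snp_grm(panel, part$non_blocked))
    if (!length(models)) next

    cv <- cross_validate(y_star, models, h2 = h2_acc, k = config$k,
                         repeats = config$repeats, seed = config$seed)
    cv_objects[[as.character(t)]] <- cv
    cm <- cv$metrics
    cm$r2_threshold <- t
    cv_rows[[length(cv_rows) + 1L]] <- cm

    for (hm in intersect(c("G_H_BLUP", "G_H_BLUP+GBLUP"), names(models))) {
      ref <- if ("GBLUP_In_Block" %in% names(models)) "GBLUP_In_Block"
             else if ("GBLUP" %in% names(models)) "GBLUP" else NA
      if (is.na(ref) || ref == hm) next
      cmp <- compare_models(cv, y_star, ref, hm)
      cmp_rows[[length(cmp_rows) + 1L]] <- data.frame(
        r2_threshold = t, model_ref = ref, model_alt = hm,
        t_mean = cmp$t_mean, p_mean = cmp$p_mean, n = cmp$n)
    }
  }

  block_summary <- do.call(rbind, block_rows)
  cv_metrics <- if (length(cv_rows)) do.call(rbind, cv_rows) else NULL
  comparisons <- if (length(cmp_rows)) do.call(rbind, cmp_rows) else NULL
  cv_summary <- if (!is.null(cv_metrics)) {
    agg <- stats::aggregate(cbind(cor, accuracy, bias) ~ model + r2_threshold,
                            data = cv_metrics, FUN = mean)
    agg[order(agg$r2_threshold, agg$model), ]
  } else NULL

  res <- structure(list(qc_report = qc$report, h2 = h2,
                        whole_fit = whole_fit,
                        block_summary = block_summary,
                        cv_metrics = cv_metrics, cv_summary = cv_summary,
                        comparisons = comparisons, partitions = partitions,
                        cv_objects = cv_objects, y_star = y_star,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_reports(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result: h2 =", round(x$h2, 4), "\n")
  cat("block summary:\n"); print(x$block_summary, row.names = FALSE)
  if (!is.null(x$cv_summary)) {
    cat("cross-validation (means over repeats):\n")
    print(x$cv_summary, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$comparisons)) {
    cat("model comparisons (Hotelling-Williams, mean over repeats):\n")
    print(x$comparisons, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

write_pipeline_reports <- function(res, out_dir) {
  wt <- function(df, name) if (!is.null(df))
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  write_qc_report(res$qc_report, file.path(out_dir, "qc_report.tsv"))
  write_fit_report(res$whole_fit, file.path(out_dir, "whole_data_fit.tsv"))
  wt(res$block_summary, "block_summary.tsv")
  wt(res$cv_metrics, "cv_metrics.tsv")
  wt(res$cv_summary, "cv_summary.tsv")
  wt(res$comparisons, "model_comparisons.tsv")
  manifest <- data.frame(
    key = c("package_version", "seed", "k", "repeats", "trait",
            "r2_thresholds", "models"),
    value = c(as.character(utils::packageVersion("hapblup")),
              res$config$seed, res$config$k, res$config$repeats,
              res$config$trait,
              paste(res$config$r2_thresholds, collapse = ","),
              paste(res$config$models, collapse = ",")))
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
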