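#' Read a phased VCF into a panel
#'
#' Reads a VCF (plain or bgzipped) with phased GT fields and returns a
#' \code{\link{phased_panel}}. Only bi-allelic SNP records are supported;
#' the GT separator must be \code{"|"} for every called genotype —
#' an unphased \code{"/"} is an error, since downstream haplotype work is
#' meaningless on unphased data. Missing alleles (\code{"."}) become NA.
#'
#' @param path path to the VCF file.
#' @param multiallelic how to treat records with >1 ALT allele:
#'   \code{"error"} (default) or \code{"skip"} (dropped, with a message).
#' @return A \code{phased_panel}; sample order follows the VCF header.
#' @export
read_phased_vcf <- function(path, multiallelic = c("error", "skip")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt) | is.na(alt)
  if (any(multi)) {
    if (multiallelic == "error")
      stop(sum(multi), " multi-allelic record(s), first at ",
           fix[which(multi)[1], "CHROM"], ":", fix[which(multi)[1], "POS"])
    message("skipping ", sum(multi), " multi-allelic record(s)")
  }
  keep <- which(!multi)
  if (!length(keep)) stop("no bi-allelic records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  sample_ids <- colnames(gt)
  n <- length(sample_ids); m <- nrow(gt)

  unph <- matrix(grepl("/", gt), nrow = nrow(gt))
  if (any(unph)) {
    w <- which(unph, arr.ind = TRUE)[1, ]
    stop("unphased genotype '", gt[w[1], w[2]], "' at record ",
         fix[w[1], "ID"], " (", fix[w[1], "CHROM"], ":", fix[w[1], "POS"],
         ") sample ", sample_ids[w[2]])
  }
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  code <- function(a) {
    x <- suppressWarnings(as.integer(a))     # "." and NA -> NA
    if (any(!is.na(x) & !(x %in% 0:1)))
      stop("allele index outside {0,1} in GT field")
    x
  }
  # haps: 2n rows x m variants; gt is m x n
  haps <- matrix(NA_integer_, nrow = 2L * n, ncol = m)
  haps[seq(1L, 2L * n, 2L), ] <- t(matrix(code(a1), nrow = m))
  haps[seq(2L, 2L * n, 2L), ] <- t(matrix(code(a2), nrow = m))

  variants <- data.frame(chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                                     paste0(fix[, "CHROM"], "_", fix[, "POS"]),
                                     fix[, "ID"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  ord <- order(variants$chrom, variants$pos)
  phased_panel(haps[, ord, drop = FALSE], variants[ord, , drop = FALSE],
               sample_ids)
}

#' Write a panel as a phased VCF
#'
#' Emits a minimal VCFv4.2 with phased GT fields; inverse of
#' \code{\link{read_phased_vcf}} (round-trips exactly).
#'
#' @param panel a \code{phased_panel}.
#' @param path output path; \code{".gz"} suffix is added by the writer if
#'   absent (bgzipped output).
#' @return The path written, invisibly.
#' @export
write_phased_vcf <- function(panel, path) {
  m <- n_variants(panel); n <- n_samples(panel)
  h <- panel$haps
  a1 <- h[seq(1L, 2L * n, 2L), , drop = FALSE]
  a2 <- h[seq(2L, 2L * n, 2L), , drop = FALSE]
  tochr <- function(x) ifelse(is.na(x), ".", as.character(x))
  gt <- matrix(paste0(tochr(t(a1)), "|", tochr(t(a2))), nrow = m)
  gt[gt == ".|."] <- ".|."
  colnames(gt) <- panel$sample_ids
  gt <- cbind(FORMAT = rep("GT", m), gt)
  fix <- cbind(CHROM = panel$variants$chrom,
               POS = as.character(panel$variants$pos),
               ID = panel$variants$id,
               REF = panel$variants$ref,
               ALT = panel$variants$alt,
               QUAL = ".", FILTER = "PASS", INFO = ".")
  v <- methods::new(methods::className("vcfR", "vcfR"),
           meta = c("##fileformat=VCFv4.2",
                    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">"),
           fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Counted (ALT) allele frequencies
#'
#' Frequency of the counted allele at each variant, over non-missing
#' haplotypes. This is the \eqn{p_i} entering the genomic relationship
#' matrix; the minor allele frequency used in QC is
#' \code{pmin(p, 1 - p)}.
#'
#' @param panel a \code{phased_panel}.
#' @return numeric vector of length \code{n_variants(panel)}.
#' @export
allele_frequencies <- function(panel) {
  h <- panel$haps
  nn <- colSums(!is.na(h))
  if (any(nn == 0))
    stop("variant(s) with all haplotypes missing: ",
         paste(panel$variants$id[nn == 0], collapse = ", "))
  colSums(h, na.rm = TRUE) / nn
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on genotype counts at a bi-allelic locus: with the
#' allele totals fixed, the p-value is the sum of the conditional
#' probabilities of every heterozygote count no more probable than the one
#' observed (probability-ordering two-sided rule, as is standard for chip
#' QC where the chi-square approximation fails at rare alleles).
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotyped individual required")
  nA <- 2L * n_AA + n_Aa                 # count of the rarer-or-not allele A
  # work with the minor allele so the enumeration is over its het counts
  n_minor <- min(nA, 2L * n - nA)
  het_obs <- n_Aa
  hets <- seq.int(n_minor %% 2L, n_minor, by = 2L)  # feasible het counts
  # conditional P(het | allele totals) ∝ n! / (n_hom_maj! n_het! n_hom_min!) 2^het
  n_hom_min <- (n_minor - hets) / 2
  n_hom_maj <- n - hets - n_hom_min
  lp <- lgamma(n + 1) - lgamma(n_hom_maj + 1) - lgamma(hets + 1) -
    lgamma(n_hom_min + 1) + hets * log(2)
  lp <- lp - max(lp)
  pr <- exp(lp); pr <- pr / sum(pr)
  p_obs <- pr[match(het_obs, hets)]
  if (is.na(p_obs)) stop("observed heterozygote count infeasible for allele totals")
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

#' Apply variant- and sample-level quality control
#'
#' Removes variants failing call rate, minor-allele-frequency or exact
#' Hardy-Weinberg thresholds (each variant is counted once, under the first
#' failing filter, in the order call rate, MAF, HWE), then removes samples
#' whose call rate over the retained variants falls below
#' \code{sample_call_rate_min}.
#'
#' @param panel a \code{phased_panel}.
#' @param call_rate_min minimum variant call rate (default 0.90).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_p_min minimum exact HWE p-value (default 1e-6).
#' @param sample_call_rate_min minimum per-sample call rate (default 0.90).
#' @return list with elements \code{panel} (filtered) and \code{report}
#'   (class \code{qc_report}: tallies per filter).
#' @export
apply_variant_qc <- function(panel, call_rate_min = 0.90, maf_min = 0.01,
                             hwe_p_min = 1e-6, sample_call_rate_min = 0.90) {
  thr <- c(call_rate_min, maf_min, hwe_p_min, sample_call_rate_min)
  if (any(thr < 0 | thr > 1)) stop("QC thresholds must lie in [0, 1]")
  h <- panel$haps
  m <- n_variants(panel); n <- n_samples(panel)
  odd <- seq(1L, 2L * n, 2L)
  d <- h[odd, , drop = FALSE] + h[odd + 1L, , drop = FALSE]  # NA if either missing

  call_rate <- colSums(!is.na(d)) / n
  fail_cr <- call_rate < call_rate_min

  p <- colSums(h, na.rm = TRUE) / pmax(colSums(!is.na(h)), 1L)
  maf <- pmin(p, 1 - p)
  fail_maf <- !fail_cr & maf < maf_min

  fail_hwe <- rep(FALSE, m)
  cand <- which(!fail_cr & !fail_maf)
  for (j in cand) {
    dj <- d[!is.na(d[, j]), j]
    pv <- hwe_exact_test(sum(dj == 0L), sum(dj == 1L), sum(dj == 2L))
    fail_hwe[j] <- pv < hwe_p_min
  }

  keep_v <- which(!(fail_cr | fail_maf | fail_hwe))
  if (!length(keep_v)) stop("empty panel after QC")

  scr <- rowSums(!is.na(d[, keep_v, drop = FALSE])) / length(keep_v)
  keep_s <- which(scr >= sample_call_rate_min)
  if (!length(keep_s)) stop("empty panel after QC (all samples removed)")

  out <- subset_panel(panel, variants = keep_v, samples = keep_s)
  report <- structure(list(n_variants_in = m,
                           n_removed_call_rate = sum(fail_cr),
                           n_removed_maf = sum(fail_maf),
                           n_removed_hwe = sum(fail_hwe),
                           n_samples_removed = n - length(keep_s),
                           n_variants_out = length(keep_v)),
                      class = "qc_report")
  list(panel = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:\n",
      " variants in:        ", x$n_variants_in, "\n",
      " removed call rate:  ", x$n_removed_call_rate, "\n",
      " removed MAF:        ", x$n_removed_maf, "\n",
      " removed HWE:        ", x$n_removed_hwe, "\n",
      " samples removed:    ", x$n_samples_removed, "\n",
      " variants out:       ", x$n_variants_out, "\n")
  invisible(x)
}

#' Write a QC report as tab-delimited text
#' @param report a \code{qc_report}.
#' @param path output path.
#' @return path, invisibly.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(metric = names(unclass(report)),
                   value = unlist(report, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
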