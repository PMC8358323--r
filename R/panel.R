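#' Construct a phased genotype panel
#'
#' A \code{phased_panel} holds the two resolved haplotypes of every
#' individual at a set of bi-allelic variants, plus variant metadata. It is
#' the single container the rest of the pipeline (LD, haploblocks, dosage
#' coding, relationship matrices) consumes.
#'
#' @param haps integer matrix of allele codes in \{0, 1\} (NA = missing),
#'   with \code{2 * n_samples} rows — rows \code{2i - 1} and \code{2i} are the
#'   two haplotypes of sample \code{i} — and one column per variant.
#' @param variants data.frame with columns \code{chrom}, \code{pos},
#'   \code{id}, \code{ref}, \code{alt}; one row per variant, sorted by
#'   (chrom, pos) with strictly increasing positions within a chromosome.
#' @param sample_ids character vector of sample identifiers.
#' @return An object of class \code{phased_panel}.
#' @export
phased_panel <- function(haps, variants, sample_ids) {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  n <- length(sample_ids)
  if (n < 1L) stop("panel must contain at least one sample")
  if (nrow(haps) != 2L * n)
    stop("haps must have 2 rows per sample (got ", nrow(haps),
         " rows for ", n, " samples)")
  if (ncol(haps) != nrow(variants))
    stop("haps columns (", ncol(haps), ") != variants rows (",
         nrow(variants), ")")
  if (nrow(variants) < 1L) stop("panel must contain at least one variant")
  need <- c("chrom", "pos", "id", "ref", "alt")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("variants is missing column(s): ", paste(miss, collapse = ", "))
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  bad <- !(haps %in% c(0L, 1L) | is.na(haps))
  if (any(bad)) stop("hap codes must be 0, 1 or NA (bi-allelic panel)")
  if (any(variants$ref == variants$alt))
    stop("ref and alt alleles must differ at every variant")
  # positions strictly increasing within chromosome, chromosomes grouped
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  rownames(haps) <- paste(rep(sample_ids, each = 2L), 1:2, sep = "_")
  rownames(variants) <- NULL
  structure(list(haps = haps, variants = variants,
                 sample_ids = as.character(sample_ids)),
            class = "phased_panel")
}

#' @export
print.phased_panel <- function(x, ...) {
  cat("phased_panel:", n_samples(x), "samples x", n_variants(x),
      "variants on chromosome(s)",
      paste(unique(x$variants$chrom), collapse = ", "), "\n")
  nm <- sum(is.na(x$haps))
  if (nm > 0) cat("  missing haplotype calls:", nm, "\n")
  invisible(x)
}

#' Number of samples in a panel
#' @param panel a \code{phased_panel}.
#' @return integer count.
#' @export
n_samples <- function(panel) length(panel$sample_ids)

#' Number of variants in a panel
#' @param panel a \code{phased_panel}.
#' @return integer count.
#' @export
n_variants <- function(panel) nrow(panel$variants)

#' Subset a panel by variants and/or samples
#'
#' @param panel a \code{phased_panel}.
#' @param variants integer indices of variants to keep (in panel order).
#' @param samples integer indices of samples to keep.
#' @return A new \code{phased_panel}.
#' @export
subset_panel <- function(panel, variants = NULL, samples = NULL) {
  haps <- panel$haps
  vtab <- panel$variants
  ids <- panel$sample_ids
  if (!is.null(variants)) {
    haps <- haps[, variants, drop = FALSE]
    vtab <- vtab[variants, , drop = FALSE]
  }
  if (!is.null(samples)) {
    rows <- as.vector(rbind(2L * samples - 1L, 2L * samples))
    haps <- haps[rows, , drop = FALSE]
    ids <- ids[samples]
  }
  phased_panel(haps, vtab, ids)
}

#' Genotype dosage matrix of the counted (ALT) allele
#'
#' @param panel a \code{phased_panel}.
#' @return integer matrix [n_samples x n_variants] with entries 0/1/2
#'   (NA where either haplotype is missing), rownames = sample ids.
#' @export
genotype_dosage <- function(panel) {
  h <- panel$haps
  odd <- seq(1L, nrow(h), by = 2L)
  d <- h[odd, , drop = FALSE] + h[odd + 1L, , drop = FALSE]
  rownames(d) <- panel$sample_ids
  colnames(d) <- panel$variants$id
  d
}

stop_if_missing <- function(panel, what) {
  if (anyNA(panel$haps))
    stop(what, " requires complete phased data (panel has missing calls)")
  invisible(TRUE)
}
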