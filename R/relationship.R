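#' SNP-based genomic relationship matrix (VanRaden)
#'
#' \deqn{G = (M - P)(M - P)' / (2 \sum_i p_i (1 - p_i))}
#' where M is the 0/1/2 counted-allele dosage matrix over the chosen
#' marker subset and P has columns \eqn{2 p_i}. The frequencies are the
#' counted-allele frequencies of \emph{this} panel (all samples), so a
#' single G serves the whole analysis and every cross-validation split.
#'
#' @param panel a \code{phased_panel} with complete data.
#' @param snp_subset integer variant indices (default: all variants).
#'   Use \code{blocked_indices(partition)} for an in-block G and
#'   \code{partition$non_blocked} for a non-blocked G.
#' @return object of class \code{grm}: list with \code{values}
#'   (symmetric n x n matrix), \code{kind = "snp_G"}, \code{n_markers}.
#' @export
snp_grm <- function(panel, snp_subset = seq_len(n_variants(panel))) {
  stop_if_missing(panel, "snp_grm")
  if (!length(snp_subset)) stop("snp_subset is empty")
  M <- genotype_dosage(panel)[, snp_subset, drop = FALSE]
  p <- allele_frequencies(panel)[snp_subset]
  if (any(p %in% c(0, 1)))
    stop("monomorphic variant(s) in subset: ",
         paste(utils::head(panel$variants$id[snp_subset][p %in% c(0, 1)], 5),
               collapse = ", "))
  W <- sweep(M, 2L, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(W) / denom
  new_grm((G + t(G)) / 2, kind = "snp_G", n_markers = length(snp_subset),
          ids = panel$sample_ids)
}

#' Haplotype-based genomic relationship matrix
#'
#' \deqn{G_H = M_H M_H' / Q_H} on the uncentred, unscaled haplotype-allele
#' dosage matrix, exactly as defined for the haplotype model; entries are
#' therefore nonnegative. A centred variant (columns centred at their
#' means before the product) is available for sensitivity analysis.
#'
#' @param dosage a \code{hap_dosage} from \code{\link{dosage_matrix}}.
#' @param center centre the dosage columns first (default FALSE).
#' @return a \code{grm} with \code{kind = "haplotype_G_H"}.
#' @export
haplotype_grm <- function(dosage, center = FALSE) {
  M <- dosage$M_H
  if (is.null(M) || !ncol(M) || !nrow(M)) stop("empty dosage matrix")
  if (center) M <- sweep(M, 2L, colMeans(M))
  G <- tcrossprod(M) / dosage$Q_H
  new_grm((G + t(G)) / 2, kind = "haplotype_G_H", n_markers = dosage$Q_H,
          ids = rownames(dosage$M_H))
}

new_grm <- function(values, kind, n_markers, ids) {
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, kind = kind, n_markers = n_markers),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm (", x$kind, "): ", nrow(x$values), " x ", ncol(x$values),
      ", built from ", x$n_markers,
      if (x$kind == "snp_G") " markers" else " haplotype alleles", "\n",
      sep = "")
  invisible(x)
}

#' Write a relationship matrix as text
#'
#' \code{format = "dense"}: full matrix with id header;
#' \code{format = "gcta"}: GCTA-style long form (i, j, n_markers, value)
#' over the lower triangle plus an id file at \code{paste0(path, ".id")}.
#'
#' @param grm a \code{grm}.
#' @param path output path.
#' @param format \code{"dense"} or \code{"gcta"}.
#' @return path, invisibly.
#' @export
write_grm <- function(grm, path, format = c("dense", "gcta")) {
  format <- match.arg(format)
  V <- grm$values
  if (format == "dense") {
    utils::write.table(cbind(id = rownames(V), as.data.frame(V)), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    n <- nrow(V)
    ij <- which(lower.tri(V, diag = TRUE), arr.ind = TRUE)
    df <- data.frame(i = ij[, 1], j = ij[, 2],
                     n_markers = grm$n_markers, value = V[ij])
    df <- df[order(df$i, df$j), ]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(fid = rownames(V), iid = rownames(V)),
                       paste0(path, ".id"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a dense relationship matrix written by \code{write_grm}
#' @param path path to a dense GRM file.
#' @param kind stored in the result (default "snp_G").
#' @return a \code{grm}.
#' @export
read_grm <- function(path, kind = "snp_G") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  ids <- df$id
  V <- as.matrix(df[, -1, drop = FALSE])
  new_grm(V, kind = kind, n_markers = NA_integer_, ids = ids)
}
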