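#' Enumerate the haplotype alleles observed in a block
#'
#' A haplotype allele is one distinct combination of SNP alleles observed
#' on a single chromosome copy across the block's markers. Only observed
#' combinations are catalogued (with their counts over the 2n phased
#' haplotypes); the catalogue is ordered lexicographically on the 0/1
#' allele string so matrices are reproducible across runs.
#'
#' @param panel a \code{phased_panel} with complete data.
#' @param block one block from a \code{\link{build_haploblocks}} partition
#'   (a list with \code{variant_indices}).
#' @return list with \code{alleles} (character vector of 0/1 strings),
#'   \code{display} (upper/lower-case letter form, A/a for the first SNP,
#'   B/b for the second, ...), \code{counts} (observed haplotype counts)
#'   and \code{variant_indices}.
#' @export
enumerate_block_alleles <- function(panel, block) {
  stop_if_missing(panel, "enumerate_block_alleles")
  idx <- block$variant_indices
  H <- panel$haps[, idx, drop = FALSE]
  strings <- apply(H, 1L, paste, collapse = "")
  tab <- table(strings)
  alleles <- sort(names(tab))            # lexicographic, deterministic
  list(alleles = alleles,
       display = vapply(alleles, allele_display, character(1)),
       counts = as.integer(tab[alleles]),
       variant_indices = idx)
}

# "01" -> "Ab": position k uses the k-th letter, upper-case for code 0
allele_display <- function(s) {
  codes <- strtoi(strsplit(s, "")[[1]])
  letters_up <- LETTERS[(seq_along(codes) - 1L) %% 26L + 1L]
  paste(ifelse(codes == 0L, letters_up, tolower(letters_up)), collapse = "")
}

#' Haplotype-allele dosage matrix M_H
#'
#' Builds the pseudo-marker matrix: one column per (block, haplotype
#' allele), entry = number of the individual's two phased haplotypes that
#' carry that allele (0, 1 or 2). Within any block each individual's row
#' segment sums to 2 (a diplotype contributes exactly two allele copies).
#' Q_H is the total number of haplotype alleles over all blocks.
#'
#' @param panel a \code{phased_panel} with complete data.
#' @param partition a \code{block_partition} built from the same panel.
#' @return object of class \code{hap_dosage}: list with \code{M_H}
#'   (integer matrix [n_samples x Q_H]), \code{Q_H}, and \code{column_map}
#'   (data.frame: block, allele, display, count).
#' @export
dosage_matrix <- function(panel, partition) {
  stop_if_missing(panel, "dosage_matrix")
  n <- n_samples(panel)
  if (!length(partition$blocks))
    stop("partition contains no haploblocks; dosage matrix is empty")
  odd <- seq(1L, 2L * n, 2L)
  segs <- vector("list", length(partition$blocks))
  maps <- vector("list", length(partition$blocks))
  for (b in seq_along(partition$blocks)) {
    cat_b <- enumerate_block_alleles(panel, partition$blocks[[b]])
    H <- panel$haps[, cat_b$variant_indices, drop = FALSE]
    strings <- apply(H, 1L, paste, collapse = "")
    code <- match(strings, cat_b$alleles)
    if (anyNA(code))
      stop("internal error: observed haplotype absent from block catalogue")
    q <- length(cat_b$alleles)
    seg <- matrix(0L, nrow = n, ncol = q)
    h1 <- code[odd]; h2 <- code[odd + 1L]
    seg[cbind(seq_len(n), h1)] <- seg[cbind(seq_len(n), h1)] + 1L
    seg[cbind(seq_len(n), h2)] <- seg[cbind(seq_len(n), h2)] + 1L
    colnames(seg) <- paste0("b", b, ":", cat_b$display)
    segs[[b]] <- seg
    maps[[b]] <- data.frame(block = b, allele = cat_b$alleles,
                            display = cat_b$display, count = cat_b$counts,
                            stringsAsFactors = FALSE)
  }
  M_H <- do.call(cbind, segs)
  rownames(M_H) <- panel$sample_ids
  structure(list(M_H = M_H, Q_H = ncol(M_H),
                 column_map = do.call(rbind, maps)),
            class = "hap_dosage")
}

#' @export
print.hap_dosage <- function(x, ...) {
  cat("hap_dosage:", nrow(x$M_H), "samples x Q_H =", x$Q_H,
      "haplotype alleles over", max(x$column_map$block), "blocks\n")
  invisible(x)
}

#' Write a dosage matrix as delimited text
#' @param dosage a \code{hap_dosage}.
#' @param path output path.
#' @param sparse write triplet form (row, col, value) instead of dense.
#' @return path, invisibly.
#' @export
write_dosage_matrix <- function(dosage, path, sparse = FALSE) {
  M <- dosage$M_H
  if (sparse) {
    nz <- which(M != 0L, arr.ind = TRUE)
    df <- data.frame(sample = rownames(M)[nz[, 1]],
                     column = colnames(M)[nz[, 2]],
                     dosage = M[nz])
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(cbind(sample = rownames(M), as.data.frame(M)), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
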