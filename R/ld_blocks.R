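#' Linkage disequilibrium between two variants from phased haplotypes
#'
#' Haplotype frequencies are counted directly over the 2n phased
#' chromosomes; then \eqn{D = p_{A1B1} p_{A2B2} - p_{A1B2} p_{A2B1}} and
#' \eqn{r^2 = D^2 / (p_{A1} p_{A2} p_{B1} p_{B2})}. Allele 1 at each locus
#' is the REF (hap code 0), allele 2 the ALT (hap code 1); r-squared is
#' invariant to that labelling.
#'
#' @param panel a \code{phased_panel} with complete data.
#' @param i,j variant indices (both must be polymorphic).
#' @return list with \code{D}, \code{r2}, haplotype frequencies
#'   (\code{p_A1B1}, \code{p_A1B2}, \code{p_A2B1}, \code{p_A2B2}) and
#'   allele frequencies (\code{p_A1}, \code{p_A2}, \code{p_B1}, \code{p_B2}).
#' @export
ld_r2 <- function(panel, i, j) {
  stop_if_missing(panel, "ld_r2")
  a <- panel$haps[, i]
  b <- panel$haps[, j]
  ld_r2_haps(a, b, panel$variants$id[c(i, j)])
}

# core on two 0/1 haplotype vectors
ld_r2_haps <- function(a, b, ids = c("i", "j")) {
  nh <- length(a)
  pA2 <- mean(a); pB2 <- mean(b)         # ALT frequencies
  if (pA2 %in% c(0, 1))
    stop("undefined LD (zero variance) at variant ", ids[1])
  if (pB2 %in% c(0, 1))
    stop("undefined LD (zero variance) at variant ", ids[2])
  p11 <- sum(a == 0L & b == 0L) / nh     # A1B1
  p12 <- sum(a == 0L & b == 1L) / nh     # A1B2
  p21 <- sum(a == 1L & b == 0L) / nh     # A2B1
  p22 <- sum(a == 1L & b == 1L) / nh     # A2B2
  D <- p11 * p22 - p12 * p21
  r2 <- D^2 / ((1 - pA2) * pA2 * (1 - pB2) * pB2)
  list(D = D, r2 = r2,
       p_A1B1 = p11, p_A1B2 = p12, p_A2B1 = p21, p_A2B2 = p22,
       p_A1 = 1 - pA2, p_A2 = pA2, p_B1 = 1 - pB2, p_B2 = pB2)
}

# pairwise r2 matrix for a set of variant columns (complete, polymorphic)
ld_r2_matrix <- function(haps) {
  p <- colMeans(haps)
  # r = cor of haplotype indicator vectors; r^2 equals D^2/(pA1 pA2 pB1 pB2)
  r <- stats::cor(haps)
  r * r
}

#' Build haploblocks at an r-squared threshold
#'
#' Greedy left-to-right scan over the consecutive variants of one
#' chromosome: the current block absorbs the next variant while its
#' r-squared with \emph{every} variant already in the block meets the
#' threshold; otherwise the block is closed (emitted if it holds at least
#' two SNPs, its lone SNP marked non-blocked otherwise) and a new block
#' starts at the failing variant. Every pair inside every emitted block
#' therefore satisfies \code{r2 >= r2_threshold}. Blocks never skip
#' markers, so the non-blocked set is well defined.
#'
#' @param panel a \code{phased_panel}, complete and polymorphic.
#' @param chrom chromosome label present in the panel.
#' @param r2_threshold threshold in (0, 1].
#' @return object of class \code{block_partition}: list with \code{blocks}
#'   (each a list with \code{chrom}, \code{variant_indices} — global panel
#'   indices — \code{n_snps}, \code{span_bp}), \code{non_blocked} (global
#'   indices), \code{r2_threshold} and a \code{summary} list.
#' @export
build_haploblocks <- function(panel, chrom, r2_threshold) {
  if (r2_threshold <= 0 || r2_threshold > 1)
    stop("r2_threshold must lie in (0, 1]")
  stop_if_missing(panel, "build_haploblocks")
  idx <- which(panel$variants$chrom == chrom)
  if (!length(idx)) stop("unknown chromosome: ", chrom)
  H <- panel$haps[, idx, drop = FALSE]
  p <- colMeans(H)
  if (any(p %in% c(0, 1)))
    stop("monomorphic variant(s) on chromosome ", chrom,
         "; run QC before block construction")
  m <- length(idx)
  blocks <- list(); non_blocked <- integer(0)
  cur <- 1L                       # local indices of current candidate block
  if (m >= 2L) {
    for (k in 2L:m) {
      r2k <- as.vector(stats::cor(H[, cur, drop = FALSE], H[, k]))^2
      if (all(r2k >= r2_threshold)) {
        cur <- c(cur, k)
      } else {
        if (length(cur) >= 2L) blocks[[length(blocks) + 1L]] <- cur
        else non_blocked <- c(non_blocked, cur)
        cur <- k
      }
    }
  }
  if (length(cur) >= 2L) blocks[[length(blocks) + 1L]] <- cur
  else non_blocked <- c(non_blocked, cur)

  pos <- panel$variants$pos[idx]
  blocks <- lapply(blocks, function(b)
    list(chrom = chrom, variant_indices = idx[b], n_snps = length(b),
         span_bp = pos[b[length(b)]] - pos[b[1]]))
  new_block_partition(blocks, idx[non_blocked], r2_threshold,
                      n_total = m)
}

new_block_partition <- function(blocks, non_blocked, r2_threshold, n_total) {
  nb <- length(blocks)
  n_blocked <- sum(vapply(blocks, `[[`, integer(1), "n_snps"))
  structure(list(blocks = blocks,
                 non_blocked = non_blocked,
                 r2_threshold = r2_threshold,
                 summary = list(n_blocks = nb,
                                n_blocked_snps = n_blocked,
                                n_non_blocked = length(non_blocked),
                                mean_snps_per_block =
                                  if (nb) n_blocked / nb else NA_real_)),
            class = "block_partition")
}

#' @export
print.block_partition <- function(x, ...) {
  s <- x$summary
  cat("block_partition (r2 >=", x$r2_threshold, "):", s$n_blocks,
      "haploblocks,", s$n_blocked_snps, "blocked SNPs,",
      s$n_non_blocked, "non-blocked SNPs",
      if (s$n_blocks) sprintf("(mean %.2f SNPs/block)", s$mean_snps_per_block)
      else "", "\n")
  invisible(x)
}

#' Build haploblocks chromosome by chromosome over a whole panel
#'
#' Applies \code{\link{build_haploblocks}} separately to every chromosome
#' (blocks never span chromosomes) and concatenates the partitions.
#'
#' @param panel a \code{phased_panel}.
#' @param r2_threshold threshold in (0, 1].
#' @return a \code{block_partition} over all panel variants.
#' @export
build_block_partition <- function(panel, r2_threshold) {
  parts <- lapply(unique(panel$variants$chrom), function(ch)
    build_haploblocks(panel, ch, r2_threshold))
  blocks <- do.call(c, lapply(parts, `[[`, "blocks"))
  non_blocked <- sort(unlist(lapply(parts, `[[`, "non_blocked")))
  new_block_partition(blocks, non_blocked, r2_threshold,
                      n_total = n_variants(panel))
}

#' Blocked variant indices of a partition
#' @param partition a \code{block_partition}.
#' @return sorted integer vector of panel variant indices inside blocks.
#' @export
blocked_indices <- function(partition) {
  sort(unlist(lapply(partition$blocks, `[[`, "variant_indices")))
}

#' LD decay profile
#'
#' Mean r-squared of all polymorphic variant pairs on one chromosome,
#' binned by physical distance into half-open windows
#' \code{[k*window_bp, (k+1)*window_bp)} up to \code{max_dist_bp}.
#' Pairs at distance 0 are excluded; bins with no pairs are reported with
#' \code{n_pairs = 0} and \code{mean_r2 = NA}.
#'
#' @param panel a \code{phased_panel} with complete data.
#' @param chrom chromosome label.
#' @param max_dist_bp maximum pair distance considered (default 100000).
#' @param window_bp bin width in bp (default 1000).
#' @return data.frame with \code{bin_start}, \code{bin_end},
#'   \code{mean_r2}, \code{n_pairs}.
#' @export
ld_decay_profile <- function(panel, chrom, max_dist_bp = 100000L,
                             window_bp = 1000L) {
  if (window_bp < 1L) stop("window_bp must be >= 1")
  if (max_dist_bp < window_bp) stop("max_dist_bp must be >= window_bp")
  stop_if_missing(panel, "ld_decay_profile")
  idx <- which(panel$variants$chrom == chrom)
  if (!length(idx)) stop("unknown chromosome: ", chrom)
  pos <- panel$variants$pos[idx]
  H <- panel$haps[, idx, drop = FALSE]
  p <- colMeans(H)
  poly <- which(p > 0 & p < 1)
  n_bins <- ceiling(max_dist_bp / window_bp)
  sums <- numeric(n_bins); cnts <- integer(n_bins)
  if (length(poly) >= 2L) {
    R2 <- ld_r2_matrix(H[, poly, drop = FALSE])
    pp <- pos[poly]
    for (a in 1:(length(poly) - 1L)) {
      dist <- pp[(a + 1L):length(poly)] - pp[a]
      ok <- which(dist > 0 & dist <= max_dist_bp)
      if (!length(ok)) next
      bin <- dist[ok] %/% window_bp + 1L
      bin[bin > n_bins] <- n_bins       # distance == max_dist_bp lands in last bin
      r2v <- R2[a, a + ok]
      for (u in seq_along(ok)) {
        sums[bin[u]] <- sums[bin[u]] + r2v[u]
        cnts[bin[u]] <- cnts[bin[u]] + 1L
      }
    }
  }
  data.frame(bin_start = (seq_len(n_bins) - 1L) * window_bp,
             bin_end = seq_len(n_bins) * window_bp,
             mean_r2 = ifelse(cnts > 0, sums / pmax(cnts, 1L), NA_real_),
             n_pairs = cnts)
}

#' Write haploblocks as tab-delimited text
#'
#' One row per block: chrom, start_pos, end_pos, n_snps, comma-joined SNP
#' ids (PLINK \code{.blocks.det}-like layout).
#'
#' @param partition a \code{block_partition}.
#' @param panel the panel the partition was built from.
#' @param path output path.
#' @return path, invisibly.
#' @export
write_block_table <- function(partition, panel, path) {
  rows <- lapply(partition$blocks, function(b) {
    v <- panel$variants[b$variant_indices, ]
    data.frame(chrom = b$chrom, start_pos = v$pos[1],
               end_pos = v$pos[nrow(v)], n_snps = b$n_snps,
               snp_ids = paste(v$id, collapse = ","))
  })
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(chrom = character(0), start_pos = integer(0),
                        end_pos = integer(0), n_snps = integer(0),
                        snp_ids = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
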