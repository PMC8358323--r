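# Shared fixture builders. All fixtures are constructed in code so the
# suite carries no data files.

# panel from an explicit haplotype matrix (2n rows x m variants)
make_panel <- function(haps, chrom = "1", pos = NULL, ids = NULL) {
  haps <- as.matrix(haps)
  m <- ncol(haps); n <- nrow(haps) / 2
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(n))
  phased_panel(haps,
               data.frame(chrom = chrom, pos = pos,
                          id = sprintf("v%03d", seq_len(m)),
                          ref = "A", alt = "C", stringsAsFactors = FALSE),
               ids)
}

# random polymorphic panel (complete data)
random_panel <- function(n, m, seed = 1, p_range = c(0.15, 0.85)) {
  set.seed(seed)
  repeat {
    p <- runif(m, p_range[1], p_range[2])
    H <- vapply(p, function(pp) as.integer(runif(2 * n) < pp),
                integer(2 * n))
    cm <- colMeans(H)
    if (all(cm > 0 & cm < 1)) return(make_panel(H))
  }
}

# panel with exact haplotype frequencies at 2 loci:
# counts of (A1B1, A1B2, A2B1, A2B2) over the 2n haplotypes
two_locus_panel <- function(counts) {
  stopifnot(sum(counts) %% 2 == 0)
  combos <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  H <- combos[rep(1:4, counts), , drop = FALSE]
  make_panel(H)
}

# write a small phased VCF as plain text; returns the path
write_vcf_text <- function(gt_rows, path = tempfile(fileext = ".vcf"),
                           samples = paste0("S", seq_along(strsplit(gt_rows[[1]]$gt, " ")[[1]]))) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(gt_rows, function(r)
    paste(c(r$chrom %||% "1", r$pos, r$id %||% paste0("v", r$pos), r$ref %||% "A",
            r$alt %||% "C", ".", "PASS", ".", "GT",
            strsplit(r$gt, " ")[[1]]), collapse = "\t"),
    character(1))
  writeLines(c(hdr, body), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent oracle: r2 from explicit haplotype-frequency counting
oracle_r2 <- function(a, b) {
  nh <- length(a)
  f <- c(sum(a == 0 & b == 0), sum(a == 0 & b == 1),
         sum(a == 1 & b == 0), sum(a == 1 & b == 1)) / nh
  D <- f[1] * f[4] - f[2] * f[3]
  pA1 <- f[1] + f[2]; pB1 <- f[1] + f[3]
  D^2 / (pA1 * (1 - pA1) * pB1 * (1 - pB1))
}

# independent oracle: dense restricted log-likelihood (no 2*pi constant)
oracle_rll <- function(y, Vlist, theta) {
  n <- length(y)
  V <- Reduce(`+`, Map(function(K, s) s * K, Vlist, theta[-length(theta)])) +
    theta[length(theta)] * diag(n)
  X <- matrix(1, n, 1)
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)[1, 1]
  P <- Vi - (Vi %*% X %*% t(X) %*% Vi) / XtViX
  -0.5 * (determinant(V)$modulus[1] + log(XtViX) +
            crossprod(y, P %*% y)[1, 1])
}
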