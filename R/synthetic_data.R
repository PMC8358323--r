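#' Simulation configuration
#'
#' Parameters of the founder-mosaic genotype simulator and the additive
#' phenotype generator. The defaults define a desk-scale population with
#' the statistical structure the haploblock pipeline assumes: runs of
#' SNPs in strong mutual LD (founder mosaics), interleaved low-LD
#' singleton SNPs, an additive polygenic trait of chosen heritability and
#' sex/year/covariate fixed effects.
#'
#' @param n_individuals number of diploid individuals (default 600).
#' @param n_blocks number of LD blocks (default 40).
#' @param snps_per_block SNPs per block, length-2 range sampled uniformly
#'   (default c(8, 8)).
#' @param founders_per_block distinct founder haplotypes per block
#'   (default 4; 2 gives perfect within-block LD).
#' @param n_loose_snps independent non-block SNPs interleaved between
#'   blocks (default 80).
#' @param recomb_prob probability that a gamete redraws its founder
#'   lineage between adjacent blocks; 1 makes blocks fully independent,
#'   the default 0.5 leaves mild adjacent-block correlation (the redraw
#'   can land on the same founder, so lineage correlation decays as the
#'   gap between blocks grows).
#' @param founder_switch_prob per-site probability that a founder
#'   haplotype switches between the two ancestral haplotypes it is a
#'   mosaic of (default 0.08); controls how fast within-block r-squared
#'   decays with distance.
#' @param leakage_rate per-site allele flip probability inside blocks
#'   (default 0.02); erodes within-block LD.
#' @param n_qtl number of causal variants (default 100).
#' @param h2_target realized narrow-sense heritability in (0, 1)
#'   (default 0.5).
#' @param qtl_effect_sd SD of the i.i.d. normal QTL effects (default 1).
#' @param sex_levels,year_levels factor levels for the fixed effects.
#' @param sex_effects,year_effects true level effects (first level = 0
#'   reference if NULL, others drawn once from the stated defaults).
#' @param entry_weight_range,fattening_days_range covariate ranges.
#' @param beta_entry_weight,beta_fattening_days true covariate slopes.
#' @param mu trait intercept.
#' @param chrom chromosome label (default "1").
#' @param snp_spacing_bp within-block marker spacing (default 1000).
#' @param block_gap_bp gap between consecutive blocks (default 50000).
#' @param seed integer RNG seed.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_individuals = 600L, n_blocks = 40L,
                       snps_per_block = c(8L, 8L), founders_per_block = 4L,
                       n_loose_snps = 80L, recomb_prob = 0.5,
                       founder_switch_prob = 0.08,
                       leakage_rate = 0.02, n_qtl = 100L, h2_target = 0.5,
                       qtl_effect_sd = 1,
                       sex_levels = c("M", "F"),
                       year_levels = as.character(2008:2015),
                       sex_effects = NULL, year_effects = NULL,
                       entry_weight_range = c(180, 320),
                       fattening_days_range = c(300, 500),
                       beta_entry_weight = 0.05, beta_fattening_days = 0.02,
                       mu = 50, chrom = "1", snp_spacing_bp = 1000L,
                       block_gap_bp = 50000L, seed = 1L) {
  if (h2_target <= 0 || h2_target >= 1) stop("h2_target must lie in (0, 1)")
  rt <- c(recomb_prob, founder_switch_prob, leakage_rate)
  if (any(rt < 0 | rt > 1)) stop("rates must lie in [0, 1]")
  rm(rt)
  if (min(n_individuals, n_blocks, founders_per_block, n_qtl) < 1)
    stop("counts must be >= 1")
  if (length(snps_per_block) == 1L) snps_per_block <- rep(snps_per_block, 2L)
  if (is.null(sex_effects)) sex_effects <- c(0, 4)[seq_along(sex_levels)]
  if (is.null(year_effects))
    year_effects <- c(0, seq(-2, 2, length.out = max(length(year_levels) - 1L, 1L)))[
      seq_along(year_levels)]
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a phased genotype panel with block LD structure
#'
#' Each block carries a small pool of founder haplotypes, themselves
#' mosaics of two ancestral haplotypes (one all-REF, one all-ALT) with a
#' per-site switch probability, so alleles within a block sit in strong
#' mutual LD that decays with distance — the structure LD-threshold block
#' construction is built for. Each gamete keeps or redraws its founder
#' lineage between blocks with probability \code{recomb_prob} and flips
#' individual alleles at the leakage rate, which further erodes
#' within-block r-squared. Non-block ("loose") SNPs are drawn
#' independently per haplotype from a random allele frequency, so their
#' LD with everything else is at sampling noise. Monomorphic sites are
#' resampled (bounded retries), so the output is polymorphic throughout.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{panel} (a \code{phased_panel}) and
#'   \code{truth} (list: block index per variant — NA for loose SNPs —
#'   founder haplotypes, config).
#' @export
simulate_haplotype_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  n <- config$n_individuals
  nh <- 2L * n
  B <- config$n_blocks
  sizes <- if (config$snps_per_block[1] == config$snps_per_block[2])
    rep(config$snps_per_block[1], B)
  else sample(config$snps_per_block[1]:config$snps_per_block[2], B, TRUE)

  founders <- vector("list", B)
  for (b in seq_len(B)) {
    for (try in 1:50) {
      # each founder is a Markov mosaic of the two ancestral haplotypes
      f <- t(vapply(seq_len(config$founders_per_block), function(fi) {
        state <- sample(0:1, 1L)
        out <- integer(sizes[b])
        for (s in seq_len(sizes[b])) {
          if (s > 1L && stats::runif(1) < config$founder_switch_prob)
            state <- 1L - state
          out[s] <- state
        }
        out
      }, integer(sizes[b])))
      # every site polymorphic across the founder pool
      cm <- colMeans(f)
      if (all(cm > 0 & cm < 1)) break
      if (try == 50) stop("could not draw polymorphic founders for block ", b)
    }
    founders[[b]] <- f
  }

  # founder lineage per gamete per block: Markov chain along the genome
  lineage <- matrix(0L, nrow = nh, ncol = B)
  lineage[, 1] <- sample.int(config$founders_per_block, nh, TRUE)
  if (B > 1) for (b in 2:B) {
    redraw <- stats::runif(nh) < config$recomb_prob
    lineage[, b] <- ifelse(redraw,
                           sample.int(config$founders_per_block, nh, TRUE),
                           lineage[, b - 1])
  }

  block_haps <- vector("list", B)
  for (b in seq_len(B)) {
    h <- founders[[b]][lineage[, b], , drop = FALSE]
    if (config$leakage_rate > 0) {
      flip <- matrix(stats::runif(length(h)) < config$leakage_rate, nrow = nh)
      h <- (h + flip) %% 2L
    }
    # resample monomorphic sites from the panel's own haplotypes
    for (try in 1:50) {
      cm <- colMeans(h)
      mono <- which(cm == 0 | cm == 1)
      if (!length(mono)) break
      for (j in mono) h[sample.int(nh, max(2L, round(nh * 0.05))), j] <-
          sample(0:1, max(2L, round(nh * 0.05)), TRUE)
      if (try == 50) stop("monomorphic block after simulation (block ", b, ")")
    }
    block_haps[[b]] <- h
  }

  loose <- NULL
  if (config$n_loose_snps > 0) {
    pf <- stats::runif(config$n_loose_snps, 0.1, 0.9)
    loose <- vapply(pf, function(p) {
      for (try in 1:50) {
        x <- as.integer(stats::runif(nh) < p)
        if (any(x == 1L) && any(x == 0L)) return(x)
      }
      stop("monomorphic loose SNP after retries")
    }, integer(nh))
  }

  # interleave: block b, then its share of loose SNPs
  per_gap <- if (config$n_loose_snps > 0)
    diff(round(seq(0, config$n_loose_snps, length.out = B + 1L))) else rep(0L, B)
  cols <- list(); block_of <- integer(0); pos <- integer(0)
  cursor <- 1L; loose_used <- 0L
  for (b in seq_len(B)) {
    cols[[length(cols) + 1L]] <- block_haps[[b]]
    block_of <- c(block_of, rep(b, sizes[b]))
    pos <- c(pos, cursor + (seq_len(sizes[b]) - 1L) * config$snp_spacing_bp)
    cursor <- pos[length(pos)] + config$block_gap_bp
    if (per_gap[b] > 0) {
      sel <- loose[, loose_used + seq_len(per_gap[b]), drop = FALSE]
      cols[[length(cols) + 1L]] <- sel
      block_of <- c(block_of, rep(NA_integer_, per_gap[b]))
      pos <- c(pos, cursor + (seq_len(per_gap[b]) - 1L) * config$block_gap_bp)
      cursor <- pos[length(pos)] + config$block_gap_bp
      loose_used <- loose_used + per_gap[b]
    }
  }
  haps <- do.call(cbind, cols)
  m <- ncol(haps)
  variants <- data.frame(chrom = config$chrom, pos = pos,
                         id = sprintf("snp%05d", seq_len(m)),
                         ref = "A", alt = "C", stringsAsFactors = FALSE)
  panel <- phased_panel(haps, variants,
                        sprintf("ind%04d", seq_len(n)))
  list(panel = panel,
       truth = list(block_of = block_of, founders = founders,
                    config = config))
}

#' Simulate phenotypes with known architecture on a panel
#'
#' Samples \code{n_qtl} causal variants among the panel's markers, draws
#' i.i.d. normal allele-substitution effects, and scales the residuals so
#' the \emph{realized} heritability var(g)/(var(g)+var(e)) equals
#' \code{h2_target} exactly. Fixed effects (sex, year, entry weight,
#' fattening days) are then added with the configured true coefficients.
#'
#' @param panel a \code{phased_panel} from
#'   \code{\link{simulate_haplotype_panel}}.
#' @param truth the \code{truth} element returned with the panel.
#' @param config the same \code{\link{sim_config}}.
#' @return list with \code{pheno} (data.frame: id, trait, sex, year,
#'   entry_weight, fattening_days) and \code{truth} extended with
#'   \code{tbv} (true breeding values), \code{qtl_idx},
#'   \code{qtl_effects}, \code{realized_h2}, fixed-effect coefficients.
#' @export
simulate_phenotypes <- function(panel, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed + 777L)
  n <- n_samples(panel); m <- n_variants(panel)
  if (config$n_qtl > m) stop("n_qtl exceeds the number of simulated variants")
  qtl <- sort(sample.int(m, config$n_qtl))
  eff <- stats::rnorm(config$n_qtl, 0, config$qtl_effect_sd)
  D <- genotype_dosage(panel)[, qtl, drop = FALSE]
  g <- as.vector(D %*% eff)
  vg <- stats::var(g)
  if (vg == 0) stop("zero genetic variance: all QTL monomorphic or effects null")
  e <- stats::rnorm(n)
  e <- e - mean(e)
  e <- e * sqrt(vg * (1 - config$h2_target) / config$h2_target / stats::var(e))
  realized_h2 <- vg / (vg + stats::var(e))

  sex <- sample(config$sex_levels, n, TRUE)
  year <- sample(config$year_levels, n, TRUE)
  entry_weight <- stats::runif(n, config$entry_weight_range[1],
                               config$entry_weight_range[2])
  fattening_days <- round(stats::runif(n, config$fattening_days_range[1],
                                       config$fattening_days_range[2]))
  fx <- config$sex_effects[match(sex, config$sex_levels)] +
    config$year_effects[match(year, config$year_levels)] +
    config$beta_entry_weight * entry_weight +
    config$beta_fattening_days * fattening_days
  yobs <- config$mu + fx + g + e
  pheno <- data.frame(id = panel$sample_ids, trait = yobs, sex = sex,
                      year = year, entry_weight = entry_weight,
                      fattening_days = fattening_days,
                      stringsAsFactors = FALSE)
  truth$tbv <- g
  truth$qtl_idx <- qtl
  truth$qtl_effects <- eff
  truth$realized_h2 <- realized_h2
  truth$fixed_effects <- list(mu = config$mu,
                              sex = stats::setNames(config$sex_effects,
                                                    config$sex_levels),
                              year = stats::setNames(config$year_effects,
                                                     config$year_levels),
                              beta_entry_weight = config$beta_entry_weight,
                              beta_fattening_days = config$beta_fattening_days)
  list(pheno = pheno, truth = truth)
}

#' Write simulation truth as tab-delimited text
#' @param truth the extended truth list from \code{simulate_phenotypes}.
#' @param panel the simulated panel.
#' @param dir output directory (created if needed).
#' @return dir, invisibly.
#' @export
write_sim_truth <- function(truth, panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(id = panel$sample_ids, tbv = truth$tbv),
    file.path(dir, "true_breeding_values.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(variant = panel$variants$id[truth$qtl_idx],
               effect = truth$qtl_effects),
    file.path(dir, "qtl_effects.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(variant = panel$variants$id,
               block = ifelse(is.na(truth$block_of), "loose",
                              as.character(truth$block_of))),
    file.path(dir, "true_blocks.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
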