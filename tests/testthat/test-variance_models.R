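# fixed K for small-n fixtures: PSD, informative structure; a small
# n_markers gives a strongly structured (far-from-identity) matrix
make_fixture_K <- function(n, seed = 1, n_markers = n + 4) {
  set.seed(seed)
  W <- matrix(rnorm(n * n_markers), n)
  K <- tcrossprod(W) / n_markers
  K / mean(diag(K))
}

test_that("constant phenotype lands on the boundary with a warning", {
  K <- make_fixture_K(6)
  expect_warning(fit <- fit_single_grm_reml(rep(3, 6), K), "constant")
  expect_equal(fit$vc$h2, 0)
  expect_equal(fit$gebv, rep(0, 6))
})

test_that("single-GRM REML matches a dense grid-search oracle (n = 6)", {
  n <- 6
  K <- make_fixture_K(n, seed = 2)
  set.seed(3)
  y <- as.vector(chol(0.6 * K + 0.4 * diag(n)) %*% rnorm(n)) + 2
  fit <- fit_single_grm_reml(y, K)

  # coarse-to-fine grid over (sigma2_a, sigma2_e) on the dense restricted
  # likelihood, independent of the eigendecomposition route
  best <- c(NA, NA); bestll <- -Inf
  grid <- expand.grid(sa = seq(0.01, 3, length.out = 60),
                      se = seq(0.01, 3, length.out = 60))
  for (i in seq_len(nrow(grid))) {
    ll <- oracle_rll(y, list(K), c(grid$sa[i], grid$se[i]))
    if (ll > bestll) { bestll <- ll; best <- c(grid$sa[i], grid$se[i]) }
  }
  for (pass in 1:3) {
    rng_a <- best[1] + seq(-0.05, 0.05, length.out = 41) / 10^(pass - 1)
    rng_e <- best[2] + seq(-0.05, 0.05, length.out = 41) / 10^(pass - 1)
    grid <- expand.grid(sa = pmax(rng_a, 1e-4), se = pmax(rng_e, 1e-4))
    for (i in seq_len(nrow(grid))) {
      ll <- oracle_rll(y, list(K), c(grid$sa[i], grid$se[i]))
      if (ll > bestll) { bestll <- ll; best <- c(grid$sa[i], grid$se[i]) }
    }
  }
  expect_equal(fit$vc$sigma2_a, best[1], tolerance = 2e-3)
  expect_equal(fit$vc$sigma2_e, best[2], tolerance = 2e-3)
  # the profile optimum is at least as good as the best grid point
  expect_gte(oracle_rll(y, list(K), c(fit$vc$sigma2_a, fit$vc$sigma2_e)),
             bestll - 1e-6)
})

test_that("REML is scale-equivariant and h2 is scale-free", {
  K <- make_fixture_K(40, seed = 4)
  set.seed(5)
  y <- as.vector(chol(0.5 * K + 0.5 * diag(40)) %*% rnorm(40))
  f1 <- fit_single_grm_reml(y, K)
  f2 <- fit_single_grm_reml(3 * y, K)
  expect_equal(f2$vc$sigma2_a, 9 * f1$vc$sigma2_a, tolerance = 1e-5)
  expect_equal(f2$vc$sigma2_e, 9 * f1$vc$sigma2_e, tolerance = 1e-5)
  expect_equal(f2$vc$h2, f1$vc$h2, tolerance = 1e-6)
})

test_that("heritability is the genetic fraction of total variance", {
  expect_equal(heritability(list(sigma2_a = 1, sigma2_e = 3)), 0.25)
  expect_equal(heritability(list(sigma2_a = 0, sigma2_e = 3)), 0)
  expect_equal(heritability(list(sigma2_a = 1, sigma2_au = 1,
                                 sigma2_e = 2)), 0.5)
  expect_error(heritability(list(sigma2_a = 0, sigma2_e = 0)), "zero total")
})

test_that("two-GRM REML matches a 3-D grid-search oracle (n = 8)", {
  n <- 8
  K1 <- make_fixture_K(n, seed = 6)
  K2 <- make_fixture_K(n, seed = 7)
  set.seed(8)
  y <- as.vector(chol(0.5 * K1 + 0.4 * K2 + 0.6 * diag(n)) %*% rnorm(n))
  fit <- fit_two_grm_reml(y, K1, K2)
  th <- c(fit$vc$sigma2_a, fit$vc$sigma2_au, fit$vc$sigma2_e)

  best <- rep(NA, 3); bestll <- -Inf
  gr <- seq(0.02, 2.5, length.out = 18)
  for (a in gr) for (b in gr) for (e in gr) {
    ll <- oracle_rll(y, list(K1, K2), c(a, b, e))
    if (ll > bestll) { bestll <- ll; best <- c(a, b, e) }
  }
  for (pass in 1:3) {
    span <- 0.15 / 3^(pass - 1)
    g1 <- pmax(best[1] + seq(-span, span, length.out = 11), 1e-4)
    g2 <- pmax(best[2] + seq(-span, span, length.out = 11), 1e-4)
    g3 <- pmax(best[3] + seq(-span, span, length.out = 11), 1e-4)
    for (a in g1) for (b in g2) for (e in g3) {
      ll <- oracle_rll(y, list(K1, K2), c(a, b, e))
      if (ll > bestll) { bestll <- ll; best <- c(a, b, e) }
    }
  }
  # AI-REML must do at least as well as the refined grid, at the same optimum
  expect_gte(oracle_rll(y, list(K1, K2), pmax(th, 1e-12)), bestll - 1e-5)
  expect_equal(th, best, tolerance = 0.02)
})

test_that("a zero-variance second component is driven to the boundary", {
  n <- 300
  cfg <- sim_config(n_individuals = n, n_blocks = 15, n_loose_snps = 30,
                    seed = 9)
  panel <- simulate_haplotype_panel(cfg)$panel
  G <- snp_grm(panel)
  # strongly structured second matrix so sigma2_au is identifiable and,
  # since the data carry no such component, estimated near zero
  K2 <- make_fixture_K(n, seed = 10, n_markers = 25)
  set.seed(11)
  y <- as.vector(chol(0.5 * G$values + 1e-8 * diag(n) + 0.5 * diag(n)) %*% rnorm(n))
  fit <- fit_two_grm_reml(y, G, K2)
  expect_lt(fit$vc$sigma2_au, 0.1 * fit$vc$sigma2_a)
})

test_that("identical K1 and K2 trigger the identifiability warning", {
  K <- make_fixture_K(12, seed = 12)
  set.seed(13)
  y <- rnorm(12)
  expect_warning(fit_two_grm_reml(y, K, K), "not separately identifiable")
})

test_that("two-component fit with one component pinned matches the single fit", {
  n <- 60
  K1 <- make_fixture_K(n, seed = 14)
  set.seed(15)
  y <- as.vector(chol(0.7 * K1 + 0.5 * diag(n)) %*% rnorm(n))
  single <- fit_single_grm_reml(y, K1)
  # a second matrix carrying no signal: its component should vanish and
  # the remaining components should agree with the single-GRM fit
  K2 <- make_fixture_K(n, seed = 16)
  two <- fit_two_grm_reml(y, K1, K2)
  if (two$vc$sigma2_au < 1e-6) {
    expect_equal(two$vc$sigma2_a, single$vc$sigma2_a, tolerance = 0.02)
    expect_equal(two$vc$sigma2_e, single$vc$sigma2_e, tolerance = 0.02)
  }
  # restricted likelihood of the nested model can never beat the wider one
  expect_gte(two$vc$loglik, single$vc$loglik - 1e-4)
})

test_that("REML recovers a simulated heritability (generative oracle)", {
  # moderate-n version of the recovery check; the full 50-replicate run at
  # n = 1000 lives in the acceptance suite
  cfg <- sim_config(n_individuals = 400, n_blocks = 20, n_loose_snps = 40,
                    h2_target = 0.5, seed = 17)
  sim <- simulate_haplotype_panel(cfg)
  ph <- simulate_phenotypes(sim$panel, sim$truth, cfg)
  adj <- adjust_phenotypes(ph$pheno, "trait")
  fit <- fit_single_grm_reml(adj$y_star, snp_grm(sim$panel))
  expect_equal(fit$vc$h2, 0.5, tolerance = 0.15)
})

test_that("GEBV prediction degenerates correctly", {
  K <- make_fixture_K(10, seed = 18)
  vc <- list(mu = 0, sigma2_a = 0, sigma2_au = NULL, sigma2_e = 1)
  expect_equal(predict_gebv(vc, rnorm(7), K, 1:7, 8:10), c(0, 0, 0))
  # validation individual unrelated to training: gebv 0
  K0 <- diag(10)
  vc1 <- list(mu = 0, sigma2_a = 1, sigma2_e = 1)
  set.seed(19)
  expect_equal(predict_gebv(vc1, rnorm(7), K0, 1:7, 8:10), c(0, 0, 0))
  expect_error(predict_gebv(vc1, rnorm(7), K0, 1:7, 7:10), "disjoint")
})

test_that("GRM-based prediction equals SNP-BLUP ridge on the same markers", {
  panel <- random_panel(40, 60, seed = 20)
  M <- genotype_dosage(panel)
  p <- allele_frequencies(panel)
  W <- sweep(M, 2, 2 * p)
  cdenom <- 2 * sum(p * (1 - p))
  G <- snp_grm(panel)
  trn <- 1:30; val <- 31:40
  set.seed(21)
  y <- as.vector(0.8 * scale(W %*% rnorm(60)) + rnorm(40))
  vc <- list(mu = NA, sigma2_a = 0.6, sigma2_e = 0.9)
  got <- predict_gebv(vc, y[trn], G, trn, val)

  # marker-effect (ridge) route: same GLS mean, u-hat from the training
  # normal equations, prediction W_val u-hat
  s2u <- vc$sigma2_a / cdenom
  Vtt <- s2u * tcrossprod(W[trn, ]) + vc$sigma2_e * diag(length(trn))
  Vi <- solve(Vtt)
  mu <- sum(Vi %*% y[trn]) / sum(Vi)
  uhat <- s2u * t(W[trn, ]) %*% (Vi %*% (y[trn] - mu))
  ridge <- as.vector(W[val, ] %*% uhat)
  expect_equal(got, ridge, tolerance = 1e-8)
})
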