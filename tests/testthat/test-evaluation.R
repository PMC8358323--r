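make_pheno <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(id = sprintf("i%03d", 1:n),
             trait = rnorm(n, 50, 5),
             sex = sample(c("M", "F"), n, TRUE),
             year = sample(2010:2013, n, TRUE),
             entry_weight = runif(n, 200, 300),
             fattening_days = round(runif(n, 300, 450)))
}

test_that("adjustment is the identity when fixed effects carry no variation", {
  ph <- make_pheno(30, seed = 1)
  ph$sex <- "M"; ph$year <- 2010
  ph$entry_weight <- 250; ph$fattening_days <- 400
  adj <- adjust_phenotypes(ph, "trait")
  expect_equal(unname(adj$y_star), ph$trait)
})

test_that("group means are equalized by adjustment", {
  n <- 40
  ph <- make_pheno(n, seed = 2)
  ph$sex <- rep(c("M", "F"), each = n / 2)
  ph$year <- 2010; ph$entry_weight <- 250; ph$fattening_days <- 400
  ph$trait <- ifelse(ph$sex == "M", 10, 20) + rnorm(n, 0, 0.5)
  adj <- adjust_phenotypes(ph, "trait")
  mM <- mean(adj$y_star[ph$sex == "M"])
  mF <- mean(adj$y_star[ph$sex == "F"])
  expect_equal(mM, mF, tolerance = 1e-10)
  expect_equal(mean(adj$y_star), mean(ph$trait))
})

test_that("adjustment matches an independent normal-equations solve", {
  ph <- make_pheno(60, seed = 3)
  b_true <- c(sexM = 3, yr = 1.5)
  ph$trait <- ph$trait + ifelse(ph$sex == "M", 3, 0) +
    1.5 * (ph$year - 2010) + 0.1 * ph$entry_weight
  adj <- adjust_phenotypes(ph, "trait")
  X <- model.matrix(~ factor(ph$sex) + factor(ph$year) + ph$entry_weight +
                      ph$fattening_days)
  beta <- solve(crossprod(X), crossprod(X, ph$trait))
  resid <- ph$trait - X %*% beta
  expect_equal(unname(adj$y_star), as.vector(resid) + mean(ph$trait),
               tolerance = 1e-10)
})

test_that("missing columns and collinear covariates are rejected", {
  ph <- make_pheno(20, seed = 4)
  expect_error(adjust_phenotypes(ph[, -3], "trait"), "missing column")
  ph2 <- make_pheno(20, seed = 5)
  ph2$fattening_days <- 2 * ph2$entry_weight
  expect_error(adjust_phenotypes(ph2, "trait"), "collinear")
})

test_that("accuracy and bias follow their closed forms", {
  expect_equal(prediction_accuracy(c(1, 2, 3, 4), c(1, 2, 3, 4), 1), 1)
  set.seed(6)
  y <- rnorm(50); g <- 0.4 * y + rnorm(50, 0, 0.5)
  expect_equal(prediction_accuracy(y, g, 0.25), cor(y, g) / 0.5)
  # cor = 0.3, h2 = 0.25 -> 0.6, built by direct evaluation
  expect_equal(cor(y, g) / sqrt(0.25), prediction_accuracy(y, g, 0.25))
  expect_error(prediction_accuracy(y, rep(1, 50), 0.25), "zero variance")

  expect_equal(regression_bias(g, g), 1)
  expect_equal(regression_bias(2 * g, g), 2)
  ols <- coef(lm(y ~ g))[2]
  expect_equal(regression_bias(y, g), unname(ols), tolerance = 1e-12)
  # accuracy invariant under positive affine rescale of gebv; bias halves
  expect_equal(prediction_accuracy(y, 2 * g + 1, 0.25),
               prediction_accuracy(y, g, 0.25))
  expect_equal(regression_bias(y, 2 * g), regression_bias(y, g) / 2)
})

test_that("Hotelling-Williams statistic matches its closed form", {
  ht0 <- hotelling_test(0.45, 0.45, 0.7, 50)
  expect_equal(ht0$t, 0)
  expect_equal(ht0$p, 1)

  ht <- hotelling_test(0.5, 0.4, 0.8, 103)
  expect_equal(ht$detR, 0.27, tolerance = 1e-12)
  expect_equal(ht$t, 1.8257, tolerance = 1e-4)
  expect_equal(ht$df, 100L)
  expect_equal(ht$p, 2 * pt(ht$t, 100, lower.tail = FALSE))

  # p decreases as |t| grows (monotone in the correlation gap)
  ps <- vapply(seq(0.40, 0.1, by = -0.05), function(rjh)
    hotelling_test(0.5, rjh, 0.6, 103)$p, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(hotelling_test(0.9, -0.9, 0.9, 50), "degenerate")
  expect_error(hotelling_test(0.5, 0.4, 0.8, 3), "n must be")
})

test_that("Hotelling test holds its type-I error under a trivariate null", {
  # null: both models equally correlated with the phenotype
  set.seed(7)
  n <- 60; nrep <- 1500
  S <- matrix(c(1, 0.5, 0.5, 0.5, 1, 0.6, 0.5, 0.6, 1), 3)
  L <- chol(S)
  rej <- 0L
  for (r in seq_len(nrep)) {
    X <- matrix(rnorm(3 * n), n) %*% L
    ht <- hotelling_test(cor(X[, 1], X[, 2]), cor(X[, 1], X[, 3]),
                         cor(X[, 2], X[, 3]), n)
    if (ht$p <= 0.05) rej <- rej + 1L
  }
  expect_equal(rej / nrep, 0.05, tolerance = 0.3)
})

test_that("fold assignments are balanced, exhaustive and seeded", {
  f <- make_cv_folds(1233, k = 5, repeats = 10, seed = 42)
  expect_equal(dim(f), c(1233, 10))
  for (r in 1:10) {
    sizes <- table(f[, r])
    expect_equal(sum(sizes), 1233)
    expect_lte(diff(range(sizes)), 1)
  }
  expect_identical(f, make_cv_folds(1233, k = 5, repeats = 10, seed = 42))
  expect_false(identical(f[, 1], make_cv_folds(1233, 5, 1, seed = 43)[, 1]))
})

# small CV setting shared by the next blocks
cv_setting <- function() {
  cfg <- sim_config(n_individuals = 150, n_blocks = 10, n_loose_snps = 20,
                    h2_target = 0.5, seed = 23)
  sim <- simulate_haplotype_panel(cfg)
  ph <- simulate_phenotypes(sim$panel, sim$truth, cfg)
  adj <- adjust_phenotypes(ph$pheno, "trait")
  part <- build_block_partition(sim$panel, 0.4)
  dm <- dosage_matrix(sim$panel, part)
  list(panel = sim$panel, y = adj$y_star,
       G = snp_grm(sim$panel), GH = haplotype_grm(dm))
}

test_that("cross-validation is deterministic and shares folds across models", {
  s <- cv_setting()
  models <- list(GBLUP = list(K = s$G), G_H_BLUP = list(K = s$GH))
  cv1 <- cross_validate(s$y, models, h2 = 0.5, k = 5, repeats = 2, seed = 1)
  cv2 <- cross_validate(s$y, models, h2 = 0.5, k = 5, repeats = 2, seed = 1)
  expect_identical(cv1$metrics, cv2$metrics)
  expect_identical(cv1$gebv, cv2$gebv)
  # every individual predicted exactly once per repeat, same folds for all
  expect_false(anyNA(cv1$gebv))
  expect_equal(nrow(cv1$metrics), 4)
})

test_that("model self-comparison gives p = 1 and cross-comparison runs", {
  s <- cv_setting()
  models <- list(GBLUP = list(K = s$G), G_H_BLUP = list(K = s$GH))
  cv <- cross_validate(s$y, models, h2 = 0.5, k = 5, repeats = 2, seed = 2)
  self <- compare_models(cv, s$y, "GBLUP", "GBLUP")
  expect_true(all(self$per_repeat$p == 1))
  expect_true(all(self$per_repeat$t == 0))
  cmp <- compare_models(cv, s$y, "GBLUP", "G_H_BLUP")
  expect_equal(nrow(cmp$per_repeat), 2)
  expect_true(all(cmp$per_repeat$p > 0 & cmp$per_repeat$p <= 1))
  expect_equal(sign(cmp$per_repeat$t),
               sign(cmp$per_repeat$r_jk - cmp$per_repeat$r_jh))
  expect_error(compare_models(cv, s$y, "GBLUP", "nope"), "not found")
})

test_that("GBLUP cross-validation tracks a reference ridge-regression CV", {
  cfg <- sim_config(n_individuals = 250, n_blocks = 12, n_loose_snps = 26,
                    h2_target = 0.5, n_qtl = 60, seed = 29)
  sim <- simulate_haplotype_panel(cfg)
  ph <- simulate_phenotypes(sim$panel, sim$truth, cfg)
  adj <- adjust_phenotypes(ph$pheno, "trait")
  y <- adj$y_star
  G <- snp_grm(sim$panel)
  cv <- cross_validate(y, list(GBLUP = list(K = G)), h2 = 0.5,
                       k = 5, repeats = 2, seed = 31)
  acc <- mean(cv$metrics$accuracy)
  expect_gt(acc, 0)

  # reference: ridge regression on centred markers with lambda from a
  # whole-data REML fit, same folds
  M <- genotype_dosage(sim$panel)
  p <- allele_frequencies(sim$panel)
  W <- sweep(M, 2, 2 * p)
  cdenom <- 2 * sum(p * (1 - p))
  whole <- fit_single_grm_reml(y, G)
  lam <- cdenom * whole$vc$sigma2_e / whole$vc$sigma2_a
  accs <- c()
  for (r in 1:2) {
    pred <- rep(NA_real_, length(y))
    for (f in 1:5) {
      val <- which(cv$folds[, r] == f); trn <- which(cv$folds[, r] != f)
      Wt <- W[trn, ]; yt <- y[trn]
      uh <- solve(crossprod(Wt) + lam * diag(ncol(W)),
                  crossprod(Wt, yt - mean(yt)))
      pred[val] <- as.vector(W[val, ] %*% uh)
    }
    accs <- c(accs, cor(y, pred) / sqrt(0.5))
  }
  expect_equal(acc, mean(accs), tolerance = 0.1)
})
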