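#' Adjust phenotypes for fixed effects
#'
#' Ordinary least-squares fit of the trait on sex and year (factors) and
#' on entry body weight and number of fattening days (covariates); the
#' adjusted phenotype is residual + overall trait mean, so it keeps the
#' trait's scale and centre while removing the fixed-effect structure.
#'
#' @param pheno data.frame with columns \code{id}, the trait, \code{sex},
#'   \code{year}, \code{entry_weight}, \code{fattening_days}.
#' @param trait name of the trait column.
#' @return list with \code{y_star} (named numeric vector, names = ids),
#'   \code{trait}, \code{fit} (the \code{lm} object).
#' @export
adjust_phenotypes <- function(pheno, trait) {
  need <- c("id", trait, "sex", "year", "entry_weight", "fattening_days")
  miss <- setdiff(need, names(pheno))
  if (length(miss))
    stop("phenotype table is missing column(s): ", paste(miss, collapse = ", "))
  df <- data.frame(y = pheno[[trait]],
                   sex = factor(pheno$sex), year = factor(pheno$year),
                   entry_weight = pheno$entry_weight,
                   fattening_days = pheno$fattening_days)
  singles <- c(names(which(table(df$sex) == 1L)),
               names(which(table(df$year) == 1L)))
  if (length(singles))
    warning("factor level(s) with a single observation: ",
            paste(singles, collapse = ", "))
  # drop constant terms so the design stays full rank
  terms <- c(if (nlevels(droplevels(df$sex)) > 1L) "sex",
             if (nlevels(droplevels(df$year)) > 1L) "year",
             if (stats::var(df$entry_weight) > 0) "entry_weight",
             if (stats::var(df$fattening_days) > 0) "fattening_days")
  if (!length(terms)) {
    y_star <- df$y
  } else {
    fml <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
    fit <- stats::lm(fml, data = df)
    if (any(is.na(stats::coef(fit))))
      stop("collinear fixed effects: ",
           paste(names(which(is.na(stats::coef(fit)))), collapse = ", "))
    y_star <- stats::residuals(fit) + mean(df$y)
  }
  names(y_star) <- pheno$id
  list(y_star = y_star, trait = trait,
       fit = if (length(terms)) fit else NULL)
}

#' Prediction accuracy
#'
#' Pearson correlation between adjusted phenotypes and GEBVs in the
#' validation set, divided by the square root of the trait heritability.
#'
#' @param y_star adjusted phenotypes.
#' @param gebv genomic estimated breeding values (same length >= 3).
#' @param h2 trait heritability in (0, 1].
#' @return accuracy (can exceed 1 in small samples).
#' @export
prediction_accuracy <- function(y_star, gebv, h2) {
  if (h2 <= 0 || h2 > 1) stop("h2 must lie in (0, 1]")
  if (length(y_star) != length(gebv) || length(y_star) < 3)
    stop("y_star and gebv must have equal length >= 3")
  if (stats::var(y_star) == 0 || stats::var(gebv) == 0)
    stop("zero variance in y_star or gebv: correlation undefined")
  stats::cor(y_star, gebv) / sqrt(h2)
}

#' Dispersion bias of GEBVs
#'
#' Regression coefficient of the adjusted phenotype on the GEBVs,
#' \eqn{b = Cov(gebv, y^*) / Var(gebv)}; b = 1 means neither inflation
#' nor deflation of the predictions.
#'
#' @param y_star adjusted phenotypes.
#' @param gebv GEBVs with positive variance.
#' @return the slope b.
#' @export
regression_bias <- function(y_star, gebv) {
  if (stats::var(gebv) == 0) stop("zero GEBV variance: slope undefined")
  stats::cov(gebv, y_star) / stats::var(gebv)
}

#' Hotelling-Williams test for two dependent correlations
#'
#' Tests \eqn{H_0: \rho_{jk} = \rho_{jh}} where both correlations share
#' variable j (here: the adjusted phenotype against two models' GEBVs):
#' \deqn{t = (r_{jk} - r_{jh}) \sqrt{ \frac{(n-3)(1 + r_{kh})}{2 |R|} },
#'   \quad df = n - 3}
#' \deqn{|R| = 1 + 2 r_{jk} r_{jh} r_{kh} - r_{jk}^2 - r_{jh}^2 - r_{kh}^2}
#'
#' @param r_jk,r_jh the two correlations with the shared variable.
#' @param r_kh correlation between the two non-shared variables.
#' @param n number of observations (>= 4).
#' @param alternative \code{"two.sided"} (default) or \code{"greater"}
#'   (\eqn{P(T \ge t)}, the one-sided form).
#' @return list with \code{r_jk}, \code{r_jh}, \code{r_kh}, \code{n},
#'   \code{detR}, \code{t}, \code{df}, \code{p}.
#' @export
hotelling_test <- function(r_jk, r_jh, r_kh, n,
                           alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (n < 4) stop("n must be >= 4 (df = n - 3 >= 1)")
  if (any(abs(c(r_jk, r_jh, r_kh)) > 1)) stop("correlations must lie in [-1, 1]")
  detR <- 1 + 2 * r_jk * r_jh * r_kh - r_jk^2 - r_jh^2 - r_kh^2
  if (detR <= 1e-12) {
    # |R| -> 0 with equal correlations (e.g. a model against itself):
    # the statistic's limit is 0, not a failure
    if (abs(r_jk - r_jh) <= 1e-12) {
      return(list(r_jk = r_jk, r_jh = r_jh, r_kh = r_kh, n = n, detR = detR,
                  t = 0, df = as.integer(n - 3), p = 1))
    }
    stop("degenerate correlation triple: |R| = ", format(detR), " <= 0")
  }
  t_stat <- (r_jk - r_jh) * sqrt((n - 3) * (1 + r_kh) / (2 * detR))
  df <- n - 3
  p <- switch(alternative,
              two.sided = 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE),
              greater = stats::pt(t_stat, df, lower.tail = FALSE))
  list(r_jk = r_jk, r_jh = r_jh, r_kh = r_kh, n = n, detR = detR,
       t = t_stat, df = as.integer(df), p = min(p, 1))
}

#' Seeded k-fold assignments
#'
#' Random partition of n individuals into k folds of as-equal-as-possible
#' size, repeated \code{repeats} times. All models evaluated on a run
#' share these assignments, which the dependent-correlation test requires.
#'
#' @param n number of individuals.
#' @param k folds per repeat.
#' @param repeats number of repeats.
#' @param seed integer RNG seed.
#' @return integer matrix [n x repeats] of fold labels 1..k.
#' @export
make_cv_folds <- function(n, k = 5L, repeats = 10L, seed = 1L) {
  if (k < 2L) stop("k must be >= 2")
  if (n < k) stop("n must be >= k")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  base <- rep(seq_len(k), length.out = n)
  vapply(seq_len(repeats), function(r) sample(base), integer(n))
}

#' Repeated k-fold cross-validation over a set of GBLUP models
#'
#' For every repeat, every fold and every model: variance components are
#' re-estimated by REML on the training individuals, validation GEBVs are
#' predicted through the relationship covariance, and per-repeat metrics
#' (correlation with the adjusted phenotype, accuracy, dispersion bias)
#' are computed on the validation predictions pooled across the k folds.
#' All models use identical fold assignments.
#'
#' @param y_star adjusted phenotype vector.
#' @param models named list of model specs; each spec is
#'   \code{list(K = grm)} for a single-component model or
#'   \code{list(K = grm, K2 = grm)} for a two-component model.
#' @param h2 heritability used in the accuracy denominator (the
#'   whole-data single-GRM estimate for the trait).
#' @param k folds (default 5).
#' @param repeats repeats (default 10).
#' @param seed RNG seed for the fold assignments.
#' @return object of class \code{cv_result}: list with \code{metrics}
#'   (data.frame: model, repeat_, cor, accuracy, bias), \code{gebv}
#'   (array [n x repeats x models] of pooled validation predictions),
#'   \code{folds} (matrix from \code{\link{make_cv_folds}}), \code{h2},
#'   \code{seed}, \code{summary} (per-model means and SDs).
#' @export
cross_validate <- function(y_star, models, h2, k = 5L, repeats = 10L,
                           seed = 1L) {
  n <- length(y_star)
  folds <- make_cv_folds(n, k = k, repeats = repeats, seed = seed)
  if (min(table(folds[, 1])) < 2L) stop("fold with < 2 validation individuals")
  model_names <- names(models)
  if (is.null(model_names) || any(model_names == ""))
    stop("models must be a named list")
  gebv <- array(NA_real_, dim = c(n, repeats, length(models)),
                dimnames = list(NULL, NULL, model_names))
  rows <- list()
  for (r in seq_len(repeats)) {
    for (mi in seq_along(models)) {
      spec <- models[[mi]]
      pred <- rep(NA_real_, n)
      for (f in seq_len(k)) {
        val <- which(folds[, r] == f)
        trn <- which(folds[, r] != f)
        Ktt <- grm_values(spec$K)[trn, trn, drop = FALSE]
        if (is.null(spec$K2)) {
          fit <- fit_single_grm_reml(y_star[trn], Ktt)
        } else {
          fit <- fit_two_grm_reml(y_star[trn],
                                  Ktt,
                                  grm_values(spec$K2)[trn, trn, drop = FALSE])
        }
        pred[val] <- predict_gebv(fit$vc, y_star[trn], spec$K, trn, val,
                                  K2 = spec$K2)
      }
      gebv[, r, mi] <- pred
      cc <- if (stats::var(pred) > 0) stats::cor(y_star, pred) else NA_real_
      rows[[length(rows) + 1L]] <-
        data.frame(model = model_names[mi], repeat_ = r, cor = cc,
                   accuracy = cc / sqrt(h2),
                   bias = if (stats::var(pred) > 0)
                     regression_bias(y_star, pred) else NA_real_)
    }
  }
  metrics <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(metrics, metrics$model), function(d)
    data.frame(model = d$model[1], mean_cor = mean(d$cor),
               mean_accuracy = mean(d$accuracy), sd_accuracy = stats::sd(d$accuracy),
               mean_bias = mean(d$bias))))
  rownames(agg) <- NULL
  structure(list(metrics = metrics, gebv = gebv, folds = folds, h2 = h2,
                 seed = seed, summary = agg[match(model_names, agg$model), ]),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result:", dim(x$gebv)[3], "model(s),", ncol(x$folds),
      "repeat(s) of", max(x$folds[, 1]), "folds on", nrow(x$folds),
      "individuals (h2 =", round(x$h2, 3), ")\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Compare two models' prediction accuracy with the Hotelling-Williams test
#'
#' Per repeat, on the pooled validation predictions: \code{r_jk} =
#' cor(y*, gebv of model 1), \code{r_jh} = cor(y*, gebv of model 2),
#' \code{r_kh} = cor of the two models' gebv vectors; the test is applied
#' per repeat and the reported p is the mean over repeats.
#'
#' @param cv a \code{cv_result}.
#' @param y_star the adjusted phenotypes the CV was run on.
#' @param model1,model2 names of the two models in \code{cv}.
#' @param alternative passed to \code{\link{hotelling_test}}.
#' @return list with \code{per_repeat} (data.frame: repeat_, r_jk, r_jh,
#'   r_kh, t, df, p) and \code{p_mean}, \code{t_mean}, \code{n}.
#' @export
compare_models <- function(cv, y_star, model1, model2,
                           alternative = "two.sided") {
  mnames <- dimnames(cv$gebv)[[3]]
  if (!(model1 %in% mnames) || !(model2 %in% mnames))
    stop("model name(s) not found in cv_result")
  n <- nrow(cv$folds)
  if (length(y_star) != n) stop("y_star length does not match cv_result")
  rows <- lapply(seq_len(ncol(cv$folds)), function(r) {
    g1 <- cv$gebv[, r, model1]; g2 <- cv$gebv[, r, model2]
    ht <- hotelling_test(stats::cor(y_star, g1), stats::cor(y_star, g2),
                         stats::cor(g1, g2), n, alternative = alternative)
    data.frame(repeat_ = r, r_jk = ht$r_jk, r_jh = ht$r_jh, r_kh = ht$r_kh,
               t = ht$t, df = ht$df, p = ht$p)
  })
  per_repeat <- do.call(rbind, rows)
  list(per_repeat = per_repeat, p_mean = mean(per_repeat$p),
       t_mean = mean(per_repeat$t), n = n,
       models = c(model1, model2), alternative = alternative)
}
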