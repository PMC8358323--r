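#' Single-relationship-matrix REML fit (GBLUP)
#'
#' Fits \eqn{y = 1\mu + a + e} with \eqn{a \sim N(0, \sigma^2_a K)} and
#' \eqn{e \sim N(0, \sigma^2_e I)} by restricted maximum likelihood.
#' K is eigendecomposed once and the restricted likelihood is profiled
#' over the single variance ratio \eqn{\gamma = \sigma^2_a/\sigma^2_e},
#' so the fit is a 1-D optimisation — fast and free of convergence
#' trouble. BLUP solutions for a (the GEBVs of the fitted individuals)
#' are returned alongside the components.
#'
#' @param y numeric phenotype vector (adjusted phenotypes; the only fixed
#'   effect fitted is the intercept).
#' @param K a \code{grm} or bare symmetric matrix conformable with y.
#' @return object of class \code{model_fit}: list with \code{vc}
#'   (mu, sigma2_a, sigma2_e, h2, loglik, converged, n_iter), \code{gebv},
#'   \code{model_kind}.
#' @export
fit_single_grm_reml <- function(y, K) {
  V <- grm_values(K)
  n <- length(y)
  if (nrow(V) != n) stop("K dimension (", nrow(V), ") != length(y) (", n, ")")
  if (stats::var(y) < 1e-300) {
    warning("constant phenotype: variance components at lower boundary, h2 reported as 0")
    vc <- list(mu = mean(y), sigma2_a = 0, sigma2_e = 0, h2 = 0,
               loglik = NA_real_, converged = TRUE, n_iter = 0L)
    return(structure(list(vc = vc, gebv = rep(0, n), model_kind = "GBLUP"),
                     class = "model_fit"))
  }
  eg <- eigen(V, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values)))
    stop("K is not positive semidefinite (min eigenvalue ",
         format(min(eg$values)), ")")
  d <- pmax(eg$values, 0)
  w <- crossprod(eg$vectors, y)[, 1]
  x <- crossprod(eg$vectors, rep(1, n))[, 1]

  # restricted log-likelihood profiled over log gamma, gamma = s2a/s2e
  rll_profile <- function(lg) {
    g <- exp(lg)
    v <- g * d + 1
    xtvx <- sum(x^2 / v)
    beta <- sum(x * w / v) / xtvx
    rss <- sum((w - x * beta)^2 / v)
    s2e <- rss / (n - 1)
    -0.5 * ((n - 1) * log(s2e) + sum(log(v)) + log(xtvx) + (n - 1))
  }
  opt <- stats::optimize(rll_profile, interval = c(-25, 25), maximum = TRUE,
                         tol = 1e-10)
  lg <- opt$maximum
  # boundary handling: ratio pinned to ~0 or ~Inf
  g <- exp(lg)
  v <- g * d + 1
  xtvx <- sum(x^2 / v)
  mu <- sum(x * w / v) / xtvx
  s2e <- sum((w - x * mu)^2 / v) / (n - 1)
  s2a <- g * s2e
  if (lg <= -25 + 1e-6) { s2a <- 0 }
  h2 <- if (s2a + s2e > 0) s2a / (s2a + s2e) else 0
  # BLUP of a: s2a K V^{-1} (y - mu), V = s2a K + s2e I, in the eigenbasis
  gebv <- eg$vectors %*% ((s2a * d / (s2a * d + s2e)) * (w - x * mu))
  vc <- list(mu = mu, sigma2_a = s2a, sigma2_e = s2e, h2 = h2,
             loglik = opt$objective - 0.5 * (n - 1) * log(2 * pi),
             converged = TRUE, n_iter = 1L)
  structure(list(vc = vc, gebv = as.vector(gebv), model_kind = "GBLUP"),
            class = "model_fit")
}

#' Two-relationship-matrix REML fit
#'
#' Fits \eqn{y = 1\mu + a + a_u + e} with two uncorrelated genetic
#' components, \eqn{a \sim N(0, \sigma^2_a K_1)} (e.g. haploblock effects
#' through G_H) and \eqn{a_u \sim N(0, \sigma^2_{au} K_2)} (e.g.
#' non-blocked SNP effects through G), by average-information REML.
#' When an AI step leaves the parameter space or decreases the restricted
#' likelihood, an EM-REML step (\eqn{\sigma^2 + (\sigma^4/n)(y'PKPy -
#' tr(PK))}) is taken instead. GEBVs are the sum of the two BLUP
#' solutions, \eqn{\hat a + \hat a_u}.
#'
#' @param y numeric phenotype vector.
#' @param K1,K2 \code{grm}s or matrices conformable with y.
#' @param max_iter maximum REML iterations (default 200).
#' @param tol convergence tolerance on the restricted log-likelihood
#'   change and relative parameter change (default 1e-6).
#' @return a \code{model_fit} whose \code{vc} also carries
#'   \code{sigma2_au}; \code{h2} uses total genetic variance
#'   \eqn{(\sigma^2_a + \sigma^2_{au})} in the numerator.
#' @export
fit_two_grm_reml <- function(y, K1, K2, max_iter = 200L, tol = 1e-6) {
  V1 <- grm_values(K1); V2 <- grm_values(K2)
  n <- length(y)
  if (nrow(V1) != n || nrow(V2) != n) stop("K1/K2 not conformable with y")
  if (isTRUE(all.equal(V1, V2, tolerance = 1e-12,
                       check.attributes = FALSE)))
    warning("K1 and K2 are identical: components not separately identifiable")
  vy <- stats::var(y)
  if (vy < 1e-300) {
    warning("constant phenotype: variance components at lower boundary, h2 reported as 0")
    vc <- list(mu = mean(y), sigma2_a = 0, sigma2_au = 0, sigma2_e = 0,
               h2 = 0, loglik = NA_real_, converged = TRUE, n_iter = 0L)
    return(structure(list(vc = vc, gebv = rep(0, n),
                          model_kind = "G_H_BLUP+GBLUP"),
                     class = "model_fit"))
  }
  floor_v <- 1e-10 * vy
  X <- matrix(1, n, 1)
  Ks <- list(V1, V2, diag(n))
  theta <- c(vy / 3, vy / 3, vy / 3)

  reml_parts <- function(theta) {
    V <- theta[1] * V1 + theta[2] * V2 + theta[3] * diag(n)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)[1, 1]
    P <- Vi - tcrossprod(ViX) / XtViX
    Py <- P %*% y
    rll <- -0.5 * (2 * sum(log(diag(ch))) + log(XtViX) +
                     crossprod(y, Py)[1, 1]) - 0.5 * (n - 1) * log(2 * pi)
    list(P = P, Py = Py, rll = rll, Vi = Vi, ViX = ViX, XtViX = XtViX)
  }

  cur <- reml_parts(theta)
  if (is.null(cur)) stop("initial variance matrix not positive definite")
  converged <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    P <- cur$P; Py <- cur$Py
    PKPy <- lapply(Ks, function(K) P %*% (K %*% Py))
    score <- vapply(seq_along(Ks), function(i)
      -0.5 * (sum(P * Ks[[i]]) - crossprod(Py, Ks[[i]] %*% Py)[1, 1]),
      numeric(1))
    AI <- matrix(0, 3, 3)
    KPy <- lapply(Ks, function(K) K %*% Py)
    for (i in 1:3) for (j in i:3) {
      AI[i, j] <- AI[j, i] <- 0.5 * crossprod(KPy[[i]], P %*% KPy[[j]])[1, 1]
    }
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(step)) {
      # step-halve the AI update until inside the space and not worse
      s <- step
      for (half in 1:20) {
        cand <- theta + s
        if (all(cand >= floor_v)) {
          nxt <- reml_parts(cand)
          if (!is.null(nxt) && nxt$rll >= cur$rll - 1e-10) {
            accepted <- TRUE; break
          }
        }
        s <- s / 2
      }
      if (accepted) { new_theta <- theta + s }
    }
    if (!accepted) {
      # EM-REML fallback: sigma_i^2 + (sigma_i^4 / n) (y'P K P y - tr(P K))
      em <- vapply(seq_along(Ks), function(i)
        theta[i] + (theta[i]^2 / n) *
          (crossprod(Py, Ks[[i]] %*% Py)[1, 1] - sum(P * Ks[[i]])),
        numeric(1))
      new_theta <- pmax(em, floor_v)
      nxt <- reml_parts(new_theta)
      if (is.null(nxt)) break
    }
    rel <- max(abs(new_theta - theta) / pmax(abs(theta), floor_v))
    dll <- abs(nxt$rll - cur$rll)
    theta <- new_theta; cur <- nxt
    if (dll < tol && rel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("two-component REML did not converge in ", max_iter,
            " iterations; returning current estimates")
  theta[theta <= floor_v * (1 + 1e-9)] <- pmax(theta[theta <= floor_v * (1 + 1e-9)] - floor_v, 0)
  # fixed effect and BLUPs at the converged components
  V <- theta[1] * V1 + theta[2] * V2 + theta[3] * diag(n)
  Vi <- chol2inv(chol(V + diag(1e-12 * vy, n)))
  ViX <- Vi %*% X
  mu <- (crossprod(X, Vi %*% y) / crossprod(X, ViX))[1, 1]
  r <- y - mu
  Vir <- Vi %*% r
  a1 <- theta[1] * (V1 %*% Vir)
  a2 <- theta[2] * (V2 %*% Vir)
  tot <- sum(theta)
  vc <- list(mu = mu, sigma2_a = theta[1], sigma2_au = theta[2],
             sigma2_e = theta[3],
             h2 = if (tot > 0) (theta[1] + theta[2]) / tot else 0,
             loglik = cur$rll, converged = converged, n_iter = it)
  structure(list(vc = vc, gebv = as.vector(a1 + a2),
                 model_kind = "G_H_BLUP+GBLUP"),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  vc <- x$vc
  cat("model_fit (", x$model_kind, "):\n", sep = "")
  cat("  mu =", signif(vc$mu, 5), "\n")
  cat("  sigma2_a =", signif(vc$sigma2_a, 5))
  if (!is.null(vc$sigma2_au)) cat("  sigma2_au =", signif(vc$sigma2_au, 5))
  cat("  sigma2_e =", signif(vc$sigma2_e, 5), "\n")
  cat("  h2 =", round(vc$h2, 4), " loglik =", signif(vc$loglik, 8),
      " converged =", vc$converged, "\n")
  invisible(x)
}

#' Narrow-sense heritability from variance components
#'
#' \eqn{h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_e)}; for a
#' two-component fit the numerator is the total genetic variance
#' \eqn{\sigma^2_a + \sigma^2_{au}}.
#'
#' @param vc the \code{vc} element of a \code{model_fit} (or any list
#'   with \code{sigma2_a}, optionally \code{sigma2_au}, and
#'   \code{sigma2_e}).
#' @return heritability in [0, 1].
#' @export
heritability <- function(vc) {
  s2g <- vc$sigma2_a + (if (is.null(vc$sigma2_au)) 0 else vc$sigma2_au)
  tot <- s2g + vc$sigma2_e
  if (any(c(s2g, vc$sigma2_e) < 0)) stop("variance components must be >= 0")
  if (tot <= 0) stop("zero total variance: heritability undefined")
  s2g / tot
}

#' Predict validation GEBVs from a training fit
#'
#' Solves the training mixed model at the supplied variance components and
#' propagates breeding values to the validation individuals through the
#' relationship covariance:
#' \deqn{\hat g_{val} = \Sigma_{vt} (\Sigma_{tt} + \sigma^2_e I)^{-1}
#'       (y_t - \hat\mu)}
#' where \eqn{\Sigma = \sigma^2_a K} (plus \eqn{\sigma^2_{au} K_2} for a
#' two-component fit) and \eqn{\hat\mu} is the GLS intercept on the
#' training data. The residual variance acts as the ridge on the training
#' system, so the solve is well conditioned whenever \eqn{\sigma^2_e > 0}.
#'
#' @param vc variance components (\code{vc} of a \code{model_fit}).
#' @param y_train training phenotypes.
#' @param K full-panel \code{grm} (or matrix) over all individuals; for a
#'   two-component fit pass \code{K2} as well.
#' @param train_idx,val_idx disjoint integer index sets into K's rows.
#' @param K2 optional second relationship matrix (two-component fits).
#' @return numeric GEBV vector for \code{val_idx}.
#' @export
predict_gebv <- function(vc, y_train, K, train_idx, val_idx, K2 = NULL) {
  if (length(intersect(train_idx, val_idx)))
    stop("train_idx and val_idx must be disjoint")
  V <- grm_values(K)
  s2au <- if (is.null(vc$sigma2_au)) 0 else vc$sigma2_au
  Sig <- vc$sigma2_a * V
  if (!is.null(K2)) Sig <- Sig + s2au * grm_values(K2)
  if (vc$sigma2_a + s2au <= 0) return(rep(0, length(val_idx)))
  Stt <- Sig[train_idx, train_idx, drop = FALSE]
  Svt <- Sig[val_idx, train_idx, drop = FALSE]
  nt <- length(train_idx)
  Vtt <- Stt + diag(vc$sigma2_e, nt)
  ch <- tryCatch(chol(Vtt), error = function(e)
    stop("singular training system (condition number ~ ",
         format(kappa(Vtt)), ")"))
  Vi <- chol2inv(ch)
  one <- rep(1, nt)
  mu <- sum(Vi %*% y_train) / sum(Vi %*% one)
  as.vector(Svt %*% (Vi %*% (y_train - mu)))
}

grm_values <- function(K) {
  if (inherits(K, "grm")) K$values else as.matrix(K)
}

#' Write a fit report as tab-delimited text
#' @param fit a \code{model_fit}.
#' @param path output path.
#' @return path, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  vc <- fit$vc
  df <- data.frame(model = fit$model_kind, mu = vc$mu,
                   sigma2_a = vc$sigma2_a,
                   sigma2_au = if (is.null(vc$sigma2_au)) NA else vc$sigma2_au,
                   sigma2_e = vc$sigma2_e, h2 = vc$h2, loglik = vc$loglik,
                   converged = vc$converged, n_iter = vc$n_iter)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
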