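#' Universal kriging with exponential covariance, fit by maximum likelihood
#'
#' Residual spatial structure around the PLS mean is modelled as a stationary
#' Gaussian process with exponential covariance
#' `C(h) = sigma2 * exp(-h / phi)` plus a nugget `tau2` at h = 0. The three
#' covariance parameters are estimated by maximising the Gaussian likelihood
#' with the mean coefficients beta profiled out by generalised least squares;
#' optimisation runs unconstrained in log(tau2, sigma2, phi) from several
#' variogram-guided starting points, because the likelihood surface is
#' multi-modal in the range parameter.
#'
#' @name universal-kriging
NULL

#' Negative log-likelihood with profiled mean coefficients
#'
#' `Sigma(theta) = sigma2 * exp(-D/phi) + tau2 * I`; beta is replaced by its
#' GLS estimate `(F' Sigma^-1 F)^-1 F' Sigma^-1 y`. A numerically singular
#' covariance returns a large penalty instead of an error so optimisers can
#' step past it.
#'
#' @param theta numeric c(tau2, sigma2, phi) on the natural scale.
#' @param F_design design matrix (intercept + PLS scores), full column rank.
#' @param y response (sqrt scale).
#' @param D pairwise distance matrix in km.
#' @param reml if TRUE return the restricted (REML) negative log-likelihood,
#'   which adds the log-determinant of the GLS information and drops the
#'   mean-model degrees of freedom from the dimension term.
#' @return scalar NLL; attribute `"beta"` carries the profiled coefficients
#'   when the evaluation succeeds.
#' @export
uk_nll <- function(theta, F_design, y, D, reml = FALSE) {
  tau2 <- theta[1]; sigma2 <- theta[2]; phi <- theta[3]
  n <- length(y)
  if (any(!is.finite(theta)) || tau2 < 0 || sigma2 < 0 || phi <= 0)
    return(1e10)
  Sigma <- sigma2 * exp(-D / phi)
  diag(Sigma) <- diag(Sigma) + tau2
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  Ft <- forwardsolve(t(ch), F_design)
  yt <- forwardsolve(t(ch), y)
  XtX <- crossprod(Ft)
  beta <- tryCatch(solve(XtX, crossprod(Ft, yt)), error = function(e) NULL)
  if (is.null(beta)) return(1e10)
  r <- yt - Ft %*% beta
  nll <- 0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(r^2))
  if (reml) {
    ld <- determinant(XtX, logarithm = TRUE)
    if (ld$sign <= 0) return(1e10)
    nll <- nll + 0.5 * (as.numeric(ld$modulus) - ncol(F_design) * log(2 * pi))
  }
  if (!is.finite(nll)) return(1e10)
  attr(nll, "beta") <- drop(beta)
  nll
}

# empirical semivariogram of a residual vector: gamma(h) = mean of
# squared half-differences per distance bin
empirical_variogram <- function(resid, D, n_bins = 10, max_frac = 0.5) {
  n <- length(resid)
  iu <- which(upper.tri(D))
  d <- D[iu]
  g <- 0.5 * (outer(resid, resid, "-")^2)[iu]
  dmax <- max(d) * max_frac
  keep <- d <= dmax & d > 0
  d <- d[keep]; g <- g[keep]
  br <- seq(0, dmax, length.out = n_bins + 1)
  bin <- cut(d, br, include.lowest = TRUE)
  data.frame(dist = tapply(d, bin, mean),
             gamma = tapply(g, bin, mean),
             n = as.integer(table(bin)))
}

# variogram-guided initial values for (tau2, sigma2, phi)
uk_starts <- function(resid, D) {
  s2 <- stats::var(resid)
  vg <- empirical_variogram(resid, D)
  vg <- vg[!is.na(vg$gamma) & vg$n > 0, ]
  dmax <- max(D)
  if (nrow(vg) >= 3) {
    nug <- max(min(vg$gamma[1], 0.9 * s2), 0.05 * s2)
    sill <- max(mean(utils::tail(vg$gamma, 3)), nug * 1.1)
    psill <- max(sill - nug, 0.05 * s2)
    target <- nug + 0.63 * psill
    i <- which(vg$gamma >= target)[1]
    rng <- if (is.na(i)) dmax / 4 else max(vg$dist[i], dmax / 50)
    guided <- c(nug, psill, rng)
  } else {
    guided <- c(0.5 * s2, 0.5 * s2, dmax / 4)
  }
  list(guided,
       c(0.1 * s2, 0.9 * s2, dmax / 10),
       c(0.9 * s2, 0.1 * s2, dmax / 3))
}

#' Fit universal kriging by profile maximum likelihood
#'
#' When the optimum is not meaningfully better than the nested iid model
#' (within 2 NLL units, an AIC-style allowance for the two extra covariance
#' parameters), the nugget-only model is returned: near phi = 0 the
#' likelihood cannot separate partial sill from nugget, and the iid fit is
#' the parsimonious resolution of that ridge.
#'
#' @param scores matrix of mean-model covariates (PLS scores); an intercept
#'   is added internally.
#' @param y sqrt-scale response.
#' @param coords site coordinates (projected km, or lon/lat with
#'   `metric = "greatcircle"`); must be distinct.
#' @param metric distance metric, see [dist_km()].
#' @param n_sites_min minimum training size (default 10).
#' @param maxit optimiser iteration cap per start.
#' @param reml estimate covariance parameters by restricted maximum
#'   likelihood instead of ML (default FALSE).
#' @return object of class `uk_model`: `beta`, `tau2`, `sigma2`, `phi`,
#'   training coordinates/design/response and factored covariance.
#' @export
fit_uk <- function(scores, y, coords, metric = c("euclidean", "greatcircle"),
                   n_sites_min = 10, maxit = 400, reml = FALSE) {
  metric <- match.arg(metric)
  coords <- as.matrix(coords)
  scores <- as.matrix(scores)
  n <- length(y)
  if (n < n_sites_min) stop("universal kriging needs >= ", n_sites_min, " sites")
  D <- dist_km(coords, metric = metric)
  if (min(D[upper.tri(D)]) <= 0)
    stop("duplicate site coordinates: kriging covariance would be singular")
  F_design <- cbind(intercept = 1, scores)
  ols <- stats::lm.fit(F_design, y)
  starts <- uk_starts(ols$residuals, D)
  obj <- function(lt) as.numeric(uk_nll(exp(lt), F_design, y, D, reml = reml))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(log(pmax(s, 1e-8)), obj, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) && fit$value < 1e9 &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stop("maximum-likelihood fit failed to converge from all starting values")
  # Boundary guard: as phi -> 0 the likelihood cannot separate sill from
  # nugget, so spatially independent data can land anywhere on that ridge.
  # Prefer the nested iid model (sigma2 = 0) unless the spatial parameters
  # improve the NLL by more than 2 units (an AIC-style charge for the two
  # extra covariance parameters).
  tau2_iid <- if (reml) sum(ols$residuals^2) / (n - ncol(F_design))
              else mean(ols$residuals^2)
  nll_iid <- as.numeric(uk_nll(c(tau2_iid, 0, stats::median(D)), F_design, y,
                               D, reml = reml))
  if (nll_iid <= best$value + 2) {
    return(uk_model_at(c(tau2_iid, 0, stats::median(D)), scores, y, coords,
                       metric = metric))
  }
  uk_model_at(exp(best$par), scores, y, coords, metric = metric)
}

#' Build a universal-kriging model at fixed covariance parameters
#'
#' The mean coefficients are the profiled GLS estimate at the given theta;
#' no optimisation is performed. [fit_uk()] calls this at the maximum-
#' likelihood theta, but it is also useful for plug-in covariance parameters.
#'
#' @param theta c(tau2, sigma2, phi).
#' @inheritParams fit_uk
#' @return a `uk_model`.
#' @export
uk_model_at <- function(theta, scores, y, coords,
                        metric = c("euclidean", "greatcircle")) {
  metric <- match.arg(metric)
  coords <- as.matrix(coords)
  F_design <- cbind(intercept = 1, as.matrix(scores))
  n <- length(y)
  D <- dist_km(coords, metric = metric)
  nll <- uk_nll(theta, F_design, y, D)
  beta <- attr(nll, "beta")
  if (is.null(beta)) stop("covariance at theta is numerically singular")
  Sigma <- theta[2] * exp(-D / theta[3])
  diag(Sigma) <- diag(Sigma) + theta[1]
  ch <- chol(Sigma + diag(1e-12 * (theta[1] + theta[2]), n))
  resid <- y - drop(F_design %*% beta)
  Sinv_r <- backsolve(ch, forwardsolve(t(ch), resid))
  Ft <- forwardsolve(t(ch), F_design)
  structure(list(beta = beta, tau2 = theta[1], sigma2 = theta[2],
                 phi = theta[3], metric = metric, coords = coords,
                 F_design = F_design, y = y, nll = as.numeric(nll),
                 chol = ch, Sinv_r = Sinv_r, FtSiF = crossprod(Ft)),
            class = "uk_model")
}

#' Universal-kriging prediction at new locations
#'
#' `pred = F_new beta + c' Sigma^-1 (y - F beta)` with
#' `c = sigma2 * exp(-d(new, train)/phi)`. The kriging standard error (sqrt
#' scale) accounts for mean-coefficient uncertainty.
#'
#' @param model a `uk_model`.
#' @param scores_new covariates at prediction locations.
#' @param coords_new coordinates of prediction locations.
#' @param se if TRUE also return kriging standard errors.
#' @return numeric predictions, or a list(pred, se) when `se = TRUE`.
#' @export
predict_uk <- function(model, scores_new, coords_new, se = FALSE) {
  Fn <- cbind(intercept = 1, as.matrix(scores_new))
  d <- dist_km(as.matrix(coords_new), model$coords, metric = model$metric)
  cmat <- model$sigma2 * exp(-d / model$phi)
  pred <- drop(Fn %*% model$beta) + drop(cmat %*% model$Sinv_r)
  if (!se) return(pred)
  ct <- forwardsolve(t(model$chol), t(cmat))
  Ft <- forwardsolve(t(model$chol), model$F_design)
  u <- t(Fn) - crossprod(Ft, ct)
  v <- model$sigma2 + model$tau2 - colSums(ct^2) +
    colSums(u * solve(model$FtSiF, u))
  list(pred = pred, se = sqrt(pmax(v, 0)))
}
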