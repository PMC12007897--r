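#' The combined PLS + universal kriging exposure model
#'
#' Prediction pipeline, applied in fixed order: feature matrix -> PLS scores
#' -> universal-kriging prediction on the sqrt concentration scale ->
#' back-transform (clamped squaring) to native units. The response is
#' sqrt-transformed before fitting; no bias correction is applied on the way
#' back.
#'
#' @param X training feature matrix (`feature_matrix` or plain matrix with
#'   column names).
#' @param y_native native-scale annual observations (>= 0).
#' @param coords training site coordinates.
#' @param k number of PLS components (typically 2 or 3, selectable by
#'   conventional cross-validation).
#' @param metric distance metric, see [dist_km()].
#' @param pollutant,year optional metadata carried in the model.
#' @return object of class `plsuk`.
#' @export
fit_plsuk <- function(X, y_native, coords, k = 2,
                      metric = c("euclidean", "greatcircle"),
                      pollutant = NA_character_, year = NA_integer_) {
  metric <- match.arg(metric)
  if (inherits(X, "feature_matrix")) X <- X$values
  y_sqrt <- sqrt_transform(y_native)
  pls <- fit_pls(X, y_sqrt, k = k)
  uk <- fit_uk(pls$scores, y_sqrt, coords, metric = metric)
  structure(list(pls = pls, uk = uk, pollutant = pollutant, year = year,
                 k = k, metric = metric,
                 variable_names = pls$variable_names),
            class = "plsuk")
}

#' Predict concentrations from a fitted PLS-UK model
#'
#' New feature columns must align exactly (names and order) with the
#' training variables; mismatches are an error, never silently reordered.
#'
#' @param object a `plsuk` model.
#' @param X_new feature matrix at prediction locations.
#' @param coords_new prediction coordinates (same convention as training).
#' @param se if TRUE include the sqrt-scale kriging standard error.
#' @param ... unused.
#' @return data.frame: `pred_native`, `pred_sqrt` and (if requested)
#'   `se_sqrt`.
#' @export
predict.plsuk <- function(object, X_new, coords_new, se = FALSE, ...) {
  if (inherits(X_new, "feature_matrix")) X_new <- X_new$values
  X_new <- as.matrix(X_new)
  cn <- colnames(X_new)
  tv <- object$variable_names
  if (is.null(cn) || length(cn) < length(tv) ||
      !identical(cn[seq_along(tv)], tv)) {
    if (is.null(cn) || !all(tv %in% cn))
      stop("prediction features do not align with training variable_names")
  }
  scores <- pls_transform(object$pls, X_new)
  out <- predict_uk(object$uk, scores, coords_new, se = se)
  if (se) {
    data.frame(pred_native = back_transform(out$pred),
               pred_sqrt = out$pred, se_sqrt = out$se)
  } else {
    data.frame(pred_native = back_transform(out), pred_sqrt = out)
  }
}

#' Serialise / restore a PLS-UK model as JSON
#'
#' All matrices are written row-major with dimensions; the kriging factors
#' are rebuilt from the stored training data on load, so the file holds only
#' data and parameters.
#'
#' @param model a `plsuk`.
#' @param path file path.
#' @export
plsuk_write_json <- function(model, path) {
  mat <- function(m) list(dim = dim(m), data = as.numeric(t(m)))
  obj <- list(
    format = "airlur-plsuk-1",
    pollutant = model$pollutant, year = model$year, k = model$k,
    metric = model$metric, variable_names = model$variable_names,
    pls = list(x_mean = as.numeric(model$pls$x_mean),
               x_scale = as.numeric(model$pls$x_scale),
               y_mean = model$pls$y_mean, q = model$pls$q,
               W = mat(model$pls$W), P = mat(model$pls$P)),
    uk = list(beta = as.numeric(model$uk$beta), tau2 = model$uk$tau2,
              sigma2 = model$uk$sigma2, phi = model$uk$phi,
              coords = mat(model$uk$coords), y = model$uk$y,
              scores = mat(model$uk$F_design[, -1, drop = FALSE])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname plsuk_write_json
#' @export
plsuk_read_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(o$format, "airlur-plsuk-1")) stop("unrecognised model file")
  unmat <- function(m) matrix(m$data, m$dim[1], m$dim[2], byrow = TRUE)
  vn <- o$variable_names
  k <- o$k
  W <- unmat(o$pls$W); P <- unmat(o$pls$P)
  dimnames(W) <- dimnames(P) <- list(vn, sprintf("comp%d", seq_len(k)))
  x_mean <- stats::setNames(o$pls$x_mean, vn)
  x_scale <- stats::setNames(o$pls$x_scale, vn)
  rotation <- W %*% solve(crossprod(P, W))
  pls <- structure(list(n_components = k, x_mean = x_mean, x_scale = x_scale,
                        variable_names = vn, W = W, P = P, q = o$pls$q,
                        rotation = rotation, y_mean = o$pls$y_mean),
                   class = "pls_model")
  coords <- unmat(o$uk$coords)
  scores <- unmat(o$uk$scores)
  y <- o$uk$y
  theta <- c(o$uk$tau2, o$uk$sigma2, o$uk$phi)
  D <- dist_km(coords, metric = o$metric)
  Sigma <- theta[2] * exp(-D / theta[3])
  diag(Sigma) <- diag(Sigma) + theta[1]
  ch <- chol(Sigma + diag(1e-12 * (theta[1] + theta[2]), nrow(Sigma)))
  F_design <- cbind(intercept = 1, scores)
  resid <- y - drop(F_design %*% o$uk$beta)
  Ft <- forwardsolve(t(ch), F_design)
  uk <- structure(list(beta = o$uk$beta, tau2 = theta[1], sigma2 = theta[2],
                       phi = theta[3], metric = o$metric, coords = coords,
                       F_design = F_design, y = y, nll = NA_real_, chol = ch,
                       Sinv_r = backsolve(ch, forwardsolve(t(ch), resid)),
                       FtSiF = crossprod(Ft)),
                  class = "uk_model")
  structure(list(pls = pls, uk = uk, pollutant = o$pollutant, year = o$year,
                 k = k, metric = o$metric, variable_names = vn),
            class = "plsuk")
}
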