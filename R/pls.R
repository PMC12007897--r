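#' Partial least squares for a univariate response
#'
#' The mean component of the exposure model: several hundred correlated
#' buffer variables are reduced to a handful (typically 2-3) of orthogonal
#' summary scores that maximise covariance with the sqrt-scale concentration.
#' Classical PLS1 (NIPALS): the first weight vector is proportional to
#' X'y on the centred/scaled predictors; X is deflated between components.
#' With k equal to the rank of the centred predictors, fitted values
#' coincide with ordinary least squares.
#'
#' @param X numeric matrix (sites x variables) or a `feature_matrix`.
#' @param y numeric response (sqrt-scale observations).
#' @param k number of components (>= 1, <= rank of centred X).
#' @return object of class `pls_model`: weights `W`, loadings `P`,
#'   y-loadings `q`, training scores `T`, centring/scaling vectors, the
#'   retained variable names, and `fitted`.
#' @export
fit_pls <- function(X, y, k = 2) {
  if (inherits(X, "feature_matrix")) X <- X$values
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  if (k < 1) stop("k must be >= 1")
  if (nrow(X) != length(y)) stop("X and y dimensions disagree")
  if (anyNA(X) || anyNA(y)) stop("missing cells are not allowed in PLS input")
  x_mean <- colMeans(X)
  x_sd <- apply(X, 2, stats::sd)
  keep <- x_sd > 1e-12
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " zero-variance column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
    x_mean <- x_mean[keep]; x_sd <- x_sd[keep]
  }
  if (ncol(X) == 0) stop("no non-constant predictor columns")
  Xs <- sweep(sweep(X, 2, x_mean), 2, x_sd, "/")
  y_mean <- mean(y)
  f <- y - y_mean
  n <- nrow(Xs); p <- ncol(Xs)
  W <- P <- matrix(0, p, k)
  Tm <- matrix(0, n, k)
  q <- numeric(k)
  E <- Xs
  for (j in seq_len(k)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-10 * max(1, sqrt(sum(f^2)))) {
      if (j == 1)
        stop("degenerate PLS fit: response is orthogonal to every predictor")
      stop("k = ", k, " exceeds the usable rank of the centred predictors (",
           j - 1, " components extractable)")
    }
    w <- w / nw
    t <- drop(E %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12)
      stop("k = ", k, " exceeds the usable rank of the centred predictors")
    pj <- drop(crossprod(E, t)) / tt
    q[j] <- sum(f * t) / tt
    E <- E - tcrossprod(t, pj)
    f <- f - q[j] * t
    W[, j] <- w; P[, j] <- pj; Tm[, j] <- t
  }
  rotation <- W %*% solve(crossprod(P, W))
  dimnames(W) <- dimnames(P) <- dimnames(rotation) <-
    list(colnames(X), sprintf("comp%d", seq_len(k)))
  colnames(Tm) <- sprintf("comp%d", seq_len(k))
  structure(list(n_components = k, x_mean = x_mean, x_scale = x_sd,
                 variable_names = colnames(X), W = W, P = P, q = q,
                 rotation = rotation, scores = Tm, y_mean = y_mean,
                 fitted = y_mean + drop(Tm %*% q)),
            class = "pls_model")
}

#' Project new data onto fitted PLS components
#'
#' Applies the training centring/scaling and the PLS rotation
#' `W (P'W)^{-1}`; on the training matrix this reproduces the training
#' scores to machine precision.
#'
#' @param model a `pls_model`.
#' @param X_new matrix with the training variables as (a superset of) its
#'   columns, or a `feature_matrix`.
#' @return matrix of scores (rows x k).
#' @export
pls_transform <- function(model, X_new) {
  if (inherits(X_new, "feature_matrix")) X_new <- X_new$values
  X_new <- as.matrix(X_new)
  if (is.null(colnames(X_new)))
    colnames(X_new) <- sprintf("V%d", seq_len(ncol(X_new)))
  miss <- setdiff(model$variable_names, colnames(X_new))
  if (length(miss) > 0)
    stop("new data lacks training variables: ", paste(miss, collapse = ", "))
  X_new <- X_new[, model$variable_names, drop = FALSE]
  Xs <- sweep(sweep(X_new, 2, model$x_mean), 2, model$x_scale, "/")
  Xs %*% model$rotation
}

#' @export
predict.pls_model <- function(object, X_new, ...) {
  object$y_mean + drop(pls_transform(object, X_new) %*% object$q)
}
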