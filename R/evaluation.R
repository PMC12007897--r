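#' Model evaluation: forward selection, dual cross-validation, metrics
#'
#' Variables enter the model by greedy forward selection: the first is the
#' one most correlated with the response, each later one maximises the
#' partial F-statistic of the augmented ordinary-least-squares model against
#' the current one. Model testing uses two 10-fold cross-validations —
#' conventional (random site partition) and spatially clustered (k-means
#' folds on site coordinates, probing extrapolation far from monitors) — and
#' two pooled metrics: MSE-based R2 (fit to the 1:1 line; can be negative)
#' and standardised RMSE (RMSE / mean observed concentration).
#'
#' @name evaluation
NULL

#' Forward variable selection by partial F-statistic
#'
#' Step 1 picks the variable with the highest absolute Pearson correlation
#' with `y`; each later step picks the candidate maximising
#' `F = ((SSE_reduced - SSE_full)/1) / (SSE_full/(n - p_full))`, where
#' `p_full` counts the intercept. Implemented by incremental Gram-Schmidt
#' orthogonalisation (one rank-1 update per step), which selects the same
#' variable as refitting OLS per candidate because the F ranking is monotone
#' in the SSE reduction at fixed step. Ties break by variable-name order;
#' numerically collinear candidates are skipped.
#'
#' @param X numeric matrix or `feature_matrix`.
#' @param y response vector.
#' @param max_vars number of variables to select (<= ncol(X)).
#' @return object of class `selection_path`: `variables` (ordered names),
#'   `partial_f`, `sse` (per step, after adding the variable), `skipped`.
#' @export
forward_select <- function(X, y, max_vars) {
  if (inherits(X, "feature_matrix")) X <- X$values
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  if (max_vars > ncol(X)) stop("max_vars exceeds the number of variables")
  n <- nrow(X)
  # order columns by name so which.max tie-breaks lexicographically
  ord <- order(colnames(X))
  Xo <- X[, ord, drop = FALSE]
  nm <- colnames(Xo)
  # centre (intercept-only base model); Q holds the orthonormal basis built
  r <- y - mean(y)
  E <- sweep(Xo, 2, colMeans(Xo))
  cn2_init <- colSums(E^2)
  alive <- cn2_init > 1e-12 * max(cn2_init, 1)   # constants can never enter
  sse0 <- sum(r^2)
  selected <- character(0)
  fstat <- sse <- numeric(0)
  skipped <- character(0)
  sse_cur <- sse0
  for (step in seq_len(max_vars)) {
    if (!any(alive)) break
    cn2 <- colSums(E^2)
    tol <- 1e-10 * pmax(cn2_init, 1e-300)
    collinear <- alive & cn2 <= tol
    if (any(collinear)) {
      skipped <- c(skipped, nm[collinear])
      alive[collinear] <- FALSE
      if (!any(alive)) break
    }
    proj <- colSums(E * r)
    red <- ifelse(alive, proj^2 / pmax(cn2, 1e-300), -Inf)
    j <- which.max(red)          # first max in name order
    if (!is.finite(red[j]) || red[j] <= 0) break
    p_full <- step + 1           # intercept + selected vars
    sse_new <- sse_cur - red[j]
    f <- (red[j] / 1) / (sse_new / (n - p_full))
    qv <- E[, j] / sqrt(cn2[j])
    # deflate remaining candidates and the residual by the new basis vector
    E <- E - tcrossprod(qv, drop(crossprod(E, qv)))
    r <- r - qv * sum(qv * r)
    selected <- c(selected, nm[j])
    fstat <- c(fstat, unname(f))
    sse <- c(sse, unname(sse_new))
    sse_cur <- sse_new
    alive[j] <- FALSE
  }
  structure(list(variables = selected, partial_f = fstat, sse = sse,
                 sse_null = sse0, skipped = skipped),
            class = "selection_path")
}

#' Assign sites to cross-validation folds
#'
#' Conventional: a seeded random partition with fold sizes differing by at
#' most one. Clustered: k-means on site coordinates with deterministic
#' farthest-point seeding plus seeded random restarts; each cluster is one
#' fold, so fold sizes are unequal by design.
#'
#' @param coords site coordinate matrix.
#' @param scheme `"conventional"` or `"clustered"`.
#' @param k_folds number of folds (default 10).
#' @param seed integer seed.
#' @param restarts k-means restarts for the clustered scheme.
#' @return integer vector of fold labels in 1..k_folds, one per site.
#' @export
make_folds <- function(coords, scheme = c("conventional", "clustered"),
                       k_folds = 10, seed = 1, restarts = 50) {
  scheme <- match.arg(scheme)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < k_folds) stop("need at least as many sites as folds")
  if (scheme == "conventional") {
    return(with_seed(seed, sample(rep_len(seq_len(k_folds), n))))
  }
  with_seed(seed, {
    # farthest-point seeding: start at the site nearest the centroid
    D <- dist_km(coords)
    start <- which.min(colSums(sweep(coords, 2, colMeans(coords))^2))
    centers_idx <- start
    for (j in 2:k_folds) {
      dmin <- apply(D[, centers_idx, drop = FALSE], 1, min)
      centers_idx <- c(centers_idx, which.max(dmin))
    }
    best <- stats::kmeans(coords, centers = coords[centers_idx, ],
                          iter.max = 100)
    for (tries in seq_len(restarts)) {
      km <- tryCatch(stats::kmeans(coords, centers = k_folds, iter.max = 100),
                     error = function(e) NULL)
      if (!is.null(km) && length(unique(km$cluster)) == k_folds &&
          km$tot.withinss < best$tot.withinss) best <- km
    }
    if (length(unique(best$cluster)) != k_folds)
      stop("k-means produced an empty cluster after bounded retries")
    as.integer(best$cluster)
  })
}

#' MSE-based R-squared (fit to the 1:1 line)
#'
#' `1 - sum((pred - obs)^2) / sum((obs - mean(obs))^2)`. Unlike the squared
#' correlation, this penalises bias and slope errors and can be negative.
#'
#' @param obs,pred native-scale observations and predictions.
#' @return unitless scalar.
#' @export
mse_r2 <- function(obs, pred) {
  if (length(obs) < 2) stop("need >= 2 observations")
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) stop("mse_r2 undefined for constant observations")
  1 - sum((pred - obs)^2) / sst
}

#' Standardised root-mean-square error
#'
#' RMSE divided by the mean observed concentration; unitless, comparable
#' across pollutants.
#'
#' @inheritParams mse_r2
#' @return unitless scalar.
#' @export
srmse <- function(obs, pred) {
  m <- mean(obs)
  if (m <= 0) stop("srmse requires mean(obs) > 0")
  sqrt(mean((pred - obs)^2)) / m
}

#' Cross-validate the full PLS-UK pipeline
#'
#' For each fold, forward selection, PLS and the kriging fit are recomputed
#' from the training sites only (no leakage of standardisation, selection or
#' covariance parameters); held-out sites are predicted, back-transformed,
#' and metrics computed over the pooled held-out predictions on the native
#' scale.
#'
#' @param X feature matrix (`feature_matrix` or named matrix).
#' @param y_native native-scale annual observations.
#' @param coords site coordinates.
#' @param scheme fold scheme, see [make_folds()].
#' @param k_pls number of PLS components.
#' @param n_predictors number of variables forward selection keeps per fold;
#'   NULL uses all variables.
#' @param k_folds number of folds.
#' @param seed integer seed (fold assignment).
#' @param metric distance metric.
#' @return object of class `cv_report`: scheme, fold_of_site, predictions
#'   (site_id, fold, obs, pred), mse_r2, srmse, n_predictors.
#' @export
cross_validate <- function(X, y_native, coords,
                           scheme = c("conventional", "clustered"),
                           k_pls = 2, n_predictors = NULL, k_folds = 10,
                           seed = 1, metric = c("euclidean", "greatcircle")) {
  scheme <- match.arg(scheme); metric <- match.arg(metric)
  ids <- if (inherits(X, "feature_matrix")) X$site_ids else rownames(X)
  if (inherits(X, "feature_matrix")) X <- X$values
  X <- as.matrix(X)
  coords <- as.matrix(coords)
  n <- nrow(X)
  if (is.null(ids)) ids <- sprintf("site%04d", seq_len(n))
  folds <- make_folds(coords, scheme, k_folds = k_folds, seed = seed)
  obs <- pred <- rep(NA_real_, n)
  for (f in sort(unique(folds))) {
    tr <- folds != f; te <- !tr
    if (sum(tr) < 10)
      stop("fold ", f, " leaves < 10 training sites; use fewer folds")
    Xtr <- X[tr, , drop = FALSE]
    ytr <- y_native[tr]
    # columns constant on this training fold carry no information and are
    # removed up front (forward selection skips them anyway)
    vars <- colnames(X)[apply(Xtr, 2, stats::sd) > 1e-12]
    if (!is.null(n_predictors) && n_predictors < length(vars)) {
      sel <- forward_select(Xtr[, vars, drop = FALSE], sqrt_transform(ytr),
                            n_predictors)
      vars <- sel$variables
    }
    m <- fit_plsuk(Xtr[, vars, drop = FALSE], ytr, coords[tr, , drop = FALSE],
                   k = k_pls, metric = metric)
    p <- predict(m, X[te, vars, drop = FALSE], coords[te, , drop = FALSE])
    obs[te] <- y_native[te]
    pred[te] <- p$pred_native
  }
  structure(list(scheme = scheme,
                 fold_of_site = stats::setNames(folds, ids),
                 predictions = data.frame(site_id = ids, fold = folds,
                                          obs = obs, pred = pred),
                 mse_r2 = mse_r2(obs, pred), srmse = srmse(obs, pred),
                 n_predictors = if (is.null(n_predictors)) ncol(X)
                                else n_predictors,
                 k_pls = k_pls, seed = seed),
            class = "cv_report")
}

#' Choose the number of PLS components by conventional cross-validation
#'
#' Runs [cross_validate()] for each candidate component count (typically 2
#' and 3) and returns the candidate with the highest conventional-CV MSE-R2.
#'
#' @inheritParams cross_validate
#' @param k_candidates component counts to compare.
#' @return list: `k` (the chosen count) and `table` (per-candidate metrics).
#' @export
select_k_pls <- function(X, y_native, coords, k_candidates = c(2, 3),
                         n_predictors = NULL, k_folds = 10, seed = 1,
                         metric = c("euclidean", "greatcircle")) {
  metric <- match.arg(metric)
  rows <- lapply(k_candidates, function(k) {
    cv <- cross_validate(X, y_native, coords, scheme = "conventional",
                         k_pls = k, n_predictors = n_predictors,
                         k_folds = k_folds, seed = seed, metric = metric)
    data.frame(k_pls = k, mse_r2 = cv$mse_r2, srmse = cv$srmse)
  })
  tab <- do.call(rbind, rows)
  list(k = tab$k_pls[which.max(tab$mse_r2)], table = tab)
}

#' Sweep cross-validated performance over the number of predictors
#'
#' Runs [cross_validate()] for every (n_predictors, scheme) combination and
#' returns a tidy table — the performance-versus-model-size curve on which
#' the parsimony argument (around 30 predictors suffices; more overfits)
#' rests.
#'
#' @inheritParams cross_validate
#' @param grid ascending vector of predictor counts.
#' @param schemes fold schemes to evaluate.
#' @return data.frame: n_predictors, scheme, mse_r2, srmse, seed.
#' @export
sweep_n_predictors <- function(X, y_native, coords, grid,
                               schemes = c("conventional", "clustered"),
                               k_pls = 2, k_folds = 10, seed = 1,
                               metric = c("euclidean", "greatcircle")) {
  if (is.unsorted(grid)) stop("grid must be sorted ascending")
  metric <- match.arg(metric)
  rows <- list()
  for (np in grid) {
    for (sc in schemes) {
      cv <- cross_validate(X, y_native, coords, scheme = sc, k_pls = k_pls,
                           n_predictors = np, k_folds = k_folds, seed = seed,
                           metric = metric)
      rows[[length(rows) + 1]] <-
        data.frame(n_predictors = np, scheme = sc, mse_r2 = cv$mse_r2,
                   srmse = cv$srmse, seed = seed)
    }
  }
  do.call(rbind, rows)
}
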