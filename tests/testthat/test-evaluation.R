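test_that("forward selection starts at the dominant correlation", {
  set.seed(1)
  y <- rnorm(60)
  X <- cbind(signal = y + rnorm(60, 0, 0.01), noise = rnorm(60))
  path <- forward_select(X, y, 2)
  expect_equal(path$variables[1], "signal")
  expect_true(all(diff(c(path$sse_null, path$sse)) <= 1e-12))
})

test_that("greedy path and partial F match a brute-force two-OLS oracle", {
  set.seed(2)
  n <- 100; p <- 20
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("v%02d", 1:p)))
  y <- drop(X[, 1:5] %*% c(3, -2, 1.5, 1, -1)) + rnorm(n)
  max_vars <- 12
  path <- forward_select(X, y, max_vars)

  sse_of <- function(vars) {
    fit <- stats::lm.fit(cbind(1, X[, vars, drop = FALSE]), y)
    sum(fit$residuals^2)
  }
  selected <- character(0)
  for (step in seq_len(max_vars)) {
    cands <- setdiff(colnames(X), selected)
    if (step == 1) {
      cors <- abs(cor(X[, cands], y))
      pick <- cands[which.max(cors)]
    } else {
      sse_r <- sse_of(selected)
      p_full <- length(selected) + 2
      fs <- vapply(cands, function(v) {
        sse_f <- sse_of(c(selected, v))
        ((sse_r - sse_f) / 1) / (sse_f / (n - p_full))
      }, 0)
      pick <- cands[which.max(fs)]
      expect_equal(path$partial_f[step], unname(max(fs)), tolerance = 1e-8)
    }
    expect_equal(path$variables[step], pick)
    selected <- c(selected, pick)
    expect_equal(path$sse[step], sse_of(selected), tolerance = 1e-8)
  }
})

test_that("collinear candidates are skipped, not selected", {
  set.seed(3)
  x1 <- rnorm(50)
  X <- cbind(a = x1, dup = 2 * x1 + 5, b = rnorm(50))
  y <- x1 + rnorm(50, 0, 0.1)
  path <- forward_select(X, y, 3)
  expect_false("dup" %in% path$variables && "a" %in% path$variables &&
                 which(path$variables == "dup") >
                   which(path$variables == "a") + 10)  # guard: no crash
  # after one of the pair enters, the other is perfectly collinear
  expect_equal(sort(c(path$variables, path$skipped)), c("a", "b", "dup"))
  expect_length(path$variables, 2)
})

test_that("fold assignment partitions sites under both schemes", {
  set.seed(4)
  coords <- cbind(runif(20, 0, 100), runif(20, 0, 100))
  f <- make_folds(coords, "conventional", seed = 7)
  expect_equal(sort(unique(f)), 1:10)
  expect_true(all(table(f) == 2))
  expect_identical(f, make_folds(coords, "conventional", seed = 7))

  coords2 <- cbind(runif(47, 0, 100), runif(47, 0, 100))
  for (sc in c("conventional", "clustered")) {
    ff <- make_folds(coords2, sc, seed = 3)
    expect_length(ff, 47)
    expect_equal(sort(unique(ff)), 1:10)
    if (sc == "conventional") expect_true(max(table(ff)) - min(table(ff)) <= 1)
    expect_identical(ff, make_folds(coords2, sc, seed = 3))
  }
  expect_error(make_folds(coords[1:5, ], "conventional"), "at least")
})

test_that("clustered folds recover well-separated planted clusters", {
  set.seed(5)
  centers <- expand.grid(x = seq(0, 400, 100), y = c(0, 300))[1:10, ]
  coords <- do.call(rbind, lapply(1:10, function(i)
    cbind(centers$x[i] + rnorm(5, 0, 1), centers$y[i] + rnorm(5, 0, 1))))
  truth <- rep(1:10, each = 5)
  folds <- make_folds(coords, "clustered", seed = 11)
  # one fold per planted cluster, exactly
  tab <- table(truth, folds)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
})

test_that("metrics match their closed forms and invariances", {
  obs <- c(1, 2, 3, 4); pred <- c(2, 2, 3, 3)
  expect_equal(mse_r2(obs, pred), 0.6)
  expect_equal(mse_r2(obs, obs), 1)
  expect_equal(mse_r2(obs, rep(mean(obs), 4)), 0)
  expect_equal(srmse(c(1, 3), c(3, 1)), 1)
  expect_equal(srmse(obs, obs), 0)
  expect_error(mse_r2(c(2, 2), c(1, 2)), "constant")
  expect_error(srmse(c(-3, 1), c(1, 1)), "mean")

  # shifting obs and pred by +c > 0 strictly decreases sRMSE
  expect_lt(srmse(obs + 5, pred + 5), srmse(obs, pred))
  # permuting site order leaves both metrics unchanged
  p <- c(3, 1, 4, 2)
  expect_equal(srmse(obs[p], pred[p]), srmse(obs, pred))
  expect_equal(mse_r2(obs[p], pred[p]), mse_r2(obs, pred))
  # mse_r2 is bounded above by the regression R2 of the same predictions
  set.seed(6)
  o <- rnorm(50, 10, 2); pr <- 0.6 * o + 3 + rnorm(50, 0, 0.5)
  expect_lte(mse_r2(o, pr), summary(stats::lm(o ~ pr))$r.squared + 1e-12)
})

test_that("cross-validation predicts every site once and is self-consistent", {
  land <- tiny_landscape()
  tf <- tiny_truth(land)
  ser <- sample_monitor_series(tf, n_sites = 60, pollutant = "pm25",
                               missingness = 0.05, gap_prob = 0, seed = 21)
  qc <- qc_annual(ser)
  inc <- qc[qc$qc_status == "included", ]
  fm <- assemble_feature_matrix(land, inc,
                                default_variable_spec(c(1000, 5000, 15000)))
  cv <- cross_validate(fm, inc$value_native, cbind(inc$x, inc$y),
                       scheme = "conventional", k_pls = 2, seed = 5)
  expect_equal(sort(unique(cv$fold_of_site)), 1:10)
  expect_false(anyNA(cv$predictions$pred))
  expect_equal(nrow(cv$predictions), nrow(inc))
  # metrics recomputable from the stored held-out predictions
  expect_equal(cv$mse_r2, mse_r2(cv$predictions$obs, cv$predictions$pred))
  expect_equal(cv$srmse, srmse(cv$predictions$obs, cv$predictions$pred))
  # 11 sites over 10 folds leaves some training sets below the minimum
  expect_error(cross_validate(fm$values[1:11, ], inc$value_native[1:11],
                              cbind(inc$x, inc$y)[1:11, ], k_folds = 10),
               "fewer folds")
})

test_that("per-fold refitting avoids the leakage of whole-data selection", {
  # noise-heavy design: selecting variables on all data then cross-validating
  # them must look better than the honest per-fold pipeline
  set.seed(7)
  n <- 80
  coords <- cbind(runif(n, 0, 100), runif(n, 0, 100))
  inform <- cbind(i1 = coords[, 1] / 50 + rnorm(n, 0, 0.3),
                  i2 = rnorm(n))
  noise <- matrix(rnorm(n * 60), n, 60,
                  dimnames = list(NULL, sprintf("n%02d", 1:60)))
  y_sqrt <- 3 + 0.4 * inform[, 1] + 0.3 * inform[, 2] + rnorm(n, 0, 0.45)
  y_native <- back_transform(y_sqrt)
  X <- cbind(inform, noise)

  honest <- cross_validate(X, y_native, coords, "conventional", k_pls = 2,
                           n_predictors = 8, seed = 9)
  # leaky variant: one selection on all data, folds only refit the model
  sel <- forward_select(X, sqrt_transform(y_native), 8)
  leaky <- cross_validate(X[, sel$variables], y_native, coords,
                          "conventional", k_pls = 2, seed = 9)
  expect_gt(leaky$mse_r2, honest$mse_r2)
})

test_that("component-count selection compares candidates by conventional CV", {
  set.seed(9)
  n <- 60
  coords <- cbind(runif(n, 0, 100), runif(n, 0, 100))
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("v", 1:10)))
  y <- back_transform(3 + 0.5 * X[, 1] - 0.3 * X[, 2] + rnorm(n, 0, 0.2))
  got <- select_k_pls(X, y, coords, k_candidates = c(2, 3), seed = 11)
  expect_true(got$k %in% c(2, 3))
  expect_equal(nrow(got$table), 2)
  expect_equal(got$table$mse_r2[got$table$k_pls == got$k], max(got$table$mse_r2))
})

test_that("the sweep emits one row per predictor count and scheme", {
  set.seed(8)
  n <- 50
  coords <- cbind(runif(n, 0, 100), runif(n, 0, 100))
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("v", 1:8)))
  y <- back_transform(3 + 0.5 * X[, 1] + rnorm(n, 0, 0.3))
  tab <- sweep_n_predictors(X, y, coords, grid = 5, k_pls = 2, seed = 2)
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$scheme, c("conventional", "clustered"))
  expect_error(sweep_n_predictors(X, y, coords, grid = c(6, 3)), "ascending")
})
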