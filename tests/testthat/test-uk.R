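test_that("NLL reduces to the iid Gaussian NLL when sigma2 = 0", {
  set.seed(1)
  n <- 25
  F_design <- cbind(1, rnorm(n))
  y <- drop(F_design %*% c(2, 1)) + rnorm(n, 0, 0.5)
  D <- dist_km(cbind(runif(n), runif(n)))
  tau2 <- 0.3
  got <- as.numeric(uk_nll(c(tau2, 0, 5), F_design, y, D))
  beta <- stats::lm.fit(F_design, y)$coefficients
  r <- y - drop(F_design %*% beta)
  want <- 0.5 * (n * log(2 * pi) + n * log(tau2) + sum(r^2) / tau2)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("NLL matches direct multivariate-normal evaluation on a tiny system", {
  coords <- rbind(c(0, 0), c(3, 4), c(10, 0))
  F_design <- cbind(1, c(0.5, -1, 2))
  y <- c(1.2, 0.7, 2.4)
  theta <- c(0.1, 0.6, 7)
  D <- dist_km(coords)
  Sigma <- theta[2] * exp(-D / theta[3]) + theta[1] * diag(3)
  # profiled beta by explicit GLS, then the dense MVN density
  Si <- solve(Sigma)
  beta <- solve(t(F_design) %*% Si %*% F_design,
                t(F_design) %*% Si %*% y)
  r <- y - F_design %*% beta
  want <- 0.5 * (3 * log(2 * pi) + determinant(Sigma)$modulus +
                   t(r) %*% Si %*% r)
  got <- uk_nll(theta, F_design, y, D)
  expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-10)
  expect_equal(attr(got, "beta"), drop(beta), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("NLL is location-scale equivariant: scaling y adds n log c", {
  set.seed(2)
  n <- 30
  coords <- cbind(runif(n, 0, 50), runif(n, 0, 50))
  F_design <- cbind(1, rnorm(n))
  D <- dist_km(coords)
  y <- rnorm(n, 3, 1)
  theta <- c(0.2, 0.5, 10)
  cc <- 2.5
  # variances scale by c^2, phi unchanged
  nll1 <- as.numeric(uk_nll(theta, F_design, y, D))
  nll2 <- as.numeric(uk_nll(c(cc^2 * theta[1:2], theta[3]), F_design,
                            cc * y, D))
  expect_equal(nll2, nll1 + n * log(cc), tolerance = 1e-8)
})

test_that("kriging predictions match the dense linear-algebra oracle", {
  set.seed(3)
  n <- 30
  coords <- cbind(runif(n, 0, 60), runif(n, 0, 60))
  scores <- cbind(rnorm(n), rnorm(n))
  y <- 2 + scores %*% c(1, -0.5) + rnorm(n, 0, 0.3)
  theta <- c(0.05, 0.4, 12)
  m <- uk_model_at(theta, scores, drop(y), coords)
  new_coords <- cbind(runif(10, 0, 60), runif(10, 0, 60))
  new_scores <- cbind(rnorm(10), rnorm(10))
  got <- predict_uk(m, new_scores, new_coords)

  # oracle: assemble every matrix from the definition with dense solves
  F_tr <- cbind(1, scores); F_new <- cbind(1, new_scores)
  D <- dist_km(coords)
  Sigma <- theta[2] * exp(-D / theta[3]) + theta[1] * diag(n)
  Si <- solve(Sigma)
  beta <- solve(t(F_tr) %*% Si %*% F_tr, t(F_tr) %*% Si %*% y)
  cmat <- theta[2] * exp(-dist_km(new_coords, coords) / theta[3])
  want <- drop(F_new %*% beta + cmat %*% Si %*% (y - F_tr %*% beta))
  expect_lt(max(abs(got - want)) / max(abs(want)), 1e-8)
})

test_that("noiseless kriging interpolates training observations exactly", {
  set.seed(4)
  n <- 25
  coords <- cbind(runif(n, 0, 40), runif(n, 0, 40))
  scores <- cbind(rnorm(n))
  y <- drop(2 + 0.5 * scores + rnorm(n, 0, 0.4))
  m <- uk_model_at(c(0, 0.5, 10), scores, y, coords)
  pred <- predict_uk(m, scores, coords)
  expect_lt(max(abs(pred - y)), 1e-6)
})

test_that("far from all monitors the prediction collapses to the mean", {
  set.seed(5)
  n <- 20
  coords <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  scores <- cbind(rnorm(n))
  y <- drop(1 + scores + rnorm(n, 0, 0.2))
  theta <- c(0.1, 0.5, 5)
  m <- uk_model_at(theta, scores, y, coords)
  far <- cbind(1e6, 1e6)
  sc <- cbind(0.7)
  got <- predict_uk(m, sc, far, se = TRUE)
  expect_equal(got$pred, drop(cbind(1, sc) %*% m$beta), tolerance = 1e-10)
  # prediction variance approaches tau2 + sigma2 (plus mean uncertainty)
  expect_gte(got$se^2, theta[1] + theta[2] - 1e-8)
})

test_that("kriging reproduces constants and ignores site order", {
  set.seed(6)
  n <- 20
  coords <- cbind(runif(n, 0, 30), runif(n, 0, 30))
  scores <- cbind(rnorm(n))
  m <- uk_model_at(c(0.1, 0.3, 8), scores, rep(4.2, n), coords)
  newc <- cbind(runif(5, 0, 30), runif(5, 0, 30))
  expect_equal(predict_uk(m, cbind(rnorm(5)), newc), rep(4.2, 5),
               tolerance = 1e-9)

  # permuting training sites leaves predictions unchanged
  y <- drop(1 + scores + rnorm(n, 0, 0.3))
  p <- sample(n)
  m1 <- uk_model_at(c(0.05, 0.4, 10), scores, y, coords)
  m2 <- uk_model_at(c(0.05, 0.4, 10), scores[p, , drop = FALSE], y[p],
                    coords[p, ])
  sc_new <- cbind(rnorm(5))
  expect_equal(predict_uk(m1, sc_new, newc), predict_uk(m2, sc_new, newc),
               tolerance = 1e-9)
})

test_that("duplicate coordinates and tiny training sets are rejected", {
  coords <- rbind(c(0, 0), c(1, 1), c(0, 0), c(2, 2), c(3, 3),
                  c(4, 4), c(5, 5), c(6, 6), c(7, 7), c(8, 8))
  expect_error(fit_uk(cbind(rnorm(10)), rnorm(10), coords), "duplicate")
  expect_error(fit_uk(cbind(rnorm(5)), rnorm(5),
                      cbind(1:5, 1:5) + runif(10)), ">= 10")
})

test_that("ML recovers covariance parameters from simulated fields", {
  # n = 200 per replicate; median relative error of each of tau2, sigma2,
  # phi below 30% over 20 seeded replicates
  true <- c(tau2 = 0.05, sigma2 = 0.2, phi = 20)
  rel <- matrix(NA_real_, 20, 3)
  nll_fit_le_truth <- logical(20)
  for (i in 1:20) {
    sim <- simulate_uk_data(200, tau2 = true[1], sigma2 = true[2],
                            phi = true[3], seed = 100 + i)
    m <- fit_uk(sim$scores, sim$y, sim$coords)
    est <- c(m$tau2, m$sigma2, m$phi)
    rel[i, ] <- abs(est - true) / true
    D <- dist_km(sim$coords)
    nll_true <- as.numeric(uk_nll(true, cbind(1, sim$scores), sim$y, D))
    nll_fit_le_truth[i] <- m$nll <= nll_true + 1e-6
  }
  med <- apply(rel, 2, median)
  expect_lt(med[1], 0.3)
  expect_lt(med[2], 0.3)
  expect_lt(med[3], 0.3)
  # optimiser sanity: fitted NLL beats the truth's NLL almost always
  expect_gte(mean(nll_fit_le_truth), 0.9)
})

test_that("REML adds the information log-determinant to the likelihood", {
  set.seed(7)
  n <- 30
  coords <- cbind(runif(n, 0, 50), runif(n, 0, 50))
  F_design <- cbind(1, rnorm(n))
  y <- drop(F_design %*% c(2, 1)) + rnorm(n, 0, 0.4)
  D <- dist_km(coords)
  theta <- c(0.1, 0.3, 12)
  Sigma <- theta[2] * exp(-D / theta[3]) + theta[1] * diag(n)
  Si <- solve(Sigma)
  want_extra <- 0.5 * (determinant(t(F_design) %*% Si %*% F_design)$modulus -
                         2 * log(2 * pi))
  ml <- as.numeric(uk_nll(theta, F_design, y, D))
  reml <- as.numeric(uk_nll(theta, F_design, y, D, reml = TRUE))
  expect_equal(reml - ml, as.numeric(want_extra), tolerance = 1e-8)
  # REML fit runs and recovers parameters of the same order as ML
  sim <- simulate_uk_data(120, seed = 9)
  m_reml <- fit_uk(sim$scores, sim$y, sim$coords, reml = TRUE)
  expect_gt(m_reml$phi, 0)
  expect_gte(m_reml$tau2, 0)
})

test_that("spatially independent data yield a small fitted spatial fraction", {
  frac <- numeric(10)
  for (i in 1:10) {
    sim <- simulate_uk_data(120, tau2 = 0.25, sigma2 = 0, phi = 10,
                            seed = 300 + i)
    m <- fit_uk(sim$scores, sim$y, sim$coords)
    frac[i] <- m$sigma2 / (m$sigma2 + m$tau2)
  }
  expect_lt(median(frac), 0.2)
})
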