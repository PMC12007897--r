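#' Ground-truth concentration field
#'
#' The model assumes sqrt-scale concentrations decompose into a linear mean in
#' geographic covariates plus a stationary Gaussian random field (GRF) with
#' exponential covariance. The synthetic truth is built exactly that way, so
#' the fitting stage has a recoverable target: `field = offset + covariates
#' %*% coeffs + GRF(partial_sill, range_km)` on the sqrt scale. The nugget is
#' carried as site-level micro-scale/measurement variance and added when
#' monitor series are sampled, not to the smooth field itself.
#'
#' The GRF is simulated exactly and lazily: the first evaluation draws from
#' the unconditional multivariate normal via Cholesky factorisation; later
#' evaluations draw from the Gaussian conditional on every point already
#' materialised. Re-evaluating a point returns the memoised value, so the
#' field behaves as a fixed (if progressively revealed) surface.
#'
#' @name truth-field
NULL

#' Generate a ground-truth concentration field
#'
#' @param landscape a `landscape` from [generate_landscape()].
#' @param coeffs numeric length 4: sqrt-scale intercept and weights on the
#'   urban, traffic and source covariates of [truth_covariates()]. The default
#'   gives annual means in a realistic fine-particle range (roughly 5-20
#'   ug/m3) with a positive mean surface everywhere.
#' @param partial_sill GRF variance, sqrt-concentration units squared (>= 0).
#' @param range_km exponential correlation range phi in km (> 0).
#' @param nugget micro-scale/measurement variance applied per monitor (>= 0).
#' @param seed integer seed for the field's private RNG stream.
#' @return an object of class `truth_field`.
#' @export
generate_truth_field <- function(landscape,
                                 coeffs = c(2.0, 3.0, 0.6, 0.3),
                                 partial_sill = 0.09, range_km = 60,
                                 nugget = 0.01, seed = 1) {
  if (partial_sill < 0 || nugget < 0) stop("variance parameters must be >= 0")
  if (range_km <= 0) stop("range_km must be > 0")
  if (length(coeffs) != 4) stop("coeffs must have length 4 (intercept + 3 covariates)")
  state <- new.env(parent = emptyenv())
  state$P <- matrix(numeric(0), ncol = 2)
  state$z <- numeric(0)
  state$rng <- with_seed(seed, {
    runif(1)
    get(".Random.seed", envir = globalenv())
  })
  structure(list(landscape = landscape, coeffs = as.numeric(coeffs),
                 partial_sill = partial_sill, range_km = range_km,
                 nugget = nugget, seed = seed, state = state),
            class = "truth_field")
}

# run expr under the field's private RNG stream, persisting its state
with_field_rng <- function(field, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  assign(".Random.seed", field$state$rng, envir = globalenv())
  res <- expr
  field$state$rng <- get(".Random.seed", envir = globalenv())
  if (had) assign(".Random.seed", old, envir = globalenv())
  else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  res
}

#' Evaluate the noise-free sqrt-scale truth at points
#'
#' Returns mean + GRF on the sqrt scale (no nugget). Points already evaluated
#' return their memoised GRF draw; new points are drawn conditionally on all
#' previous ones, so the joint law over any evaluation sequence is the exact
#' stationary GRF.
#'
#' @param field a `truth_field`.
#' @param pts n x 2 matrix of projected km coordinates.
#' @return numeric vector of sqrt-scale concentrations.
#' @export
truth_eval <- function(field, pts) {
  pts <- matrix(as.numeric(as.matrix(pts)), ncol = 2)
  cv <- truth_covariates(field$landscape, pts)
  mu <- drop(cbind(1, cv) %*% field$coeffs)
  if (field$partial_sill == 0) return(mu)
  mu + grf_eval(field, pts)
}

grf_eval <- function(field, pts) {
  st <- field$state
  key <- function(m) paste(sprintf("%.13g", m[, 1]), sprintf("%.13g", m[, 2]))
  out <- numeric(nrow(pts))
  kP <- key(st$P)
  kq <- key(pts)
  hit <- match(kq, kP)
  # duplicates within the batch resolve to the first occurrence
  first <- match(kq, kq)
  need <- which(is.na(hit) & first == seq_along(kq))
  if (length(need) > 0) {
    Q <- pts[need, , drop = FALSE]
    s2 <- field$partial_sill; phi <- field$range_km
    Sqq <- s2 * exp(-dist_km(Q) / phi)
    if (nrow(st$P) == 0) {
      mu_c <- rep(0, nrow(Q)); Sc <- Sqq
    } else {
      Spp <- s2 * exp(-dist_km(st$P) / phi)
      Spq <- s2 * exp(-dist_km(st$P, Q) / phi)
      ch <- chol(Spp + diag(1e-10 * s2, nrow(Spp)))
      A <- backsolve(ch, forwardsolve(t(ch), Spq))   # Spp^-1 Spq
      mu_c <- drop(crossprod(Spq, backsolve(ch, forwardsolve(t(ch), st$z))))
      Sc <- Sqq - crossprod(Spq, A)
      Sc <- (Sc + t(Sc)) / 2
    }
    znew <- with_field_rng(field, {
      Lc <- t(chol(Sc + diag(1e-10 * s2 + 1e-12, nrow(Sc))))
      drop(mu_c + Lc %*% rnorm(nrow(Q)))
    })
    st$P <- rbind(st$P, Q)
    st$z <- c(st$z, znew)
    kP <- key(st$P)
    hit <- match(kq, kP)
  }
  out[] <- st$z[hit]
  out
}

#' Evaluate the truth on the native concentration scale
#'
#' Back-transforms the sqrt-scale field: negative sqrt values clamp to zero
#' before squaring, so native concentrations are always >= 0.
#' @inheritParams truth_eval
#' @export
truth_eval_native <- function(field, pts) back_transform(truth_eval(field, pts))
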