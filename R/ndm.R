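#' Evolve a regional pathology pattern under network diffusion
#'
#' The Network Diffusion Model propagates a pathology pattern `x0` along the
#' connectome as heat-like diffusion: `x(t) = exp(-beta H t) x0`. The matrix
#' exponential is evaluated spectrally from the Laplacian's cached
#' eigendecomposition, `U diag(exp(-lambda beta t)) U' x0`.
#'
#' @param L a [build_laplacian()] object.
#' @param x0 numeric vector of initial regional pathology, length `n_regions`.
#' @param beta diffusivity in 1/year; must be nonnegative.
#' @param t elapsed time in years; must be nonnegative.
#' @return numeric vector `x(t)` of evolved pathology.
#' @export
ndm_evolve <- function(L, x0, beta, t) {
  .check_ndm_args(L, x0, beta, t)
  if (beta * t == 0) return(as.numeric(x0))   # semigroup identity, exact
  w <- crossprod(L$U, x0)
  drop(L$U %*% (exp(-L$lambdas * beta * t) * w))
}

#' Accumulated atrophy under network diffusion
#'
#' Atrophy is modelled as the time-integral of pathology,
#' `Phi(t) = integral_0^t x(tau) dtau`. The integral has the closed spectral
#' form `U diag(g) U' x0` with `g_i = (1 - exp(-lambda_i beta t)) /
#' (lambda_i beta)` for nonzero modes and `g_i = t` for zero modes; the
#' numerator is computed with `expm1` for stability at small `lambda beta t`.
#'
#' @inheritParams ndm_evolve
#' @return numeric vector `Phi(t)` of accumulated atrophy (zero at `t = 0`).
#' @export
ndm_accumulate <- function(L, x0, beta, t) {
  .check_ndm_args(L, x0, beta, t)
  lam <- L$lambdas
  s <- beta * t
  g <- numeric(length(lam))
  zero <- .zero_modes(L)
  if (beta == 0) {
    g[] <- t
  } else {
    g[zero] <- t
    nz <- !zero
    g[nz] <- -expm1(-lam[nz] * s) / (lam[nz] * beta)
  }
  w <- crossprod(L$U, x0)
  drop(L$U %*% (g * w))
}

#' Modified Laplacian relating baseline atrophy to its rate of change
#'
#' For a signal following the diffusion-and-accumulation model, the
#' instantaneous rate of change of atrophy at time `t` is a fixed linear map
#' of the accumulated atrophy: `dPhi/dt = beta * Htilde(beta t) * Phi(t)`.
#' `Htilde(s)` shares the Laplacian's eigenvectors and has eigenbasis diagonal
#' `1/s` on the zero mode and `lambda_i exp(-lambda_i s) / (1 - exp(-lambda_i
#' s))` elsewhere, computed as `lambda / expm1(lambda s)` for stability.
#'
#' @param L a [build_laplacian()] object with exactly one zero mode.
#' @param betat dimensionless product `beta * t`; must be positive.
#' @return symmetric matrix `Htilde(betat)`.
#' @export
modified_laplacian <- function(L, betat) {
  if (!is.numeric(betat) || length(betat) != 1 || !is.finite(betat) || betat <= 0) {
    stop("betat must be a single positive number")
  }
  .check_single_zero_mode(L)
  d <- .htilde_diag(L, betat)
  M <- L$U %*% (d * t(L$U))
  (M + t(M)) / 2
}

# eigenbasis diagonal of Htilde(s); lambda/expm1(lambda*s) underflows cleanly
# to 0 for lambda*s > ~745
.htilde_diag <- function(L, s) {
  lam <- L$lambdas
  d <- numeric(length(lam))
  zero <- .zero_modes(L)
  d[zero] <- 1 / s
  nz <- !zero
  d[nz] <- lam[nz] / expm1(lam[nz] * s)
  d
}

.zero_modes <- function(L) {
  lmax <- max(L$lambdas)
  if (lmax <= 0) rep(TRUE, length(L$lambdas)) else L$lambdas < L$zero_tol * lmax
}

#' Model-predicted regional atrophy slopes at baseline
#'
#' Applies the baseline-rate relation `dPhi/dt = beta * Htilde(beta t_base) *
#' Phi_base`, evaluated spectrally without forming the matrix.
#'
#' @param L a [build_laplacian()] object with exactly one zero mode.
#' @param beta diffusivity in 1/year, positive.
#' @param t_base years between pathology onset and the baseline scan, positive.
#' @param phi_base numeric vector of baseline regional atrophy.
#' @return numeric vector of predicted atrophy slopes (atrophy units / year).
#' @export
predicted_slope <- function(L, beta, t_base, phi_base) {
  if (beta <= 0 || t_base <= 0) stop("beta and t_base must be positive")
  if (length(phi_base) != length(L$lambdas)) {
    stop("phi_base length does not match Laplacian dimension")
  }
  .check_single_zero_mode(L)
  d <- .htilde_diag(L, beta * t_base)
  w <- crossprod(L$U, phi_base)
  beta * drop(L$U %*% (d * w))
}

.check_ndm_args <- function(L, x0, beta, t) {
  stopifnot(inherits(L, "laplacian"))
  if (length(x0) != length(L$lambdas)) {
    stop("x0 length (", length(x0), ") does not match Laplacian dimension (",
         length(L$lambdas), ")")
  }
  if (!is.numeric(beta) || length(beta) != 1 || beta < 0) stop("beta must be a nonnegative scalar")
  if (!is.numeric(t) || length(t) != 1 || t < 0) stop("t must be a nonnegative scalar")
}
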