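# Poisson random field machinery for the McDonald-Kreitman selection model.
#
# Under genic selection with scaled coefficient gamma = 2*Ne*s, the relative
# fixation rate of selected mutations is H(gamma) = 2*gamma / (1 - e^{-2*gamma})
# and the relative expected number of selected polymorphisms observable in a
# sample of n chromosomes is
#   G(gamma, n) = I(gamma, n) / I(0, n),
#   I(gamma, n) = Int_0^1 (1 - q^n - (1-q)^n) * f(q; gamma) dq,
#   f(q; gamma) = (1 - e^{-2*gamma*(1-q)}) / ((1 - e^{-2*gamma}) * q * (1-q)).
# The neutral denominator has the closed form I(0, n) = a_n.

#' Relative fixation rate under selection
#'
#' \eqn{H(\gamma) = 2\gamma / (1 - e^{-2\gamma})} with the removable
#' singularity \eqn{H(0) = 1} handled explicitly. Satisfies the identity
#' \eqn{H(\gamma) = e^{2\gamma} H(-\gamma)}.
#'
#' @param gamma Scaled selection coefficient \eqn{2 N_e s} (vectorised).
#' @return Relative fixation rate (neutral = 1).
#' @export
prf_fixation_factor <- function(gamma) {
  out <- numeric(length(gamma))
  small <- abs(gamma) < 1e-8
  out[small] <- 1 + gamma[small]  # first-order expansion at 0
  g <- gamma[!small]
  out[!small] <- 2 * g / (1 - exp(-2 * g))
  out
}

# Stationary frequency density of selected mutations (sampling-factor-free).
prf_density <- function(q, gamma) {
  if (abs(gamma) < 1e-8) return((1 - q) / (q * (1 - q)) * (1 + gamma * q))
  (1 - exp(-2 * gamma * (1 - q))) / ((1 - exp(-2 * gamma)) * q * (1 - q))
}

#' Relative expected sampled polymorphism under selection
#'
#' Ratio of the expected number of segregating selected mutations in a
#' sample of \code{n} chromosomes to the neutral expectation, computed by
#' adaptive quadrature. The integrand's \eqn{1/q} and \eqn{1/(1-q)}
#' endpoint singularities are tamed by the sampling factor
#' \eqn{1 - q^n - (1-q)^n}; finite endpoint limits are supplied explicitly.
#'
#' @param gamma Scaled selection coefficient (scalar).
#' @param n Sample size in chromosomes (\code{n >= 2}).
#' @param rel.tol Quadrature relative tolerance.
#' @return \eqn{G(\gamma, n)}, with \eqn{G(0, n) = 1}.
#' @export
prf_polymorphism_factor <- function(gamma, n, rel.tol = 1e-10) {
  if (n < 2) stop("n must be >= 2")
  if (abs(gamma) < 1e-12) return(1)
  integrand <- function(q) {
    v <- (1 - q^n - (1 - q)^n) * prf_density(q, gamma)
    # endpoint limits: q -> 0 gives n (sampling factor ~ n*q); q -> 1 gives
    # n * 2*gamma*e^{0}/(1 - e^{-2*gamma}) / 1 ... both finite
    v[q == 0] <- n
    v[q == 1] <- n * 2 * gamma / (1 - exp(-2 * gamma))
    v
  }
  I <- tryCatch(
    stats::integrate(integrand, 0, 1, rel.tol = rel.tol,
                     subdivisions = 400L),
    error = function(e) stop("PRF quadrature failed for gamma = ", gamma,
                             ", n = ", n, ": ", conditionMessage(e)))
  I$value / a_n(n)
}

# Vectorised G via a cached interpolation grid per sample size; used inside
# MCMC loops where millions of evaluations are needed. Grid spans
# gamma in [-25, 25] at step 0.05 with linear interpolation (~1e-5 relative
# accuracy); outside the grid the exact quadrature is called.
prf_g_interpolator <- local({
  cache <- new.env(parent = emptyenv())
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    grid <- seq(-25, 25, by = 0.05)
    vals <- vapply(grid, prf_polymorphism_factor, numeric(1), n = n,
                   rel.tol = 1e-9)
    f <- function(gamma) {
      out <- numeric(length(gamma))
      inside <- gamma >= -25 & gamma <= 25
      if (any(inside))
        out[inside] <- stats::approx(grid, vals, xout = gamma[inside])$y
    if (any(!inside))
        out[!inside] <- vapply(gamma[!inside], prf_polymorphism_factor,
                               numeric(1), n = n)
      out
    }
    cache[[key]] <- f
    f
  }
})

#' Log-likelihood of McDonald-Kreitman tables under the PRF model
#'
#' Independent Poisson counts per locus: \code{Ps ~ Pois(theta_s * a_n)},
#' \code{Ds ~ Pois(theta_s * (tau + 1))},
#' \code{Pn ~ Pois(theta_r * a_n * G(gamma, n))},
#' \code{Dn ~ Pois(theta_r * (tau + 1) * H(gamma))}. The silent class is the
#' neutral anchor (\eqn{\gamma = 0}); the lineage weighting of divergence is
#' fixed at 1 (a single outgroup cannot apportion fixations to branches).
#'
#' @param tables Data frame with columns \code{Ps}, \code{Pn}, \code{Ds},
#'   \code{Dn}, \code{n} (one row per locus).
#' @param theta_s,theta_r Per-locus silent and replacement mutation
#'   parameters (locus-wide, positive).
#' @param gamma Per-locus selection coefficients.
#' @param tau Scaled divergence time (shared across loci, positive).
#' @return Log-likelihood (scalar).
#' @export
prf_loglik <- function(tables, theta_s, theta_r, gamma, tau) {
  if (any(theta_s <= 0) || any(theta_r <= 0) || tau <= 0)
    stop("theta_s, theta_r and tau must be positive")
  an <- a_n(tables$n)
  G <- vapply(seq_len(nrow(tables)), function(i)
    prf_polymorphism_factor(gamma[i], tables$n[i]), numeric(1))
  H <- prf_fixation_factor(gamma)
  sum(stats::dpois(tables$Ps, theta_s * an, log = TRUE) +
      stats::dpois(tables$Ds, theta_s * (tau + 1), log = TRUE) +
      stats::dpois(tables$Pn, theta_r * an * G, log = TRUE) +
      stats::dpois(tables$Dn, theta_r * (tau + 1) * H, log = TRUE))
}
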