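# Maximum-likelihood HKA with per-locus selection factors.
#
# Poisson likelihood on counts:
#   S_i ~ Pois(k_i * theta_i * a_{n_i}),
#   D_i ~ Pois(theta_i * (T + k_i)),
# where k_i scales polymorphism and the ancestral-polymorphism component of
# divergence; k = 1 is neutral, k > 1 balancing-selection-like diversity
# excess, k < 1 sweep-like deficit. T is fixed (default 15). With T fixed
# the likelihood separates by locus and theta_i has the closed-form
# conditional MLE theta_i(k) = (S_i + D_i)/(k*a_i + T + k), so fitting
# reduces to a one-dimensional profile maximisation in log k per free locus.

# Continuous extension of the Poisson log-mass (x may be an expectation,
# not just an integer count): x*log(lambda) - lambda - lgamma(x + 1).
log_pois <- function(x, lambda) {
  out <- -lambda - lgamma(x + 1)
  pos <- x > 0
  out[pos] <- out[pos] + x[pos] * log(lambda[pos])
  out
}

#' mlHKA log-likelihood
#'
#' @param table A polymorphism/divergence table
#'   (see \code{\link{poly_div_table}}).
#' @param theta Per-locus theta (locus-wide, positive).
#' @param k Per-locus selection factors (positive).
#' @param T_div Scaled divergence time (positive).
#' @return Log-likelihood (scalar).
#' @export
mlhka_loglik <- function(table, theta, k, T_div) {
  table <- poly_div_table(table)
  if (any(theta <= 0) || any(k <= 0) || T_div <= 0)
    stop("theta, k and T_div must be positive")
  a <- a_n(table$n)
  sum(log_pois(table$S, k * theta * a) +
      log_pois(table$D, theta * (T_div + k)))
}

# Per-locus profile log-likelihood at selection factor k.
mlhka_profile_locus <- function(S, D, a, T_div, k) {
  theta <- (S + D) / (k * a + T_div + k)
  if (theta <= 0) theta <- 1e-12
  log_pois(S, k * theta * a) + log_pois(D, theta * (T_div + k))
}

#' Fit the mlHKA model
#'
#' Maximises the likelihood with \code{k} free at the loci named in
#' \code{free_k_loci} and pinned to 1 elsewhere. Each free \code{k} is
#' profiled over a wide grid in \code{log k} and polished with Brent's
#' method; the neutral value \code{k = 1} is always evaluated so the free
#' model's likelihood can never fall below the nested neutral one.
#'
#' @param table A polymorphism/divergence table.
#' @param free_k_loci Character vector of locus names (or integer indices)
#'   whose selection factor is free; empty for the neutral model.
#' @param T_div Scaled divergence time, fixed during fitting (default 15).
#' @param k_bounds Search range for free selection factors.
#' @return Object of class \code{mlhka}: \code{logLik}, \code{k_hat},
#'   \code{theta_hat}, \code{free} (logical per locus), \code{T_div}.
#' @export
mlhka_fit <- function(table, free_k_loci = character(0), T_div = 15,
                      k_bounds = c(1e-3, 1e3)) {
  table <- poly_div_table(table)
  a <- a_n(table$n)
  nloci <- nrow(table)
  free <- if (is.numeric(free_k_loci)) seq_len(nloci) %in% free_k_loci
    else table$locus %in% free_k_loci
  if (is.character(free_k_loci) &&
      length(setdiff(free_k_loci, table$locus)))
    stop("unknown locus in free_k_loci: ",
         paste(setdiff(free_k_loci, table$locus), collapse = ", "))

  k_hat <- rep(1, nloci)
  lnl <- numeric(nloci)
  for (i in seq_len(nloci)) {
    if (!free[i]) {
      lnl[i] <- mlhka_profile_locus(table$S[i], table$D[i], a[i], T_div, 1)
      next
    }
    f <- function(logk) mlhka_profile_locus(table$S[i], table$D[i], a[i],
                                            T_div, exp(logk))
    grid <- seq(log(k_bounds[1]), log(k_bounds[2]), length.out = 61L)
    vals <- vapply(grid, f, numeric(1))
    best <- which.max(vals)
    lo <- grid[max(1L, best - 1L)]
    hi <- grid[min(length(grid), best + 1L)]
    opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-10)
    # never fall below the nested neutral point
    at1 <- f(0)
    if (opt$objective >= at1) {
      k_hat[i] <- exp(opt$maximum)
      lnl[i] <- opt$objective
    } else {
      k_hat[i] <- 1
      lnl[i] <- at1
    }
  }
  theta_hat <- (table$S + table$D) / (k_hat * a + T_div + k_hat)
  structure(list(
    table = table, logLik = sum(lnl), k_hat = k_hat,
    theta_hat = theta_hat, free = free, T_div = T_div,
    free_loci = table$locus[free]),
    class = "mlhka")
}

#' @export
logLik.mlhka <- function(object, ...) {
  val <- object$logLik
  attr(val, "df") <- sum(object$free) + nrow(object$table)
  class(val) <- "logLik"
  val
}

#' @export
coef.mlhka <- function(object, ...) {
  stats::setNames(object$k_hat, object$table$locus)
}

#' @export
print.mlhka <- function(x, ...) {
  cat("mlHKA fit (", nrow(x$table), " loci, T = ", x$T_div, ")\n", sep = "")
  cat("  free k at:",
      if (length(x$free_loci)) paste(x$free_loci, collapse = ", ")
      else "none (neutral model)", "\n")
  cat("  ln L =", format(x$logLik, digits = 8), "\n")
  if (any(x$free))
    cat("  k_hat:", paste(x$table$locus[x$free], "=",
                          format(x$k_hat[x$free], digits = 4),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Likelihood-ratio test between nested fits
#'
#' \code{LR = 2 (lnL_alt - lnL_null)}, referred to a chi-square with
#' \code{df} degrees of freedom. A negative LR beyond numerical tolerance
#' signals an optimiser failure in whatever produced the log-likelihoods
#' and is reported as an invalid result (no p-value), not as a number.
#'
#' @param lnL_null,lnL_alt Log-likelihoods of the nested and the free
#'   model; \code{mlhka} objects are accepted.
#' @param df Degrees of freedom (number of freed parameters).
#' @param tol Tolerance below zero before the result is declared invalid.
#' @return Object of class \code{lrt_result}: \code{LR}, \code{df},
#'   \code{p}, \code{valid}, \code{diagnostic}.
#' @export
lrt <- function(lnL_null, lnL_alt, df = 1L, tol = 1e-8) {
  if (inherits(lnL_null, "mlhka")) lnL_null <- lnL_null$logLik
  if (inherits(lnL_alt, "mlhka")) lnL_alt <- lnL_alt$logLik
  LR <- 2 * (lnL_alt - lnL_null)
  if (LR < -tol) {
    return(structure(list(
      LR = NA_real_, df = df, p = NA_real_, valid = FALSE,
      diagnostic = sprintf(
        "alternative log-likelihood below null by %.6g: optimiser failure",
        lnL_null - lnL_alt)),
      class = "lrt_result"))
  }
  LR <- max(LR, 0)
  structure(list(LR = LR, df = df,
                 p = stats::pchisq(LR, df, lower.tail = FALSE),
                 valid = TRUE, diagnostic = NULL),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  if (!x$valid) {
    cat("LRT invalid:", x$diagnostic, "\n")
  } else {
    cat("LRT: LR =", format(x$LR, digits = 6), " df =", x$df,
        " p =", format(x$p, digits = 4), "\n")
  }
  invisible(x)
}

#' mlHKA selection test for one locus
#'
#' Convenience wrapper: fits the neutral model and the model with a free
#' selection factor at \code{locus}, and performs the likelihood-ratio test
#' with one degree of freedom.
#'
#' @param table A polymorphism/divergence table.
#' @param locus Locus name to test.
#' @param T_div Fixed divergence time.
#' @return List with the two \code{mlhka} fits, the \code{lrt_result}, and
#'   \code{k_hat} at the tested locus.
#' @export
mlhka_locus_test <- function(table, locus, T_div = 15) {
  fit0 <- mlhka_fit(table, character(0), T_div = T_div)
  fit1 <- mlhka_fit(table, locus, T_div = T_div)
  test <- lrt(fit0, fit1, df = 1L)
  list(neutral = fit0, selection = fit1, lrt = test,
       k_hat = fit1$k_hat[fit1$table$locus == locus])
}
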