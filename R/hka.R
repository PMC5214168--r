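# Multilocus HKA goodness-of-fit test.
#
# Single-species layout: polymorphism within the focal species (S_i) and
# divergence to the outgroup (D_i) at L loci. Method-of-moments fit:
#   E[S_i] = theta_i * a_{n_i},  E[D_i] = theta_i * (T + 1),
# with per-locus constraints S_i + D_i = E[S_i] + E[D_i] and the overall
# constraint sum(D) = (T+1) * sum(theta). The relative ancestral population
# size of the original formulation is fixed at 1 (no second-species
# polymorphism data is used), which adds the single ancestral-coalescent
# unit to T in E[D].

#' Validate and normalise a polymorphism/divergence table
#'
#' @param table Data frame with one row per locus and columns \code{S}
#'   (silent segregating sites), \code{D} (silent fixed differences to the
#'   outgroup), \code{L} (silent sites) and \code{n} (chromosomes); an
#'   optional \code{locus} column supplies names.
#' @return The table with a \code{locus} column, checked.
#' @export
poly_div_table <- function(table) {
  table <- as.data.frame(table)
  need <- c("S", "D", "L", "n")
  if (!all(need %in% names(table)))
    stop("table needs columns ", paste(need, collapse = ", "))
  if (!"locus" %in% names(table))
    table$locus <- paste0("locus", seq_len(nrow(table)))
  if (any(table$S < 0) || any(table$D < 0)) stop("S and D must be >= 0")
  if (any(table$n < 2)) stop("all n must be >= 2")
  if (any(table$L <= 0)) stop("all L must be > 0")
  table
}

# Moment fit: solve for T by a monotone one-dimensional root, theta per
# locus in closed form given T.
fit_hka_params <- function(table) {
  a <- a_n(table$n)
  tot <- table$S + table$D
  theta_of <- function(T) tot / (a + T + 1)
  g <- function(T) (T + 1) * sum(theta_of(T)) - sum(table$D)
  boundary <- FALSE
  if (sum(table$D) == 0) {
    T_hat <- -1 + 1e-9
    boundary <- TRUE
  } else if (sum(table$S) == 0) {
    T_hat <- Inf
    boundary <- TRUE
  } else {
    lo <- -1 + 1e-9
    hi <- 10
    while (g(hi) < 0 && hi < 1e12) hi <- hi * 10
    if (g(hi) < 0)
      stop("HKA moment fit did not converge; residual g(", hi, ") = ",
           g(hi))
    T_hat <- stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
  }
  list(theta_hat = theta_of(T_hat), T_hat = T_hat, boundary = boundary)
}

#' Multilocus HKA test
#'
#' Fits the neutral model by the method of moments and computes the
#' goodness-of-fit statistic
#' \deqn{X^2 = \sum_i (S_i - \hat S_i)^2/\mathrm{Var}(S_i) +
#'              (D_i - \hat D_i)^2/\mathrm{Var}(D_i)}
#' with \eqn{\mathrm{Var}(S_i) = \hat S_i + \hat\theta_i^2 b_{n_i}} and
#' \eqn{\mathrm{Var}(D_i) = \hat D_i + \hat\theta_i^2}, referred to a
#' chi-square with \code{df = L - 1}. Loci with zero fitted variance are
#' dropped with a warning. An optional parametric-bootstrap p-value
#' resimulates from the fitted null (coalescent polymorphism, Poisson
#' divergence) and refits each replicate.
#'
#' @param table A polymorphism/divergence table
#'   (see \code{\link{poly_div_table}}).
#' @param sim_reps Parametric-bootstrap replicates (0 = chi-square p only).
#' @param seed Optional RNG seed for the bootstrap.
#' @return Object of class \code{hka}: per-locus \code{theta_hat}, fitted
#'   \code{T_hat}, per-locus deviation contributions, \code{X2}, \code{df},
#'   \code{p_chi} and (optionally) \code{p_sim}.
#' @export
hka_test <- function(table, sim_reps = 0L, seed = NULL) {
  table <- poly_div_table(table)
  if (nrow(table) < 2L) stop(">=2 loci required")
  fit <- fit_hka_params(table)
  res <- hka_statistic(table, fit$theta_hat, fit$T_hat)
  res$boundary <- fit$boundary
  if (fit$boundary)
    warning("HKA fit at parameter boundary (all S or all D zero)")
  if (sim_reps > 0L)
    res$p_sim <- hka_parametric_p(table, reps = sim_reps, seed = seed,
                                  observed_x2 = res$X2)
  res
}

#' HKA goodness-of-fit statistic at given parameters
#'
#' @param table A polymorphism/divergence table.
#' @param theta_hat Per-locus theta (locus-wide).
#' @param T_hat Scaled divergence time.
#' @return Object of class \code{hka} (without \code{p_sim}).
#' @export
hka_statistic <- function(table, theta_hat, T_hat) {
  table <- poly_div_table(table)
  a <- a_n(table$n)
  b <- b_n(table$n)
  S_exp <- theta_hat * a
  D_exp <- theta_hat * (T_hat + 1)
  var_S <- S_exp + theta_hat^2 * b
  var_D <- D_exp + theta_hat^2
  usable <- var_S > 0 & var_D > 0
  if (!all(usable))
    warning(sum(!usable), " locus/loci with zero fitted variance dropped")
  dev_S <- (table$S - S_exp)^2 / var_S
  dev_D <- (table$D - D_exp)^2 / var_D
  X2 <- sum(dev_S[usable] + dev_D[usable])
  df <- sum(usable) - 1L
  structure(list(
    table = table, theta_hat = theta_hat, T_hat = T_hat,
    expected = data.frame(locus = table$locus, S_exp = S_exp, D_exp = D_exp,
                          var_S = var_S, var_D = var_D,
                          dev_S = dev_S, dev_D = dev_D),
    X2 = X2, df = df,
    p_chi = stats::pchisq(X2, df, lower.tail = FALSE),
    p_sim = NULL, boundary = FALSE),
    class = "hka")
}

#' Parametric-bootstrap p-value for the HKA statistic
#'
#' Simulates \code{reps} tables from the fitted neutral model (per-locus
#' coalescent polymorphism at the fitted theta, Poisson divergence at
#' \code{theta * (T+1)}), refits each and recomputes the statistic;
#' the p-value is the add-one exceedance fraction.
#'
#' @param table A polymorphism/divergence table.
#' @param reps Number of simulated tables.
#' @param seed Optional RNG seed.
#' @param observed_x2 Observed statistic; computed from \code{table} if
#'   missing.
#' @return Simulated p-value in \eqn{[1/(reps+1), 1]}.
#' @export
hka_parametric_p <- function(table, reps = 1000L, seed = NULL,
                             observed_x2 = NULL) {
  table <- poly_div_table(table)
  if (!is.null(seed)) set.seed(seed)
  fit <- fit_hka_params(table)
  if (is.null(observed_x2))
    observed_x2 <- hka_statistic(table, fit$theta_hat, fit$T_hat)$X2
  hits <- 0L
  for (r in seq_len(reps)) {
    sim <- simulate_hka_table(fit$theta_hat, fit$T_hat, table$n, table$L)
    sfit <- fit_hka_params(sim)
    x2 <- hka_statistic(sim, sfit$theta_hat, sfit$T_hat)$X2
    if (x2 >= observed_x2) hits <- hits + 1L
  }
  (1 + hits) / (reps + 1)
}

#' Simulate a polymorphism/divergence table under the neutral model
#'
#' Per locus, polymorphism counts come from a neutral coalescent genealogy
#' (Poisson mutations at rate theta/2 per unit branch length, so S carries
#' the full coalescent variance) and divergence counts are Poisson with
#' mean \code{theta * (T + 1)}.
#'
#' @param theta Per-locus locus-wide theta.
#' @param T_div Scaled divergence time.
#' @param n Per-locus sample sizes.
#' @param L Per-locus silent site counts (carried through to the table).
#' @param seed Optional RNG seed.
#' @return A polymorphism/divergence table.
#' @export
simulate_hka_table <- function(theta, T_div, n, L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nloci <- length(theta)
  S <- integer(nloci)
  for (i in seq_len(nloci)) {
    tree <- sim_genealogy(n[i])
    S[i] <- stats::rpois(1, theta[i] / 2 * tree$total_length)
  }
  D <- stats::rpois(nloci, theta * (T_div + 1))
  poly_div_table(data.frame(S = S, D = D, L = L, n = n))
}

#' @export
print.hka <- function(x, ...) {
  cat("Multilocus HKA test (", nrow(x$table), " loci)\n", sep = "")
  cat("  T_hat =", format(x$T_hat, digits = 6),
      if (x$boundary) "(boundary)" else "", "\n")
  cat("  X2 =", format(x$X2, digits = 6), " df =", x$df,
      " p_chi =", format(x$p_chi, digits = 4), "\n")
  if (!is.null(x$p_sim))
    cat("  p_sim =", format(x$p_sim, digits = 4), "\n")
  invisible(x)
}

#' @export
summary.hka <- function(object, ...) {
  print(object)
  cat("\nPer-locus deviations:\n")
  print(object$expected, digits = 4)
  invisible(object)
}
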