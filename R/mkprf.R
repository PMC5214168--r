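# McDonald-Kreitman tables and hierarchical Bayesian Poisson random field
# estimation of per-locus selection coefficients gamma = 2*Ne*s.
#
# Model per locus i (tau = scaled divergence time, shared):
#   Ps_i ~ Pois(theta_s_i * a_{n_i})          silent polymorphism
#   Ds_i ~ Pois(theta_s_i * (tau + 1))        silent divergence
#   Pn_i ~ Pois(theta_r_i * a_{n_i} * G(gamma_i, n_i))
#   Dn_i ~ Pois(theta_r_i * (tau + 1) * H(gamma_i))
# with hierarchical prior gamma_i ~ Normal(mu_class, sigma^2), a flat prior
# on each class mean mu, and flat priors on the positive theta's. The
# sampler is a Gibbs/Metropolis hybrid: both thetas and the class means are
# conjugate (Gamma and Normal draws); gamma gets a random-walk Metropolis
# step with G evaluated through a cached interpolation grid.

#' Build a McDonald-Kreitman table from polarized variants
#'
#' Partitions variants into the 2x2 silent/replacement x polymorphic/fixed
#' layout. Silent = synonymous + noncoding. Variants with unresolved effect
#' (coding columns outside intact codons) are not counted.
#'
#' @param polarized A \code{polarized_variants} data frame from a
#'   single-species alignment.
#' @param n Chromosomes sampled.
#' @param locus_id Locus name.
#' @param class Locus class, \code{"candidate"} or \code{"reference"}.
#' @return One-row data frame: \code{locus}, \code{Ps}, \code{Pn},
#'   \code{Ds}, \code{Dn}, \code{n}, \code{class}.
#' @export
build_mk_table <- function(polarized, n, locus_id = "locus",
                           class = "candidate") {
  eff <- polarized$effect
  silent <- !is.na(eff) & eff %in% c("synonymous", "noncoding")
  repl <- !is.na(eff) & eff == "nonsynonymous"
  fixed <- polarized$status == "fixed_difference"
  data.frame(locus = locus_id,
             Ps = sum(silent & !fixed), Pn = sum(repl & !fixed),
             Ds = sum(silent & fixed), Dn = sum(repl & fixed),
             n = as.integer(n), class = class,
             stringsAsFactors = FALSE)
}

check_mk_tables <- function(tables) {
  tables <- as.data.frame(tables)
  need <- c("Ps", "Pn", "Ds", "Dn", "n")
  if (!all(need %in% names(tables)))
    stop("MK tables need columns ", paste(need, collapse = ", "))
  if (!"locus" %in% names(tables))
    tables$locus <- paste0("locus", seq_len(nrow(tables)))
  if (!"class" %in% names(tables)) tables$class <- "candidate"
  cnt <- as.matrix(tables[, need])
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("MK counts must be non-negative integers")
  if (any(tables$n < 2)) stop("all n must be >= 2")
  tables
}

#' Hierarchical Bayesian PRF estimation of selection coefficients
#'
#' Metropolis-within-Gibbs sampler over per-locus silent and replacement
#' mutation parameters, per-locus selection coefficients gamma, and one
#' class-level mean gamma per locus class (e.g. candidate vs reference).
#'
#' @param tables Data frame of MK tables: columns \code{locus}, \code{Ps},
#'   \code{Pn}, \code{Ds}, \code{Dn}, \code{n}, \code{class}.
#' @param cycles Total MCMC cycles.
#' @param burn_in Cycles discarded before sampling.
#' @param thin Keep every \code{thin}-th cycle after burn-in.
#' @param seed Optional RNG seed.
#' @param tau Scaled divergence time (fixed; default 15).
#' @param sigma2 Variance of the hierarchical Normal prior on gamma.
#' @param proposal_sd Random-walk proposal standard deviation for gamma.
#' @return Object of class \code{mkprf_fit}: per-locus posterior summary
#'   (\code{mean}, \code{q025}, \code{q975}, CI-excludes-zero flag),
#'   class-mean posterior samples, gamma traces (thinned), acceptance
#'   rates and chain settings.
#' @export
run_mkprf <- function(tables, cycles = 1e5, burn_in = 1e3, thin = 10L,
                      seed = NULL, tau = 15, sigma2 = 4,
                      proposal_sd = 0.5) {
  tables <- check_mk_tables(tables)
  if (cycles <= burn_in) stop("cycles must exceed burn_in")
  if (!is.null(seed)) set.seed(seed)
  nloci <- nrow(tables)
  an <- a_n(tables$n)
  cls <- factor(tables$class)
  cls_idx <- as.integer(cls)
  ncls <- nlevels(cls)
  m_cls <- tabulate(cls_idx, ncls)

  # cached G interpolators, one per distinct sample size
  g_funs <- lapply(unique(tables$n), prf_g_interpolator)
  names(g_funs) <- as.character(unique(tables$n))
  g_of <- function(gamma) {
    out <- numeric(nloci)
    for (nv in names(g_funs)) {
      sel <- tables$n == as.integer(nv)
      out[sel] <- g_funs[[nv]](gamma[sel])
    }
    out
  }

  # init at neutral values / moment estimates
  gamma <- rep(0, nloci)
  mu <- rep(0, ncls)
  theta_s <- (tables$Ps + tables$Ds + 0.5) / (an + tau + 1)
  theta_r <- (tables$Pn + tables$Dn + 0.5) / (an + tau + 1)
  G <- g_of(gamma)
  H <- prf_fixation_factor(gamma)

  # replacement-arm log-likelihood for the gamma MH step
  rep_loglik <- function(theta_r, G, H) {
    lPn <- theta_r * an * G
    lDn <- theta_r * (tau + 1) * H
    tables$Pn * log(lPn) - lPn + tables$Dn * log(lDn) - lDn
  }

  n_keep <- floor((cycles - burn_in) / thin)
  gamma_samp <- matrix(NA_real_, n_keep, nloci)
  mu_samp <- matrix(NA_real_, n_keep, ncls)
  kept <- 0L
  accepts <- numeric(nloci)

  for (it in seq_len(cycles)) {
    # Gibbs: theta_s and theta_r (flat prior -> Gamma posteriors)
    theta_s <- stats::rgamma(nloci, shape = tables$Ps + tables$Ds + 1,
                             rate = an + tau + 1)
    theta_r <- stats::rgamma(nloci, shape = tables$Pn + tables$Dn + 1,
                             rate = an * G + (tau + 1) * H)
    # MH: gamma (vectorised across loci)
    prop <- gamma + stats::rnorm(nloci, 0, proposal_sd)
    Gp <- g_of(prop)
    Hp <- prf_fixation_factor(prop)
    ll0 <- rep_loglik(theta_r, G, H)
    ll1 <- rep_loglik(theta_r, Gp, Hp)
    if (any(is.nan(ll0)) || any(is.nan(ll1)))
      stop("NaN likelihood in mkprf chain at cycle ", it,
           "; gamma = ", paste(format(gamma, digits = 3), collapse = ","))
    lpr <- (ll1 - (prop - mu[cls_idx])^2 / (2 * sigma2)) -
           (ll0 - (gamma - mu[cls_idx])^2 / (2 * sigma2))
    acc <- log(stats::runif(nloci)) < lpr
    gamma[acc] <- prop[acc]
    G[acc] <- Gp[acc]
    H[acc] <- Hp[acc]
    accepts <- accepts + acc
    # Gibbs: class means (flat prior -> Normal posterior)
    gbar <- vapply(seq_len(ncls), function(c)
      mean(gamma[cls_idx == c]), numeric(1))
    mu <- stats::rnorm(ncls, gbar, sqrt(sigma2 / m_cls))

    if (it > burn_in && (it - burn_in) %% thin == 0L && kept < n_keep) {
      kept <- kept + 1L
      gamma_samp[kept, ] <- gamma
      mu_samp[kept, ] <- mu
    }
  }
  acc_rate <- accepts / cycles
  if (any(acc_rate < 0.01) || any(acc_rate > 0.99))
    warning("mkprf acceptance rate outside (1%, 99%) at ",
            sum(acc_rate < 0.01 | acc_rate > 0.99),
            " locus/loci; consider retuning proposal_sd")

  summ <- data.frame(
    locus = tables$locus, class = tables$class, n = tables$n,
    gamma_mean = colMeans(gamma_samp),
    gamma_q025 = apply(gamma_samp, 2, stats::quantile, 0.025),
    gamma_q975 = apply(gamma_samp, 2, stats::quantile, 0.975),
    stringsAsFactors = FALSE)
  summ$excludes_zero <- summ$gamma_q025 > 0 | summ$gamma_q975 < 0
  colnames(mu_samp) <- levels(cls)
  colnames(gamma_samp) <- tables$locus
  structure(list(
    tables = tables, summary = summ, mu_samples = mu_samp,
    gamma_samples = gamma_samp, acceptance = acc_rate,
    settings = list(cycles = cycles, burn_in = burn_in, thin = thin,
                    seed = seed, tau = tau, sigma2 = sigma2,
                    proposal_sd = proposal_sd)),
    class = "mkprf_fit")
}

#' @export
print.mkprf_fit <- function(x, ...) {
  cat("mkprf fit: ", nrow(x$summary), " loci, ",
      x$settings$cycles, " cycles (burn-in ", x$settings$burn_in,
      ", thin ", x$settings$thin, ")\n", sep = "")
  cat("mean acceptance:", format(mean(x$acceptance), digits = 3), "\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' @export
coef.mkprf_fit <- function(object, ...) {
  stats::setNames(object$summary$gamma_mean, object$summary$locus)
}

#' @export
summary.mkprf_fit <- function(object, ...) {
  cls_mean <- colMeans(object$mu_samples)
  cls_ci <- apply(object$mu_samples, 2, stats::quantile, c(0.025, 0.975))
  list(per_locus = object$summary,
       class_means = data.frame(class = colnames(object$mu_samples),
                                mean = cls_mean,
                                q025 = cls_ci[1, ], q975 = cls_ci[2, ]))
}

#' @export
plot.mkprf_fit <- function(x, ...) {
  s <- x$summary
  op <- graphics::par(mfrow = c(1, 2), mar = c(8, 4, 2, 1))
  on.exit(graphics::par(op))
  cols <- ifelse(s$class == s$class[which.max(s$class == "candidate")] &
                   s$class == "candidate", "firebrick", "grey40")
  graphics::plot(seq_len(nrow(s)), s$gamma_mean, ylim =
                   range(c(s$gamma_q025, s$gamma_q975)), pch = 19,
                 col = cols, xaxt = "n", xlab = "",
                 ylab = expression(gamma == 2 * N[e] * s), ...)
  graphics::segments(seq_len(nrow(s)), s$gamma_q025,
                     seq_len(nrow(s)), s$gamma_q975, col = cols)
  graphics::abline(h = 0, lty = 2)
  graphics::axis(1, at = seq_len(nrow(s)), labels = s$locus, las = 2,
                 cex.axis = 0.6)
  dens <- apply(x$mu_samples, 2, stats::density, simplify = FALSE)
  xl <- range(vapply(dens, function(d) range(d$x), numeric(2)))
  yl <- c(0, max(vapply(dens, function(d) max(d$y), numeric(1))))
  graphics::plot(NA, xlim = xl, ylim = yl, xlab = "class mean gamma",
                 ylab = "posterior density")
  for (i in seq_along(dens))
    graphics::lines(dens[[i]], lty = i)
  graphics::legend("topright", legend = names(dens), lty = seq_along(dens),
                   bty = "n")
  invisible(x)
}

#' Simulate MK tables from the PRF model
#'
#' Forward draws of the four Poisson counts at given parameters; the
#' natural synthetic unit for validating \code{\link{run_mkprf}}.
#'
#' @param theta_s,theta_r Per-locus silent/replacement mutation parameters.
#' @param gamma Per-locus selection coefficients.
#' @param n Per-locus sample sizes.
#' @param tau Scaled divergence time.
#' @param class Per-locus class labels.
#' @param seed Optional RNG seed.
#' @return MK table data frame.
#' @export
simulate_mk_tables <- function(theta_s, theta_r, gamma, n, tau = 15,
                               class = "candidate", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nloci <- length(gamma)
  an <- a_n(n)
  G <- vapply(seq_len(nloci), function(i)
    prf_polymorphism_factor(gamma[i], n[i]), numeric(1))
  H <- prf_fixation_factor(gamma)
  check_mk_tables(data.frame(
    locus = paste0("locus", seq_len(nloci)),
    Ps = stats::rpois(nloci, theta_s * an),
    Pn = stats::rpois(nloci, theta_r * an * G),
    Ds = stats::rpois(nloci, theta_s * (tau + 1)),
    Dn = stats::rpois(nloci, theta_r * (tau + 1) * H),
    n = n, class = rep_len(class, nloci), stringsAsFactors = FALSE))
}
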