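#' Chi-square goodness of fit to a Poisson degree law
#'
#' Karl–Pearson test of a degree sample against Poisson(lambda) with
#' lambda estimated by maximum likelihood (the sample mean). Expected
#' counts are binned per degree with an open-ended top bin, then pooled
#' from the bottom (k = 0 upwards) and from the top downwards until every
#' pooled tail bin has expected count at least 5 (Cochran's rule). One
#' degree of freedom is subtracted for the estimated lambda.
#'
#' @param degrees Non-negative integer degree sample.
#' @return An object of class `"poisson_fit"`: `lambda_mle`, `chi2`,
#'   `dof`, `p_value`, and `table` (the pooled observed/expected counts;
#'   `bin_lo`/`bin_hi` give each bin's degree range, `Inf` for the open
#'   top bin).
#' @examples
#' poisson_gof(rpois(200, 9.3))
#' @export
poisson_gof <- function(degrees) {
  if (any(degrees < 0) || any(degrees != floor(degrees)))
    stop_bad_arg("`degrees` must be non-negative integers")
  n <- length(degrees)
  if (n < 30) warning("fewer than 30 observations: chi-square approximation is weak")
  lambda <- mean(degrees)
  kmax <- max(degrees)
  obs <- tabulate(degrees + 1L, nbins = kmax + 1L)   # counts for 0..kmax-1
  # final bin is open-ended: k >= kmax
  obs <- c(obs[seq_len(kmax)], sum(degrees >= kmax))
  expd <- c(dpois(0:(kmax - 1L), lambda), 1 - ppois(kmax - 1L, lambda)) * n
  lo <- 0:kmax
  hi <- c(0:(kmax - 1L), Inf)
  # pool from the bottom up
  while (length(expd) > 1L && expd[1] < 5) {
    expd[2] <- expd[2] + expd[1]; obs[2] <- obs[2] + obs[1]
    lo <- lo[-1]; hi <- hi[-1]; expd <- expd[-1]; obs <- obs[-1]
    lo[1] <- 0
  }
  # and from the top down
  while (length(expd) > 1L && expd[length(expd)] < 5) {
    nb <- length(expd)
    expd[nb - 1L] <- expd[nb - 1L] + expd[nb]
    obs[nb - 1L] <- obs[nb - 1L] + obs[nb]
    lo <- lo[-nb]; hi <- hi[-nb]; expd <- expd[-nb]; obs <- obs[-nb]
    hi[length(hi)] <- Inf
  }
  if (length(expd) < 3L)
    stop_bad_arg("fewer than 3 bins remain after pooling")
  chi2 <- sum((obs - expd) ^ 2 / expd)
  dof <- length(expd) - 2L
  structure(list(lambda_mle = lambda, chi2 = chi2, dof = dof,
                 p_value = pchisq(chi2, dof, lower.tail = FALSE),
                 table = data.frame(bin_lo = lo, bin_hi = hi,
                                    observed = obs, expected = expd)),
            class = "poisson_fit")
}

#' @export
print.poisson_fit <- function(x, ...) {
  cat(sprintf(
    "Poisson goodness of fit: lambda = %.4g, chi2 = %.4g (dof %d), p = %.4g\n",
    x$lambda_mle, x$chi2, x$dof, x$p_value))
  invisible(x)
}

#' Discrete power-law tail fit with bootstrap KS p-value
#'
#' Clauset-style fit of the tail of a degree sample to the discrete
#' power law \eqn{p(k) \propto k^{-\alpha}}, `k >= k_min`. For every
#' candidate `k_min` (each observed degree value with at least
#' `min_tail` observations at or above it) the exponent is estimated by
#' maximum likelihood and the Kolmogorov–Smirnov distance between the
#' empirical tail CDF and the fitted law computed; the `k_min`
#' minimizing the distance is selected. The p-value comes from a
#' semiparametric bootstrap: synthetic samples draw below-`k_min` values
#' from the empirical body and tail values from the fitted law, are
#' refitted from scratch, and the p-value is the fraction whose KS
#' distance is at least the observed one (values `>= 0.1` are
#' conventionally taken as consistency with a power-law tail).
#' Zero degrees are excluded before fitting.
#'
#' @param degrees Non-negative integer degree sample.
#' @param n_bootstrap Bootstrap replicates for the p-value (default
#'   2500; 0 skips the bootstrap and returns `p_value = NA`).
#' @param min_tail Minimum tail size for a candidate `k_min`.
#' @param seed Optional integer seed.
#' @return An object of class `"powerlaw_fit"`: `alpha`, `k_min`,
#'   `ks_D`, `p_value`, `n_tail`.
#' @examples
#' fit_power_law(rpowerlaw(500, 2.5, seed = 1), n_bootstrap = 50, seed = 2)
#' @export
fit_power_law <- function(degrees, n_bootstrap = 2500, min_tail = 10,
                          seed = NULL) {
  if (any(degrees < 0) || any(degrees != floor(degrees)))
    stop_bad_arg("`degrees` must be non-negative integers")
  x <- degrees[degrees >= 1]
  fit <- powerlaw_scan(x, min_tail)
  if (is.null(fit)) stop_bad_arg("no admissible k_min: tail too small")
  p_value <- NA_real_
  if (n_bootstrap > 0) {
    n <- length(x)
    body <- x[x < fit$k_min]
    p_tail <- 1 - length(body) / n
    p_value <- with_seed(seed, {
      hits <- 0L
      for (b in seq_len(n_bootstrap)) {
        from_tail <- runif(n) < p_tail
        xb <- integer(n)
        xb[from_tail] <- rpowerlaw(sum(from_tail), fit$alpha, fit$k_min)
        if (any(!from_tail))
          xb[!from_tail] <- sample(body, sum(!from_tail), replace = TRUE)
        fb <- powerlaw_scan(xb, min_tail)
        if (!is.null(fb) && fb$ks_D >= fit$ks_D) hits <- hits + 1L
      }
      hits / n_bootstrap
    })
  }
  structure(c(fit, list(p_value = p_value, n_bootstrap = n_bootstrap)),
            class = "powerlaw_fit")
}

# k_min scan: returns alpha, k_min, ks_D, n_tail for the KS-optimal
# candidate, or NULL when no candidate has a large enough tail.
powerlaw_scan <- function(x, min_tail) {
  cands <- sort(unique(x))
  cands <- cands[vapply(cands, function(km) sum(x >= km), numeric(1)) >=
                 min_tail]
  if (!length(cands)) return(NULL)
  best <- NULL
  for (km in cands) {
    tail_v <- x[x >= km]
    alpha <- powerlaw_alpha_mle(tail_v, km)
    D <- powerlaw_ks_distance(tail_v, alpha, km)
    if (is.null(best) || D < best$ks_D)
      best <- list(alpha = alpha, k_min = km, ks_D = D,
                   n_tail = length(tail_v))
  }
  best
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "Power-law tail fit: alpha = %.4g, k_min = %d, D = %.4g (n_tail %d)\n",
    x$alpha, x$k_min, x$ks_D, x$n_tail))
  if (!is.na(x$p_value))
    cat(sprintf("  bootstrap KS p-value = %.4g (%d replicates)\n",
                x$p_value, x$n_bootstrap))
  invisible(x)
}

#' Log-log power regression of a degree distribution
#'
#' Ordinary least squares of `log p(k)` on `log k` over the support
#' `k >= 1` (degree 0 excluded), for the model `p(k) = C k^(-gamma)`.
#' A high adjusted R-squared suggests, but does not establish, a power
#' law.
#'
#' @param dist A [degree_dist()] object, or any list with numeric `k`
#'   and `p`.
#' @return An object of class `"potential_regression"`: `gamma`, `C`,
#'   `r2_adjusted`, `n_points`.
#' @examples
#' d <- list(k = c(1, 2, 4, 8), p = 0.5 * c(1, 2, 4, 8)^-2)
#' potential_regression(d)
#' @export
potential_regression <- function(dist) {
  keep <- dist$k >= 1 & dist$p > 0
  k <- dist$k[keep]; p <- dist$p[keep]
  if (length(k) < 3L)
    stop_bad_arg("need at least 3 support points with k >= 1 and p > 0")
  fit <- lm(log(p) ~ log(k))
  s <- summary(fit)
  structure(list(gamma = -unname(coef(fit)[2]),
                 C = exp(unname(coef(fit)[1])),
                 r2_adjusted = s$adj.r.squared,
                 n_points = length(k)),
            class = "potential_regression")
}

#' @export
print.potential_regression <- function(x, ...) {
  cat(sprintf(
    "Power regression p(k) = C k^-gamma: gamma = %.4g, C = %.4g, adj R2 = %.4g\n",
    x$gamma, x$C, x$r2_adjusted))
  invisible(x)
}

#' Discrete power law with exponential cutoff
#'
#' Probability mass of \eqn{p(k) \propto k^{-\alpha} e^{-k/\kappa}}
#' normalized over integers `k >= k_min` — the degree family that
#' combines a power-law body (preferential attachment) with an
#' exponential tail cutoff (random attachment), and the one that best
#' describes observed enmity degrees.
#'
#' @param k Integer degrees, `>= 1`.
#' @param alpha Power-law exponent, `> 0`.
#' @param kappa Cutoff scale, `> 0`.
#' @param k_min Lower support bound, default 1.
#' @return Numeric vector of probabilities.
#' @examples
#' sum(powerlaw_cutoff_pdf(1:500, 2, 10))  # 1
#' @export
powerlaw_cutoff_pdf <- function(k, alpha, kappa, k_min = 1L) {
  if (!is.numeric(alpha) || alpha <= 0) stop_bad_arg("`alpha` must be > 0")
  if (!is.numeric(kappa) || kappa <= 0) stop_bad_arg("`kappa` must be > 0")
  k_min <- check_count(k_min, "k_min", min = 1L)
  # normalization: chunked summation until the added mass is negligible
  z <- 0
  lo <- as.numeric(k_min)
  chunk <- 1e5
  repeat {
    ks <- lo:min(lo + chunk - 1, lo + 2e7)
    add <- sum(ks ^ (-alpha) * exp(-ks / kappa))
    z <- z + add
    lo <- lo + length(ks)
    if (add < z * 1e-12 || lo > k_min + 2e7) break
  }
  out <- k ^ (-alpha) * exp(-k / kappa) / z
  out[k < k_min | k != floor(k)] <- 0
  out
}

#' Two-sample Kolmogorov–Smirnov comparison of degree samples
#'
#' The maximum absolute difference `D` between the two empirical CDFs,
#' with the asymptotic two-sample p-value. Used to compare generated
#' degree sequences against an observed or reference sample (degree 0
#' included).
#'
#' @param sample_a,sample_b Non-empty numeric samples.
#' @return A list with `D` and `p_value`.
#' @examples
#' ks_two_sample(rpois(100, 9), rpois(100, 9))
#' @export
ks_two_sample <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b))
    stop_bad_arg("both samples must be non-empty")
  kt <- suppressWarnings(ks.test(sample_a, sample_b))
  list(D = unname(kt$statistic), p_value = kt$p.value)
}
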