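# Kinetic and statistical estimators: Bell-Evans force dependence,
# truncation-corrected exponential dwell fits, Hill binding isotherms,
# Gaussian mixtures of loop sizes, and partial Pearson correlations.

#' Bell-Evans dissociation rate at a given force
#'
#' k(F) = k0 exp(F x_dagger / kBT): the single-barrier (Kramers/Bell-Evans)
#' force dependence of a rupture rate, with activation distance x_dagger
#' and extrapolated zero-force rate k0.
#'
#' @param force force, pN.
#' @param k0 zero-force rate, s^-1.
#' @param x_dagger activation distance, nm.
#' @param kbt thermal energy, pN.nm.
#' @return rate in s^-1.
#' @export
bell_evans_rate <- function(force, k0, x_dagger, kbt = kbt_default) {
  k0 * exp(force * x_dagger / kbt)
}

#' Fit the Bell-Evans model to per-force mean dwell times
#'
#' Linear least squares of ln k = ln(1 / <tau>) against force: the slope is
#' x_dagger / kBT and the intercept ln k0. Unweighted by default; per-force
#' standard errors of ln k can be supplied for a weighted fit.
#'
#' @param force distinct test forces, pN (>= 3).
#' @param mean_dwell mean dwell time per force, s (> 0).
#' @param se_log_k optional SEs of ln k (weights 1/se^2).
#' @param kbt thermal energy, pN.nm.
#' @return object of class `bell_evans_fit` with `k0` (s^-1), `x_dagger`
#'   (nm), their SEs, the extrapolated zero-force dwell `tau0 = 1/k0`, and
#'   the per-force table.
#' @export
fit_bell_evans <- function(force, mean_dwell, se_log_k = NULL,
                           kbt = kbt_default) {
  stopifnot(length(force) == length(mean_dwell))
  if (length(unique(force)) < 3)
    stop("need mean dwells at 3 or more distinct forces")
  if (any(mean_dwell <= 0)) stop("mean dwells must be positive")
  logk <- log(1 / mean_dwell)
  w <- if (is.null(se_log_k)) NULL else 1 / se_log_k^2
  fit <- stats::lm(logk ~ force, weights = w)
  cf <- stats::coef(fit)
  ses <- suppressWarnings(summary(fit)$coefficients[, "Std. Error"])
  k0 <- exp(cf[[1]])
  structure(list(k0 = k0, x_dagger = cf[[2]] * kbt, tau0 = 1 / k0,
                 se = c(k0 = k0 * ses[[1]], x_dagger = ses[[2]] * kbt),
                 kbt = kbt,
                 data = data.frame(force = force, mean_dwell = mean_dwell,
                                   log_k = logk),
                 fit = fit),
            class = "bell_evans_fit")
}

#' @export
print.bell_evans_fit <- function(x, ...) {
  cat(sprintf("Bell-Evans fit: k0 = %.3g s^-1 (tau0 = %.1f s), x_dagger = %.2f nm\n",
              x$k0, x$tau0, x$x_dagger))
  invisible(x)
}

#' Single-exponential fit of a dwell-time sample
#'
#' Maximum-likelihood estimate of the exponential time constant from dwells
#' truncated at the Nyquist floor: for dwells observed only above
#' `min_dwell`, memorylessness gives the unbiased estimate
#' tau = mean(dwell - min_dwell), with SE tau / sqrt(n). A binned-histogram
#' single-exponential fit (A exp(-t / tau)) is also performed and its
#' R-squared reported for comparability with histogram-based analyses.
#'
#' @param dwells dwell times, s, already filtered at `min_dwell`.
#' @param min_dwell truncation floor, s.
#' @param n_bins histogram bins for the comparability fit.
#' @return object of class `exp_fit` with `tau`, `se`, `n`, `tau_hist`,
#'   `r_squared`, and a `degenerate` flag for zero-variance samples.
#' @export
fit_exponential <- function(dwells, min_dwell = 0.02, n_bins = 30) {
  n <- length(dwells)
  if (n < 20) stop("need at least 20 dwells")
  if (any(dwells < min_dwell))
    stop("dwells below the truncation floor; filter at min_dwell first")
  degenerate <- stats::sd(dwells) < 1e-12
  if (degenerate)
    warning("zero-variance dwell sample; exponential fit is degenerate")
  tau <- mean(dwells - min_dwell)
  se <- tau / sqrt(n)
  tau_hist <- NA_real_
  r2 <- NA_real_
  if (!degenerate) {
    h <- graphics::hist(dwells, breaks = n_bins, plot = FALSE)
    keep <- h$counts > 0
    hd <- data.frame(t = h$mids[keep], count = h$counts[keep])
    hfit <- tryCatch(
      minpack.lm::nlsLM(count ~ A * exp(-t / tau_h), data = hd,
                        start = list(A = max(hd$count), tau_h = max(tau, 1e-3)),
                        lower = c(0, 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(hfit)) {
      tau_hist <- stats::coef(hfit)[["tau_h"]]
      resid <- hd$count - stats::predict(hfit)
      r2 <- 1 - sum(resid^2) / sum((hd$count - mean(hd$count))^2)
    }
  }
  structure(list(tau = tau, se = se, n = n, min_dwell = min_dwell,
                 tau_hist = tau_hist, r_squared = r2,
                 degenerate = degenerate),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("exponential dwell fit: tau = %.3f +/- %.3f s (n = %d, hist R^2 = %.3f)\n",
              x$tau, x$se, x$n, x$r_squared))
  invisible(x)
}

#' Fit the Hill binding isotherm
#'
#' Nonlinear least squares of f = C^n / (Kd^n + C^n) to a bound-fraction
#' versus concentration table. The Hill coefficient floats by default and
#' can be fixed (e.g. n = 1 for non-cooperative binding).
#'
#' @param conc ligand concentrations (>= 4), nM.
#' @param fraction bound fractions in [0, 1].
#' @param fix_n `NULL` to float the Hill coefficient, or a fixed value.
#' @return object of class `hill_fit` with `kd` (nM), `hill_n`, SEs.
#' @export
fit_hill <- function(conc, fraction, fix_n = NULL) {
  stopifnot(length(conc) == length(fraction))
  if (length(conc) < 4) stop("need at least 4 concentrations")
  if (any(fraction < 0 | fraction > 1)) stop("fractions must lie in [0, 1]")
  if (all(fraction == 0) || all(fraction == 1))
    stop("non-identifiable: all fractions saturated")
  pos <- conc > 0 & fraction > 0 & fraction < 1
  kd0 <- if (any(pos)) stats::approx(fraction[pos], conc[pos], xout = 0.5,
                                     ties = mean)$y else stats::median(conc)
  if (is.na(kd0)) kd0 <- stats::median(conc[conc > 0])
  dat <- data.frame(conc = conc, f = fraction)
  if (is.null(fix_n)) {
    fit <- minpack.lm::nlsLM(f ~ conc^n / (kd^n + conc^n), data = dat,
                             start = list(kd = kd0, n = 1),
                             lower = c(1e-6, 0.1), upper = c(Inf, 10),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    n_fixed <- fix_n
    fit <- minpack.lm::nlsLM(f ~ conc^n_fixed / (kd^n_fixed + conc^n_fixed),
                             data = dat, start = list(kd = kd0),
                             lower = 1e-6,
                             control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  cf <- stats::coef(fit)
  ses <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                  error = function(e) rep(NA_real_, length(cf)))
  structure(list(kd = cf[["kd"]],
                 hill_n = if (is.null(fix_n)) cf[["n"]] else fix_n,
                 se = c(kd = unname(ses[1]),
                        n = if (is.null(fix_n)) unname(ses[2]) else NA_real_),
                 fixed_n = !is.null(fix_n), data = dat, fit = fit),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: Kd = %.2f nM, n = %.2f%s\n", x$kd, x$hill_n,
              if (x$fixed_n) " (fixed)" else ""))
  invisible(x)
}

#' Gaussian-mixture fit of a loop-size sample
#'
#' One-dimensional Gaussian mixture fitted by expectation-maximization
#' (model-based clustering with unequal variances); when the number of
#' components is not given it is chosen by BIC over 1-4 components.
#' Requires at least 50 observations per expected component.
#'
#' @param x sample (e.g. loop sizes delta L, bp).
#' @param n_components number of components, or `NULL` for BIC selection.
#' @param max_components upper bound for BIC selection.
#' @return object of class `gmm_fit` with `$components` (weight, mean, sd,
#'   ordered by mean), `$n_components`, `$bic`, `$loglik`.
#' @export
fit_gaussian_mixture <- function(x, n_components = NULL, max_components = 4) {
  n <- length(x)
  g_max <- if (is.null(n_components)) max_components else n_components
  if (n < 50 * min(g_max, if (is.null(n_components)) 1 else n_components))
    stop("need at least 50 observations per expected component")
  G <- if (is.null(n_components)) seq_len(min(max_components, floor(n / 50)))
       else n_components
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller frame
  fit <- mclust::Mclust(x, G = G, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed")
  p <- fit$parameters
  comp <- data.frame(weight = p$pro, mean = as.numeric(p$mean),
                     sd = sqrt(p$variance$sigmasq))
  if (nrow(comp) > 1 && length(p$variance$sigmasq) == 1)
    comp$sd <- rep(sqrt(p$variance$sigmasq), nrow(comp))
  comp <- comp[order(comp$mean), ]
  rownames(comp) <- NULL
  structure(list(components = comp, n_components = fit$G, bic = fit$bic,
                 loglik = fit$loglik, n = n),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture: %d component(s), BIC %.1f\n",
              x$n_components, x$bic))
  for (i in seq_len(nrow(x$components)))
    cat(sprintf("  %.2f x N(%.0f, %.0f)\n", x$components$weight[i],
                x$components$mean[i], x$components$sd[i]))
  invisible(x)
}

#' Pearson correlation with zero to two controlled variables
#'
#' Zero-order Pearson correlation, or first/second-order partial
#' correlation computed by the standard recursion
#' r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)).
#' The p-value is two-sided from the t statistic with n - 2 - order
#' degrees of freedom.
#'
#' @param x,y numeric vectors.
#' @param controls `NULL`, a vector, or a data frame / matrix with at most
#'   two columns of controlling variables.
#' @return object of class `correlation_result` with `r`, `order`, `p`,
#'   `n`, `controls`.
#' @export
partial_correlation <- function(x, y, controls = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  z <- if (is.null(controls)) NULL else as.data.frame(controls)
  k <- if (is.null(z)) 0L else ncol(z)
  if (k > 2) stop("at most two controlling variables are supported")
  if (n < k + 3) stop("too few observations for the requested order")
  pc2 <- function(rxy, rxz, ryz) {
    den <- sqrt((1 - rxz^2) * (1 - ryz^2))
    if (den < 1e-12) stop("perfectly collinear controlling variable")
    (rxy - rxz * ryz) / den
  }
  if (k == 0) {
    r <- stats::cor(x, y)
  } else if (k == 1) {
    r <- pc2(stats::cor(x, y), stats::cor(x, z[[1]]), stats::cor(y, z[[1]]))
  } else {
    # recursion: partial out z1, then z2 among the first-order coefficients
    r_xy_1 <- pc2(stats::cor(x, y), stats::cor(x, z[[1]]), stats::cor(y, z[[1]]))
    r_x2_1 <- pc2(stats::cor(x, z[[2]]), stats::cor(x, z[[1]]),
                  stats::cor(z[[2]], z[[1]]))
    r_y2_1 <- pc2(stats::cor(y, z[[2]]), stats::cor(y, z[[1]]),
                  stats::cor(z[[2]], z[[1]]))
    r <- pc2(r_xy_1, r_x2_1, r_y2_1)
  }
  df <- n - 2L - k
  r_cl <- min(max(r, -1), 1)
  p <- if (abs(r_cl) >= 1) 0 else {
    tstat <- r_cl * sqrt(df / (1 - r_cl^2))
    2 * stats::pt(-abs(tstat), df)
  }
  structure(list(r = r, order = k, p = p, n = n,
                 controls = if (is.null(z)) character(0) else names(z)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  lab <- c("zero", "first", "second")[x$order + 1]
  cat(sprintf("%s-order correlation: r = %.3f (p = %.3g, n = %d)\n",
              lab, x$r, x$p, x$n))
  invisible(x)
}
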