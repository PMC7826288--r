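# Two-state Gaussian hidden Markov analysis of constant-force hopping
# traces, and the Boltzmann open-probability energetics built on top of it.

hmm_em_once <- function(x, mu, sigma, A, init, max_iter, tol) {
  ll_trace <- numeric(0)
  prev <- -Inf
  for (it in seq_len(max_iter)) {
    fb <- hmm_forward_backward(x, mu, sigma, A, init)
    ll_trace <- c(ll_trace, fb$loglik)
    g <- fb$gamma
    w <- colSums(g)
    mu <- c(sum(g[, 1] * x), sum(g[, 2] * x)) / w
    sigma <- sqrt(sum(g[, 1] * (x - mu[1])^2 + g[, 2] * (x - mu[2])^2) / length(x))
    sigma <- max(sigma, 1e-8)
    xi <- fb$xi
    A <- xi / rowSums(xi)
    A[A < 1e-12] <- 1e-12
    A <- A / rowSums(A)
    init <- pmax(g[1, ], 1e-12)
    init <- init / sum(init)
    if (it > 1 && fb$loglik - prev < tol) break
    prev <- fb$loglik
  }
  list(mu = mu, sigma = sigma, A = A, init = init,
       loglik = ll_trace[length(ll_trace)], ll_trace = ll_trace)
}

#' Fit a two-state Gaussian HMM to a constant-force hopping trace
#'
#' Expectation-maximization training of a two-state hidden Markov model
#' with Gaussian emissions (state-specific means, common SD), initialised
#' by 2-means clustering of the extension values with random restarts (the
#' best likelihood is kept). States are decoded by the most-probable path
#' (Viterbi); the higher-extension state is labelled `forward` (the more
#' open fork) and the lower one `backward`. Dwells are the decoded run
#' lengths divided by the sampling rate; boundary-truncated runs are
#' excluded and only dwells above the Nyquist floor (20 ms) are retained.
#'
#' @param x an `mt_trace` at constant force or a numeric vector (then
#'   `rate` must be given).
#' @param rate sampling rate, Hz.
#' @param max_iter maximal EM iterations.
#' @param tol EM convergence tolerance on the log-likelihood.
#' @param n_restarts number of random EM restarts.
#' @param min_dwell dwell retention floor, s.
#' @param seed optional seed for the restart initialisations.
#' @param force_tol maximal force excursion allowed in the segment.
#' @return object of class `hmm_fit`: decoded `$path` (factor
#'   backward/forward), emission `$means` and `$sigma`, transition matrix
#'   `$A` and `$rates` (s^-1), dwell lists `$dwell_forward` /
#'   `$dwell_backward`, `$loglik`, `$ll_trace` and `$force`.
#' @export
fit_two_state_hmm <- function(x, rate = NULL, max_iter = 500, tol = 1e-6,
                              n_restarts = 5, min_dwell = 0.02, seed = NULL,
                              force_tol = 0.5) {
  force <- NA_real_
  if (inherits(x, "mt_trace")) {
    if (max(x$force) - min(x$force) > force_tol)
      stop("segment is not at constant force")
    force <- stats::median(x$force)
    rate <- sampling_rate(x)
    x <- x$extension
  }
  if (is.null(rate)) stop("sampling rate required")
  x <- as.numeric(x)
  n <- length(x)
  if (n < 500) stop("need at least 500 samples")
  if (diff(range(x)) <= 0 || stats::sd(x) < 1e-12)
    stop("fewer than two states resolvable (constant signal)")
  if (!is.null(seed)) set.seed(seed)

  km <- stats::kmeans(x, centers = 2, nstart = 5)
  if (abs(diff(km$centers)) < 1e-9 * stats::sd(x))
    stop("fewer than two states resolvable")
  base_mu <- sort(as.numeric(km$centers))
  base_sigma <- max(stats::sd(x - km$centers[km$cluster]), 1e-8)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    mu <- if (r == 1) base_mu else sort(base_mu + stats::rnorm(2, 0, base_sigma))
    A0 <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2)
    fit <- hmm_em_once(x, mu, base_sigma, A0, c(0.5, 0.5), max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  # order states so state 2 is the forward (higher-extension) state
  if (best$mu[1] > best$mu[2]) {
    best$mu <- rev(best$mu)
    best$A <- best$A[2:1, 2:1]
    best$init <- rev(best$init)
  }
  if (abs(diff(best$mu)) < 1e-6 * max(best$sigma, 1e-12))
    stop("fewer than two states resolvable")
  path_i <- hmm_viterbi(x, best$mu, best$sigma, best$A, best$init)
  path <- factor(c("backward", "forward")[path_i],
                 levels = c("backward", "forward"))
  r <- rle(path_i)
  dw <- r$lengths / rate
  st <- r$values
  if (length(dw) > 2) {
    interior <- 2:(length(dw) - 1)
    dw_i <- dw[interior]; st_i <- st[interior]
  } else { dw_i <- numeric(0); st_i <- integer(0) }
  keep <- dw_i > min_dwell
  rates <- best$A[cbind(1:2, 2:1)] * rate  # per-second leaving rates
  structure(list(path = path, means = best$mu, sigma = best$sigma,
                 A = best$A,
                 rates = c(backward_to_forward = rates[1],
                           forward_to_backward = rates[2]),
                 dwell_forward = dw_i[keep & st_i == 2],
                 dwell_backward = dw_i[keep & st_i == 1],
                 n_transitions = length(r$lengths) - 1L,
                 loglik = best$loglik, ll_trace = best$ll_trace,
                 sampling_rate = rate, force = force, n = n),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("two-state HMM: levels %.2f / %.2f nm (sigma %.2f), %d transitions, logL %.1f\n",
              x$means[1], x$means[2], x$sigma, x$n_transitions, x$loglik))
  invisible(x)
}

#' Open probability of a decoded hopping trace
#'
#' Fraction of time spent in the forward (open) state, with a
#' binomial-style standard error based on the number of decoded dwells.
#'
#' @param hmm an [fit_two_state_hmm()] result.
#' @return list with `p_open`, `se`, `force`, `n_dwells`.
#' @export
open_probability <- function(hmm) {
  stopifnot(inherits(hmm, "hmm_fit"))
  p <- mean(hmm$path == "forward")
  n_dwell <- max(hmm$n_transitions, 1L)
  list(p_open = p, se = sqrt(p * (1 - p) / n_dwell), force = hmm$force,
       n_dwells = n_dwell)
}

#' Fit the Boltzmann open-probability relation
#'
#' Weighted nonlinear least squares of the two-state Boltzmann relation
#' P_o(F) = 1 / (1 + exp((F_half - F) dx / kBT)) to an open-probability
#' versus force table. The opening free energy is reported as
#' dG = F_half dx / kBT (in kBT units). Note the exponent carries the
#' 1/kBT factor required for dimensional consistency.
#'
#' @param force forces, pN (at least 4, spanning both sides of F_half).
#' @param p_open open probabilities in [0, 1].
#' @param se optional standard errors (weights 1/se^2).
#' @param kbt thermal energy, pN.nm.
#' @return object of class `boltzmann_fit` with `f_half` (pN), `delta_x`
#'   (nm), `delta_g_kbt`, standard errors and the fitted table.
#' @export
fit_boltzmann <- function(force, p_open, se = NULL, kbt = kbt_default) {
  stopifnot(length(force) == length(p_open))
  if (length(force) < 4) stop("need at least 4 forces")
  if (all(p_open >= 0.5) || all(p_open <= 0.5))
    stop("non-identifiable: open probabilities all on one side of 1/2")
  w <- if (is.null(se)) rep(1, length(force)) else 1 / pmax(se, 1e-3)^2
  dat <- data.frame(force = force, p = p_open)
  f_half0 <- stats::approx(p_open, force, xout = 0.5, ties = mean)$y
  if (is.na(f_half0)) f_half0 <- mean(force)
  fit <- minpack.lm::nlsLM(
    p ~ 1 / (1 + exp((f_half - force) * delta_x / kbt)),
    data = dat, weights = w,
    start = list(f_half = f_half0, delta_x = 10),
    lower = c(min(force) - 5, 0.01), upper = c(max(force) + 5, 200),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  ses <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                  error = function(e) c(NA_real_, NA_real_))
  dg <- cf[["f_half"]] * cf[["delta_x"]] / kbt
  structure(list(f_half = cf[["f_half"]], delta_x = cf[["delta_x"]],
                 delta_g_kbt = dg,
                 se = c(f_half = unname(ses[1]), delta_x = unname(ses[2])),
                 kbt = kbt, data = dat, fit = fit),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann fit: F_1/2 = %.2f pN, dx = %.2f nm, dG = %.1f kBT\n",
              x$f_half, x$delta_x, x$delta_g_kbt))
  invisible(x)
}

#' @export
predict.boltzmann_fit <- function(object, force, ...) {
  1 / (1 + exp((object$f_half - force) * object$delta_x / object$kbt))
}

#' Mean dwell per state as a function of force
#'
#' Summarises a set of HMM fits at different forces into per-state mean
#' dwell curves with standard errors.
#'
#' @param fits list of [fit_two_state_hmm()] results (>= 3 forces).
#' @return data frame with `force`, `state`, `mean_dwell`, `se`, `n`.
#' @export
dwell_vs_force <- function(fits) {
  if (length(fits) < 3) stop("need HMM fits at 3 or more forces")
  rows <- lapply(fits, function(f) {
    do.call(rbind, lapply(c("forward", "backward"), function(s) {
      d <- f[[paste0("dwell_", s)]]
      data.frame(force = f$force, state = s,
                 mean_dwell = if (length(d)) mean(d) else NA_real_,
                 se = if (length(d) > 1) stats::sd(d) / sqrt(length(d)) else NA_real_,
                 n = length(d))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$state, out$force), ]
}

#' Dwell-time differences between two conditions at matched forces
#'
#' Joins two [dwell_vs_force()] tables on (force, state) and reports the
#' dwell difference (condition b minus condition a) with propagated SE.
#'
#' @param a,b dwell tables from [dwell_vs_force()].
#' @param force_tol match tolerance on force, pN.
#' @return data frame with `force`, `state`, `dwell_a`, `dwell_b`,
#'   `difference`, `se`.
#' @export
dwell_difference <- function(a, b, force_tol = 0.05) {
  out <- NULL
  for (i in seq_len(nrow(a))) {
    j <- which(b$state == a$state[i] & abs(b$force - a$force[i]) <= force_tol)
    if (!length(j)) next
    j <- j[1]
    out <- rbind(out, data.frame(
      force = a$force[i], state = a$state[i],
      dwell_a = a$mean_dwell[i], dwell_b = b$mean_dwell[j],
      difference = b$mean_dwell[j] - a$mean_dwell[i],
      se = sqrt(sum(c(a$se[i], b$se[j])^2, na.rm = TRUE))))
  }
  out
}
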