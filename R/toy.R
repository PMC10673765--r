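#' Two-exponential toy data-generating process
#'
#' The mean is `y*(t) = exp(-t) + exp(-t / 10)` — a fast and a slow decay —
#' observed with IID Gaussian noise of variance `sigma2`.  A single
#' exponential `theta1 * exp(-t / theta2)` fitted to these data is
#' discrepant: no parameter choice reproduces the mean for all `t`, so the
#' estimate depends on which observation times are used for training.
#'
#' @param t time(s).
#' @return the noise-free mean `y*(t)`.
#' @export
toy_truth <- function(t) exp(-t) + exp(-t / 10)

#' Single-exponential model prediction
#' @param t time(s).
#' @param theta numeric `c(theta1, theta2)`: amplitude and time constant.
#' @export
toy_model <- function(t, theta) theta[1] * exp(-t / theta[2])

#' Observation-time design sets for the toy example
#'
#' Ten designs: `T1`-`T4` and their union `T_all` with 11 observations each
#' (sampling intervals 0.01, 0.1, 0.1, 0.05), and primed counterparts with a
#' ten-fold increase in sampling rate (101 observations).  Two printed-set
#' ambiguities in the source are encoded explicitly: `T1`'s endpoint is read
#' as 0.1 (the only reading giving 11 equally spaced points), and `T_all'`
#' defaults to the union of the primed sets, with `tall_literal = TRUE`
#' giving the literal union-of-unprimed reading.
#'
#' @param tall_literal use the literal (unprimed-union) reading of `T_all'`.
#' @return named list of sorted, deduplicated observation-time vectors.
#' @export
toy_designs <- function(tall_literal = FALSE) {
  T1 <- seq(0, 0.1, by = 0.01)
  T2 <- seq(0, 1, by = 0.1)
  T3 <- seq(0.2, 1.2, by = 0.1)
  T4 <- seq(0.5, 1, by = 0.05)
  T_all <- sort(unique(round(c(T1, T2, T3, T4), 10)))
  T1p <- seq(0, 0.01, by = 0.001)
  T2p <- seq(0, 1, by = 0.01)
  T3p <- seq(0.2, 1.2, by = 0.01)
  T4p <- seq(0.5, 1, by = 0.005)
  T_allp <- if (tall_literal) T_all else
    sort(unique(round(c(T1p, T2p, T3p, T4p), 10)))
  list(T1 = T1, T2 = T2, T3 = T3, T4 = T4, T_all = T_all,
       T1p = T1p, T2p = T2p, T3p = T3p, T4p = T4p, T_allp = T_allp)
}

#' Sample noisy observations of the toy process
#'
#' @param times observation times.
#' @param sigma2 noise variance (default 1e-4).
#' @param seed integer seed.
#' @return tibble with columns `time` and `z`.
#' @export
toy_sample <- function(times, sigma2 = 1e-4, seed = 1) {
  stopifnot(sigma2 > 0)
  set.seed(seed)
  tibble::tibble(time = times,
                 z = toy_truth(times) +
                   stats::rnorm(length(times), 0, sqrt(sigma2)))
}

#' Least-squares fit of the single-exponential model
#'
#' Minimises the sum of squared residuals over the box `(0, 10)^2` (the
#' prior support) by multi-start bounded quasi-Newton search with a
#' Levenberg-Marquardt polish.  Tests verify the returned minimum against a
#' brute-force lattice oracle.
#'
#' @param times observation times (>= 2).
#' @param z observations at `times`.
#' @param n_starts random extra starts beyond the deterministic start grid.
#' @param seed seed for the random starts.
#' @return list of class `toy_fit` with `theta` (`c(theta1, theta2)`),
#'   `sse`, and `rmse`.
#' @export
toy_fit <- function(times, z, n_starts = 8, seed = 1) {
  stopifnot(length(times) >= 2, length(times) == length(z))
  sse <- function(th) {
    if (any(th <= 0) || any(th >= 10)) return(1e10)
    sum((toy_model(times, th) - z)^2)
  }
  set.seed(seed)
  starts <- rbind(
    expand.grid(theta1 = c(0.5, 2, 8), theta2 = c(0.2, 2, 8)),
    matrix(stats::runif(2 * n_starts, 0.01, 9.99), ncol = 2,
           dimnames = list(NULL, c("theta1", "theta2"))))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), sse, method = "L-BFGS-B",
                   lower = c(1e-8, 1e-8), upper = c(10 - 1e-8, 10 - 1e-8)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) {
      best <- res
    }
  }
  pol <- tryCatch(
    suppressWarnings_nlslm(best$par,
                       fn = function(th) toy_model(times, th) - z,
                       lower = c(1e-8, 1e-8),
                       upper = c(10 - 1e-8, 10 - 1e-8)),
    error = function(e) NULL)
  if (!is.null(pol) && sse(pol$par) < best$value) {
    best <- list(par = pol$par, value = sse(pol$par))
  }
  structure(list(theta = stats::setNames(best$par, c("theta1", "theta2")),
                 sse = best$value,
                 rmse = sqrt(best$value / length(z))),
            class = "toy_fit")
}

#' @export
print.toy_fit <- function(x, ...) {
  cat("<toy_fit> theta1 =", format(x$theta[1]), " theta2 =",
      format(x$theta[2]), " rmse =", format(x$rmse), "\n")
  invisible(x)
}

toy_log_posterior <- function(th, times, z, sigma2) {
  if (any(th <= 0) || any(th >= 10)) return(-Inf)
  -sum((toy_model(times, th) - z)^2) / (2 * sigma2)
}

#' Bayesian posterior for the toy model via adaptive Metropolis
#'
#' Adaptive-covariance random-walk Metropolis (Haario-type: the proposal
#' covariance is `2.38^2 / d` times the running sample covariance, plus a
#' small jitter) with a Gaussian likelihood of known variance and
#' independent `U(0, 10)` priors on both parameters; proposals outside the
#' prior box are always rejected.  Runs several parallel chains and reports
#' a split-chain convergence diagnostic (flagged above 1.05).
#'
#' @inheritParams toy_sample
#' @param z observations at `times`.
#' @param n_chains number of chains (default 4).
#' @param n_iter iterations per chain (default 25000).
#' @param burn_in discarded initial iterations per chain (default 5000).
#' @param init optional initial `c(theta1, theta2)`; default the
#'   least-squares fit (chains are jittered around it).
#' @param seed integer seed.
#' @return list with `samples` (pooled post-burn-in tibble: `chain`,
#'   `theta1`, `theta2`), `rhat` (per-parameter), `acceptance_rate`, and
#'   `converged`.
#' @export
toy_posterior <- function(times, z, sigma2 = 1e-4, n_chains = 4,
                          n_iter = 25000, burn_in = 5000, init = NULL,
                          seed = 1) {
  if (is.null(init)) init <- unname(toy_fit(times, z)$theta)
  set.seed(seed)
  d <- 2
  keep <- vector("list", n_chains)
  acc_total <- 0
  for (ch in seq_len(n_chains)) {
    th <- pmin(pmax(init * (1 + 0.05 * stats::rnorm(d)), 1e-4), 10 - 1e-4)
    lp <- toy_log_posterior(th, times, z, sigma2)
    out <- matrix(NA_real_, n_iter, d)
    mu <- th
    S <- diag(c(1e-4, 1e-4))
    eps <- 1e-10 * diag(d)
    n_acc <- 0
    for (i in seq_len(n_iter)) {
      prop_cov <- if (i > 200) (2.38^2 / d) * S + eps else diag(1e-4, d)
      L <- chol(prop_cov)
      prop <- th + as.vector(t(L) %*% stats::rnorm(d))
      lp_prop <- toy_log_posterior(prop, times, z, sigma2)
      if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
        th <- prop
        lp <- lp_prop
        n_acc <- n_acc + 1
      }
      out[i, ] <- th
      # running mean/covariance update
      delta <- th - mu
      mu <- mu + delta / i
      if (i > 1) S <- S * (i - 2) / (i - 1) + (delta %o% (th - mu)) / (i - 1)
    }
    acc_total <- acc_total + n_acc / n_iter
    keep[[ch]] <- tibble::tibble(chain = ch,
                                 theta1 = out[-seq_len(burn_in), 1],
                                 theta2 = out[-seq_len(burn_in), 2])
  }
  samples <- dplyr::bind_rows(keep)
  rhat <- c(theta1 = split_rhat(samples, "theta1"),
            theta2 = split_rhat(samples, "theta2"))
  converged <- all(rhat < 1.05)
  if (!converged) {
    warning("MCMC convergence diagnostic exceeds 1.05 (rhat = ",
            paste(signif(rhat, 4), collapse = ", "), ")", call. = FALSE)
  }
  list(samples = samples, rhat = rhat,
       acceptance_rate = acc_total / n_chains, converged = converged)
}

# split-chain potential-scale-reduction diagnostic
split_rhat <- function(samples, var) {
  halves <- lapply(split(samples[[var]], samples$chain), function(x) {
    h <- length(x) %/% 2
    list(x[seq_len(h)], x[h + seq_len(h)])
  })
  chains <- unlist(halves, recursive = FALSE)
  m <- length(chains)
  n <- length(chains[[1]])
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Spread-of-prediction band over toy design fits
#'
#' Evaluates each design's fitted single-exponential curve on a common time
#' grid and returns the per-time envelope and midpoint, mirroring the
#' protocol-ensemble band for the ion-channel models.
#'
#' @param fits list of `toy_fit`s (one per design).
#' @param t_grid prediction time grid (default 201 points on `[0, 2]`).
#' @return tibble with columns `time`, `lower`, `mid`, `upper` plus the
#'   per-design predictions as a `member_predictions` attribute.
#' @export
toy_predict_band <- function(fits, t_grid = seq(0, 2, length.out = 201)) {
  stopifnot(length(fits) >= 1)
  P <- vapply(fits, function(f) toy_model(t_grid, f$theta),
              numeric(length(t_grid)))
  P <- matrix(P, nrow = length(t_grid))
  lower <- apply(P, 1, min)
  upper <- apply(P, 1, max)
  structure(
    tibble::tibble(time = t_grid, lower = lower,
                   mid = (lower + upper) / 2, upper = upper),
    member_predictions = P)
}
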