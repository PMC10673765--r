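# Independent oracles used across the suite.  These deliberately avoid the
# package's own solver paths: the matrix exponential is computed by eigen
# decomposition in R, and fixed-voltage trajectories by the spectral closed
# form, so agreement with the package's propagator is a genuine dual-route
# check.

# closed-form solution of dx/dt = A x at fixed A via eigen decomposition
expm_eigen <- function(A, t) {
  e <- eigen(A)
  Re(e$vectors %*% diag(exp(e$values * t), nrow(A)) %*% solve(e$vectors))
}

solve_fixed_voltage_oracle <- function(A, x0, times) {
  t(vapply(times, function(t) as.numeric(expm_eigen(A, t) %*% x0),
           numeric(length(x0))))
}

# random connected chain model with n states; rates kept well inside the
# default bound box so all fits/simulations are feasible
random_chain_model <- function(n, seed, conducting = n) {
  set.seed(seed)
  states <- paste0("S", seq_len(n))
  k <- n - 1L
  theta <- numeric(0)
  tr <- NULL
  for (i in seq_len(k)) {
    a_f <- 10^runif(1, -3, -0.5)
    b_f <- runif(1, 0, 0.04)
    a_b <- 10^runif(1, -3, -0.5)
    b_b <- runif(1, 0, 0.04)
    theta <- c(theta, a_f, b_f, a_b, b_b)
    m <- length(theta)
    tr <- rbind(tr, data.frame(
      from = c(states[i], states[i + 1]),
      to = c(states[i + 1], states[i]),
      kind = c("exp_increasing", "exp_decreasing"),
      a = c(m - 3L, m - 1L),
      b = c(m - 2L, m)))
  }
  names(theta) <- paste0("q", seq_along(theta))
  markov_model(paste0("chain", n), states, conducting, tr, theta,
               g = runif(1, 0.05, 0.5))
}

# simple two-state C <-> O model with explicit rates
two_state_model <- function(a1 = 0.02, b1 = 0.03, a2 = 0.05, b2 = 0.02,
                            g = 0.2) {
  markov_model(
    "two_state", c("C", "O"), "O",
    data.frame(from = c("C", "O"), to = c("O", "C"),
               kind = c("exp_increasing", "exp_decreasing"),
               a = c(1L, 3L), b = c(2L, 4L)),
    c(a1 = a1, b1 = b1, a2 = a2, b2 = b2), g)
}

# short step protocol used by fast tests
mini_protocol <- function(name = "mini", sample_rate = 1) {
  voltage_protocol(
    name,
    dplyr::bind_rows(
      step_seg_t(100, -80), step_seg_t(150, 20), step_seg_t(100, -40),
      ramp_seg_t(50, -40, 40), step_seg_t(100, -120)),
    v_hold = -80, sample_rate = sample_rate)
}

step_seg_t <- function(duration, v) {
  tibble::tibble(duration = duration, v_start = v, v_end = v)
}
ramp_seg_t <- function(duration, v0, v1) {
  tibble::tibble(duration = duration, v_start = v0, v_end = v1)
}

# 99% credible-region disjointness via within-sample Mahalanobis quantiles
credible_regions_overlap <- function(sa, sb, level = 0.99) {
  xa <- as.matrix(sa[c("theta1", "theta2")])
  xb <- as.matrix(sb[c("theta1", "theta2")])
  inside <- function(x, ref) {
    mu <- colMeans(ref)
    S <- stats::cov(ref)
    d_ref <- stats::mahalanobis(ref, mu, S)
    q <- stats::quantile(d_ref, level)
    any(stats::mahalanobis(x, mu, S) <= q)
  }
  inside(xb, xa) || inside(xa, xb)
}
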