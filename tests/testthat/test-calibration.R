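test_that("rmse has the closed form and checks lengths", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  y <- rnorm(20)
  expect_equal(rmse(y, y + 0.7), 0.7)
  expect_error(rmse(1:3, 1:4), "length mismatch")
})

test_that("log-likelihood is the Gaussian form and peaks with the RMSE minimum", {
  m <- two_state_model()
  p <- mini_protocol()
  d <- generate_synthetic(m, p, sigma = 1, seed = 2)
  # zero-residual value: z equals the noise-free trace
  d0 <- d
  d0$current <- attr(d, "truth_meta")$y_true
  n <- nrow(d0)
  expect_equal(log_likelihood(m, d0, sigma = 1), -n / 2 * log(2 * pi))
  # quadratic scaling: doubling residuals quadruples the quadratic term
  da <- d; da$current <- attr(d, "truth_meta")$y_true + 0.1
  db <- d; db$current <- attr(d, "truth_meta")$y_true + 0.2
  la <- log_likelihood(m, da, sigma = 1) + n / 2 * log(2 * pi)
  lb <- log_likelihood(m, db, sigma = 1) + n / 2 * log(2 * pi)
  expect_equal(lb, 4 * la, tolerance = 1e-9)
  # objective equivalence on random small perturbations of theta
  set.seed(5)
  y_obs <- d$current
  cands <- lapply(1:12, function(i) m$theta_f * exp(rnorm(4, 0, 0.2)))
  r_vals <- vapply(cands, function(th)
    rmse(simulate_current(m, p, theta_f = th)$current, y_obs), numeric(1))
  l_vals <- vapply(cands, function(th)
    log_likelihood(m, d, theta_f = th, sigma = 0.3), numeric(1))
  expect_equal(order(r_vals), order(-l_vals))
})

test_that("rate-bound checks use the closed-form maximum over the voltage range", {
  m <- two_state_model()
  cfg <- fit_config()
  expect_true(check_rate_bounds(m, m$theta_f, cfg))
  # constant rate inside the box
  mc <- markov_model("c", c("A", "B"), "B",
                     data.frame(from = "A", to = "B", kind = "constant",
                                a = 1L, b = NA),
                     theta_f = c(k = 1), g = 1)
  expect_true(check_rate_bounds(mc, c(k = 1), cfg))
  expect_false(check_rate_bounds(mc, c(k = 2e3), cfg))
  expect_false(check_rate_bounds(mc, c(k = 1e-5), cfg))
  # increasing law peaks at +60 mV; boundary value is inside (closed bounds)
  b <- 0.05
  a_boundary <- 1e3 / exp(b * 60)
  m2 <- two_state_model(a1 = a_boundary, b1 = b)
  expect_true(check_rate_bounds(m2, m2$theta_f, cfg))
  m3 <- two_state_model(a1 = a_boundary * 10.01, b1 = b)
  expect_false(check_rate_bounds(m3, m3$theta_f, cfg))
  # decreasing law peaks at -120 mV
  m4 <- two_state_model(a2 = 1e3 / exp(0.02 * 120) * 1.01, b2 = 0.02)
  expect_false(check_rate_bounds(m4, m4$theta_f, cfg))
})

test_that("initial guesses follow the log10-uniform law and respect the bounds", {
  m <- beattie_model()
  cfg <- fit_config(seed = 1)
  g1 <- sample_initial_guess(m, cfg, seed = 42)
  g2 <- sample_initial_guess(m, cfg, seed = 42)
  expect_identical(g1, g2)
  expect_equal(g1$g, m$g)
  draws <- t(vapply(1:200, function(s)
    sample_initial_guess(m, cfg, seed = s)$theta_f, m$theta_f))
  expect_true(all(draws >= 1e-7 & draws <= 1e-1))
  expect_true(all(vapply(1:200, function(s)
    check_rate_bounds(m, draws[s, ], cfg), logical(1))))
  # log10 spread: sd of a U(-7,-1) variate is about 1.73 decades
  expect_equal(sd(log10(draws)), sqrt(36 / 12), tolerance = 0.1)
})

test_that("fit recovers a two-state model and matches a grid-search oracle", {
  m <- two_state_model(a1 = 0.02, b1 = 0.03, a2 = 0.05, b2 = 0.02, g = 0.2)
  p <- mini_protocol(sample_rate = 2)
  d <- generate_synthetic(m, p, sigma = 0.02, seed = 11)
  # restrict to the two 'a' parameters for the brute-force comparison:
  # profile the objective on a 200 x 200 lattice in (log a1, log a2)
  z <- d$current
  obj_ab <- function(a1, a2) {
    th <- c(a1 = a1, b1 = 0.03, a2 = a2, b2 = 0.02)
    rmse(simulate_current(m, p, theta_f = th)$current, z)
  }
  cfg <- fit_config(n_restarts = 4, seed = 2, cma_max_gen = 120,
                    init_candidates = 5)
  est <- fit_model(m, d, config = cfg)
  # full fit recovers all parameters well at this noise level
  expect_lt(max(abs(c(est$theta_f, est$g) / c(m$theta_f, m$g) - 1)), 0.1)
  expect_lt(est$rmse_train, 0.021)
  # self-consistency: re-simulation reproduces rmse_train
  y_hat <- simulate_current(m, p, theta_f = est$theta_f, g = est$g)$current
  expect_equal(rmse(y_hat, z), est$rmse_train, tolerance = 1e-10)
  # grid oracle: lattice minimum lies within one cell of the fit
  grid1 <- exp(seq(log(0.02) - 0.5, log(0.02) + 0.5, length.out = 200))
  grid2 <- exp(seq(log(0.05) - 0.5, log(0.05) + 0.5, length.out = 200))
  vals <- outer(grid1, grid2, Vectorize(obj_ab))
  idx <- which(vals == min(vals), arr.ind = TRUE)[1, ]
  cell <- diff(log(grid1))[1]
  expect_lt(abs(log(grid1[idx[1]]) - log(est$theta_f["a1"])), 2 * cell)
  expect_lt(abs(log(grid2[idx[2]]) - log(est$theta_f["a2"])), 2 * cell)
})

test_that("noiseless data with a warm start give back the truth", {
  m <- two_state_model()
  p <- mini_protocol(sample_rate = 2)
  sim <- simulate_current(m, p)
  d <- generate_synthetic(m, p, sigma = 1e-12, seed = 1)
  d$current <- sim$current   # exactly noise-free
  cfg <- fit_config(n_restarts = 1, seed = 1, cma_max_gen = 50)
  est <- fit_restricted(m, d, lambda = 1, config = cfg, n_restarts = 0,
                        warm_start = m$theta_f, g_ref = m$g)
  expect_lt(est$rmse_train, 1e-8)
  expect_equal(unname(est$theta_f), unname(m$theta_f), tolerance = 1e-4)
})

test_that("conductance pinning is exact and restricted fits never beat free ones", {
  m <- two_state_model()
  p <- mini_protocol(sample_rate = 2)
  d <- generate_synthetic(m, p, sigma = 0.02, seed = 21)
  cfg <- fit_config(n_restarts = 2, seed = 3, cma_max_gen = 100,
                    init_candidates = 5)
  est4 <- fit_restricted(m, d, lambda = 4, config = cfg, n_restarts = 2)
  expect_equal(est4$g, 4 * m$g)
  expect_equal(est4$lambda, 4)
  est1 <- fit_restricted(m, d, lambda = 1, config = cfg, n_restarts = 2)
  # data were generated at lambda = 1: nested feasible sets
  expect_gte(est4$rmse_train, est1$rmse_train)
})

test_that("lambda sweep warm-starts outward from 1 and profiles the objective", {
  m <- two_state_model()
  p <- mini_protocol(sample_rate = 2)
  d <- generate_synthetic(m, p, sigma = 0.02, seed = 31)
  cfg <- fit_config(n_restarts = 2, n_restarts_continuation = 1, seed = 5,
                    cma_max_gen = 100, init_candidates = 5)
  lams <- c(1 / 4, 1, 4)
  sw <- lambda_sweep(m, d, lambdas = lams, config = cfg)
  expect_named(sw, paste0("lambda_", lams))
  for (i in seq_along(lams)) {
    expect_equal(sw[[i]]$g, lams[i] * m$g)
  }
  r <- vapply(sw, function(e) e$rmse_train, numeric(1))
  expect_equal(unname(which.min(r)), 2L)  # minimised at lambda = 1
  # singleton grid reduces to the pinned fit
  sw1 <- lambda_sweep(m, d, lambdas = 1, config = cfg)
  expect_length(sw1, 1L)
  expect_equal(sw1[[1]]$g, m$g)
})

test_that("tidy and glance methods expose estimates and metadata", {
  m <- two_state_model()
  p <- mini_protocol(sample_rate = 1)
  d <- generate_synthetic(m, p, sigma = 0.05, seed = 41)
  cfg <- fit_config(n_restarts = 1, seed = 1, cma_max_gen = 40,
                    init_candidates = 2)
  est <- fit_model(m, d, config = cfg)
  td <- tidy(est)
  expect_named(td, c("term", "estimate"))
  expect_equal(td$term, c("a1", "b1", "a2", "b2", "g"))
  gl <- glance(est)
  expect_equal(gl$training_protocol, "mini")
  expect_equal(gl$rmse_train, est$rmse_train)
  expect_true(all(est$restart_log$rmse >= est$rmse_train - 1e-12))
})
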