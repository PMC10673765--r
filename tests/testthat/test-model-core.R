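test_that("rate matrix columns sum to zero and off-diagonals match rate laws", {
  m <- two_state_model()
  for (V in c(-120, -80, 0, 37.5, 60)) {
    A <- build_rate_matrix(m, V)
    expect_equal(colSums(A), c(C = 0, O = 0), tolerance = 1e-14)
    expect_equal(A["O", "C"], 0.02 * exp(0.03 * V))
    expect_equal(A["C", "O"], 0.05 * exp(-0.02 * V))
  }
  # all rate scales zero -> zero matrix
  m0 <- two_state_model(a1 = 0, a2 = 0)
  expect_equal(build_rate_matrix(m0, -20), matrix(0, 2, 2,
    dimnames = list(c("C", "O"), c("C", "O"))))
})

test_that("packaged models match their published structure", {
  b <- beattie_model()
  expect_equal(n_states(b), 4L)
  expect_length(b$theta_f, 8L)
  expect_equal(b$states[b$conducting], "O")
  w <- wang_model()
  expect_equal(n_states(w), 5L)
  expect_length(w$theta_f, 14L)  # 15 parameters in total with g
  expect_equal(w$states[w$conducting], "O")
  # rank N-1 at the holding potential: conservation makes A singular
  for (m in list(b, w)) {
    A <- build_rate_matrix(m, -80)
    sv <- svd(A)$d
    expect_lt(sv[length(sv)], 1e-12 * sv[1])
    expect_gt(sv[length(sv) - 1], 1e-8 * sv[1])
  }
})

test_that("declared rates are strictly positive over the protocol voltage range", {
  for (m in list(beattie_model(), wang_model())) {
    tr <- m$transitions
    for (r in seq_len(nrow(tr))) {
      law <- rate_law(tr$kind[r], m$theta_f[tr$a[r]],
                      if (tr$kind[r] == "constant") 0 else m$theta_f[tr$b[r]])
      k <- eval_rate(law, seq(-120, 60, by = 5))
      expect_true(all(is.finite(k) & k > 0))
    }
  }
})

test_that("steady state solves A x = 0 with unit mass and matches closed form", {
  # two-state closed form x_inf = (k2, k1) / (k1 + k2)
  m <- two_state_model()
  V <- -30
  k1 <- 0.02 * exp(0.03 * V)
  k2 <- 0.05 * exp(-0.02 * V)
  expect_equal(unname(steady_state(m, V)), c(k2, k1) / (k1 + k2),
               tolerance = 1e-12)
  # symmetric rates -> (1/2, 1/2)
  ms <- two_state_model(a1 = 0.03, b1 = 0, a2 = 0.03, b2 = 0)
  expect_equal(unname(steady_state(ms, 11)), c(0.5, 0.5), tolerance = 1e-12)
  # packaged models: A x = 0, sum 1, in [0,1]
  for (mod in list(beattie_model(), wang_model())) {
    for (V in c(-120, -80, 0, 60)) {
      x <- steady_state(mod, V)
      expect_lt(max(abs(build_rate_matrix(mod, V) %*% x)), 1e-10)
      expect_equal(sum(x), 1, tolerance = 1e-12)
      expect_true(all(x >= 0 & x <= 1))
    }
  }
})

test_that("steady state agrees with long-time integration at the holding potential", {
  m <- beattie_model()
  x_inf <- steady_state(m, -80)
  A <- build_rate_matrix(m, -80)
  x_long <- as.numeric(expm_eigen(A, 1e5) %*% rep(0.25, 4))
  expect_equal(unname(x_inf), x_long, tolerance = 1e-6)
  # local stability: perturb and integrate back
  x_pert <- x_inf + c(0.02, -0.01, 0.005, -0.015)
  x_back <- as.numeric(expm_eigen(A, 1e5) %*% x_pert)
  expect_equal(x_back, unname(x_inf), tolerance = 1e-6)
})

test_that("steady state of most-closed kind at rest: open fraction is small", {
  expect_lt(steady_state(beattie_model(), -80)["O"], 0.05)
  expect_lt(steady_state(wang_model(), -80)["O"], 0.05)
})

test_that("conservation-reduced system reproduces the full dynamics", {
  # two-state reduction: dx1/dt = -(k1 + k2) x1 + k2
  m <- two_state_model()
  V <- 10
  red <- reduce_system(m)$affine(V)
  k1 <- 0.02 * exp(0.03 * V)
  k2 <- 0.05 * exp(-0.02 * V)
  expect_equal(as.numeric(red$Ar), -(k1 + k2))
  expect_equal(as.numeric(red$br), k2)
  # random chain models: reduced trajectory (via lsoda path) vs full oracle
  for (seed in 1:4) {
    n <- 2 + (seed %% 3)
    mod <- random_chain_model(n, seed)
    p <- mini_protocol()
    x_red <- solve_states(mod, p, method = "lsoda")
    x_ana <- solve_states(mod, p, method = "analytic")
    expect_lt(max(abs(x_red - x_ana)), 1e-6)
    expect_equal(rowSums(x_red), rep(1, nrow(x_red)), tolerance = 1e-7)
  }
})

test_that("single-state degenerate model is constant at 1", {
  m1 <- markov_model("point", "S1", 1L,
                     data.frame(from = character(), to = character(),
                                kind = character(), a = integer(),
                                b = integer()),
                     theta_f = c(q = 1), g = 0.1)
  expect_equal(unname(steady_state(m1, -80)), 1)
})

test_that("structural errors are caught", {
  expect_error(
    markov_model("bad", c("A", "B"), "B",
                 data.frame(from = "A", to = "Z", kind = "constant",
                            a = 1L, b = NA),
                 theta_f = c(k = 0.1), g = 1),
    "unknown state")
  # disconnected graph: no unique conservative steady state
  expect_error(
    markov_model("disc", c("A", "B", "C"), "C",
                 data.frame(from = "A", to = "B", kind = "constant",
                            a = 1L, b = NA),
                 theta_f = c(k = 0.1), g = 1),
    "disconnected")
  expect_error(eval_rate(rate_law("exp_increasing", 1e300, 1), 60),
               "non-finite")
})

test_that("model definition files round-trip exactly", {
  for (maker in list(beattie_model, wang_model)) {
    m <- maker()
    path <- withr::local_tempfile(fileext = ".json")
    write_markov_model(m, path)
    m2 <- read_markov_model(path)
    expect_equal(m2$theta_f, m$theta_f)
    expect_equal(m2$g, m$g)
    expect_equal(m2$states, m$states)
    expect_equal(m2$transitions, m$transitions)
    expect_equal(m2$conducting, m$conducting)
  }
  expect_error(read_markov_model(file.path(tempdir(), "nope.json")),
               "not found")
})
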