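# a cheap fake estimate, bypassing optimisation
fake_estimate <- function(model, protocol_name, theta_f = model$theta_f,
                          g = model$g) {
  structure(
    list(model_name = model$name, theta_f = theta_f, g = g, lambda = 1,
         training_protocol = protocol_name, rmse_train = NA_real_,
         n_restarts_used = 0L, best_restart_index = 0L,
         restart_log = tibble::tibble(), seed = 0L),
    class = "parameter_estimate")
}

perturbed_ensemble <- function(model, n_members, seed = 1, scale = 0.15) {
  set.seed(seed)
  members <- lapply(seq_len(n_members), function(i) {
    fake_estimate(model, paste0("p", i),
                  theta_f = model$theta_f * exp(rnorm(length(model$theta_f),
                                                      0, scale)),
                  g = model$g * exp(rnorm(1, 0, scale)))
  })
  ensemble_from_estimates(members, model)
}

test_that("band is the member envelope with the exact midpoint", {
  m <- two_state_model()
  p <- mini_protocol()
  ens <- perturbed_ensemble(m, 4)
  band <- predict_ensemble(ens, p)
  P <- attr(band, "member_predictions")
  expect_equal(dim(P), c(nrow(band), 4L))
  expect_equal(band$lower, apply(P, 1, min))
  expect_equal(band$upper, apply(P, 1, max))
  expect_identical(band$mid, (band$lower + band$upper) / 2)
  expect_true(all(band$lower <= band$mid & band$mid <= band$upper))
  # singleton ensemble: zero width
  b1 <- predict_ensemble(ensemble_from_estimates(
    list(fake_estimate(m, "only")), m), p)
  expect_equal(b1$lower, b1$upper)
  expect_equal(band_width_summary(b1)$max, 0)
})

test_that("percentile bands are nested inside the min/max envelope", {
  m <- two_state_model()
  p <- mini_protocol()
  ens <- perturbed_ensemble(m, 6)
  full <- predict_ensemble(ens, p)
  b80 <- predict_ensemble(ens, p, level = 0.8)
  expect_true(all(b80$lower >= full$lower - 1e-12))
  expect_true(all(b80$upper <= full$upper + 1e-12))
  expect_identical(b80$mid, (b80$lower + b80$upper) / 2)
  expect_error(predict_ensemble(ens, p, level = 1.2))
})

test_that("bands cannot shrink as members are added", {
  m <- two_state_model()
  p <- mini_protocol()
  for (trial in 1:25) {
    ens_small <- perturbed_ensemble(m, 3, seed = trial)
    extra <- fake_estimate(m, "extra",
                           theta_f = m$theta_f * exp(rnorm(4, 0, 0.2)))
    ens_big <- ensemble_from_estimates(c(ens_small$members, list(extra)), m)
    b_small <- predict_ensemble(ens_small, p)
    b_big <- predict_ensemble(ens_big, p)
    expect_true(all(b_big$lower <= b_small$lower + 1e-12))
    expect_true(all(b_big$upper >= b_small$upper - 1e-12))
  }
})

test_that("band and crossval are invariant under member permutation", {
  m <- two_state_model()
  p <- mini_protocol()
  ens <- perturbed_ensemble(m, 5)
  perm <- c(3, 1, 5, 2, 4)
  ens_p <- ensemble_from_estimates(ens$members[perm], m)
  b1 <- predict_ensemble(ens, p)
  b2 <- predict_ensemble(ens_p, p)
  expect_equal(b2$lower, b1$lower)
  expect_equal(b2$upper, b1$upper)
  d <- generate_synthetic(m, p, sigma = 0.02, seed = 5)
  cv1 <- crossval(ens, list(d))
  cv2 <- crossval(ens_p, list(d))
  expect_equal(dplyr::arrange(cv1, train), dplyr::arrange(cv2, train))
})

test_that("crossval diagonal equals the member training RMSE", {
  m <- two_state_model()
  p <- mini_protocol()
  d <- generate_synthetic(m, p, sigma = 0.02, seed = 9)
  cfg <- fit_config(n_restarts = 1, seed = 1, cma_max_gen = 40,
                    init_candidates = 2)
  est <- fit_model(m, d, config = cfg)
  ens <- ensemble_from_estimates(list(est), m)
  cv <- crossval(ens, list(d))
  expect_equal(cv$rmse[cv$train == "mini" & cv$validation == "mini"],
               est$rmse_train, tolerance = 1e-10)
})

test_that("crossval accepts noise replicates and reports their spread", {
  m <- two_state_model()
  p <- mini_protocol()
  ens <- ensemble_from_estimates(list(fake_estimate(m, "truth")), m)
  reps <- lapply(1:6, function(s) generate_synthetic(m, p, sigma = 0.05,
                                                     seed = s))
  cv <- crossval(ens, list(reps))
  expect_equal(cv$n_replicates, 6L)
  expect_false(is.na(cv$rmse_sd))
  # the truth-member residuals are pure noise: rmse concentrates at sigma
  expect_equal(cv$rmse, 0.05, tolerance = 0.1)
})

test_that("coverage counts the truth inside the envelope", {
  m <- two_state_model()
  p <- mini_protocol()
  ens <- perturbed_ensemble(m, 4)
  band <- predict_ensemble(ens, p)
  cov_mid <- band_coverage(band, band$mid)
  expect_equal(cov_mid$fraction, 1)
  cov_out <- band_coverage(band, band$upper + 1)
  expect_equal(cov_out$fraction, 0)
  expect_error(band_coverage(band, band$mid[-1]), "aligned")
})

test_that("width summaries and their invariance to interior members", {
  m <- two_state_model()
  p <- mini_protocol()
  ens <- perturbed_ensemble(m, 4)
  band <- predict_ensemble(ens, p)
  w <- band_width_summary(band)
  expect_equal(w$width, band$upper - band$lower)
  expect_gte(min(w$width), 0)
  # adding the midpoint curve as a member leaves the envelope unchanged
  # (use an existing member's parameters scaled to stay inside)
  inner <- fake_estimate(m, "inner", theta_f = ens$members[[1]]$theta_f,
                         g = ens$members[[1]]$g)
  ens2 <- ensemble_from_estimates(c(ens$members, list(inner)), m)
  b2 <- predict_ensemble(ens2, p)
  expect_equal(band_width_summary(b2)$width, w$width)
})

test_that("train_ensemble fits one member per distinct protocol", {
  m <- two_state_model()
  p1 <- mini_protocol("p1")
  p2 <- voltage_protocol("p2", dplyr::bind_rows(step_seg_t(150, 0),
                                                step_seg_t(150, -100)),
                         sample_rate = 1)
  d1 <- generate_synthetic(m, p1, sigma = 0.02, seed = 1)
  d2 <- generate_synthetic(m, p2, sigma = 0.02, seed = 2)
  cfg <- fit_config(n_restarts = 1, seed = 1, cma_max_gen = 60,
                    init_candidates = 3)
  ens <- train_ensemble(m, list(d1, d2), config = cfg, share_starts = TRUE)
  expect_length(ens$members, 2L)
  expect_equal(ens$training_protocols, c("p1", "p2"))
  expect_error(train_ensemble(m, list(d1, d1), config = cfg), "distinct")
  td <- tidy(ens)
  expect_equal(nrow(td), 2L * 5L)
  expect_equal(nrow(glance(ens)), 2L)
})

test_that("autoplot methods return ggplot objects", {
  m <- two_state_model()
  p <- mini_protocol()
  ens <- perturbed_ensemble(m, 3)
  band <- predict_ensemble(ens, p)
  expect_s3_class(autoplot(band), "ggplot")
  d <- generate_synthetic(m, p, sigma = 0.02, seed = 3)
  cv <- crossval(ens, list(d))
  expect_s3_class(autoplot(cv), "ggplot")
})
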