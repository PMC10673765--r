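#' Root-mean-square error between two current traces
#'
#' @param y,z numeric vectors of equal length (nA).
#' @return non-negative scalar, `sqrt(mean((y - z)^2))`.
#' @export
rmse <- function(y, z) {
  if (length(y) != length(z)) {
    stop("rmse: length mismatch (", length(y), " vs ", length(z), ")",
         call. = FALSE)
  }
  stopifnot(length(y) >= 1)
  sqrt(mean((y - z)^2))
}

#' Gaussian IID log-likelihood of a dataset under the model
#'
#' With known noise standard deviation `sigma`, the log-likelihood is
#' `-(n/2) log(2 pi sigma^2) - SSE / (2 sigma^2)`, so for fixed `sigma` its
#' argmax over parameters coincides with the RMSE argmin.
#'
#' @param model a [markov_model()].
#' @param dataset an `ion_dataset` (see [generate_synthetic()]).
#' @param conditions an [ionic_conditions()].
#' @param theta_f kinetic parameters; default the model's.
#' @param g maximal conductance; default the model's.
#' @param sigma noise SD (nA); defaults to the dataset's recorded value.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(model, dataset, conditions = ionic_conditions(),
                           theta_f = model$theta_f, g = model$g,
                           sigma = attr(dataset, "sigma")) {
  stopifnot(sigma > 0)
  y <- simulate_current(model, attr(dataset, "protocol"), conditions,
                        theta_f, g)$current
  n <- length(y)
  sse <- sum((y - dataset$current)^2)
  -n / 2 * log(2 * pi * sigma^2) - sse / (2 * sigma^2)
}

#' Calibration configuration
#'
#' Houses the multi-start optimisation settings: restart counts, the
#' transition-rate box constraint (closed bounds on the maximum rate over
#' the protocol voltage range), the log10-uniform initial-guess law for
#' kinetic parameters, and optimiser controls.
#'
#' @param n_restarts restarts for primary fits (default 25).
#' @param n_restarts_continuation restarts for warm-started
#'   conductance-pinned continuation fits (default 5).
#' @param rate_bound_low,rate_bound_high bounds (ms^-1) on the maximum
#'   transition rate over `V` in `[-120, 60]` mV; defaults `1.67e-5`, `1e3`.
#' @param init_low_exp,init_high_exp exponents of the log10-uniform
#'   initial-guess distribution (defaults -7, -1).
#' @param seed root seed for initial guesses and the stochastic search.
#' @param tol relative objective-change stopping tolerance.
#' @param cma_popsize population size (`NULL` = `4 + floor(3 log(n))`).
#' @param cma_max_gen generation cap for the stochastic search.
#' @param polish run a Levenberg-Marquardt refinement after each restart.
#' @param max_resample cap on initial-guess rejection resampling.
#' @param init_candidates initial guesses drawn per restart; the restart
#'   starts from the best-scoring one (best-of-k seeding).
#' @param search_thin during the global search phase, evaluate the objective
#'   on every `search_thin`-th observation (1 = no thinning); the final
#'   refinement and the reported training RMSE always use the full grid.
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(n_restarts = 25, n_restarts_continuation = 5,
                       rate_bound_low = 1.67e-5, rate_bound_high = 1e3,
                       init_low_exp = -7, init_high_exp = -1,
                       seed = 1, tol = 1e-11,
                       cma_popsize = NULL, cma_max_gen = 300,
                       polish = TRUE, max_resample = 1e4,
                       init_candidates = 10, search_thin = 1L) {
  stopifnot(n_restarts >= 1, n_restarts_continuation >= 1,
            rate_bound_low > 0, rate_bound_low < rate_bound_high,
            init_low_exp < init_high_exp, init_candidates >= 1,
            search_thin >= 1)
  structure(as.list(environment()), class = "fit_config")
}

#' Check the transition-rate box constraint
#'
#' True iff every declared transition's maximum rate over
#' `V` in `[-120, 60]` mV lies inside the (closed) configured bounds.  The
#' maximum is closed-form: at `V = +60` for increasing rates, `V = -120` for
#' decreasing ones, and the constant itself otherwise.
#'
#' @param model a [markov_model()].
#' @param theta_f kinetic parameter vector.
#' @param config a [fit_config()].
#' @return logical scalar.
#' @export
check_rate_bounds <- function(model, theta_f = model$theta_f,
                              config = fit_config()) {
  k <- max_rates(model, theta_f)
  all(k >= config$rate_bound_low & k <= config$rate_bound_high)
}

max_rates <- function(model, theta_f) {
  tr <- model$transitions
  a <- theta_f[tr$a]
  b <- ifelse(tr$kind == "constant", 0, theta_f[tr$b])
  ifelse(tr$kind == "exp_increasing", a * exp(b * 60),
         ifelse(tr$kind == "exp_decreasing", a * exp(b * 120), a))
}

# smooth log-scale distance to the feasible rate box, 0 inside
rate_bound_violation <- function(model, theta_f, config) {
  if (any(!is.finite(theta_f)) || any(theta_f < 0)) return(Inf)
  k <- max_rates(model, theta_f)
  if (any(k <= 0)) return(Inf)
  sum(pmax(0, log(k) - log(config$rate_bound_high)) +
        pmax(0, log(config$rate_bound_low) - log(k)))
}

#' Sample an initial parameter guess
#'
#' Kinetic parameters are drawn with `log10(p) ~ U(init_low_exp,
#' init_high_exp)` and rejection-resampled until [check_rate_bounds()]
#' passes; the conductance is set to `g_init` (by default the value used for
#' data generation in the synthetic studies).  Deterministic under `seed`.
#'
#' @inheritParams check_rate_bounds
#' @param g_init conductance for the guess (uS).
#' @param seed integer seed.
#' @return named list with elements `theta_f` and `g`.
#' @export
sample_initial_guess <- function(model, config = fit_config(),
                                 g_init = model$g, seed = config$seed) {
  set.seed(seed)
  np <- length(model$theta_f)
  for (i in seq_len(config$max_resample)) {
    theta <- stats::setNames(
      10^stats::runif(np, config$init_low_exp, config$init_high_exp),
      names(model$theta_f))
    if (check_rate_bounds(model, theta, config)) {
      return(list(theta_f = theta, g = g_init))
    }
  }
  stop("failed to sample a feasible initial guess within ",
       config$max_resample, " draws", call. = FALSE)
}

# per-parameter optimisation transform: rate scales ('a' slots) and the
# conductance are searched in log space, voltage sensitivities ('b' slots)
# untransformed
param_transforms <- function(model, include_g) {
  tr <- model$transitions
  type <- rep("identity", length(model$theta_f))
  type[unique(tr$a)] <- "log"
  if (include_g) type <- c(type, "log")
  type
}

to_search <- function(theta, type) ifelse(type == "log", log(theta), theta)
from_search <- function(phi, type) ifelse(type == "log", exp(phi), phi)
search_scales <- function(type) ifelse(type == "log", 2.0, 0.05)

# fast precompiled objective: RMSE of the simulated current against z, with
# a large additive penalty (1e6 + distance) outside the feasible rate box.
# svalue()/sresiduals() evaluate on a thinned observation grid for the
# global search phase; value()/residuals() always use the full grid.
make_objective <- function(model, dataset, conditions, config,
                           fix_g = NULL) {
  protocol <- attr(dataset, "protocol")
  tobs_full <- observation_times(protocol)
  thin <- max(1L, as.integer(config$search_thin %||% 1L))
  keep <- seq(1L, length(tobs_full), by = thin)
  bp <- segment_breakpoints(protocol)
  seg <- protocol$segments
  v_obs <- voltage_at(protocol, tobs_full)
  drive_full <- v_obs - conditions$E_rev
  z_full <- dataset$current
  np <- length(model$theta_f)
  tr_idx <- list(
    from = match(model$transitions$from, model$states) - 1L,
    to = match(model$transitions$to, model$states) - 1L,
    kind = rate_kind_code(model$transitions$kind),
    a = model$transitions$a,
    b = ifelse(model$transitions$kind == "constant", NA_integer_,
               model$transitions$b))
  nst <- length(model$states)
  fast_steady <- function(theta_f) {
    a <- unname(theta_f[tr_idx$a])
    b <- ifelse(is.na(tr_idx$b), 0, unname(theta_f[tr_idx$b]))
    k <- ifelse(tr_idx$kind == 0L, a,
                ifelse(tr_idx$kind == 1L, a * exp(b * protocol$v_hold),
                       a * exp(-b * protocol$v_hold)))
    A <- matrix(0, nst, nst)
    for (r in seq_along(k)) {
      i <- tr_idx$to[r] + 1L
      j <- tr_idx$from[r] + 1L
      A[i, j] <- A[i, j] + k[r]
      A[j, j] <- A[j, j] - k[r]
    }
    red <- reduce_matrix(A)
    x <- tryCatch({
      xr <- solve(red$Ar, -red$br)
      c(xr, 1 - sum(xr))
    }, error = function(e) NULL)
    if (is.null(x) || any(!is.finite(x))) {
      return(steady_state(model, protocol$v_hold, theta_f))
    }
    pmin(pmax(x, 0), 1) / sum(pmin(pmax(x, 0), 1))
  }
  simulate_theta <- function(theta_f, g, idx_times, drive) {
    x0 <- fast_steady(theta_f)
    a <- unname(theta_f[tr_idx$a])
    b <- ifelse(is.na(tr_idx$b), 0, unname(theta_f[tr_idx$b]))
    x <- .propagate_cpp(length(model$states), tr_idx$from, tr_idx$to,
                        tr_idx$kind, a, b, unname(x0),
                        bp[-length(bp)], bp[-1], seg$v_start, seg$v_end,
                        idx_times, 0.5)
    g * x[, model$conducting] * drive
  }
  split_par <- function(theta) {
    if (is.null(fix_g)) {
      list(theta_f = stats::setNames(theta[seq_len(np)],
                                     names(model$theta_f)),
           g = theta[np + 1L])
    } else {
      list(theta_f = stats::setNames(theta, names(model$theta_f)),
           g = fix_g)
    }
  }
  resid_on <- function(theta, idx_times, drive, z) {
    p <- split_par(theta)
    tryCatch(simulate_theta(p$theta_f, p$g, idx_times, drive) - z,
             error = function(e) rep(1e3, length(z)))
  }
  value_on <- function(theta, idx_times, drive, z) {
    p <- split_par(theta)
    if (any(!is.finite(p$theta_f)) || !is.finite(p$g)) return(1e8)
    # graded penalties so the search is always pulled back to feasibility:
    # negative parameters and rate-bound violations rank by their distance
    neg <- sum(pmax(0, -p$theta_f)) + max(0, -p$g)
    if (neg > 0) return(1e7 + 1e3 * neg)
    viol <- rate_bound_violation(model, pmax(p$theta_f, 1e-300), config)
    if (viol > 0) return(1e6 + viol)
    y <- tryCatch(simulate_theta(p$theta_f, p$g, idx_times, drive),
                  error = function(e) NULL)
    if (is.null(y) || any(!is.finite(y))) return(1e7)
    sqrt(mean((y - z)^2))
  }
  list(
    n_par = if (is.null(fix_g)) np + 1L else np,
    split = split_par,
    residuals = function(theta)
      resid_on(theta, tobs_full, drive_full, z_full),
    value = function(theta)
      value_on(theta, tobs_full, drive_full, z_full),
    sresiduals = function(theta)
      resid_on(theta, tobs_full[keep], drive_full[keep], z_full[keep]),
    svalue = function(theta)
      value_on(theta, tobs_full[keep], drive_full[keep], z_full[keep]))
}

# --- compact CMA-ES ((mu/mu_w, lambda), rank-one + rank-mu updates) -------
# No installed R package provides this algorithm; implemented from the
# standard published update equations.  Minimises fn over unscaled R^n.
cma_es_min <- function(fn, x0, sigma0 = 1, popsize = NULL, max_gen = 300,
                       tol = 1e-11, seed = 1) {
  n <- length(x0)
  set.seed(seed)
  lambda <- if (is.null(popsize)) 4L + floor(3 * log(n)) else popsize
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- x0
  sigma <- sigma0
  pc <- ps <- numeric(n)
  B <- diag(n); D <- rep(1, n); C <- diag(n); invsqrtC <- diag(n)
  eigen_age <- 0
  # the start point is a candidate too: warm starts must never be lost to
  # a generation of worse offspring
  best_f <- fn(x0); best_x <- x0; n_eval <- 1
  recent <- rep(NA_real_, 30)

  for (gen in seq_len(max_gen)) {
    arz <- matrix(stats::rnorm(n * lambda), n, lambda)
    ary <- B %*% (D * arz)
    arx <- xmean + sigma * ary
    f <- apply(arx, 2, fn)
    n_eval <- n_eval + lambda
    ord <- order(f)
    if (f[ord[1]] < best_f) {
      best_f <- f[ord[1]]
      best_x <- arx[, ord[1]]
    }
    sel <- ord[seq_len(mu)]
    ymean <- ary[, sel, drop = FALSE] %*% w
    xmean <- xmean + sigma * as.vector(ymean)
    ps <- (1 - cs) * ps +
      sqrt(cs * (2 - cs) * mueff) * as.vector(invsqrtC %*% ymean)
    hsig <- sum(ps^2) / (1 - (1 - cs)^(2 * gen)) / n < 2 + 4 / (n + 1)
    pc <- (1 - cc) * pc +
      hsig * sqrt(cc * (2 - cc) * mueff) * as.vector(ymean)
    artmp <- ary[, sel, drop = FALSE]
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * artmp %*% (w * t(artmp))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    eigen_age <- eigen_age + 1
    if (eigen_age > max(1, floor(1 / (c1 + cmu) / n / 10))) {
      eigen_age <- 0
      C <- (C + t(C)) / 2
      eg <- eigen(C, symmetric = TRUE)
      D <- sqrt(pmax(eg$values, 1e-20))
      B <- eg$vectors
      invsqrtC <- B %*% (t(B) / D)
    }
    recent <- c(recent[-1], best_f)
    if (!anyNA(recent) &&
        (max(recent) - min(recent)) <= tol * max(1, abs(best_f))) break
    if (sigma < 1e-12) break
  }
  list(par = best_x, value = best_f, n_eval = n_eval, generations = gen)
}

# one restart: global stochastic search (optionally on the thinned grid)
# followed by a local least-squares polish; the returned value is always the
# full-grid RMSE so restarts are compared on the actual objective
run_one_restart <- function(obj, model, start, type, config, restart_seed) {
  theta0 <- if (length(start$theta_f) == obj$n_par) {
    unname(start$theta_f)
  } else {
    c(unname(start$theta_f), start$g)
  }
  scales <- search_scales(type)
  phi0 <- to_search(theta0, type) / scales
  fn <- function(psi) obj$svalue(from_search(psi * scales, type))
  res <- cma_es_min(fn, phi0, sigma0 = start$sigma0 %||% 1,
                    popsize = config$cma_popsize,
                    max_gen = config$cma_max_gen,
                    tol = config$tol, seed = restart_seed)
  theta <- from_search(res$par * scales, type)
  value <- res$value
  if (config$polish && value < 1e5) {
    pol <- tryCatch(
      suppressWarnings_nlslm(
        par = res$par,
        fn = function(psi) obj$sresiduals(from_search(psi * scales, type)),
        control = minpack.lm::nls.lm.control(maxiter = 60, ptol = 1e-12,
                                             ftol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(pol)) {
      cand <- from_search(pol$par * scales, type)
      cv <- obj$svalue(cand)
      if (is.finite(cv) && cv < value) {
        theta <- cand
        value <- cv
      }
    }
  }
  full_value <- obj$value(theta)
  list(theta = theta, value = full_value, n_eval = res$n_eval)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# nls.lm hits its iteration cap routinely during staged refinement; the
# associated warning is expected and suppressed
suppressWarnings_nlslm <- function(...) {
  suppressWarnings(minpack.lm::nls.lm(...))
}

deep_polish <- function(obj, theta, type, config, maxiter = 400) {
  scales <- search_scales(type)
  out <- list(theta = theta, value = obj$value(theta))
  pol <- tryCatch(
    suppressWarnings_nlslm(
      par = to_search(theta, type) / scales,
      fn = function(psi) obj$residuals(from_search(psi * scales, type)),
      control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                           ptol = 1e-13, ftol = 1e-15)),
    error = function(e) NULL)
  if (!is.null(pol)) {
    cand <- from_search(pol$par * scales, type)
    cv <- obj$value(cand)
    if (is.finite(cv) && cv < out$value) out <- list(theta = cand, value = cv)
  }
  out
}

new_parameter_estimate <- function(model, theta_f, g, lambda, protocol_name,
                                   rmse_train, restart_log, best_restart,
                                   seed) {
  structure(
    list(model_name = model$name,
         theta_f = stats::setNames(theta_f, names(model$theta_f)),
         g = g, lambda = lambda,
         training_protocol = protocol_name,
         rmse_train = rmse_train,
         n_restarts_used = nrow(restart_log),
         best_restart_index = best_restart,
         restart_log = restart_log,
         seed = seed),
    class = "parameter_estimate")
}

#' @export
print.parameter_estimate <- function(x, ...) {
  cat("<parameter_estimate> ", x$model_name, " trained on ",
      x$training_protocol, "\n  rmse_train = ", format(x$rmse_train),
      " nA, g = ", format(x$g), " uS (lambda = ", x$lambda, "), ",
      x$n_restarts_used, " restarts (best: #", x$best_restart_index, ")\n",
      sep = "")
  invisible(x)
}

#' Fit a Markov model to a dataset by multi-start global optimisation
#'
#' Minimises the RMSE (equivalently, maximises the Gaussian likelihood with
#' known noise) over the kinetic parameters and the maximal conductance.
#' Each restart draws an initial guess from [sample_initial_guess()] and
#' runs a CMA-ES-type stochastic search in transformed coordinates (log for
#' rate scales and the conductance, identity for voltage sensitivities),
#' with the transition-rate box enforced by a large additive penalty,
#' followed by a Levenberg-Marquardt refinement.  The restart with the
#' lowest training RMSE wins; ties break to the lowest restart index.
#'
#' @inheritParams log_likelihood
#' @param config a [fit_config()].
#' @param g_init conductance used for initial guesses (defaults to the
#'   dataset's generating value when recorded, else the model's).
#' @param extra_starts optional list of `list(theta_f, g)` warm starts run
#'   in addition to (and before) the random restarts.
#' @param n_restarts override of `config$n_restarts` (0 = warm starts only).
#' @return a `parameter_estimate`; see also [tidy()][generics::tidy] and
#'   [glance()][generics::glance] methods.
#' @export
fit_model <- function(model, dataset, conditions = ionic_conditions(),
                      config = fit_config(), g_init = NULL,
                      extra_starts = list(), n_restarts = NULL) {
  if (is.null(g_init)) {
    g_init <- attr(dataset, "truth_meta")$g %||% model$g
  }
  fit_engine(model, dataset, conditions, config, fix_g = NULL,
             g_init = g_init, extra_starts = extra_starts,
             n_restarts = n_restarts %||% config$n_restarts, lambda = 1)
}

fit_engine <- function(model, dataset, conditions, config, fix_g, g_init,
                       extra_starts, n_restarts, lambda) {
  obj <- make_objective(model, dataset, conditions, config, fix_g = fix_g)
  type <- param_transforms(model, include_g = is.null(fix_g))
  starts <- extra_starts
  k <- max(1L, as.integer(config$init_candidates %||% 1L))
  for (r in seq_len(n_restarts)) {
    # best-of-k seeding: draw k feasible guesses, start from the best-scoring
    cand_best <- NULL
    for (j in seq_len(k)) {
      s <- sample_initial_guess(model, config, g_init = g_init,
                                seed = (config$seed * 2654435L + 977L * r +
                                          j) %% 2147483647L)
      v <- obj$svalue(if (is.null(fix_g)) c(unname(s$theta_f), s$g)
                      else unname(s$theta_f))
      if (is.null(cand_best) || v < cand_best$v) {
        cand_best <- list(s = s, v = v)
      }
    }
    starts <- c(starts, list(cand_best$s))
  }
  log <- vector("list", length(starts))
  best <- NULL
  for (r in seq_along(starts)) {
    rs <- (config$seed * 1103515L + 7919L * r) %% 2147483647L
    out <- run_one_restart(obj, model, starts[[r]], type, config, rs)
    log[[r]] <- tibble::tibble(restart = r, rmse = out$value,
                               n_eval = out$n_eval)
    if (is.null(best) || out$value < best$value) {
      best <- out
      best$index <- r
    }
  }
  if (is.null(best) || !is.finite(best$value) || best$value >= 1e5) {
    stop("all restarts failed to produce a feasible fit", call. = FALSE)
  }
  if (config$polish) {
    # iterated refinement of the winning restart: alternate a narrow
    # stochastic search with Levenberg-Marquardt on the (thinned) search
    # grid until no further gain — weakly identified models have long
    # curved valleys where a single local polish stalls short of the
    # floor — then one full-grid polish to land on the exact optimum
    scales <- search_scales(type)
    sfn <- function(psi) obj$svalue(from_search(psi * scales, type))
    cur <- list(theta = best$theta, value = obj$svalue(best$theta))
    for (round in 1:2) {
      val0 <- cur$value
      res <- cma_es_min(sfn, to_search(cur$theta, type) / scales,
                        sigma0 = 0.3, popsize = config$cma_popsize,
                        max_gen = 120, tol = config$tol,
                        seed = (config$seed * 7 + 17 * round) %% 2147483647L)
      if (res$value < cur$value) {
        cur$theta <- from_search(res$par * scales, type)
        cur$value <- res$value
      }
      pol <- tryCatch(
        suppressWarnings_nlslm(
          par = to_search(cur$theta, type) / scales,
          fn = function(psi) obj$sresiduals(from_search(psi * scales, type)),
          control = minpack.lm::nls.lm.control(maxiter = 100, ptol = 1e-13,
                                               ftol = 1e-15)),
        error = function(e) NULL)
      if (!is.null(pol)) {
        cand <- from_search(pol$par * scales, type)
        cv <- obj$svalue(cand)
        if (is.finite(cv) && cv < cur$value) cur <- list(theta = cand,
                                                         value = cv)
      }
      if (val0 - cur$value < 1e-6 * max(1, val0)) break
    }
    if (obj$value(cur$theta) < best$value) {
      best$theta <- cur$theta
      best$value <- obj$value(cur$theta)
    }
    deep <- deep_polish(obj, best$theta, type, config, maxiter = 200)
    if (deep$value < best$value) best[c("theta", "value")] <- deep
  }
  p <- obj$split(best$theta)
  new_parameter_estimate(model, p$theta_f, p$g, lambda,
                         attr(dataset, "protocol")$name,
                         rmse_train = obj$value(best$theta),
                         restart_log = dplyr::bind_rows(log),
                         best_restart = best$index, seed = config$seed)
}

#' Conductance-pinned (lambda-restricted) fit
#'
#' Optimises the kinetic parameters only, with the maximal conductance fixed
#' to `lambda * g_ref` — the restriction of the parameter space used to
#' inject a controlled amount of model discrepancy (and identical to a
#' profile-likelihood computation in the conductance).  A supplied
#' `warm_start` and the model's reference kinetics are both included among
#' the starts, so the continuation never does worse than either.
#'
#' @inheritParams fit_model
#' @param lambda positive conductance scale factor.
#' @param g_ref reference conductance (defaults to the dataset's generating
#'   value when recorded, else the model's).
#' @param warm_start optional kinetic parameter vector used as an extra
#'   start (e.g. the previous estimate in a [lambda_sweep()]).
#' @param n_restarts number of random restarts (defaults to the
#'   continuation count in `config`).
#' @return a `parameter_estimate` with `g` exactly `lambda * g_ref`.
#' @export
fit_restricted <- function(model, dataset, conditions = ionic_conditions(),
                           lambda = 1, config = fit_config(),
                           g_ref = NULL, warm_start = NULL,
                           n_restarts = NULL, extra_starts = list()) {
  stopifnot(lambda > 0)
  if (is.null(g_ref)) g_ref <- attr(dataset, "truth_meta")$g %||% model$g
  extra <- c(extra_starts,
             list(list(theta_f = model$theta_f, g = lambda * g_ref,
                       sigma0 = 0.5)))
  if (!is.null(warm_start)) {
    extra <- c(list(list(theta_f = warm_start, g = lambda * g_ref,
                         sigma0 = 0.5)), extra)
  }
  fit_engine(model, dataset, conditions, config, fix_g = lambda * g_ref,
             g_init = lambda * g_ref, extra_starts = extra,
             n_restarts = n_restarts %||% config$n_restarts_continuation,
             lambda = lambda)
}

#' Sequential conductance sweep
#'
#' Fits the pinned-conductance model for each scale factor in `lambdas`,
#' starting at `lambda = 1` and continuing outward in both directions with
#' the previous estimate's kinetics as a warm start (falling back on the
#' reference kinetics when those fit better).
#'
#' @inheritParams fit_restricted
#' @param lambdas ascending vector of positive scale factors containing 1.
#' @param n_restarts_first restarts for the `lambda = 1` fit (defaults to
#'   `config$n_restarts`).
#' @return named list of `parameter_estimate`s, in `lambdas` order.
#' @export
lambda_sweep <- function(model, dataset, conditions = ionic_conditions(),
                         lambdas = c(1 / 4, 1 / 2, 1, 2, 4),
                         config = fit_config(), g_ref = NULL,
                         n_restarts_first = NULL) {
  stopifnot(!is.unsorted(lambdas), any(lambdas == 1))
  if (is.null(g_ref)) g_ref <- attr(dataset, "truth_meta")$g %||% model$g
  i1 <- which(lambdas == 1)[1]
  ests <- vector("list", length(lambdas))
  ests[[i1]] <- fit_restricted(model, dataset, conditions, lambda = 1,
                               config = config, g_ref = g_ref,
                               n_restarts = n_restarts_first %||%
                                 config$n_restarts)
  for (i in seq(i1 + 1, length.out = max(0, length(lambdas) - i1))) {
    ests[[i]] <- fit_restricted(model, dataset, conditions,
                                lambda = lambdas[i], config = config,
                                g_ref = g_ref,
                                warm_start = ests[[i - 1]]$theta_f)
  }
  for (i in seq(i1 - 1, length.out = max(0, i1 - 1), by = -1)) {
    ests[[i]] <- fit_restricted(model, dataset, conditions,
                                lambda = lambdas[i], config = config,
                                g_ref = g_ref,
                                warm_start = ests[[i + 1]]$theta_f)
  }
  stats::setNames(ests, paste0("lambda_", lambdas))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a parameter estimate into a term/estimate tibble
#' @param x a `parameter_estimate`.
#' @param ... unused.
#' @export
tidy.parameter_estimate <- function(x, ...) {
  tibble::tibble(
    term = c(names(x$theta_f), "g"),
    estimate = c(unname(x$theta_f), x$g))
}

#' One-row summary of a parameter estimate
#' @param x a `parameter_estimate`.
#' @param ... unused.
#' @export
glance.parameter_estimate <- function(x, ...) {
  tibble::tibble(
    model = x$model_name,
    training_protocol = x$training_protocol,
    lambda = x$lambda,
    rmse_train = x$rmse_train,
    n_restarts = x$n_restarts_used,
    best_restart = x$best_restart_index,
    seed = x$seed)
}
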