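#' Nernst (reversal) potential for a monovalent cation
#'
#' `E_rev = (R T / F) ln([K_out] / [K_in])`, returned in mV, with
#' `R = 8.314 J mol^-1 K^-1` and `F = 96485 C mol^-1`.
#'
#' @param K_out extracellular K+ concentration (mM), > 0.
#' @param K_in intracellular K+ concentration (mM), > 0.
#' @param temperature absolute temperature (K), > 0.
#' @return reversal potential in mV.
#' @examples
#' nernst(5, 120, 293)  # approximately -80.24 mV
#' @export
nernst <- function(K_out, K_in, temperature = 293) {
  if (any(K_out <= 0) || any(K_in <= 0)) {
    stop("ion concentrations must be positive", call. = FALSE)
  }
  stopifnot(all(temperature > 0))
  1000 * (8.314 * temperature / 96485) * log(K_out / K_in)
}

#' Ionic conditions for current observation
#'
#' Defaults are 120 mM intracellular and 5 mM extracellular potassium with
#' the reversal potential fixed at -80.24 mV.  Note an inconsistency carried
#' over from the source parameterisation: the stated room temperature of
#' 298 K gives `nernst(5, 120, 298) = -81.61` mV, whereas -80.24 mV is the
#' Nernst potential at 293 K.  The packaged default keeps the fixed
#' -80.24 mV value and records `temperature = 298`; pass `E_rev = NULL` to
#' recompute from the stored temperature instead.  Neither value is silently
#' "corrected".
#'
#' @param K_out,K_in potassium concentrations (mM).
#' @param temperature absolute temperature (K).
#' @param E_rev reversal potential (mV); `NULL` to derive via [nernst()].
#' @return an object of class `ionic_conditions`.
#' @export
ionic_conditions <- function(K_out = 5, K_in = 120, temperature = 298,
                             E_rev = -80.24) {
  if (is.null(E_rev)) E_rev <- nernst(K_out, K_in, temperature)
  structure(list(K_out = K_out, K_in = K_in, temperature = temperature,
                 E_rev = E_rev),
            class = "ionic_conditions")
}

#' @export
print.ionic_conditions <- function(x, ...) {
  cat("<ionic_conditions> [K]out =", x$K_out, "mM, [K]in =", x$K_in,
      "mM, T =", x$temperature, "K, E_rev =", x$E_rev, "mV\n")
  invisible(x)
}

#' Solve the model states along a protocol
#'
#' Integrates `dx/dt = A(V(t)) x` from the steady state at the holding
#' potential, restarting at every segment boundary, and returns the state at
#' every observation time.  The default `"analytic"` method uses an exact
#' matrix-exponential propagator on constant-voltage steps and a 4th-order
#' Magnus integrator within ramps (both unconditionally stable); the
#' `"lsoda"` method integrates the conservation-reduced `(N-1)`-dimensional
#' system with `deSolve::lsoda` at absolute/relative tolerance 1e-8 and is
#' retained as an independent cross-check.
#'
#' @param model a [markov_model()].
#' @param protocol a [voltage_protocol()].
#' @param theta_f kinetic parameters (default: the model's).
#' @param method `"analytic"` (default) or `"lsoda"`.
#' @param ramp_substep maximum Magnus step inside ramps (ms).
#' @return an `n_d x N` matrix of occupancies, one column per state.
#' @export
solve_states <- function(model, protocol, theta_f = model$theta_f,
                         method = c("analytic", "lsoda"),
                         ramp_substep = 0.5) {
  method <- match.arg(method)
  tobs <- observation_times(protocol)
  x0 <- steady_state(model, protocol$v_hold, theta_f)
  bp <- segment_breakpoints(protocol)
  seg <- protocol$segments
  if (method == "analytic") {
    tr <- resolved_transitions(model, theta_f)
    x <- .propagate_cpp(length(model$states), tr$from, tr$to, tr$kind,
                        tr$a, tr$b, unname(x0),
                        bp[-length(bp)], bp[-1],
                        seg$v_start, seg$v_end, tobs, ramp_substep)
  } else {
    x <- solve_states_lsoda(model, protocol, theta_f, tobs, bp, x0)
  }
  colnames(x) <- model$states
  bad <- x < -1e-6 | x > 1 + 1e-6
  if (any(bad)) {
    warning("state occupancies outside [0, 1] beyond solver tolerance (",
            sum(bad), " entries)", call. = FALSE)
  }
  x
}

solve_states_lsoda <- function(model, protocol, theta_f, tobs, bp, x0) {
  n <- length(model$states)
  seg <- protocol$segments
  out <- matrix(NA_real_, length(tobs), n)
  xr <- unname(x0)[-n]
  eps <- 1e-9
  iobs <- which(tobs <= bp[1] + eps)
  if (length(iobs) > 0) out[iobs, ] <- rep(c(xr, 1 - sum(xr)), each = length(iobs))
  done <- length(iobs)
  for (s in seq_len(nrow(seg))) {
    t0 <- bp[s]; t1 <- bp[s + 1]
    v0 <- seg$v_start[s]
    slope <- (seg$v_end[s] - v0) / (t1 - t0)
    rhs <- function(t, y, parms) {
      A <- build_rate_matrix(model, v0 + slope * (t - t0), theta_f)
      red <- reduce_matrix(A)
      list(as.vector(red$Ar %*% y + red$br))
    }
    inseg <- which(tobs >= t0 - eps & tobs < t1 - eps)
    times <- sort(unique(round(c(t0, tobs[inseg], t1), 9)))
    sol <- deSolve::lsoda(xr, times, rhs, parms = NULL,
                          rtol = 1e-8, atol = 1e-8)
    if (length(inseg) > 0) {
      rows <- match(round(tobs[inseg], 9), round(sol[, 1], 9))
      xr_obs <- sol[rows, -1, drop = FALSE]
      out[inseg, ] <- cbind(xr_obs, 1 - rowSums(xr_obs))
    }
    xr <- as.numeric(sol[nrow(sol), -1])
  }
  out
}

#' Map a state trajectory to the noise-free current
#'
#' The observation function is `y_i = g * [O](t_i) * (V(t_i) - E_rev)` in nA
#' (conductance in uS times driving force in mV).
#'
#' @param model a [markov_model()].
#' @param x_traj state trajectory from [solve_states()], aligned with the
#'   protocol's observation grid.
#' @param protocol a [voltage_protocol()].
#' @param conditions an [ionic_conditions()].
#' @param g maximal conductance override (uS).
#' @return numeric vector of currents (nA).
#' @export
observe <- function(model, x_traj, protocol, conditions = ionic_conditions(),
                    g = model$g) {
  tobs <- observation_times(protocol)
  if (nrow(x_traj) != length(tobs)) {
    stop("state trajectory is not aligned with the observation grid",
         call. = FALSE)
  }
  open <- x_traj[, model$conducting]
  g * open * (voltage_at(protocol, tobs) - conditions$E_rev)
}

#' Simulate the noise-free current under a protocol
#'
#' @inheritParams observe
#' @inheritParams solve_states
#' @return a tibble with columns `time` (ms), `voltage` (mV), `current` (nA).
#' @export
simulate_current <- function(model, protocol, conditions = ionic_conditions(),
                             theta_f = model$theta_f, g = model$g,
                             method = "analytic") {
  x <- solve_states(model, protocol, theta_f, method = method)
  tobs <- observation_times(protocol)
  tibble::tibble(
    time = tobs,
    voltage = voltage_at(protocol, tobs),
    current = g * x[, model$conducting] * (voltage - conditions$E_rev))
}

#' Generate a synthetic voltage-clamp dataset
#'
#' Adds IID Gaussian noise of known standard deviation `sigma` to the
#' noise-free simulated current, using R's seeded generator so that an
#' identical seed reproduces the dataset bitwise.  The generating model,
#' parameters, `sigma` and seed are recorded in the dataset's metadata.
#'
#' @inheritParams simulate_current
#' @param sigma noise standard deviation (nA), > 0.
#' @param seed integer seed for the noise generator.
#' @return a tibble of class `ion_dataset` with columns `time`, `current`,
#'   and attributes `protocol`, `sigma`, `seed`, `truth_meta` (generating
#'   model name, `theta_f`, `g`, and the noise-free trace).
#' @export
generate_synthetic <- function(model, protocol,
                               conditions = ionic_conditions(),
                               sigma = 0.03, seed = 1,
                               theta_f = model$theta_f, g = model$g) {
  stopifnot(sigma > 0)
  sim <- simulate_current(model, protocol, conditions, theta_f, g)
  set.seed(seed)
  eps <- stats::rnorm(nrow(sim), 0, sigma)
  ds <- tibble::tibble(time = sim$time, current = sim$current + eps)
  new_ion_dataset(ds, protocol, sigma, seed,
                  truth_meta = list(model = model$name, theta_f = theta_f,
                                    g = g, y_true = sim$current))
}

new_ion_dataset <- function(tbl, protocol, sigma, seed, truth_meta = NULL) {
  structure(tbl,
            class = c("ion_dataset", class(tibble::tibble())),
            protocol = protocol, sigma = sigma, seed = seed,
            truth_meta = truth_meta)
}

#' @export
print.ion_dataset <- function(x, ...) {
  p <- attr(x, "protocol")
  cat("<ion_dataset> protocol ", p$name, ", n = ", nrow(x),
      ", sigma = ", attr(x, "sigma"), " nA, seed = ", attr(x, "seed"),
      "\n", sep = "")
  NextMethod()
}

#' Read / write a dataset file
#'
#' The observations are stored as a two-column CSV (`time_ms`,
#' `current_nA`); the metadata (protocol, sigma, seed, generating model and
#' parameters) go to a JSON sidecar at `paste0(path, ".meta.json")` with the
#' protocol embedded so the pair round-trips without external files.
#'
#' @param dataset an `ion_dataset`.
#' @param path CSV path.
#' @return [read_dataset()] returns an `ion_dataset`; [write_dataset()]
#'   returns `path` invisibly.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(
    data.frame(time_ms = dataset$time, current_nA = dataset$current),
    path, row.names = FALSE)
  p <- attr(dataset, "protocol")
  meta <- list(
    protocol = list(name = p$name, v_hold = p$v_hold,
                    sample_rate = p$sample_rate,
                    segments = as.data.frame(p$segments)),
    sigma = attr(dataset, "sigma"),
    seed = attr(dataset, "seed"),
    truth_meta = {
      tm <- attr(dataset, "truth_meta")[c("model", "theta_f", "g")]
      if (!is.null(tm$theta_f)) tm$theta_f <- as.list(tm$theta_f)
      tm
    })
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  tab <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  prot <- voltage_protocol(meta$protocol$name,
                           tibble::as_tibble(meta$protocol$segments),
                           v_hold = meta$protocol$v_hold,
                           sample_rate = meta$protocol$sample_rate)
  tm <- meta$truth_meta
  if (!is.null(tm$theta_f)) tm$theta_f <- unlist(tm$theta_f)
  new_ion_dataset(
    tibble::tibble(time = tab$time_ms, current = tab$current_nA),
    prot, meta$sigma, meta$seed, truth_meta = tm)
}
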