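#' Construct a voltage-dependent transition rate law
#'
#' Transition rates in Markov-state ion channel models are either constant or
#' single-exponential functions of the transmembrane voltage,
#' `k(V) = a * exp(+/- b * V)`, with `a >= 0` (ms^-1) and `b >= 0` (mV^-1).
#' A rate with `a > 0` is therefore strictly positive at every voltage.
#'
#' @param kind one of `"constant"`, `"exp_increasing"` (`a e^{+bV}`) or
#'   `"exp_decreasing"` (`a e^{-bV}`).
#' @param a rate scale (ms^-1), non-negative.
#' @param b voltage sensitivity (mV^-1), non-negative; ignored for constants.
#' @return an object of class `rate_law`.
#' @export
rate_law <- function(kind = c("constant", "exp_increasing", "exp_decreasing"),
                     a, b = 0) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(a), length(a) == 1L, a >= 0, is.finite(a),
            is.numeric(b), length(b) == 1L, b >= 0, is.finite(b))
  structure(list(kind = kind, a = a, b = b), class = "rate_law")
}

#' Evaluate a rate law at a voltage
#'
#' @param law a [rate_law()].
#' @param V voltage (mV), may be a vector.
#' @return transition rate(s) in ms^-1.
#' @export
eval_rate <- function(law, V) {
  k <- switch(law$kind,
    constant = rep(law$a, length(V)),
    exp_increasing = law$a * exp(law$b * V),
    exp_decreasing = law$a * exp(-law$b * V)
  )
  if (any(!is.finite(k))) {
    stop("non-finite transition rate (overflowing exponential) at V = ",
         paste(V[!is.finite(k)], collapse = ", "), call. = FALSE)
  }
  k
}

rate_kind_code <- function(kind) {
  match(kind, c("constant", "exp_increasing", "exp_decreasing")) - 1L
}

#' Define a Markov-state ion channel model
#'
#' A Markov model of a macroscopic ionic current is a linear ODE system over
#' fractional state occupancies, `dx/dt = A(V) x`, whose off-diagonal entries
#' are voltage-dependent transition rates and whose columns sum to zero
#' (channel-count conservation).  Current is carried by a single conducting
#' ("open") state via `I = g * [O] * (V - E_rev)`.
#'
#' Transition rates are parameterised by entries of the kinetic parameter
#' vector `theta_f`: each transition names the `theta_f` index of its rate
#' scale `a` and (for exponential laws) of its voltage sensitivity `b`, so
#' several transitions may share parameters and refitting only requires a new
#' `theta_f`.
#'
#' @param name model identifier.
#' @param states character vector of state labels.
#' @param conducting_state label (or index) of the open state.
#' @param transitions a data frame with columns `from`, `to` (state labels),
#'   `kind` (rate-law kind), `a` (index into `theta_f` of the rate scale) and
#'   `b` (index of the voltage sensitivity; `NA` for constants).
#' @param theta_f named numeric vector of kinetic parameters (positive).
#' @param g maximal conductance (uS).
#' @return an object of class `markov_model`.
#' @seealso [beattie_model()], [wang_model()], [build_rate_matrix()],
#'   [steady_state()]
#' @export
markov_model <- function(name, states, conducting_state, transitions,
                         theta_f, g) {
  stopifnot(is.character(states), length(states) >= 1L,
            !anyDuplicated(states))
  transitions <- tibble::as_tibble(transitions)
  stopifnot(all(c("from", "to", "kind", "a") %in% names(transitions)))
  if (!"b" %in% names(transitions)) transitions$b <- NA_integer_
  bad <- setdiff(c(transitions$from, transitions$to), states)
  if (length(bad) > 0) {
    stop("transition references unknown state(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  stopifnot(all(transitions$kind %in%
                  c("constant", "exp_increasing", "exp_decreasing")))
  stopifnot(is.numeric(theta_f), all(is.finite(theta_f)), all(theta_f >= 0))
  idx <- c(transitions$a, transitions$b[transitions$kind != "constant"])
  stopifnot(all(idx >= 1L), all(idx <= length(theta_f)))
  if (is.character(conducting_state)) {
    conducting_state <- match(conducting_state, states)
  }
  stopifnot(!is.na(conducting_state),
            conducting_state >= 1L, conducting_state <= length(states))
  stopifnot(is.numeric(g), length(g) == 1L, g >= 0)
  m <- structure(
    list(name = name, states = states,
         conducting = as.integer(conducting_state),
         transitions = transitions,
         theta_f = theta_f, g = g),
    class = "markov_model")
  if (!is_connected(m)) {
    stop("transition graph is disconnected: steady state not unique",
         call. = FALSE)
  }
  m
}

#' @export
print.markov_model <- function(x, ...) {
  cat("<markov_model> ", x$name, "\n", sep = "")
  cat("  states: ", paste(x$states, collapse = ", "),
      " (open: ", x$states[x$conducting], ")\n", sep = "")
  cat("  ", nrow(x$transitions), " transitions, ",
      length(x$theta_f), " kinetic parameters, g = ",
      format(x$g), " uS\n", sep = "")
  invisible(x)
}

#' Number of states of a model
#' @param model a [markov_model()].
#' @return integer count of states.
#' @export
n_states <- function(model) length(model$states)

is_connected <- function(model) {
  n <- length(model$states)
  if (n == 1L) return(TRUE)
  adj <- matrix(FALSE, n, n)
  i <- match(model$transitions$from, model$states)
  j <- match(model$transitions$to, model$states)
  adj[cbind(i, j)] <- TRUE
  adj[cbind(j, i)] <- TRUE  # undirected reachability
  seen <- c(1L)
  repeat {
    nb <- which(apply(adj[seen, , drop = FALSE], 2, any))
    new <- setdiff(nb, seen)
    if (length(new) == 0) break
    seen <- c(seen, new)
  }
  length(seen) == n
}

# transition table with integer state indices and resolved (a, b) values
resolved_transitions <- function(model, theta_f = model$theta_f) {
  tr <- model$transitions
  list(
    from = match(tr$from, model$states) - 1L,
    to = match(tr$to, model$states) - 1L,
    kind = rate_kind_code(tr$kind),
    a = theta_f[tr$a],
    b = ifelse(tr$kind == "constant", 0, theta_f[tr$b])
  )
}

#' Build the transition rate matrix at a fixed voltage
#'
#' Assembles `A(V)` such that `dx/dt = A(V) x`: entry `A[i, j]` for `i != j`
#' is the `j -> i` transition rate at voltage `V`, and diagonal entries are
#' set so every column sums to zero, which encodes conservation of the total
#' channel count.
#'
#' @param model a [markov_model()].
#' @param V voltage (mV), scalar and finite.
#' @param theta_f optional kinetic parameter vector overriding the model's.
#' @return an `N x N` numeric matrix with zero column sums.
#' @export
build_rate_matrix <- function(model, V, theta_f = model$theta_f) {
  stopifnot(is.numeric(V), length(V) == 1L, is.finite(V))
  n <- length(model$states)
  A <- matrix(0, n, n, dimnames = list(model$states, model$states))
  tr <- model$transitions
  for (r in seq_len(nrow(tr))) {
    law <- rate_law(tr$kind[r], theta_f[tr$a[r]],
                    if (tr$kind[r] == "constant") 0 else theta_f[tr$b[r]])
    k <- eval_rate(law, V)
    i <- match(tr$to[r], model$states)
    j <- match(tr$from[r], model$states)
    A[i, j] <- A[i, j] + k
    A[j, j] <- A[j, j] - k
  }
  A
}

#' Steady-state occupancy at a fixed voltage
#'
#' Solves `A(V) x = 0` subject to `sum(x) = 1`.  `A` is singular by
#' construction (conservation), so the solve uses the conservation-reduced
#' `(N-1)`-dimensional linear system; if that reduced matrix is
#' ill-conditioned the nullspace is extracted by SVD instead.
#'
#' @inheritParams build_rate_matrix
#' @return numeric occupancy vector summing to 1, entries in `[0, 1]`.
#' @export
steady_state <- function(model, V, theta_f = model$theta_f) {
  n <- length(model$states)
  if (n == 1L) return(stats::setNames(1, model$states))
  A <- build_rate_matrix(model, V, theta_f)
  red <- reduce_matrix(A)
  x <- tryCatch({
    xr <- solve(red$Ar, -red$br)
    c(xr, 1 - sum(xr))
  }, error = function(e) NULL)
  if (is.null(x) || any(!is.finite(x)) ||
      max(abs(A %*% x)) > 1e-8 * max(1, max(abs(A)))) {
    # nullspace fallback for ill-conditioned reductions
    sv <- svd(A)
    v <- sv$v[, n]
    x <- v / sum(v)
  }
  x <- pmin(pmax(x, 0), 1)
  x <- x / sum(x)
  stats::setNames(x, model$states)
}

# reduced affine form: eliminating state N via x_N = 1 - sum(x_1..x_{N-1})
# gives dx_r/dt = Ar x_r + br
reduce_matrix <- function(A) {
  n <- nrow(A)
  keep <- seq_len(n - 1L)
  Ar <- A[keep, keep, drop = FALSE] -
    matrix(A[keep, n], n - 1L, n - 1L, byrow = FALSE)
  br <- A[keep, n]
  list(Ar = Ar, br = br)
}

#' Conservation-reduced ODE description
#'
#' Channel-count conservation makes one state redundant: with
#' `x_N = 1 - sum(x_1, ..., x_{N-1})` the dynamics become the
#' `(N-1)`-dimensional affine system `dx_r/dt = Ar(V) x_r + br(V)`.
#' The returned closure evaluates `Ar` and `br` at any voltage; the
#' eliminated (last) state is recovered as `1 - sum(x_r)`.
#'
#' @inheritParams build_rate_matrix
#' @return a list with elements `dim` (`N - 1`), `eliminated` (index of the
#'   dropped state), and `affine(V)` returning `list(Ar, br)`.
#' @export
reduce_system <- function(model, theta_f = model$theta_f) {
  n <- length(model$states)
  list(
    dim = n - 1L,
    eliminated = n,
    affine = function(V) reduce_matrix(build_rate_matrix(model, V, theta_f))
  )
}
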