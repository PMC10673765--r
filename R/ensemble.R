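#' Train an ensemble of per-protocol parameter estimates
#'
#' Fits the model independently to one dataset per training protocol and
#' collects the estimates.  The variability of this ensemble's predictions
#' for unseen protocols is the empirical discrepancy signal: for a correctly
#' specified model the members agree up to noise, while a discrepant model
#' is pulled to different compromises by different protocols.
#'
#' @param model a [markov_model()].
#' @param datasets list of `ion_dataset`s, one per (distinct) training
#'   protocol.
#' @param conditions an [ionic_conditions()].
#' @param config a [fit_config()].
#' @param lambda optional conductance scale; when supplied the members are
#'   conductance-pinned fits ([fit_restricted()]) instead of free fits.
#' @param share_starts when `TRUE`, each fitted member's estimate is added
#'   to the start list of subsequent members (an optimisation heuristic
#'   applied uniformly to every model; each member still minimises its own
#'   protocol's objective over the same multi-start search).
#' @param ... passed on to the member fitting function.
#' @return an object of class `protocol_ensemble`.
#' @export
train_ensemble <- function(model, datasets, conditions = ionic_conditions(),
                           config = fit_config(), lambda = NULL,
                           share_starts = FALSE, ...) {
  names_d <- vapply(datasets, function(d) attr(d, "protocol")$name, "")
  if (anyDuplicated(names_d)) {
    stop("training protocols must be distinct", call. = FALSE)
  }
  members <- vector("list", length(datasets))
  failures <- character(0)
  shared <- list()
  for (i in seq_along(datasets)) {
    members[[i]] <- tryCatch({
      if (is.null(lambda)) {
        fit_model(model, datasets[[i]], conditions, config,
                  extra_starts = shared, ...)
      } else {
        fit_restricted(model, datasets[[i]], conditions, lambda = lambda,
                       config = config, extra_starts = shared, ...)
      }
    }, error = function(e) {
      failures <<- c(failures, paste0(names_d[i], ": ", conditionMessage(e)))
      NULL
    })
    if (share_starts && !is.null(members[[i]])) {
      shared <- c(shared, list(list(theta_f = members[[i]]$theta_f,
                                    g = members[[i]]$g, sigma0 = 0.5)))
    }
  }
  if (length(failures) > 0) {
    stop("ensemble training failed for member(s):\n  ",
         paste(failures, collapse = "\n  "), call. = FALSE)
  }
  new_ensemble(members, model, names_d)
}

new_ensemble <- function(members, model, protocol_names) {
  stopifnot(length(members) >= 1)
  structure(list(members = members, model = model,
                 training_protocols = protocol_names),
            class = "protocol_ensemble")
}

#' Assemble an ensemble from existing estimates
#'
#' @param members list of `parameter_estimate`s with distinct training
#'   protocols.
#' @param model the fitted [markov_model()].
#' @return a `protocol_ensemble`.
#' @export
ensemble_from_estimates <- function(members, model) {
  nm <- vapply(members, function(m) m$training_protocol, "")
  if (anyDuplicated(nm)) {
    stop("ensemble members must come from distinct training protocols",
         call. = FALSE)
  }
  new_ensemble(members, model, nm)
}

#' @export
print.protocol_ensemble <- function(x, ...) {
  cat("<protocol_ensemble> ", length(x$members), " members of model '",
      x$model$name, "'\n  trained on: ",
      paste(x$training_protocols, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy an ensemble into a long estimate table
#' @param x a `protocol_ensemble`.
#' @param ... unused.
#' @export
tidy.protocol_ensemble <- function(x, ...) {
  purrr::map_dfr(x$members, function(m) {
    dplyr::mutate(tidy(m), training_protocol = m$training_protocol,
                  lambda = m$lambda, .before = 1)
  })
}

#' Per-member fit summaries for an ensemble
#' @param x a `protocol_ensemble`.
#' @param ... unused.
#' @export
glance.protocol_ensemble <- function(x, ...) {
  purrr::map_dfr(x$members, glance)
}

#' Spread-of-prediction band for a validation protocol
#'
#' Simulates every ensemble member (noise-free) on the validation protocol
#' and takes the elementwise minimum and maximum as the band envelope; the
#' per-time midpoint `(lower + upper) / 2` is the ensemble point prediction.
#' The band cannot shrink as members are added.
#'
#' @param ensemble a `protocol_ensemble`.
#' @param protocol the validation [voltage_protocol()].
#' @param conditions an [ionic_conditions()].
#' @param keep_members keep the per-member prediction matrix (default TRUE).
#' @param level optional central coverage level in (0, 1); when supplied the
#'   envelope uses the per-time `(1 - level)/2` and `(1 + level)/2` member
#'   quantiles instead of the min/max (useful only with many members; the
#'   default min/max is the defining construction).
#' @return a tibble of class `prediction_band` with columns `time`, `lower`,
#'   `mid`, `upper`, and attributes `validation_protocol` and (optionally)
#'   `member_predictions` (an `n_d x n_members` matrix).
#' @export
predict_ensemble <- function(ensemble, protocol,
                             conditions = ionic_conditions(),
                             keep_members = TRUE, level = NULL) {
  preds <- lapply(seq_along(ensemble$members), function(i) {
    m <- ensemble$members[[i]]
    tryCatch(
      simulate_current(ensemble$model, protocol, conditions,
                       theta_f = m$theta_f, g = m$g)$current,
      error = function(e) {
        stop("prediction failed for member '", m$training_protocol, "': ",
             conditionMessage(e), call. = FALSE)
      })
  })
  P <- do.call(cbind, preds)
  colnames(P) <- ensemble$training_protocols
  if (is.null(level)) {
    lower <- apply(P, 1, min)
    upper <- apply(P, 1, max)
  } else {
    stopifnot(is.numeric(level), length(level) == 1L, level > 0, level < 1)
    lower <- apply(P, 1, stats::quantile, probs = (1 - level) / 2)
    upper <- apply(P, 1, stats::quantile, probs = (1 + level) / 2)
  }
  band <- tibble::tibble(
    time = observation_times(protocol),
    lower = lower, mid = (lower + upper) / 2, upper = upper)
  structure(band,
            class = c("prediction_band", class(tibble::tibble())),
            validation_protocol = protocol$name,
            member_predictions = if (keep_members) P else NULL)
}

#' Cross-validation RMSE matrix over protocol pairs
#'
#' Entry `(d, d_tilde)` is the RMSE of the prediction made with the
#' parameters trained on protocol `d` against the (noisy) data observed
#' under protocol `d_tilde`.  When `d_tilde = d` and the same dataset is
#' used, the entry equals the member's training RMSE.  For a correctly
#' specified model every entry sits at the noise floor `sigma`.
#'
#' @param ensemble a `protocol_ensemble`.
#' @param datasets named-or-ordered list of `ion_dataset`s covering every
#'   validation protocol of interest (training protocols included);
#'   alternatively a list of lists for noise-seed replicates per protocol.
#' @param conditions an [ionic_conditions()].
#' @return a tibble of class `crossval_matrix` with columns `train`,
#'   `validation`, `rmse` (mean over replicates), `rmse_sd` and
#'   `n_replicates`.
#' @export
crossval <- function(ensemble, datasets, conditions = ionic_conditions()) {
  # normalise to one list of replicate-lists per validation protocol
  reps <- lapply(datasets, function(d) if (inherits(d, "ion_dataset")) list(d) else d)
  val_names <- vapply(reps, function(r) attr(r[[1]], "protocol")$name, "")
  rows <- list()
  for (j in seq_along(reps)) {
    prot <- attr(reps[[j]][[1]], "protocol")
    preds <- lapply(ensemble$members, function(m) {
      simulate_current(ensemble$model, prot, conditions,
                       theta_f = m$theta_f, g = m$g)$current
    })
    for (i in seq_along(ensemble$members)) {
      r_vals <- vapply(reps[[j]], function(d) rmse(preds[[i]], d$current),
                       numeric(1))
      rows[[length(rows) + 1]] <- tibble::tibble(
        train = ensemble$training_protocols[i],
        validation = val_names[j],
        rmse = mean(r_vals),
        rmse_sd = if (length(r_vals) > 1) stats::sd(r_vals) else NA_real_,
        n_replicates = length(r_vals))
    }
  }
  structure(dplyr::bind_rows(rows),
            class = c("crossval_matrix", class(tibble::tibble())))
}

#' Band coverage of a noise-free truth trace
#'
#' Flags, per observation, whether the true (noise-free) data-generating
#' current lies inside the spread-of-prediction envelope, and summarises the
#' fraction covered.  The band is a heuristic range of plausible
#' predictions, not a calibrated credible interval, so coverage well below 1
#' is expected under structural discrepancy.
#'
#' @param band a `prediction_band`.
#' @param truth numeric vector of noise-free DGP currents on the band's
#'   observation grid.
#' @return list with `flags` (logical vector) and `fraction` (scalar).
#' @export
band_coverage <- function(band, truth) {
  if (length(truth) != nrow(band)) {
    stop("truth trace is not aligned with the band's observation grid",
         call. = FALSE)
  }
  flags <- truth >= band$lower & truth <= band$upper
  list(flags = flags, fraction = mean(flags))
}

#' Band width summaries
#'
#' @param band a `prediction_band`.
#' @return list with `width` (per-time, nA), `max`, and `mean`.
#' @export
band_width_summary <- function(band) {
  w <- band$upper - band$lower
  list(width = w, max = max(w), mean = mean(w))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spread-of-prediction band
#' @param object a `prediction_band`.
#' @param data optional `ion_dataset` overlaid as observations.
#' @param ... unused.
#' @export
autoplot.prediction_band <- function(object, data = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "goldenrod", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mid), colour = "grey20") +
    ggplot2::labs(x = "time (ms)", y = "current (nA)",
                  title = paste("Spread of predictions:",
                                attr(object, "validation_protocol")))
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(time = data$time, current = data$current),
      ggplot2::aes(x = .data$time, y = .data$current),
      size = 0.2, alpha = 0.3, colour = "grey50")
  }
  p
}

#' Plot a cross-validation heatmap
#' @param object a `crossval_matrix`.
#' @param ... unused.
#' @export
autoplot.crossval_matrix <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$validation, y = .data$train,
                                       fill = log10(.data$rmse))) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$rmse, 2)),
                       size = 3, colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "validation protocol", y = "training protocol",
                  fill = "log10 RMSE (nA)")
}

#' @importFrom rlang .data
NULL
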