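#' Run manifest for provenance
#'
#' Every driver records the command, a configuration snapshot, the root
#' seed, the package version and a timestamp; reruns with an identical
#' manifest reproduce identical result tables on one platform.
#'
#' @param command character label of the invoking command.
#' @param config configuration object (list-like); stored minus bulky
#'   non-scalar members.
#' @param inputs optional named character vector of input file paths;
#'   content digests are recorded.
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(command, config = list(), inputs = character()) {
  snap <- config
  snap$protocols <- NULL
  snap$fit <- if (!is.null(config$fit)) unclass(config$fit) else NULL
  snap$conditions <- if (!is.null(config$conditions))
    unclass(config$conditions) else NULL
  digests <- vapply(inputs, function(p) {
    if (file.exists(p)) {
      as.character(sum(utf8ToInt(paste(readLines(p, warn = FALSE),
                                       collapse = "\n"))))
    } else NA_character_
  }, "")
  structure(list(
    command = command,
    config = snap,
    seed = config$seed %||% NA,
    package_version = as.character(utils::packageVersion("channeluq")),
    input_digests = digests,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
}

#' Write a manifest to JSON
#' @param manifest a [run_manifest()].
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}

config_keys <- function() {
  list(sigma = 0.03, seed = 1, preset = "desk", n_noise_repeats = NA_real_,
       n_restarts = NA_real_, n_restarts_continuation = NA_real_,
       lambdas = NA_real_, rate_bound_low = 1.67e-5, rate_bound_high = 1e3,
       init_low_exp = -7, init_high_exp = -1)
}

#' Load a flat key-value configuration file
#'
#' Lines of the form `key: value` (or `key = value`); `#` comments and
#' blank lines are ignored.  Unknown keys are rejected by name; omitted
#' keys take the package defaults (sigma 0.03 nA, desk preset, the
#' conductance-scale grid, and the transition-rate bounds).  `lambdas` may
#' be a comma-separated list.
#'
#' @param path config file path.
#' @return named list of validated configuration values.
#' @export
load_config <- function(path) {
  defaults <- config_keys()
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- defaults
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[:=]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("unparseable config line: '", ln, "'", call. = FALSE)
    key <- m[2]; val <- trimws(m[3])
    if (!key %in% names(defaults)) {
      stop("unknown configuration key: '", key, "'", call. = FALSE)
    }
    out[[key]] <- if (key == "preset") {
      val
    } else if (identical(toupper(val), "NA")) {
      NA_real_
    } else {
      parsed <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
      if (anyNA(parsed)) {
        stop("configuration error: non-numeric value for '", key, "'",
             call. = FALSE)
      }
      parsed
    }
  }
  if (!is.na(out$sigma[1]) && out$sigma <= 0) {
    stop("configuration error: 'sigma' must be > 0", call. = FALSE)
  }
  if (!out$preset %in% c("desk", "full")) {
    stop("configuration error: 'preset' must be 'desk' or 'full'",
         call. = FALSE)
  }
  out
}

#' Write a configuration back to file
#' @param config named list as returned by [load_config()].
#' @param path output path.
#' @export
dump_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    paste0(k, ": ", paste(v, collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

cli_usage <- function() {
  paste(
    "usage: channeluq <command> [options]",
    "commands:",
    "  validate-protocol <protocol.csv>",
    "  simulate <model.json> <protocol.csv> <sigma> <seed> <out.csv>",
    "  fit <model.json> <dataset.csv> <out.json> [--lambda L] [--restarts N] [--seed S]",
    "  ensemble <model.json> <out_dir> <training.csv>... --validate <protocol.csv> [--seed S]",
    "  case1 [--preset desk|full] [--seed S] [--outdir DIR]",
    "  case2 [--preset desk|full] [--seed S] [--outdir DIR]",
    "  toy [--seed S] [--outdir DIR]",
    sep = "\n")
}

cli_opt <- function(args, flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 0) return(default)
  args[i[1] + 1]
}

#' Command-line entry point
#'
#' A thin shell over the package functions (see `inst/cli/channeluq` for the
#' Rscript wrapper).  Subcommands: `validate-protocol`, `simulate`, `fit`,
#' `ensemble`, `case1`, `case2`, `toy`.  Returns 0 on success, 2 on usage
#' errors and 1 on computational failure; every run that writes results
#' also writes a JSON manifest next to them.
#'
#' @param argv character vector of arguments (excluding the program name).
#' @return integer exit status, invisibly.
#' @export
cluq_main <- function(argv = character()) {
  if (length(argv) == 0) {
    message(cli_usage())
    return(invisible(2L))
  }
  cmd <- argv[1]
  args <- argv[-1]
  status <- tryCatch({
    switch(cmd,
      "validate-protocol" = cli_validate_protocol(args),
      "simulate" = cli_simulate(args),
      "fit" = cli_fit(args),
      "ensemble" = cli_ensemble(args),
      "case1" = cli_case(args, run_case1, "I"),
      "case2" = cli_case(args, run_case2, "II"),
      "toy" = cli_toy(args),
      {
        message("unknown command '", cmd, "'\n", cli_usage())
        2L
      })
  }, usage_error = function(e) {
    message(conditionMessage(e), "\n", cli_usage())
    2L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

usage_stop <- function(msg) {
  stop(structure(class = c("usage_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

cli_validate_protocol <- function(args) {
  if (length(args) < 1) usage_stop("validate-protocol needs a file")
  p <- read_protocol(args[1])
  tobs <- observation_times(p)
  v <- c(p$segments$v_start, p$segments$v_end)
  cat("protocol:", p$name, "\n")
  cat("t_dur:", protocol_duration(p), "ms\n")
  cat("n_d:", length(tobs), "\n")
  cat("voltage range: [", min(v), ",", max(v), "] mV\n")
  0L
}

cli_simulate <- function(args) {
  if (length(args) < 5) usage_stop("simulate needs model, protocol, sigma, seed, out")
  model <- read_markov_model(args[1])
  prot <- read_protocol(args[2])
  ds <- generate_synthetic(model, prot, sigma = as.numeric(args[3]),
                           seed = as.integer(args[4]))
  write_dataset(ds, args[5])
  write_manifest(run_manifest("simulate",
                              list(sigma = as.numeric(args[3]),
                                   seed = as.integer(args[4])),
                              inputs = args[1:2]),
                 paste0(args[5], ".manifest.json"))
  0L
}

cli_fit <- function(args) {
  if (length(args) < 3) usage_stop("fit needs model, dataset, out")
  model <- read_markov_model(args[1])
  ds <- read_dataset(args[2])
  seed <- as.integer(cli_opt(args, "--seed", "1"))
  restarts <- as.integer(cli_opt(args, "--restarts", "5"))
  lam <- cli_opt(args, "--lambda", NULL)
  cfg <- fit_config(n_restarts = restarts, seed = seed)
  est <- if (is.null(lam)) {
    fit_model(model, ds, config = cfg)
  } else {
    fit_restricted(model, ds, lambda = as.numeric(lam), config = cfg,
                   n_restarts = restarts)
  }
  out <- c(as.list(glance(est)),
           list(theta = as.list(est$theta_f), g = est$g,
                restart_log = est$restart_log))
  jsonlite::write_json(out, args[3], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  0L
}

cli_ensemble <- function(args) {
  val_path <- cli_opt(args, "--validate", NULL)
  seed <- as.integer(cli_opt(args, "--seed", "1"))
  restarts <- as.integer(cli_opt(args, "--restarts", "5"))
  flag_idx <- which(startsWith(args, "--"))
  drop <- c(flag_idx, flag_idx + 1)
  pos <- args[setdiff(seq_along(args), drop)]
  if (length(pos) < 3 || is.null(val_path)) {
    usage_stop("ensemble needs model, out_dir, training datasets and --validate")
  }
  model <- read_markov_model(pos[1])
  outdir <- pos[2]
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  datasets <- lapply(pos[-(1:2)], read_dataset)
  cfg <- fit_config(n_restarts = restarts, seed = seed, search_thin = 3L)
  ens <- train_ensemble(model, datasets, config = cfg, share_starts = TRUE)
  val_prot <- read_protocol(val_path)
  band <- predict_ensemble(ens, val_prot)
  P <- attr(band, "member_predictions")
  band_tab <- cbind(data.frame(time_ms = band$time, lower_nA = band$lower,
                               mid_nA = band$mid, upper_nA = band$upper),
                    stats::setNames(as.data.frame(P), colnames(P)))
  utils::write.csv(band_tab, file.path(outdir, "band.csv"),
                   row.names = FALSE)
  utils::write.csv(crossval(ens, datasets),
                   file.path(outdir, "crossval.csv"), row.names = FALSE)
  utils::write.csv(tidy(ens), file.path(outdir, "estimates.csv"),
                   row.names = FALSE)
  write_manifest(run_manifest("ensemble", list(seed = seed),
                              inputs = c(pos[1], val_path)),
                 file.path(outdir, "manifest.json"))
  0L
}

cli_case <- function(args, runner, case) {
  preset <- cli_opt(args, "--preset", "desk")
  seed <- as.integer(cli_opt(args, "--seed", "1"))
  outdir <- cli_opt(args, "--outdir", ".")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- runner(case_config(case, preset = preset, seed = seed))
  for (nm in setdiff(names(res), c("bands", "manifest", "truth"))) {
    utils::write.csv(res[[nm]], file.path(outdir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  write_manifest(res$manifest, file.path(outdir, "manifest.json"))
  0L
}

cli_toy <- function(args) {
  seed <- as.integer(cli_opt(args, "--seed", "1"))
  outdir <- cli_opt(args, "--outdir", ".")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  designs <- toy_designs()
  rows <- list()
  fits <- list()
  for (nm in names(designs)) {
    z <- toy_sample(designs[[nm]], seed = seed + match(nm, names(designs)))
    f <- toy_fit(designs[[nm]], z$z)
    fits[[nm]] <- f
    rows[[nm]] <- tibble::tibble(design = nm, n = length(designs[[nm]]),
                                 theta1 = f$theta[1], theta2 = f$theta[2],
                                 rmse = f$rmse)
  }
  utils::write.csv(dplyr::bind_rows(rows),
                   file.path(outdir, "toy_estimates.csv"), row.names = FALSE)
  band <- toy_predict_band(fits)
  utils::write.csv(band, file.path(outdir, "toy_band.csv"), row.names = FALSE)
  write_manifest(run_manifest("toy", list(seed = seed)),
                 file.path(outdir, "manifest.json"))
  0L
}
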