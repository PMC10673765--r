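#' Define a voltage-clamp protocol
#'
#' A protocol is an ordered sequence of segments, each either a constant
#' voltage step (`v_start == v_end`) or a linear ramp, preceded and followed
#' by equilibration at the holding potential.  Current is observed on an
#' equally spaced half-open grid `[0, t_dur)` at `sample_rate` observations
#' per millisecond, so the observation count is exactly
#' `n_d = sample_rate * t_dur`.
#'
#' @param name protocol identifier.
#' @param segments data frame with columns `duration` (ms, > 0), `v_start`
#'   and `v_end` (mV, within `[-120, 60]`).
#' @param v_hold holding potential (mV), default -80.
#' @param sample_rate observations per ms; default 10 (i.e. 10 kHz).
#' @return an object of class `voltage_protocol`.
#' @export
voltage_protocol <- function(name, segments, v_hold = -80, sample_rate = 10) {
  segments <- tibble::as_tibble(segments)
  stopifnot(all(c("duration", "v_start", "v_end") %in% names(segments)))
  segments <- segments[c("duration", "v_start", "v_end")]
  if (nrow(segments) == 0) {
    stop("protocol must contain at least one segment", call. = FALSE)
  }
  if (any(segments$duration <= 0)) {
    stop("all segment durations must be > 0", call. = FALSE)
  }
  v <- c(segments$v_start, segments$v_end, v_hold)
  if (any(v < -120 | v > 60)) {
    stop("segment voltages must lie within [-120, 60] mV", call. = FALSE)
  }
  stopifnot(sample_rate > 0)
  structure(
    list(name = name, v_hold = v_hold, sample_rate = sample_rate,
         segments = segments),
    class = "voltage_protocol")
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat("<voltage_protocol> ", x$name, "\n", sep = "")
  cat("  ", nrow(x$segments), " segments, t_dur = ", protocol_duration(x),
      " ms, V_hold = ", x$v_hold, " mV, ", x$sample_rate * 1000,
      " Hz sampling (n_d = ", length(observation_times(x)), ")\n", sep = "")
  invisible(x)
}

#' Total protocol duration in ms
#' @param protocol a [voltage_protocol()].
#' @return duration in ms.
#' @export
protocol_duration <- function(protocol) sum(protocol$segments$duration)

#' Segment boundary times
#'
#' Cumulative segment durations, prefixed with 0.  The simulator restarts
#' integration at every boundary so voltage discontinuities never fall inside
#' an integration interval.
#'
#' @param protocol a [voltage_protocol()].
#' @return numeric vector of boundary times (ms), length `n_segments + 1`.
#' @export
segment_breakpoints <- function(protocol) {
  c(0, cumsum(protocol$segments$duration))
}

#' Evaluate the protocol voltage at given times
#'
#' Right-continuous piecewise evaluation: a time inside a step returns the
#' constant voltage, a time inside a ramp is linearly interpolated, and times
#' before 0 or at/after the protocol end return the holding potential.
#'
#' @param protocol a [voltage_protocol()].
#' @param t time(s) in ms.
#' @return voltage(s) in mV.
#' @export
voltage_at <- function(protocol, t) {
  bp <- segment_breakpoints(protocol)
  tdur <- bp[length(bp)]
  seg <- findInterval(t, bp, rightmost.closed = FALSE)
  out <- rep(protocol$v_hold, length(t))
  inside <- t >= 0 & t < tdur
  s <- seg[inside]
  frac <- (t[inside] - bp[s]) / protocol$segments$duration[s]
  out[inside] <- protocol$segments$v_start[s] +
    frac * (protocol$segments$v_end[s] - protocol$segments$v_start[s])
  out
}

#' Observation time grid
#'
#' Returns `t_i = i / sample_rate` for `i = 0, ..., n_d - 1`, a half-open
#' grid on `[0, t_dur)` so that the count is exactly
#' `sample_rate * t_dur`.  If the duration is not a multiple of the sampling
#' interval the grid is truncated to the floor and a warning is issued.
#'
#' @param protocol a [voltage_protocol()].
#' @return strictly increasing numeric vector of times (ms).
#' @export
observation_times <- function(protocol) {
  n_exact <- protocol$sample_rate * protocol_duration(protocol)
  n <- floor(n_exact + 1e-9)
  if (abs(n_exact - n) > 1e-9) {
    warning("protocol duration is not a multiple of the sampling interval; ",
            "observation grid truncated to ", n, " points", call. = FALSE)
  }
  seq(0, by = 1 / protocol$sample_rate, length.out = n)
}

#' Read / write a voltage protocol file
#'
#' The file format is a CSV segment table (columns `duration_ms`,
#' `v_start_mV`, `v_end_mV`; comma separated, dot decimal, header row)
#' preceded by `#`-prefixed header lines carrying `name`, `v_hold` and
#' `sample_rate`.  Round-trips losslessly; invariants are validated on load.
#'
#' @param path file path.
#' @return [read_protocol()] returns a [voltage_protocol()];
#'   [write_protocol()] returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop("protocol file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  field <- function(key, default = NULL) {
    m <- grep(paste0("^#\\s*", key, "\\s*:"), hdr, value = TRUE)
    if (length(m) == 0) {
      if (is.null(default)) stop("protocol file missing header '", key, "'",
                                 call. = FALSE)
      return(default)
    }
    trimws(sub(paste0("^#\\s*", key, "\\s*:"), "", m[1]))
  }
  tab <- utils::read.csv(text = lines[!grepl("^#", lines)])
  need <- c("duration_ms", "v_start_mV", "v_end_mV")
  if (!all(need %in% names(tab))) {
    stop("protocol file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  voltage_protocol(
    name = field("name"),
    segments = tibble::tibble(duration = tab$duration_ms,
                              v_start = tab$v_start_mV,
                              v_end = tab$v_end_mV),
    v_hold = as.numeric(field("v_hold", "-80")),
    sample_rate = as.numeric(field("sample_rate", "10")))
}

#' @rdname read_protocol
#' @param protocol a [voltage_protocol()].
#' @export
write_protocol <- function(protocol, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# name: ", protocol$name),
    paste0("# v_hold: ", format(protocol$v_hold, digits = 15)),
    paste0("# sample_rate: ", format(protocol$sample_rate, digits = 15)),
    "duration_ms,v_start_mV,v_end_mV"), con)
  seg <- protocol$segments
  writeLines(paste(format(seg$duration, digits = 15, trim = TRUE),
                   format(seg$v_start, digits = 15, trim = TRUE),
                   format(seg$v_end, digits = 15, trim = TRUE), sep = ","),
             con)
  invisible(path)
}

step_seg <- function(duration, v) {
  tibble::tibble(duration = duration, v_start = v, v_end = v)
}
ramp_seg <- function(duration, v0, v1) {
  tibble::tibble(duration = duration, v_start = v0, v_end = v1)
}

# identical ramp-containing lead-in/lead-out shared by all packaged designs
lead_in_segs <- function(scale = 1) {
  dplyr::bind_rows(
    step_seg(100 * scale, -80),
    step_seg(50 * scale, -120),
    ramp_seg(150 * scale, -120, -80),
    step_seg(200 * scale, -80))
}
lead_out_segs <- function(scale = 1) {
  dplyr::bind_rows(
    step_seg(50 * scale, -120),
    ramp_seg(150 * scale, -120, -80),
    step_seg(100 * scale, -80))
}

ap_wave_segs <- function(plateau_ms, scale = 1) {
  dplyr::bind_rows(
    ramp_seg(10 * scale, -80, 40),
    ramp_seg(plateau_ms * scale, 40, -85),
    ramp_seg(20 * scale, -85, -80),
    step_seg(150 * scale, -80))
}

central_steps <- list(
  d1 = rbind(c(350, 40), c(400, -50), c(250, 20), c(300, -80), c(250, 60),
             c(150, -120), c(350, 0), c(150, -100)),
  d2 = rbind(c(350, 60), c(450, -50), c(300, 40), c(100, -100), c(300, 20),
             c(140, -120), c(360, 0), c(200, -60)),
  d3 = rbind(c(450, 0), c(400, -60), c(300, 60), c(100, -90), c(300, -20),
             c(150, -110), c(300, 40), c(200, -50)),
  d4 = rbind(c(250, -60), c(250, -20), c(300, 20), c(300, 60), c(450, -50),
             c(150, -120), c(250, 40), c(250, 0)),
  d5 = rbind(c(150, -110), c(400, 50), c(450, -55), c(300, 10), c(150, -120),
             c(300, 60), c(150, -85), c(300, 30))
)

#' Packaged voltage-clamp protocol suite
#'
#' Six short information-rich designs: `d0-like`, a validation protocol whose
#' central portion is a sequence of action-potential-shaped ramp waveforms,
#' and five training protocols `d1-like` ... `d5-like` whose central portions
#' are constant steps spanning `[-120, 60]` mV.  All share identical
#' ramp-containing lead-in and lead-out sections.  These are stand-ins
#' reproducing the published design class (step/ramp protocols with a wide
#' voltage range and an AP-shaped validation trace), not transcriptions of
#' any published protocol's exact segment table.
#'
#' The `"desk"` preset uses 1 kHz sampling and central portions of roughly
#' 1.7 s (total about 2.5 s per protocol); the `"full"` preset scales every
#' duration by 4 and samples at 10 kHz.
#'
#' @param preset `"desk"` (default) or `"full"`.
#' @return named list of [voltage_protocol()] objects
#'   (`d0-like` ... `d5-like`).
#' @export
protocol_suite <- function(preset = c("desk", "full")) {
  preset <- match.arg(preset)
  scale <- if (preset == "full") 4 else 1
  rate <- if (preset == "full") 10 else 1
  build <- function(name, central) {
    voltage_protocol(
      name,
      dplyr::bind_rows(lead_in_segs(scale), central, lead_out_segs(scale)),
      v_hold = -80, sample_rate = rate)
  }
  d0_central <- dplyr::bind_rows(lapply(c(150, 250, 350, 200),
                                        ap_wave_segs, scale = scale))
  out <- list(`d0-like` = build("d0-like", d0_central))
  for (nm in names(central_steps)) {
    m <- central_steps[[nm]]
    central <- step_seg(m[, 1] * scale, m[, 2])
    out[[paste0(nm, "-like")]] <- build(paste0(nm, "-like"), central)
  }
  out
}

#' Names of the packaged training protocols
#' @return character vector `d1-like` ... `d5-like`.
#' @export
training_protocol_names <- function() paste0("d", 1:5, "-like")

#' Dedicated parameter-recovery check protocol
#'
#' A single step design dense in activation and deactivation information:
#' strong depolarisations followed by long tails at moderately negative
#' voltages (where deactivation is slow, pinning the rate-scale
#' extrapolation to 0 mV) plus brief extreme steps.  Designed so that, for
#' the packaged four-state model at the default noise level, the expected
#' relative standard deviation of every parameter estimate is below 2%,
#' making it a sharp negative control for parameter recovery under the
#' correctly specified model.  3 s at 1 kHz in the `"desk"` preset.
#'
#' @inheritParams protocol_suite
#' @return a [voltage_protocol()] named `"recovery"`.
#' @export
recovery_protocol <- function(preset = c("desk", "full")) {
  preset <- match.arg(preset)
  scale <- if (preset == "full") 4 else 1
  rate <- if (preset == "full") 10 else 1
  central <- rbind(c(400, 40), c(450, -50), c(300, 40), c(250, -80),
                   c(250, 60), c(150, -120), c(250, 0), c(150, 20))
  voltage_protocol(
    "recovery",
    dplyr::bind_rows(lead_in_segs(scale),
                     step_seg(central[, 1] * scale, central[, 2]),
                     lead_out_segs(scale)),
    v_hold = -80, sample_rate = rate)
}
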