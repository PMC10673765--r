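#' Read a Markov model definition file
#'
#' Model definitions are plain-text JSON documents listing state names, the
#' conducting state, the transition table (rate-law kind plus the *names* of
#' the kinetic parameters used for `a` and `b`) and a named parameter table.
#' [write_markov_model()] round-trips the same format.
#'
#' @param path path to a model definition JSON file.
#' @return a [markov_model()].
#' @export
read_markov_model <- function(path) {
  if (!file.exists(path)) {
    stop("model definition file not found: ", path, call. = FALSE)
  }
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("name", "states", "conducting_state", "theta_f", "g", "transitions")
  missing <- setdiff(need, names(spec))
  if (length(missing) > 0) {
    stop("model definition is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  theta_f <- unlist(spec$theta_f)
  tr <- tibble::as_tibble(spec$transitions)
  if (!"b" %in% names(tr)) tr$b <- NA_character_
  a_idx <- match(tr$a, names(theta_f))
  b_idx <- match(tr$b, names(theta_f))
  if (any(is.na(a_idx)) || any(is.na(b_idx) & tr$kind != "constant")) {
    stop("transition references an unknown parameter name", call. = FALSE)
  }
  tr$a <- a_idx
  tr$b <- b_idx
  m <- markov_model(spec$name, spec$states, spec$conducting_state, tr,
                    theta_f, spec$g)
  m$provenance <- spec$provenance
  m$description <- spec$description
  m
}

#' Write a Markov model definition file
#'
#' @param model a [markov_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_markov_model <- function(model, path) {
  tr <- model$transitions
  pn <- names(model$theta_f)
  out <- list(
    name = model$name,
    description = model$description,
    provenance = model$provenance,
    states = model$states,
    conducting_state = model$states[model$conducting],
    theta_f = as.list(model$theta_f),
    g = model$g,
    transitions = data.frame(
      from = tr$from, to = tr$to, kind = tr$kind,
      a = pn[tr$a],
      b = ifelse(tr$kind == "constant", NA_character_, pn[tr$b]))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

builtin_model <- function(which) {
  path <- system.file("extdata", "models", paste0(which, ".json"),
                      package = "channeluq")
  if (!nzchar(path)) {
    stop("packaged model definition '", which, "' not found; ",
         "the installation appears incomplete", call. = FALSE)
  }
  read_markov_model(path)
}

#' The four-state IKr model
#'
#' Four states (C, O, I, IC) arranged in a cycle, with shared activation and
#' inactivation rate pairs: 8 kinetic parameters plus the maximal conductance
#' (9 parameters in total).  Parameter values are the packaged literature
#' cell-specific estimates; see the `provenance` field of the returned object.
#'
#' @return a [markov_model()] with 4 states.
#' @export
beattie_model <- function() builtin_model("beattie")

#' The five-state IKr model
#'
#' A linear chain C1-C2-C3-O-I with a voltage-independent C2/C3 step:
#' 14 kinetic parameters plus the maximal conductance (15 in total), using
#' the packaged 2 mM extracellular-potassium literature parameter set; see
#' the `provenance` field of the returned object.
#'
#' @return a [markov_model()] with 5 states.
#' @export
wang_model <- function() builtin_model("wang")
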