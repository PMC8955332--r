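#' Read or write a simulation scenario file
#'
#' A scenario file is a JSON snapshot of a [simulation_config()]: the
#' presentation design, the two cohort specifications and the seed. Field
#' names match the constructor arguments; validation errors itemise every
#' offending field.
#'
#' @param path Scenario file path.
#' @param config A [simulation_config()] object.
#' @return `read_scenario()` returns a `simulation_config`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop_validation("scenario file not found: ", path)
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(cnd) {
                  stop_validation("scenario file is not valid JSON: ",
                                  conditionMessage(cnd))
                })
  problems <- character(0)
  for (f in c("design", "control", "apd", "seed")) {
    if (is.null(x[[f]])) problems <- c(problems, paste0("missing field: ", f))
  }
  if (length(problems)) {
    stop_validation("invalid scenario:\n  ", paste(problems, collapse = "\n  "))
  }
  build <- function(ctor, values, what) {
    wanted <- names(formals(ctor))
    unknown <- setdiff(names(values), wanted)
    if (length(unknown)) {
      stop_validation("invalid scenario: unknown ", what, " fields: ",
                      paste(unknown, collapse = ", "))
    }
    tryCatch(do.call(ctor, values),
             error = function(cnd) {
               stop_validation("invalid scenario (", what, "): ",
                               conditionMessage(cnd))
             })
  }
  design <- build(sinb_design, x$design, "design")
  control <- build(cohort_spec, x$control, "control cohort")
  apd <- build(cohort_spec, x$apd, "apd cohort")
  simulation_config(design, control, apd, x$seed)
}

#' @rdname read_scenario
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  x <- list(
    design = unclass(config$design),
    control = unclass(config$control),
    apd = unclass(config$apd),
    seed = config$seed
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Packaged simulation scenarios
#'
#' `"default"` is the reference scenario: 33 typically developing and 22
#' APD children on the standard SinB design, with group- and ear-specific
#' psychometric midpoints calibrated so that the expected cohort means of
#' all four SNR50 measures reproduce the published cohort means of the
#' clinical SinB scoring study (APD poorer than control on every measure,
#' syllable scores below word scores in both groups, and a left-ear
#' control advantage). `"null"` is the same design with two identical,
#' exchangeable cohorts (for calibration and type-I-error work).
#'
#' @param name `"default"` or `"null"`.
#' @param seed Optional seed override.
#' @return A [simulation_config()] object.
#' @export
sinb_scenario <- function(name = c("default", "null"), seed = NULL) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("scenario_", name, ".json"),
                      package = "sinbscore", mustWork = TRUE)
  config <- read_scenario(path)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  config
}
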