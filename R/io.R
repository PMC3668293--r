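#' Write a simulation result to CSV
#'
#' Tidy long format (time, species, amount, concentration) at full double
#' precision, so write -> read is lossless.
#'
#' @param result An `insox_sim_result`.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_results <- function(result, path) {
  df <- as_tidy_result(result, concentrations = !is.null(result$model))
  if (any(!is.finite(df$amount))) {
    stop("result contains non-finite amounts", call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = ","), con)
  if (nrow(df)) {
    num <- vapply(df, is.numeric, logical(1))
    cols <- lapply(seq_along(df), function(i) {
      if (num[i]) format(df[[i]], digits = 17, trim = TRUE,
                         scientific = TRUE) else df[[i]]
    })
    writeLines(do.call(paste, c(cols, sep = ",")), con)
  }
  invisible(path)
}

#' Read a results CSV back
#'
#' @param path CSV path written by [write_results()].
#' @return data.frame (time, species, amount, and concentration if present).
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "species", "amount")
  if (!all(need %in% names(df))) {
    stop("not a results file (missing columns) at ", path, call. = FALSE)
  }
  df
}

#' Validate a run configuration
#'
#' Configurations select modules, override parameters, set the scenario and
#' solver options. Unknown keys are rejected so typos fail loudly.
#'
#' @param config Named list (e.g. from `yaml::read_yaml()`).
#' @return The validated config with defaults filled in.
#' @export
validate_run_config <- function(config) {
  allowed <- c("scenario", "scenario_args", "modules", "parameters",
               "initial_amounts", "solver", "t_end", "schedule", "out",
               "log_level")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(config$modules)) {
    bad <- setdiff(config$modules,
                   c("receptor", "irs", "akt", "phosphatases", "jnk",
                     "foxo", "transcription"))
    if (length(bad)) {
      stop("unknown modules in config: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  if (!is.null(config$solver)) {
    s <- config$solver
    bad <- setdiff(names(s), c("rtol", "atol", "method", "maxsteps"))
    if (length(bad)) {
      stop("unknown solver keys: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  defaults <- list(scenario = NULL, scenario_args = list(),
                   modules = c("receptor", "irs", "akt", "phosphatases",
                               "jnk", "foxo", "transcription"),
                   parameters = list(), initial_amounts = list(),
                   solver = list(), t_end = 60, schedule = NULL,
                   out = NULL, log_level = "info")
  utils::modifyList(defaults, config)
}

#' Build a model from a validated run configuration
#'
#' Applies parameter and initial-amount overrides
#' (`parameters: {module: {reaction: {constant: value}}}`) on top of the
#' defaults and assembles the selected modules.
#'
#' @param config Output of [validate_run_config()].
#' @return An [new_model()] object.
#' @export
model_from_config <- function(config) {
  params <- default_parameters()
  for (mod in names(config$parameters)) {
    for (rid in names(config$parameters[[mod]])) {
      ov <- config$parameters[[mod]][[rid]]
      for (nm in names(ov)) params[[mod]][[rid]][[nm]] <- ov[[nm]]
    }
  }
  amounts <- default_initial_amounts()
  for (nm in names(config$initial_amounts)) {
    amounts[[nm]] <- config$initial_amounts[[nm]]
  }
  mods <- config$modules
  sig <- intersect(mods, c("receptor", "irs", "akt", "phosphatases", "jnk"))
  parts <- lapply(sig, build_module, params = params, amounts = amounts)
  if ("foxo" %in% mods) parts <- c(parts, list(build_foxo_module()))
  if ("transcription" %in% mods) {
    parts <- c(parts, list(build_gene("InR"), build_gene("SOD2")))
  }
  merge_modules(parts)
}

#' One-line census of a model for run logs
#' @param model An [new_model()] object.
#' @return Character string.
#' @export
model_census <- function(model) {
  sprintf("%d species (%d boundary), %d reactions, %d compartments",
          nrow(model$species), sum(model$species$boundary),
          length(model$reactions), nrow(model$compartments))
}
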