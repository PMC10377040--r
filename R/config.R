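## Run configuration: a small validated key-value structure mirroring the
## scenario fields. Unknown keys are hard errors: silently ignoring them
## would hide typos in rate-constant names.

config_defaults <- function() {
  list(scenario = NULL, overrides = list(), output_dir = NULL,
       rtol = NULL, atol = NULL, log_level = "info")
}

override_keys <- c("t_end", "n_points", "p_values", "p", "seeded_class",
                   "z0", "k1", "k2", "k_minus2", "k3", "k4", "k5", "k6")

cfg_num <- function(value, key, len_ok = 1L) {
  if (!is.numeric(value) || !(length(value) %in% len_ok) ||
      any(!is.finite(value))) {
    stop(sprintf("config field '%s' must be numeric (length %s)", key,
                 paste(len_ok, collapse = " or ")), call. = FALSE)
  }
  value
}

validate_config <- function(cfg) {
  known <- names(config_defaults())
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults <- config_defaults()
  for (key in setdiff(known, names(cfg))) {
    cfg[[key]] <- defaults[[key]]
    if (!is.null(defaults[[key]]) && !identical(defaults[[key]], list())) {
      log_msg(cfg, "debug", sprintf("config: default %s = %s", key,
                                    format(defaults[[key]])))
    }
  }
  if (!is.null(cfg$scenario)) {
    if (!is.character(cfg$scenario) || length(cfg$scenario) != 1L ||
        !(cfg$scenario %in% c(scenario_names(), "custom"))) {
      stop("config field 'scenario' must be one of: ",
           paste(c(scenario_names(), "custom"), collapse = ", "),
           call. = FALSE)
    }
  }
  ov <- cfg$overrides
  if (length(ov)) {
    bad <- setdiff(names(ov), override_keys)
    if (length(bad)) {
      stop("unknown override key(s): ", paste0("overrides.", bad,
           collapse = ", "), call. = FALSE)
    }
    for (key in names(ov)) {
      v <- ov[[key]]
      if (key %in% c("p_values", "k2", "k_minus2")) {
        cfg_num(v, paste0("overrides.", key), len_ok = seq_len(99))
      } else {
        cfg_num(v, paste0("overrides.", key))
      }
      if (key %in% c("p", "p_values") && (any(v < 0) || any(v > 1))) {
        stop(sprintf("overrides.%s must lie in [0, 1]", key), call. = FALSE)
      }
      if (key %in% c("t_end", "n_points") && any(v <= 0)) {
        stop(sprintf("overrides.%s must be positive", key), call. = FALSE)
      }
    }
  }
  for (key in c("rtol", "atol")) {
    if (!is.null(cfg[[key]])) {
      cfg_num(cfg[[key]], key)
      if (cfg[[key]] <= 0) stop(sprintf("'%s' must be positive", key),
                                call. = FALSE)
    }
  }
  if (!is.character(cfg$log_level) ||
      !(cfg$log_level %in% c("quiet", "info", "debug"))) {
    stop("config field 'log_level' must be quiet, info or debug",
         call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

log_msg <- function(cfg, level, txt) {
  levels <- c(quiet = 0, info = 1, debug = 2)
  want <- levels[[if (is.null(cfg$log_level)) "info" else cfg$log_level]]
  if (levels[[level]] <= want && want > 0) message(txt)  # stderr
  invisible(NULL)
}

#' Load a run configuration from JSON or YAML
#'
#' The format is auto-detected from the file extension (`.json`, `.yaml`
#' or `.yml`). Recognized fields: `scenario`, `overrides` (a map of
#' scenario-field overrides: `t_end`, `n_points`, `p_values`, `p`,
#' `seeded_class`, `z0`, and the rate constants `k1`..`k6`,
#' `k_minus2`), `output_dir`, `rtol`, `atol`, `log_level`. Unknown keys
#' are rejected, not ignored.
#'
#' @param path Path to the configuration file.
#' @return A validated `run_config` list with defaults filled.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("config must be .json, .yaml or .yml; got .", ext, call. = FALSE))
  if (is.null(cfg)) cfg <- list()
  validate_config(cfg)
}

#' Write a run configuration
#'
#' Round-trip companion of [load_run_config()]: a config written and
#' reloaded is field-identical.
#'
#' @param cfg A `run_config` (or plain list of config fields).
#' @param path Destination `.json`, `.yaml` or `.yml` file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  cfg <- validate_config(unclass(cfg))
  out <- cfg[!vapply(cfg, is.null, logical(1))]
  out <- out[!vapply(out, function(v) identical(v, list()), logical(1))]
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(out, path)
  } else {
    stop("config must be .json, .yaml or .yml", call. = FALSE)
  }
  invisible(path)
}

#' Build a scenario specification from a configuration
#'
#' Starts from the preset named in `cfg$scenario` and applies the
#' overrides. Rate-constant overrides are applied to every member of a
#' single-antibody scenario (vector-valued `k2`/`k_minus2` to the
#' competition members); for repertoire scenarios they rebuild the
#' parameter bundle. `seeded_class` moves the initial antibody seed of
#' the single-seed repertoire presets; `z0` sets the initial antigen.
#'
#' @param cfg A `run_config` from [load_run_config()].
#' @return A `scenario_spec` ready for [run_scenario()].
#' @export
config_to_spec <- function(cfg) {
  cfg <- validate_config(unclass(cfg))
  if (is.null(cfg$scenario) || cfg$scenario == "custom") {
    stop("config must name one of the shipped scenarios: ",
         paste(scenario_names(), collapse = ", "), call. = FALSE)
  }
  spec <- scenario_preset(cfg$scenario)
  ov <- cfg$overrides
  for (key in c("t_end", "n_points")) {
    if (!is.null(ov[[key]])) spec[[key]] <- ov[[key]]
  }
  if (!is.null(cfg$rtol)) spec$rtol <- cfg$rtol
  if (!is.null(cfg$atol)) spec$atol <- cfg$atol

  model2 <- spec$model %in% c("model2_self", "model2_foreign")
  if (!is.null(ov$p_values) || !is.null(ov$p)) {
    if (!model2) stop("overrides.p applies only to repertoire scenarios",
                      call. = FALSE)
    spec$p_values <- if (!is.null(ov$p_values)) ov$p_values else ov$p
  }
  rate_keys <- intersect(names(ov),
                         c("k1", "k2", "k_minus2", "k3", "k4", "k5", "k6"))
  if (length(rate_keys)) {
    if (model2) {
      b <- spec$params
      args <- list(grid = b$grid, k3 = b$k3, k4 = b$k4, k6 = b$k6,
                   replicating = b$replicating, k1 = b$k1, k5 = b$k5)
      for (key in intersect(rate_keys, c("k1", "k3", "k4", "k5", "k6"))) {
        args[[key]] <- ov[[key]]
      }
      if (any(c("k2", "k_minus2") %in% rate_keys)) {
        stop("per-class k2/k_minus2 overrides are set through the grid, ",
             "not the config", call. = FALSE)
      }
      spec$params <- do.call(model2_params, args)
    } else if (spec$model == "model1_self") {
      for (lbl in names(spec$params)) {
        p <- unclass(spec$params[[lbl]])
        for (key in rate_keys) p[[key]] <- ov[[key]]
        spec$params[[lbl]] <- model1_params(k2 = p$k2, k_minus2 = p$k_minus2,
                                            k3 = p$k3, k4 = p$k4, k6 = p$k6,
                                            k1 = p$k1, k5 = p$k5)
      }
    } else {
      p <- unclass(spec$params)
      for (key in rate_keys) p[[key]] <- ov[[key]]
      spec$params <- competition_params(k2 = p$k2, k_minus2 = p$k_minus2,
                                        k1 = p$k1, k3 = p$k3, k4 = p$k4,
                                        k5 = p$k5, k6 = p$k6)
    }
  }
  if (!is.null(ov$z0)) {
    if (is.list(spec$initial_state)) spec$initial_state$z <- ov$z0
    else spec$initial_state["z"] <- ov$z0
  }
  if (!is.null(ov$seeded_class)) {
    if (!model2) stop("overrides.seeded_class applies only to repertoire ",
                      "scenarios", call. = FALSE)
    i <- ov$seeded_class
    n <- spec$params$grid$n
    if (i < 1 || i > n || i != round(i)) {
      stop(sprintf("overrides.seeded_class must be an integer in 1..%d", n),
           call. = FALSE)
    }
    total_seed <- sum(spec$initial_state$y)
    spec$initial_state$y <- replace(rep(0, n), as.integer(i), total_seed)
    spec$seeded_class <- as.integer(i)
  }
  spec
}
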