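#' Write / read an epoched dataset
#'
#' An epoched dataset is stored as a plain-text directory container so it
#' can be versioned, inspected and consumed outside R:
#'
#' * `meta.json` — dimensions, `tau`, `fs`, seed and the provenance hash of
#'   the generating configuration;
#' * `labels.csv` — `trial,condition` table;
#' * `data.csv` — long table `trial,time,channel,value`, with values printed
#'   at 17 significant digits so the round trip is lossless for doubles;
#' * `config.yaml` — the generating configuration (when available), used to
#'   re-derive and verify the provenance hash on read.
#'
#' @param x An `epoched_data` object (see [sample_dataset()]).
#' @param path Directory to create/overwrite.
#' @return `write_epoched()`: `path`, invisibly. `read_epoched()`: the
#'   restored `epoched_data` object (without the full config if none was
#'   stored).
#' @export
write_epoched <- function(x, path) {
  stopifnot(inherits(x, "epoched_data"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(x$data)
  meta <- list(n_trials = d[1], n_times = d[2], n_channels = d[3],
               tau = x$tau, fs = x$fs, seed = x$seed,
               provenance = x$provenance)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE)
  utils::write.csv(
    data.frame(trial = seq_len(d[1]), condition = x$labels),
    file.path(path, "labels.csv"), row.names = FALSE)
  idx <- expand.grid(trial = seq_len(d[1]), time = seq_len(d[2]),
                     channel = seq_len(d[3]))
  df <- data.frame(idx, value = sprintf("%.17g", as.vector(x$data)))
  utils::write.csv(df, file.path(path, "data.csv"), row.names = FALSE,
                   quote = FALSE)
  if (!is.null(x$config)) {
    write_config(x$config, file.path(path, "config.yaml"))
  }
  invisible(path)
}

#' @rdname write_epoched
#' @export
read_epoched <- function(path) {
  required <- c("meta.json", "labels.csv", "data.csv")
  missing <- required[!file.exists(file.path(path, required))]
  if (length(missing)) {
    stop("not a valid epoched-data container: missing ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  labels <- utils::read.csv(file.path(path, "labels.csv"))
  if (!all(c("trial", "condition") %in% names(labels))) {
    stop("labels.csv must contain columns `trial` and `condition`", call. = FALSE)
  }
  df <- utils::read.csv(file.path(path, "data.csv"))
  dims <- c(meta$n_trials, meta$n_times, meta$n_channels)
  if (nrow(df) != prod(dims)) {
    stop(sprintf("data.csv has %d rows; expected %d (%d x %d x %d)",
                 nrow(df), prod(dims), dims[1], dims[2], dims[3]),
         call. = FALSE)
  }
  df <- df[order(df$channel, df$time, df$trial), ]
  data <- array(as.numeric(df$value), dims)
  config <- NULL
  cfg_path <- file.path(path, "config.yaml")
  if (file.exists(cfg_path)) {
    config <- read_config(cfg_path)
    if (!identical(config_hash(config), meta$provenance)) {
      warning("provenance hash mismatch: config.yaml does not match the ",
              "configuration this dataset was generated from")
    }
  }
  structure(list(data = data, labels = labels$condition[order(labels$trial)],
                 tau = as.numeric(meta$tau), fs = as.numeric(meta$fs),
                 seed = meta$seed,
                 config = config, provenance = meta$provenance),
            class = "epoched_data")
}

# recursive conversion of config <-> plain lists for YAML
.config_to_list <- function(x) {
  if (inherits(x, "response_shape")) {
    c(list(.class = "response_shape"), unclass(x))
  } else if (inherits(x, "sim_effect")) {
    c(list(.class = "sim_effect"), lapply(unclass(x), .config_to_list))
  } else if (inherits(x, "spontaneous_spec")) {
    c(list(.class = "spontaneous_spec"), unclass(x))
  } else if (inherits(x, "sim_config")) {
    c(list(.class = "sim_config"), lapply(unclass(x), .config_to_list))
  } else if (is.list(x)) {
    lapply(x, .config_to_list)
  } else {
    x
  }
}

.list_to_config <- function(x) {
  if (!is.list(x)) return(x)
  cls <- x$.class
  x$.class <- NULL
  x <- lapply(x, .list_to_config)
  if (is.null(cls)) return(x)
  switch(cls,
    response_shape = do.call(response_shape, x[c("delta1", "delta2", "delta3",
                                                 "zeta1", "zeta2", "left",
                                                 "right", "jitter_sd",
                                                 "jitter_mode")]),
    spontaneous_spec = do.call(spontaneous_spec, x[setdiff(names(x), character())]),
    sim_effect = {
      kind <- x$kind
      x$kind <- NULL
      do.call(switch(kind,
                     phase_reset = effect_phase_reset,
                     additive_osc = effect_additive_osc,
                     amp_mod = effect_amp_mod,
                     slow = effect_slow), x)
    },
    sim_config = do.call(sim_config, x),
    x
  )
}

#' Write / read a simulation configuration as YAML
#'
#' All hyperparameters (AR coefficients, ranges, response-function `delta` /
#' `zeta` parameters, `theta`, effect parameters, ...) are serialised to a
#' human-editable YAML file and restored to a validated [sim_config()].
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @return `write_config()`: `path`, invisibly; `read_config()`: a
#'   [sim_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(.config_to_list(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- .list_to_config(yaml::read_yaml(path))
  if (!inherits(cfg, "sim_config")) {
    stop("file does not describe a sim_config", call. = FALSE)
  }
  cfg
}
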