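CONFIG_SCHEMA_VERSION <- "1"

#' Serialize configurations to YAML
#'
#' Both configuration types round-trip exactly through a versioned YAML
#' schema (`schema_version` key, validated on load).
#'
#' @param config a `dgm_config` or `missingness_config`.
#' @param path output YAML file.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  if (inherits(config, "dgm_config")) {
    body <- unclass(config)
    body$L1_dyn <- as.list(body$L1_dyn)
    body$L2_dyn <- as.list(body$L2_dyn)
    body$trt_model <- as.list(body$trt_model)
    obj <- list(schema_version = CONFIG_SCHEMA_VERSION, type = "dgm_config",
                config = body)
  } else if (inherits(config, "missingness_config")) {
    body <- unclass(config)
    body$slopes <- as.list(body$slopes)
    obj <- list(schema_version = CONFIG_SCHEMA_VERSION,
                type = "missingness_config", config = body)
  } else {
    msmiss_abort("msmiss_config_error", "unsupported configuration object")
  }
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a configuration from YAML
#' @param path YAML file written by [write_config()].
#' @return The validated configuration object.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    msmiss_abort("msmiss_io_error", sprintf("file '%s' does not exist", path))
  obj <- yaml::read_yaml(path)
  if (is.null(obj$schema_version) ||
      obj$schema_version != CONFIG_SCHEMA_VERSION)
    msmiss_abort("msmiss_schema_error",
                 sprintf("unsupported schema_version '%s'",
                         obj$schema_version %||% "<missing>"))
  b <- obj$config
  if (identical(obj$type, "dgm_config")) {
    dgm_config(n_times = b$n_times, p_L1 = b$p_L1,
               L2_mean = b$L2_mean, L2_sd = b$L2_sd,
               L1_dyn = unlist(b$L1_dyn), L2_dyn = unlist(b$L2_dyn),
               L2_noise_sd = b$L2_noise_sd, L1_noise_sd = b$L1_noise_sd,
               sticky = b$sticky, trt_model = unlist(b$trt_model),
               out_model = list(intercept = b$out_model$intercept,
                                trt = unlist(b$out_model$trt),
                                L1 = unlist(b$out_model$L1),
                                L2 = unlist(b$out_model$L2),
                                V = b$out_model$V),
               out_sd = b$out_sd, l1_type = b$l1_type)
  } else if (identical(obj$type, "missingness_config")) {
    cfg <- missingness_config(b$mechanism,
                              intercept = b$intercept %||% NA_real_,
                              slopes = unlist(b$slopes),
                              target = b$target,
                              targets = unlist(b$targets))
    cfg
  } else {
    msmiss_abort("msmiss_schema_error",
                 sprintf("unknown config type '%s'", obj$type %||% "<missing>"))
  }
}
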