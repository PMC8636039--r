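# Run configuration: per-stage parameter blocks with the canonical defaults,
# YAML round-trip and a reproducibility manifest.

#' Default run configuration
#'
#' Nested per-stage parameter blocks; the defaults reproduce the canonical
#' setup (shared connectivity/sigmoid constants, per-band gains, noise drive
#' mean 60 / variance 100, three-shell head, GAN architecture and optimizer,
#' 2-55 Hz preprocessing, 100-ms windows) at synthetic scale.
#'
#' @param seed Global seed.
#' @return A nested list of class `run_config`.
#' @export
default_config <- function(seed = 1L) {
  bands <- nmm_band_defaults()
  structure(list(
    seed = as.integer(seed),
    nmm = list(
      common = list(C1 = 135, C2 = 108, C3 = 33.75, C4 = 33.75, C5 = 40.5,
                    C6 = 13.5, C7 = 108, e0 = 2.5, s0 = 6, r = 0.56),
      bands = lapply(bands, function(b)
        list(A = b$A, B = b$B, G = b$G, a = b$a, b = b$b, g = b$g)),
      input = list(mean = 60, variance = 100),
      dt = 1e-3, burn_in = 2, t_total = 22,
      band_edges = list(low = c(4, 12), medium = c(12, 30), high = c(30, 55))),
    forward = list(radii = c(0.087, 0.092, 0.100),
                   conductivities = c(0.33, 0.0042, 0.33),
                   mesh_subdiv = 3, reference = "CPz", method = "analytic"),
    gan = list(window = 100, iterations = 200, lr_d = 8e-4, lr_gan = 4e-4,
               clipvalue = 1.0, decay = 1e-8, batch = 64, trials_per_iter = 4,
               dropout = 0.4, alpha = 0.2),
    pipeline = list(f_lo = 2, f_hi = 55, order = 4, window = 100, m = 3,
                    folds = 5),
    synthetic = list(n_subjects = 8, sessions = 4, trials = 6,
                     countdown_s = 3, task_s = 4, rest_s = 2, fs = 1000,
                     snr_db = 10, jitter = 0.10)),
    class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' Values present in the file override the defaults; unknown keys error.
#'
#' @param path YAML file.
#' @param cfg A `run_config` (for writing).
#' @return `read_config` returns a `run_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  merge_cfg <- function(base, over, where = "") {
    for (k in names(over)) {
      if (!k %in% names(base))
        stop("unknown config key '", paste0(where, k), "'")
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
        merge_cfg(base[[k]], over[[k]], paste0(where, k, "."))
      else over[[k]]
    }
    base
  }
  out <- merge_cfg(unclass(cfg), user)
  structure(out, class = "run_config")
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_hash <- function(cfg) {
  x <- paste(deparse(unclass(cfg)), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(x)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

#' Write a machine-readable run manifest
#'
#' Records the configuration hash, seed, package version and produced
#' artifacts so a run can be reproduced exactly.
#'
#' @param cfg The `run_config` used.
#' @param outputs Character vector of artifact paths.
#' @param path Manifest path (JSON).
#' @return Invisibly `path`.
#' @export
write_manifest <- function(cfg, outputs, path) {
  jsonlite::write_json(list(
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    package = "simbci",
    version = as.character(utils::packageVersion("simbci")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    outputs = outputs), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
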