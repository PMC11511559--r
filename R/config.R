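#' Load and validate a run configuration
#'
#' YAML configuration with sections `features`, `spatial`, `classify`,
#' `p300`, `fsm`, `simulate` plus global keys `seed`, `log_level` and
#' `out_dir`. Unknown top-level keys or section keys are rejected so typos
#' fail loudly. Every CLI run writes a resolved copy of the configuration it
#' actually used next to its outputs (see [write_resolved_config()]).
#'
#' @param path YAML file, or `NULL` for all defaults.
#' @return nested list of class `run_config` with defaults filled in.
#' @export
load_run_config <- function(path = NULL) {
  defaults <- list(
    seed = 1L, log_level = "info", out_dir = ".",
    features = list(mu_band = c(8, 12), beta_band = c(13, 30), ar_order = 4,
                    entropy_m = 2, entropy_r_scale = 0.2, perm_order = 3,
                    perm_delay = 1, higuchi_kmax = 10, welch_segment_s = 1.0,
                    welch_overlap = 0.5),
    spatial = list(car = TRUE, laplacian = "small", weighted = FALSE),
    classify = list(algorithm = "lr", train_fraction = 0.8),
    p300 = list(window_s = 0.667, band = c(0.1, 10), order = 8, ripple = 0.5,
                repetitions = 15, classifier = "rf"),
    fsm = list(table = NULL),
    simulate = list(mi = list(n_channels = 62, fs = 250, trial_s = 3.0,
                              erd_depth = 0.5, n_per_class = 50),
                    p300 = list(n_channels = 64, fs = 240, erp_amplitude = 5,
                                text = "HELLO")))
  merge_section <- function(def, user, where) {
    if (!is.list(def) || is.null(names(def)) || !is.list(user)) return(user)
    bad <- setdiff(names(user), names(def))
    if (length(bad) > 0) {
      stop("unknown config key(s)", if (nzchar(where))
        paste0(" in section '", where, "'") else "", ": ",
        paste(bad, collapse = ", "))
    }
    for (k in names(user)) {
      def[[k]] <- merge_section(def[[k]], user[[k]],
                                if (nzchar(where)) paste0(where, ".", k) else k)
    }
    def
  }
  cfg <- defaults
  if (!is.null(path)) {
    cfg <- merge_section(defaults, yaml::read_yaml(path), "")
  }
  structure(cfg, class = "run_config")
}

#' Write the resolved configuration next to run outputs
#'
#' @param cfg a `run_config`.
#' @param out_dir output directory.
#' @return the file path, invisibly.
#' @export
write_resolved_config <- function(cfg, out_dir = cfg$out_dir) {
  path <- file.path(out_dir, "resolved_config.yaml")
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
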