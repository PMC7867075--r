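#' Default pipeline configuration
#'
#' All tunables of the pipeline with defaults frozen to the method's
#' printed constants: 0.1 Hz high-pass, 1--10 Hz band-pass, 0.325 s moving
#' average, 0.365 s minimum peak interval, 2 Hz tachogram, 7 s despike
#' window, 30 s epochs and the 2 x 10 x 10 hyperparameter grid.
#'
#' @return a nested list.
#' @export
default_config <- function() {
  list(
    preprocess = list(highpass_hz = 0.1, band_hz = c(1, 10),
                      ma_window_s = 0.325),
    bcg = list(min_interval_s = 0.365, tach_fs_hz = 2,
               despike_window_s = 7, gap_flag_s = 3),
    epoch = list(len_s = 30),
    features = list(fs_scale = "binwidth"),
    staging = list(criterion = c("gini", "entropy"), depth = c(1, 10),
                   n_trees = c(1, 10), seed = 1)
  )
}

#' Read a YAML pipeline configuration
#'
#' Missing keys take their defaults; unknown keys are rejected.
#'
#' @param path YAML file.
#' @return the merged configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user, "")
}

merge_config <- function(base, user, prefix) {
  if (is.null(user)) return(base)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    bcg_error(paste0("unknown config key(s): ",
                     paste0(prefix, unknown, collapse = ", ")), "config")
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]]))
      merge_config(base[[nm]], user[[nm]], paste0(prefix, nm, "."))
    else user[[nm]]
  }
  base
}

#' Grid from a configuration entry
#'
#' Expands the \code{staging} block of a configuration (criterion choices,
#' depth range, tree-count range) into the candidate grid.
#'
#' @param config a pipeline configuration.
#' @return a \code{\link{hyper_grid}} data frame.
#' @export
config_grid <- function(config = default_config()) {
  s <- config$staging
  hyper_grid(criterion = s$criterion,
             depth = seq(s$depth[1], s$depth[2]),
             n_trees = seq(s$n_trees[1], s$n_trees[2]))
}
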