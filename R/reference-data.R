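# Bundled reference tables from a published eight-subject, two-night
# overnight head-BCG sleep study: per-subject anthropometrics and
# per-subject stage epoch counts. Used in examples and as regression
# fixtures for the summary statistics.

#' Bundled per-subject reference tables
#'
#' \code{reference_subject_info} returns subject number, age (years),
#' height (m) and weight (kg) for the eight subjects.
#' \code{reference_stage_epochs} returns the long table of per-subject
#' 30-s epoch counts per stage for the second and third study nights
#' (columns \code{day, subject, stage, epochs}).
#'
#' @return a data frame.
#' @export
reference_subject_info <- function() {
  utils::read.csv(system.file("extdata", "subject_info.csv",
                              package = "bcgsleep"))
}

#' @rdname reference_subject_info
#' @export
reference_stage_epochs <- function() {
  utils::read.csv(system.file("extdata", "stage_epoch_counts.csv",
                              package = "bcgsleep"))
}
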