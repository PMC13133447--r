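#' Cochlear-implant cohort demographics table
#'
#' Per-participant demographics of the implanted cohort used in the worked
#' examples: age, sex, duration of deafness, years of device use, implant
#' side, etiology, device brand, AzBio sentence score, and the number of
#' electrodes blocked near the implant.
#'
#' @param path TSV path (default: the packaged table).
#' @return data.frame, one row per participant.
#' @export
ci_demographics <- function(path = system.file("extdata",
                                               "ci_demographics.tsv",
                                               package = "speechTRF")) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
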