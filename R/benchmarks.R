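#' Published FID benchmark pairs for a medical-image model zoo
#'
#' Loads the bundled table of published FID measurements over a 21-model
#' medical-image generative-model zoo: for each model (and, for a 16-model
#' subset, for each combination of feature-extractor pretraining domain
#' — natural-image vs radiology — and image-normalization setting) the
#' real–real lower-bound FID, the real–synthetic FID, the number of real
#' images used, and the published rFID value. These (FIDrr, FIDrs) pairs are
#' the worked-example inputs for [rfid()].
#'
#' @return Data frame with columns `source_table` (`"models"` for the
#'   per-model table, `"normalization"` for the extractor-by-normalization
#'   cross table), `model`, `dataset`, `extractor`, `normalized`, `n_real`,
#'   `fid_rr`, `fid_rs`, `rfid_printed`.
#' @export
fid_benchmarks <- function() {
  path <- system.file("extdata", "fid_benchmarks.csv", package = "synthzoo",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
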