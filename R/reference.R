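# Normative reference moments shipped with the package.

#' Literature reference moments for healthy and MDR eyes
#'
#' Per-layer group statistics (mean and SD of thickness in microns and of
#' fractal dimension, with the reported AUROC, confidence bounds, cutoff
#' and positive likelihood ratio) for healthy eyes versus eyes with mild
#' diabetic retinopathy, as reported for time-domain macular OCT. Used to
#' parameterise the phantom cohorts, the demo study and the package's
#' arithmetic self-checks; not a substitute for a clinical normative
#' database.
#'
#' @param feature optionally restrict to `"thickness"` or `"fd"`.
#' @return data frame with columns `layer`, `feature`, `healthy_mean`,
#'   `healthy_sd`, `mdr_mean`, `mdr_sd`, `auroc`, `auroc_se`, `ci_low`,
#'   `ci_high`, `cutoff`, `plr`.
#' @examples
#' reference_moments("fd")
#' @export
reference_moments <- function(feature = NULL) {
  path <- system.file("extdata", "tdoct_reference_moments.csv",
                      package = "octfractal", mustWork = TRUE)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(feature)) tab <- tab[tab$feature == feature, , drop = FALSE]
  tab
}
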