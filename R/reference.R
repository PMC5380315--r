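# Published reference arithmetic shipped with the package.

#' Reference decision-curve threshold/weighting-factor table
#'
#' Previously reported lower and upper risk thresholds (percent) at which
#' each of the nine models showed a positive net benefit over the pack-year
#' eligibility criteria in the two trials' four arms, together with the
#' harm-ratio weighting factor printed alongside each threshold (one
#' decimal). Used as an arithmetic self-check: every printed weighting
#' factor must reproduce from its threshold via [harm_ratio()].
#'
#' @return data.frame `model`, `arm`, `bound`, `threshold_pct`, `wf_printed`.
#' @export
reference_threshold_wf <- function() {
  utils::read.csv(system.file("extdata", "reference_threshold_wf.csv",
                              package = "lcriskval"),
                  stringsAsFactors = FALSE)
}
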