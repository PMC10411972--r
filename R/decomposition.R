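#' Decompose GABA supply from transporter-blockade percent reductions
#'
#' A broad-spectrum glutamate-transporter antagonist (e.g. T-TBOA) reduces
#' IPSC amplitudes by blocking all glutamate uptake; in the knockout only the
#' glial transporters remain. The arithmetic attribution of GABA supply is
#' therefore: neuronal transporter (EAAC1) share = wild-type reduction minus
#' knockout reduction; glial share = knockout reduction; de novo synthesis
#' share = 100 minus wild-type reduction. The three shares close to 100% by
#' construction.
#'
#' @param reduction_wt_pct Percent reduction in the wild type (0-100).
#' @param reduction_ko_pct Percent reduction in the knockout (0-100,
#'   `<= reduction_wt_pct`).
#' @param context Free-text description of the synapse/measurement.
#' @return A one-row tibble with `eaac1_pct`, `glial_pct`, `denovo_pct`,
#'   `context`.
#' @export
decompose_gaba_sources <- function(reduction_wt_pct, reduction_ko_pct,
                                   context = "") {
  if (reduction_wt_pct < 0 || reduction_wt_pct > 100 ||
      reduction_ko_pct < 0 || reduction_ko_pct > 100) {
    abort("percent reductions must lie in [0, 100]")
  }
  if (reduction_ko_pct > reduction_wt_pct) {
    abort(paste0(
      "knockout reduction exceeds wild-type reduction (negative neuronal-",
      "transporter share); the decomposition is inconsistent"))
  }
  tibble(eaac1_pct = reduction_wt_pct - reduction_ko_pct,
         glial_pct = reduction_ko_pct,
         denovo_pct = 100 - reduction_wt_pct,
         context = context)
}

#' Decompose GABA supply from raw amplitude pairs
#'
#' Computes the percent reduction of each genotype's response to transporter
#' blockade (see [percent_reduction()]) and feeds the pair to
#' [decompose_gaba_sources()]. Scale-invariant in the amplitudes.
#'
#' @param amp_ctrl_wt,amp_tboa_wt Wild-type amplitudes before/after blockade
#'   (`amp_ctrl_wt > 0`).
#' @param amp_ctrl_ko,amp_tboa_ko Knockout amplitudes before/after blockade
#'   (`amp_ctrl_ko > 0`).
#' @param context Free-text description.
#' @return A one-row tibble as in [decompose_gaba_sources()].
#' @export
decomposition_from_amplitudes <- function(amp_ctrl_wt, amp_tboa_wt,
                                          amp_ctrl_ko, amp_tboa_ko,
                                          context = "") {
  decompose_gaba_sources(percent_reduction(amp_ctrl_wt, amp_tboa_wt),
                         percent_reduction(amp_ctrl_ko, amp_tboa_ko),
                         context = context)
}
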