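# Tunable thresholds for motif detection and conformational classification.

#' Classification and detection configuration
#'
#' All geometric decision thresholds and motif-detection windows in one
#' place. Distances are Angstrom; windows are residue offsets on the 0-based
#' chain index.
#'
#' @param tau_d1 DFG-in cut on `d1`, the Calpha(alphaC-Glu + 4) to
#'   DFG-Phe-tip distance. `d1 <= tau_d1` is compatible with DFG-in.
#' @param tau_d2 DFG-out cut on `d2`, the beta3-Lys tip to DFG-Phe-tip
#'   distance. `d2 <= tau_d2` is compatible with DFG-out.
#' @param tau_salt_bridge alphaC-in cut on the Glu-carboxyl to Lys-amine
#'   salt-bridge distance (side-chain atoms).
#' @param tau_salt_bridge_ca Fallback alphaC-in cut on the Glu-Lys
#'   Calpha-Calpha distance, used (and flagged) when side chains are absent.
#' @param tau_loop Activation-loop cut on the Calpha(HRD-2) to Calpha(DFG+2)
#'   distance; at or below it the loop is called `extended`, above `folded`.
#' @param hrd_pattern,dfg_pattern Regular expressions for the HRD-like and
#'   DFG-like 3-mers used by [detect_motifs()]; substitution-tolerant by
#'   default (`DYG` kinases such as NEK9 still match).
#' @param gap_range Admissible residue gap from the HRD His to the DFG Asp.
#' @param gap_target Preferred HRD-to-DFG gap; the admissible pairing
#'   minimising `|gap - gap_target|` wins.
#' @param lys_window Offsets relative to the HRD His in which the last Lys is
#'   taken as beta3-Lys.
#' @param glu_window Offsets relative to beta3-Lys in which the first Glu is
#'   taken as the alphaC Glu.
#'
#' @return A list of class `kinconform_config`.
#' @export
#' @examples
#' cfg <- conformation_config(tau_loop = 9)
#' cfg$tau_loop
conformation_config <- function(tau_d1 = 11, tau_d2 = 11,
                                tau_salt_bridge = 4.5,
                                tau_salt_bridge_ca = 12,
                                tau_loop = 10,
                                hrd_pattern = "[HY]R[DN]",
                                dfg_pattern = "D[FYWL]G",
                                gap_range = c(10L, 40L),
                                gap_target = 20L,
                                lys_window = c(-80L, -20L),
                                glu_window = c(8L, 30L)) {
  stopifnot(tau_d1 > 0, tau_d2 > 0, tau_salt_bridge > 0,
            tau_salt_bridge_ca > 0, tau_loop > 0,
            length(gap_range) == 2L, gap_range[1] <= gap_range[2],
            length(lys_window) == 2L, length(glu_window) == 2L)
  structure(
    list(tau_d1 = tau_d1, tau_d2 = tau_d2,
         tau_salt_bridge = tau_salt_bridge,
         tau_salt_bridge_ca = tau_salt_bridge_ca,
         tau_loop = tau_loop,
         hrd_pattern = hrd_pattern, dfg_pattern = dfg_pattern,
         gap_range = as.integer(gap_range), gap_target = as.integer(gap_target),
         lys_window = as.integer(lys_window), glu_window = as.integer(glu_window)),
    class = "kinconform_config"
  )
}
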