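#' Phenotype classification by hair follicle density
#'
#' Embryos with fewer than `hairlessMax` follicles per cm2 are hairless and
#' those with more than `normalMin` are normal; densities in between are
#' indeterminate.
#'
#' @param density follicle density (follicles/cm2, >= 0); vectorized.
#' @param hairlessMax exclusive upper bound for hairless (default 1).
#' @param normalMin exclusive lower bound for normal (default 4).
#' @return Character vector: `hairless`, `normal` or `indeterminate`.
#' @export
#' @examples
#' classifyPhenotype(c(0.5, 2, 4.5))
classifyPhenotype <- function(density, hairlessMax = 1, normalMin = 4) {
  stopifnot(hairlessMax < normalMin)
  if (any(density < 0)) stop("density must be non-negative")
  ifelse(density < hairlessMax, "hairless",
         ifelse(density > normalMin, "normal", "indeterminate"))
}

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (Ct_target,treated - Ct_ref,treated) -
#' (Ct_target,control - Ct_ref,control)`; returns `2^-ddCt`. Invariant to
#' adding a constant to all four Ct values.
#'
#' @param ctTargetTreated,ctRefTreated,ctTargetControl,ctRefControl finite
#'   quantification-cycle values; vectorized.
#' @return Fold change(s).
#' @export
#' @examples
#' ddctFoldChange(25, 20, 24, 21)  # 0.25
ddctFoldChange <- function(ctTargetTreated, ctRefTreated,
                           ctTargetControl, ctRefControl) {
  ct <- cbind(ctTargetTreated, ctRefTreated, ctTargetControl, ctRefControl)
  if (any(!is.finite(ct))) stop("Ct values must be finite")
  ddct <- (ctTargetTreated - ctRefTreated) -
    (ctTargetControl - ctRefControl)
  2^(-ddct)
}
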