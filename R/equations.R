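#' The published GFA-MLR model equation
#'
#' The reference linear QSAR model shipped with the package:
#'
#' log(1/IC50) = 0.12 Hypo(5-R6-08) + 0.129 Hypo(1-R2-08)
#'   - 0.276 LYS_191_HZ2^CD - 0.22 VAL_324_HB^LD + 0.433 Num_Rings5
#'   - 0.002 PMI_x - 2.65 Shadow_XYfrac - 1.667
#'
#' mixing two pharmacophore fit values, two contact-fingerprint bits and
#' three physicochemical descriptors. Evaluate with
#' [mlr_equation_eval()].
#'
#' @return List with `coefficients` (named numeric) and `intercept`.
#' @examples
#' eq <- gfa_mlr_equation()
#' zeros <- stats::setNames(rep(0, length(eq$coefficients)),
#'                          names(eq$coefficients))
#' mlr_equation_eval(eq$coefficients, eq$intercept, zeros)  # -1.667
#' @export
gfa_mlr_equation <- function() {
  list(coefficients = c(
         "Hypo(5-R6-08)" = 0.12,
         "Hypo(1-R2-08)" = 0.129,
         "LYS_191_HZ2^CD" = -0.276,
         "VAL_324_HB^LD" = -0.22,
         "Num_Rings5" = 0.433,
         "PMI_x" = -0.002,
         "Shadow_XYfrac" = -2.65),
       intercept = -1.667)
}
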