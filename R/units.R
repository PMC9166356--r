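# Small shared statistics and unit conversions.

#' Normalized flux-change statistic
#'
#' `FC = (mean_b - mean_a) / (mean_b + mean_a)`, the symmetric effect-size
#' statistic for sampled flux distributions. Positive values mean higher
#' flux in condition b; an FC of 1/3 corresponds to a 2-fold change.
#'
#' @param mean_a,mean_b condition mean fluxes.
#' @param den_tol guard for a vanishing denominator (returns `NA`).
#' @return numeric FC value.
#' @export
flux_change <- function(mean_a, mean_b, den_tol = 1e-9) {
  den <- mean_a + mean_b
  ifelse(abs(den) < den_tol, NA_real_, (mean_b - mean_a) / den)
}

#' Convert a gravimetric ATP demand to mmol
#'
#' Converts a growth-associated maintenance value given in g ATP per gDCW
#' into mmol ATP per gDCW using the molar mass of ATP.
#'
#' @param grams ATP demand (g/gDCW).
#' @param molar_mass ATP molar mass (g/mol).
#' @return demand in mmol/gDCW.
#' @export
atp_gram_to_mmol <- function(grams, molar_mass = 507.18) {
  grams / molar_mass * 1000
}
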