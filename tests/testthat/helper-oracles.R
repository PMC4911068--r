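# Independent closed-form oracles, written before the implementation and
# kept separate from it. They evaluate the model equations directly from
# their printed algebraic form, with no unit conversion machinery.

# f0 of a string: L in mm, mu in kPa
oracle_string_fo <- function(L_mm, mu_kpa, rho = 1040) {
  (1 / (2 * (L_mm / 1000))) * sqrt((mu_kpa * 1000) / rho)
}

# frequency ratio across elongation, straight from the printed formula
oracle_fo_ratio <- function(L0, L1, L2, B) {
  (L2 / L1)^-1 * exp(0.5 * B * (L2 - L1) / L0)
}

# textbook two-sided t-test on an OLS slope with n-2 df
oracle_slope_p <- function(x, y) {
  n <- length(x)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  resid <- y - a - b * x
  se <- sqrt(sum(resid^2) / (n - 2) / sum((x - mean(x))^2))
  2 * stats::pt(-abs(b / se), df = n - 2)
}
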