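#' Canonical MMPI-2 scale order
#'
#' The three validity scales (L, F, K) followed by the ten clinical scales
#' in their conventional numbering (1 = Hs ... 0 = Si). Every matrix and
#' network in this package keeps its columns/nodes in this order.
#'
#' @return Character vector of the 13 canonical scale names.
#' @export
mmpi_scales <- function() {
  c("L", "F", "K", "Hs", "D", "Hy", "Pd", "Mf", "Pa", "Pt", "Sc", "Ma", "Si")
}

# Group-wise marginal T-score moments used to calibrate the synthetic
# generator: published demographics table of a matched 714 + 714 cohort.
# Columns: healthy mean/sd, schizophrenia mean/sd.
.mmpi_tscore_moments <- function() {
  m <- matrix(c(
    # mean_h, sd_h,  mean_s, sd_s
    50.19, 13.43, 57.74, 15.37, # L
    55.65, 14.38, 62.70, 14.55, # F
    50.96, 13.01, 56.89, 14.41, # K
    58.17, 14.10, 59.26, 11.13, # Hs
    56.11, 15.62, 53.95, 10.61, # D
    60.38, 14.42, 62.99, 14.25, # Hy
    57.11, 14.53, 56.87, 11.24, # Pd
    51.19, 13.51, 52.78, 10.34, # Mf
    52.54, 10.55, 56.23,  9.85, # Pa
    57.81, 13.58, 54.00, 10.16, # Pt
    56.19, 13.31, 57.79, 11.88, # Sc
    54.66, 11.01, 56.44,  9.98, # Ma
    47.06, 12.54, 43.10,  8.93  # Si
  ), ncol = 4, byrow = TRUE)
  dimnames(m) <- list(mmpi_scales(),
                      c("mean_healthy", "sd_healthy",
                        "mean_schizophrenia", "sd_schizophrenia"))
  m
}

#' Marginal T-score calibration moments per group
#'
#' Per-scale marginal means and standard deviations (T-score units) for the
#' healthy and schizophrenia groups that the synthetic generator targets.
#'
#' @return A 13 x 4 numeric matrix with rownames [mmpi_scales()] and columns
#'   `mean_healthy`, `sd_healthy`, `mean_schizophrenia`, `sd_schizophrenia`.
#' @export
mmpi_tscore_moments <- function() .mmpi_tscore_moments()
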