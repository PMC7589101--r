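# Physical constants used throughout the package.

#' Gas constant in kcal/(mol K)
#'
#' Used wherever a Boltzmann factor or a free-energy scale is needed:
#' torsion energy maps (\code{\link{conformation_map}}), Boltzmann-weighted
#' NOEs (\code{\link{boltzmann_noe}}) and the Metropolis sampler
#' (\code{\link{sample_ensemble}}).
#'
#' @format A length-one numeric, 1.98720425864e-3 kcal/(mol K).
#' @export
R_KCAL <- 1.98720425864e-3

# kB*T in kcal/mol at temperature T (K)
kT <- function(temperature) R_KCAL * temperature
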