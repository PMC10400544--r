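## Physical constants and shared defaults.

#' Physical constants used throughout the package
#'
#' @description
#' `GAS_CONSTANT_KJ` is the molar gas constant in kJ mol^-1 K^-1 (CODATA),
#' `FARADAY_KJ_PER_V` the Faraday constant expressed in kJ V^-1 mol^-1, and
#' `DEFAULT_TEMPERATURE_K` the default temperature (298.15 K) at which
#' driving forces are evaluated.
#'
#' @name tcosa-constants
#' @keywords internal
NULL

GAS_CONSTANT_KJ <- 8.314462618e-3
FARADAY_KJ_PER_V <- 96.485
DEFAULT_TEMPERATURE_K <- 298.15

## Default metabolite concentration window (molar) for thermodynamic analyses.
DEFAULT_C_MIN <- 1e-6
DEFAULT_C_MAX <- 0.02

## Default sentinel standard Gibbs energy (kJ/mol) for reactions without a
## computed value and for pure transporters; deliberately low so that it
## imposes only mild constraints on the attached concentrations.
DEFAULT_DG_SENTINEL <- -100

## Numerical conventions shared by the scenario logic.
MDF_EQUALITY_BAND <- 1e-3   # kJ/mol; two (Sub)MDF values closer than this are "equal"
ACTIVE_FLUX_EPS <- 1e-6     # mmol gDW^-1 h^-1; fluxes above this count as active

## Valid provenance tags for standard Gibbs energies.
DG_SOURCE_TAGS <- c("computed", "default_sentinel", "median_imputed",
                    "relaxed", "unconstrained")

`%||%` <- function(a, b) if (is.null(a)) b else a
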