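#' Bulk blood properties
#'
#' Container for the physical blood constants used throughout the model.
#' The defaults are the values used in the 3D-domain surrogate (Newtonian
#' density/viscosity) and the large-vessel asymptote of the diameter-
#' dependent viscosity law.
#'
#' @param density mass density (kg/m^3).
#' @param mu_newtonian Newtonian viscosity used for the imaged-domain
#'   surrogate segments (Pa s).
#' @param mu_newtonian_limit large-diameter asymptote of the apparent
#'   viscosity law at systemic haematocrit (Pa s); the calibrated
#'   viscosity mode scales its relative values so that
#'   \eqn{\mu_{app}(d \to \infty, 0.45)} equals this number.
#' @param hct_systemic systemic haematocrit (volume fraction, in (0, 1)).
#'
#' @return an object of class `blood_properties`.
#' @export
#' @examples
#' blood_properties()
blood_properties <- function(density = 1050,
                             mu_newtonian = 0.0046,
                             mu_newtonian_limit = 4.06e-3,
                             hct_systemic = 0.45) {
  check_positive(density, "density")
  check_positive(mu_newtonian, "mu_newtonian")
  check_positive(mu_newtonian_limit, "mu_newtonian_limit")
  if (!is.numeric(hct_systemic) || length(hct_systemic) != 1L ||
      !is.finite(hct_systemic) || hct_systemic <= 0 || hct_systemic >= 1) {
    stop_domain("`hct_systemic` must lie strictly between 0 and 1")
  }
  structure(
    list(density = density,
         mu_newtonian = mu_newtonian,
         mu_newtonian_limit = mu_newtonian_limit,
         hct_systemic = hct_systemic),
    class = "blood_properties"
  )
}

#' @export
print.blood_properties <- function(x, ...) {
  cat("<blood_properties>\n")
  cat(sprintf("  density:            %g kg/m^3\n", x$density))
  cat(sprintf("  mu_newtonian:       %g Pa s (domain)\n", x$mu_newtonian))
  cat(sprintf("  mu_newtonian_limit: %g Pa s (large-vessel asymptote)\n",
              x$mu_newtonian_limit))
  cat(sprintf("  hct_systemic:       %g\n", x$hct_systemic))
  invisible(x)
}
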