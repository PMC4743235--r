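## Diameter-dependent haematocrit and apparent blood viscosity.
##
## Below ~300 um tube diameter the haematocrit drops (plasma skimming) and
## below ~10 um the cell-free marginal layer reduces the apparent
## viscosity (Fahraeus-Lindqvist effect); in very narrow tubes the red
## cells squeeze and viscosity rises again.  The empirical in-vitro law
## used here (Pries-type) expresses the apparent viscosity as a function
## of tube diameter d (um) and haematocrit.

## Classical large-diameter constant of the relative in-vitro viscosity
## law; the calibrated mode evaluates the law in relative units with this
## constant and rescales to mu_newtonian_limit at large d.
MU_REL_INF <- 3.2

#' Tube haematocrit as a function of vessel diameter
#'
#' Constant systemic haematocrit above 300 um; below, the empirical
#' logarithmic reduction `hct_systemic * (0.196 log10(d) - 0.117)`,
#' clamped at zero (the raw expression crosses zero near d = 3.95 um).
#' The discontinuity at d = 300 um is a property of the empirical law and
#' is deliberately not smoothed; the boundary itself belongs to the
#' small-diameter branch.
#'
#' @param d vessel diameter in micrometres (vectorised).
#' @param hct_systemic systemic haematocrit fraction.
#' @param log_base `"log10"` (default) or `"ln"` for the logarithm in the
#'   small-diameter branch.  The empirical fit is conventionally base-10;
#'   the natural-log variant is exposed for sensitivity checks only.
#' @return haematocrit fraction(s) in `[0, hct_systemic]`.
#' @export
#' @examples
#' haematocrit_for_diameter(500) # systemic 0.45
#' haematocrit_for_diameter(100)
haematocrit_for_diameter <- function(d, hct_systemic = 0.45,
                                     log_base = c("log10", "ln")) {
  check_positive(d, "d")
  log_base <- match.arg(log_base)
  lg <- if (log_base == "log10") log10(d) else log(d)
  small <- pmax(0, hct_systemic * (0.196 * lg - 0.117))
  ifelse(d > 300, hct_systemic, small)
}

#' Shape exponent of the haematocrit dependence
#'
#' The exponent Cd controlling how the viscosity law depends on
#' haematocrit away from 0.45:
#' \deqn{C_d = (0.8 + e^{-0.075 d})\left(-1 + \frac{1}{1 + 10^{-11} d^{12}}\right)
#'       + \frac{1}{1 + 10^{-11} d^{12}}}
#' It tends to about 1 for capillary-scale diameters and to -0.8 for
#' large vessels.
#'
#' @inheritParams haematocrit_for_diameter
#' @return dimensionless exponent(s).
#' @export
shape_exponent <- function(d) {
  check_positive(d, "d")
  s <- 1 / (1 + 1e-11 * d^12)
  (0.8 + exp(-0.075 * d)) * (-1 + s) + s
}

#' Relative apparent viscosity at haematocrit 0.45
#'
#' In-vitro viscosity law at the reference haematocrit:
#' \deqn{\mu_{0.45}(d) = 6 e^{-0.085 d} + C_\infty - 2.44 e^{-0.06 d^{0.645}}}
#' In the default `"calibrated"` mode the large-diameter constant is the
#' classical relative value \eqn{C_\infty = 3.2} and the result is in
#' relative (plasma) units.  The `"literal"` mode instead inserts the
#' absolute Newtonian limit (`props$mu_newtonian_limit`, Pa s) directly as
#' the constant; that form is dimensionally inconsistent (an absolute
#' viscosity added to relative terms) and is provided for traceability
#' only.
#'
#' @inheritParams haematocrit_for_diameter
#' @param mode `"calibrated"` (relative units, default) or `"literal"`.
#' @param props [blood_properties()], used by the literal mode.
#' @return relative viscosity (dimensionless) in calibrated mode.
#' @export
mu_045_relative <- function(d, mode = c("calibrated", "literal"),
                            props = blood_properties()) {
  check_positive(d, "d")
  mode <- match.arg(mode)
  c_inf <- if (mode == "calibrated") MU_REL_INF else props$mu_newtonian_limit
  6 * exp(-0.085 * d) + c_inf - 2.44 * exp(-0.06 * d^0.645)
}

#' Apparent blood viscosity at a given diameter and haematocrit
#'
#' Full diameter- and haematocrit-dependent apparent viscosity:
#' \deqn{\mu_{app} = \left[1 + (\mu_{0.45} - 1)
#'   \frac{(1 - Hct)^{C_d}}{(1 - 0.45)^{C_d}}
#'   \left(\frac{d}{d - 1.1}\right)^2\right]
#'   \left(\frac{d}{d - 1.1}\right)^2}
#' The wall-layer factor \eqn{(d/(d-1.1))^2} (d in um) is singular at
#' d = 1.1 um, hence the domain restriction d > 1.1 um.
#'
#' In the default calibrated mode the law is evaluated in relative units
#' and scaled by `props$mu_newtonian_limit / 3.2` so that
#' \eqn{\mu_{app}(d \to \infty, 0.45)} equals `mu_newtonian_limit`
#' (4.06e-3 Pa s by default).  In literal mode the printed mixed-unit form
#' is returned unscaled in the `mu_app` field.
#'
#' @param d vessel diameter in micrometres (vectorised).
#' @param hct haematocrit fraction in `[0, 1)`; defaults to
#'   [haematocrit_for_diameter()] evaluated at `d`.
#' @param props [blood_properties()].
#' @param mode `"calibrated"` or `"literal"` (see [mu_045_relative()]).
#' @param hct_ratio `"printed"` uses the ratio
#'   \eqn{(1-Hct)^{C_d}/(1-0.45)^{C_d}} exactly as stated;
#'   `"classical"` uses the in-vitro form
#'   \eqn{((1-Hct)^{C_d}-1)/((1-0.45)^{C_d}-1)}.
#' @param log_base passed to [haematocrit_for_diameter()] when `hct` is
#'   derived from `d`.
#' @return a data frame of class `viscosity_evaluation` with columns
#'   `diameter` (um), `hct`, `cd`, `mu_045_rel` and `mu_app` (Pa s in
#'   calibrated mode).
#' @export
#' @examples
#' apparent_viscosity(1e4, hct = 0.45)   # Newtonian limit ~ 4.06e-3 Pa s
#' apparent_viscosity(24)                # terminal capillary diameter
apparent_viscosity <- function(d, hct = NULL, props = blood_properties(),
                               mode = c("calibrated", "literal"),
                               hct_ratio = c("printed", "classical"),
                               log_base = c("log10", "ln")) {
  check_positive(d, "d")
  mode <- match.arg(mode)
  hct_ratio <- match.arg(hct_ratio)
  log_base <- match.arg(log_base)
  if (any(d <= 1.1)) {
    stop_domain("`d` must exceed 1.1 um (wall-layer factor singularity)")
  }
  if (is.null(hct)) {
    hct <- haematocrit_for_diameter(d, props$hct_systemic, log_base)
  }
  if (!is.numeric(hct) || any(!is.finite(hct)) || any(hct < 0) ||
      any(hct >= 1)) {
    stop_domain("`hct` must lie in [0, 1)")
  }
  hct <- rep_len(hct, length(d))

  cd <- shape_exponent(d)
  mu45 <- mu_045_relative(d, mode, props)
  wall <- (d / (d - 1.1))^2
  ratio <- switch(hct_ratio,
    printed   = (1 - hct)^cd / (1 - 0.45)^cd,
    classical = ((1 - hct)^cd - 1) / ((1 - 0.45)^cd - 1)
  )
  mu_rel <- (1 + (mu45 - 1) * ratio * wall) * wall
  scale <- if (mode == "calibrated") props$mu_newtonian_limit / MU_REL_INF else 1
  structure(
    data.frame(diameter = d, hct = hct, cd = cd, mu_045_rel = mu45,
               mu_app = mu_rel * scale),
    class = c("viscosity_evaluation", "data.frame")
  )
}

## scalar/vector convenience used by the tree builder: apparent viscosity
## in Pa s with the haematocrit chained from the diameter
mu_app_at <- function(d_um, props = blood_properties(),
                      mode = "calibrated", hct_ratio = "printed",
                      log_base = "log10") {
  apparent_viscosity(d_um, hct = NULL, props = props, mode = mode,
                     hct_ratio = hct_ratio, log_base = log_base)$mu_app
}
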