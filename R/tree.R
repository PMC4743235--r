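#' Parameters of the fractal peripheral tree
#'
#' @param epsilon bifurcation exponent of the power law
#'   \eqn{d_p^\varepsilon = 2\,d_c^\varepsilon}; 3.0 for laminar flow
#'   (minimum-energy result), 2.33 sometimes used for turbulent flow.
#' @param terminal_radius_um stopping radius in micrometres; a generation
#'   whose radius falls to this value or below terminates the tree
#'   (capillary level, 12 um by default).
#' @param terminal_pressure_mmhg pressure imposed at the terminal
#'   generation (mmHg); the terminal resistance is adjusted to realise
#'   it (30 mmHg by default, within the physiological capillary range).
#' @return an object of class `tree_params`.
#' @export
#' @examples
#' tree_params()
tree_params <- function(epsilon = 3.0, terminal_radius_um = 12,
                        terminal_pressure_mmhg = 30) {
  check_positive(epsilon, "epsilon")
  check_positive(terminal_radius_um, "terminal_radius_um")
  if (terminal_radius_um * 0.5 <= 1.1 / 2) {
    ## viscosity law needs diameter > 1.1 um
    stop_domain("`terminal_radius_um` must exceed 0.55 um")
  }
  check_positive(terminal_pressure_mmhg, "terminal_pressure_mmhg")
  structure(
    list(epsilon = epsilon,
         terminal_radius_um = terminal_radius_um,
         terminal_pressure_mmhg = terminal_pressure_mmhg),
    class = "tree_params"
  )
}

#' Daughter diameter under the minimum-energy power law
#'
#' Symmetric bifurcation: both daughters satisfy
#' \eqn{d_c^\varepsilon = d_p^\varepsilon / 2}, i.e.
#' \eqn{d_c = d_p \cdot 2^{-1/\varepsilon}}.
#'
#' @param d_parent parent diameter (any length unit).
#' @param epsilon bifurcation exponent.
#' @return daughter diameter in the same unit.
#' @export
#' @examples
#' daughter_diameter(2, 3) / 2  # 2^(-1/3)
daughter_diameter <- function(d_parent, epsilon = 3.0) {
  check_positive(d_parent, "d_parent")
  check_positive(epsilon, "epsilon")
  d_parent * 0.5^(1 / epsilon)
}

#' Build the symmetric fractal peripheral tree from an outlet
#'
#' Constructs the binary symmetric tree of generations from an outlet of
#' radius `root_radius` down to the first generation at or below the
#' terminal (capillary) radius.  Generation k has radius
#' \eqn{r_k = r_0 \cdot 2^{-k/\varepsilon}} and \eqn{2^k} parallel
#' vessels.  Each generation is classified into a vessel group from its
#' diameter, carries the group's length-to-radius ratio \eqn{\lambda_k}
#' (or a constant \eqn{\lambda} in `lambda = "constant"` mode, used by
#' the conventional boundary-condition variant), and the apparent blood
#' viscosity evaluated at its own diameter (or the constant Newtonian
#' value in `viscosity = "newtonian"` mode).
#'
#' When `is_ica = TRUE` the outlet is treated as the internal carotid:
#' generation 0 takes the measured-data \eqn{\lambda} of the table's
#' `ica` row instead of a group lookup; deeper generations classify as
#' usual.
#'
#' @param root_radius outlet radius in metres.
#' @param params [tree_params()].
#' @param table [vessel_group_table()].
#' @param props [blood_properties()].
#' @param lambda `"table"` for per-group lookup (default) or
#'   `"constant"` for a single value at every generation.
#' @param lambda_constant the constant \eqn{\lambda} used when
#'   `lambda = "constant"` (30 for the conventional variant).
#' @param viscosity `"apparent"` (diameter-dependent, default) or
#'   `"newtonian"` (`props$mu_newtonian` everywhere).
#' @param is_ica logical; treat the outlet as the internal carotid.
#' @param mode viscosity calibration mode, see [apparent_viscosity()].
#' @return an object of class `peripheral_tree` with elements
#'   `root_radius`, `params`, `levels` (data frame: `index`, `radius`
#'   (m), `diameter_um`, `n_vessels`, `group`, `lambda`, `mu_app`) and
#'   `n_generations` (deepest generation index, root = 0).
#' @export
#' @examples
#' tr <- build_tree(1e-3)
#' tr
build_tree <- function(root_radius, params = tree_params(),
                       table = vessel_group_table(),
                       props = blood_properties(),
                       lambda = c("table", "constant"),
                       lambda_constant = 30,
                       viscosity = c("apparent", "newtonian"),
                       is_ica = FALSE,
                       mode = c("calibrated", "literal")) {
  check_positive(root_radius, "root_radius")
  lambda <- match.arg(lambda)
  viscosity <- match.arg(viscosity)
  mode <- match.arg(mode)
  terminal_m <- params$terminal_radius_um * 1e-6
  if (root_radius <= terminal_m) {
    stop_domain("outlet smaller than capillary: root radius ",
                format(root_radius), " m is at or below the terminal radius")
  }

  ## grow until the first generation at or below the terminal radius
  ratio <- 0.5^(1 / params$epsilon)
  radii <- root_radius
  while (radii[length(radii)] > terminal_m) {
    k <- length(radii) # next index
    radii <- c(radii, root_radius * ratio^k)
  }
  idx <- seq_along(radii) - 1L
  d_um <- 2 * radii * 1e6

  if (lambda == "table") {
    grp <- classify_vessel_group(d_um * 1e-3, table)
    lam <- table$lambda[match(grp, table$group)]
    if (is_ica) {
      ica_row <- match("ica", table$group)
      if (is.na(ica_row)) stop_domain("table has no `ica` row")
      lam[1L] <- table$lambda[ica_row]
      grp[1L] <- "ica"
    }
  } else {
    grp <- rep("constant_lambda", length(idx))
    lam <- rep(lambda_constant, length(idx))
  }

  mu <- if (viscosity == "apparent") {
    mu_app_at(d_um, props, mode = mode)
  } else {
    rep(props$mu_newtonian, length(idx))
  }

  levels <- data.frame(
    index = idx,
    radius = radii,
    diameter_um = d_um,
    n_vessels = 2^idx,
    group = grp,
    lambda = lam,
    mu_app = mu,
    stringsAsFactors = FALSE
  )
  structure(
    list(root_radius = root_radius, params = params, levels = levels,
         n_generations = max(idx)),
    class = "peripheral_tree"
  )
}

#' @export
print.peripheral_tree <- function(x, ...) {
  lv <- x$levels
  cat("<peripheral_tree>\n")
  cat(sprintf("  root radius : %.4g mm\n", x$root_radius * 1e3))
  cat(sprintf("  generations : 0..%d (%d levels, %s leaf vessels)\n",
              x$n_generations, nrow(lv),
              format(2^x$n_generations, big.mark = ",")))
  cat(sprintf("  leaf radius : %.4g um (terminal %.4g um)\n",
              lv$radius[nrow(lv)] * 1e6, x$params$terminal_radius_um))
  cat(sprintf("  groups      : %s\n",
              paste(unique(lv$group), collapse = " > ")))
  invisible(x)
}
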