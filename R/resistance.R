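## Recursive Poiseuille resistance over the symmetric peripheral tree.
##
## Each generation i contributes a segment resistance
##   R_seg,i = 8 mu_i lambda_i / (pi r_i^3)      (l_i = lambda_i r_i)
## per vessel.  Working from the deepest generation upward:
##   R_out[n]   = R_terminal
##   R_in[i]    = R_seg,i + R_out[i]
##   R_out[i-1] = R_in[i] / 2       (two identical daughters in parallel)
## The equivalent resistance seen at the outlet is R_in[0].

#' Poiseuille resistance of one tree segment
#'
#' \eqn{R = 8 \mu \lambda / (\pi r^3)}: the classical
#' \eqn{8 \mu l / (\pi r^4)} with the segment length set by the
#' length-to-radius ratio, \eqn{l = \lambda r}.
#'
#' @param radius vessel radius (m).
#' @param lambda_ratio length-to-radius ratio (dimensionless).
#' @param mu dynamic viscosity (Pa s).
#' @return resistance in Pa s/m^3 (vectorised).
#' @export
#' @examples
#' segment_resistance(6e-4, 16.6667, 0.0046)
segment_resistance <- function(radius, lambda_ratio, mu) {
  check_positive(radius, "radius")
  check_positive(lambda_ratio, "lambda_ratio")
  check_positive(mu, "mu")
  8 * mu * lambda_ratio / (pi * radius^3)
}

#' Terminal resistance from terminal pressure and flow
#'
#' The lumped resistance closing the deepest generation,
#' \eqn{R = p_{terminal} / q_{terminal}} (venous reference pressure 0 on
#' its far side).  A zero terminal pressure yields zero resistance — the
#' setting of the conventional constant-\eqn{\lambda} variant.
#'
#' @param p_terminal terminal pressure (Pa), non-negative.
#' @param q_terminal flow through one terminal vessel (m^3/s), positive.
#' @return resistance in Pa s/m^3.
#' @export
terminal_resistance <- function(p_terminal, q_terminal) {
  if (!is.numeric(p_terminal) || any(!is.finite(p_terminal)) ||
      any(p_terminal < 0)) {
    stop_domain("`p_terminal` must be finite and non-negative")
  }
  if (!is.numeric(q_terminal) || any(!is.finite(q_terminal)) ||
      any(q_terminal <= 0)) {
    stop_domain("`q_terminal` must be strictly positive (unperfused outlet?)")
  }
  p_terminal / q_terminal
}

#' Per-generation resistance profile of a peripheral tree
#'
#' Runs the backward series/parallel recursion from the terminal
#' resistance up to the root.  All resistances are per single vessel of
#' their generation; parallelism enters only through the halving at each
#' symmetric bifurcation.
#'
#' @param tree a [build_tree()] result.
#' @param terminal_res terminal resistance (Pa s/m^3) closing each leaf
#'   vessel; 0 by default.
#' @return an object of class `resistance_profile` with per-level
#'   vectors `r_segment`, `r_in` (\eqn{R_i(0)}), `r_out`
#'   (\eqn{R_i(L)}), plus `terminal_resistance` and `root_resistance`
#'   (= `r_in[1]`, the resistance seen at the outlet).
#' @export
#' @examples
#' tr <- build_tree(5e-4)
#' compute_profile(tr)$root_resistance
compute_profile <- function(tree, terminal_res = 0) {
  stopifnot(inherits(tree, "peripheral_tree"))
  lv <- tree$levels
  if (!nrow(lv)) stop_domain("empty tree")
  if (!is.numeric(terminal_res) || terminal_res < 0) {
    stop_domain("`terminal_res` must be non-negative")
  }
  n1 <- nrow(lv)
  r_seg <- segment_resistance(lv$radius, lv$lambda, lv$mu_app)
  r_in <- numeric(n1)
  r_out <- numeric(n1)
  r_out[n1] <- terminal_res
  for (i in n1:1) {
    r_in[i] <- r_seg[i] + r_out[i]
    if (i > 1) r_out[i - 1] <- r_in[i] / 2
  }
  structure(
    list(r_segment = r_seg, r_in = r_in, r_out = r_out,
         terminal_resistance = terminal_res, root_resistance = r_in[1]),
    class = "resistance_profile"
  )
}

#' @export
print.resistance_profile <- function(x, ...) {
  cat("<resistance_profile>\n")
  cat(sprintf("  levels              : %d\n", length(x$r_in)))
  cat(sprintf("  root resistance     : %.6g Pa s/m^3\n", x$root_resistance))
  cat(sprintf("  terminal resistance : %.6g Pa s/m^3\n",
              x$terminal_resistance))
  invisible(x)
}

#' Pressure profile along the tree for a given root flow
#'
#' Gauge pressures (venous reference 0 beyond the terminal resistor).
#' The inlet pressure of generation i is \eqn{(q/2^i) R_i(0)}; the
#' terminal pressure is the drop across the terminal resistor,
#' \eqn{(q/2^n) R_{terminal}}.
#'
#' @param tree a [build_tree()] result.
#' @param profile matching [compute_profile()] result.
#' @param q_root flow entering the tree root (m^3/s), positive.
#' @return an object of class `pressure_profile` with `p_inlet` (Pa, one
#'   per level), `p_terminal` (Pa) and `q_root`.
#' @export
pressure_profile <- function(tree, profile, q_root) {
  stopifnot(inherits(tree, "peripheral_tree"),
            inherits(profile, "resistance_profile"))
  check_positive(q_root, "q_root")
  idx <- tree$levels$index
  q_level <- q_root / 2^idx
  p_in <- q_level * profile$r_in
  p_term <- (q_root / 2^tree$n_generations) * profile$terminal_resistance
  structure(
    list(p_inlet = p_in, p_terminal = p_term, q_root = q_root),
    class = "pressure_profile"
  )
}

#' Set the terminal resistance to hit the physiological terminal pressure
#'
#' In standalone (uncoupled) use the symmetric flow split makes the
#' terminal flow exactly \eqn{q_{root}/2^n}, so the fixed point is closed
#' form: \eqn{R_{terminal} = P_{terminal} / (q_{root}/2^n)}.  The
#' returned pressure profile then ends at exactly the configured terminal
#' pressure (30 mmHg by default).
#'
#' @param tree a [build_tree()] result.
#' @param q_root flow entering the tree root (m^3/s), positive.
#' @return list with elements `profile` ([compute_profile()] result
#'   including the adjusted terminal resistance) and `pressures`
#'   ([pressure_profile()] result).
#' @export
#' @examples
#' tr <- build_tree(1e-3)
#' sol <- solve_terminal_fixed_point(tr, 1e-6)
#' pa_to_mmhg(sol$pressures$p_terminal)  # 30
solve_terminal_fixed_point <- function(tree, q_root) {
  stopifnot(inherits(tree, "peripheral_tree"))
  check_positive(q_root, "q_root")
  n <- tree$n_generations
  q_leaf <- q_root / 2^n
  p_term <- mmhg_to_pa(tree$params$terminal_pressure_mmhg)
  r_term <- terminal_resistance(p_term, q_leaf)
  profile <- compute_profile(tree, r_term)
  list(profile = profile,
       pressures = pressure_profile(tree, profile, q_root))
}

#' Explicit-network reference computation of the root resistance
#'
#' Reference implementation used to validate the recursion: every vessel
#' of the binary tree is materialised as its own resistor (\eqn{2^i}
#' entries at generation i) and the network is reduced from the leaves by
#' elementary series and pairwise-parallel steps.  Exponential in depth,
#' so restricted to small trees.
#'
#' @param tree a [build_tree()] result with at most `max_generations`
#'   generations.
#' @param terminal_res terminal resistance per leaf vessel (Pa s/m^3).
#' @param sever_one_root_daughter logical; if `TRUE` (and the tree has at
#'   least one bifurcation) one of the root's two daughter subtrees is
#'   removed (infinite resistance), which doubles the sub-root
#'   resistance relative to the symmetric case.
#' @param max_generations enumeration cap (default 18, i.e. at most
#'   2^18 leaf resistors).
#' @return equivalent resistance at the tree root (Pa s/m^3).
#' @export
explicit_network_resistance <- function(tree, terminal_res = 0,
                                        sever_one_root_daughter = FALSE,
                                        max_generations = 18) {
  stopifnot(inherits(tree, "peripheral_tree"))
  if (tree$n_generations > max_generations) {
    stop_domain("tree too deep for explicit enumeration (",
                tree$n_generations, " > ", max_generations, " generations)")
  }
  lv <- tree$levels
  n1 <- nrow(lv)
  r_seg <- segment_resistance(lv$radius, lv$lambda, lv$mu_app)
  ## downstream equivalent resistance of each vessel at the current level
  req <- rep(r_seg[n1] + terminal_res, 2^(n1 - 1L))
  if (sever_one_root_daughter && n1 < 2L) {
    stop_domain("cannot sever a daughter of a single-level tree")
  }
  if (sever_one_root_daughter && n1 == 2L) req[1L] <- Inf
  if (n1 > 1L) {
    for (i in (n1 - 1L):1L) {
      odd <- seq(1L, length(req), by = 2L)
      par <- 1 / (1 / req[odd] + 1 / req[odd + 1L])
      req <- r_seg[i] + par
      if (sever_one_root_daughter && i == 2L) req[1L] <- Inf
    }
  }
  req[1L]
}
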