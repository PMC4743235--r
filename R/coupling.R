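## Coupling of the lumped surrogate domain with the 0D peripheral models.
##
## The exchange mirrors the 3D<->0D contract: the domain solve hands each
## outlet's flow to its peripheral model, which returns an outlet
## pressure (equivalently a lumped resistance to venous reference); the
## domain is re-solved until outlet flows stabilise.  For the
## terminal-pressure variant the outlet's lumped resistance is affine in
## 1/q: R(q) = R_tree(R_term = 0) + P_terminal / q, because the terminal
## resistor contributes R_term / 2^n and R_term = P_terminal 2^n / q.

#' Flow through a circular section from its mean velocity (and back)
#'
#' Uniform-profile convention: \eqn{Q = v \pi r^2} and
#' \eqn{v = Q / (\pi r^2)}.
#'
#' @param radius section radius (m).
#' @param velocity mean velocity (m/s), non-negative.
#' @param flow volumetric flow (m^3/s).
#' @return flow in m^3/s, or mean velocity in m/s.
#' @export
#' @examples
#' inlet_flow_from_velocity(3e-3, 0.3)
#' velocity_from_flow(inlet_flow_from_velocity(3e-3, 0.3), 3e-3)
inlet_flow_from_velocity <- function(radius, velocity) {
  check_positive(radius, "radius")
  if (any(!is.finite(velocity)) || any(velocity < 0)) {
    stop_domain("`velocity` must be non-negative")
  }
  velocity * pi * radius^2
}

#' @rdname inlet_flow_from_velocity
#' @export
velocity_from_flow <- function(flow, radius) {
  check_positive(radius, "radius")
  flow / (pi * radius^2)
}

#' Attach an outflow boundary-condition model to each outlet
#'
#' Builds the per-outlet terminal model for one of the three variants:
#' \describe{
#'   \item{`zero_pressure`}{outlet pressure identically 0 (lumped
#'     resistance 0); no peripheral tree.}
#'   \item{`conventional_0d`}{peripheral tree with constant
#'     \eqn{\lambda} (30 by default) at every generation and zero
#'     terminal resistance; the lumped resistance is constant.}
#'   \item{`present_0d`}{peripheral tree with the group-wise
#'     \eqn{\lambda} schedule; the terminal resistance tracks the outlet
#'     flow so that the terminal pressure equals the configured value
#'     (30 mmHg), making the lumped resistance flow-dependent:
#'     \eqn{R(q) = R_{tree} + P_{terminal}/q}.}
#' }
#'
#' @param outlets an [outlet_set()].
#' @param variant one of `"zero_pressure"`, `"conventional_0d"`,
#'   `"present_0d"`.
#' @param config a [run_config()].
#' @return an object of class `outlet_bcs`: one entry per outlet with
#'   the built tree (if any), its flow-independent lumped part `r_base`
#'   (Pa s/m^3) and bookkeeping fields.
#' @export
attach_boundary_conditions <- function(outlets,
                                       variant = c("present_0d",
                                                   "conventional_0d",
                                                   "zero_pressure"),
                                       config = run_config()) {
  stopifnot(inherits(outlets, "outlet_set"), inherits(config, "run_config"))
  if (is.character(variant) &&
      !all(variant %in% c("present_0d", "conventional_0d", "zero_pressure"))) {
    stop_domain("unknown variant: ",
                paste(setdiff(variant, c("present_0d", "conventional_0d",
                                         "zero_pressure")), collapse = ", "))
  }
  variant <- match.arg(variant)
  p_term_pa <- mmhg_to_pa(config$params$terminal_pressure_mmhg)
  bcs <- lapply(seq_len(nrow(outlets)), function(i) {
    o <- outlets[i, ]
    if (variant == "zero_pressure") {
      return(list(name = o$name, radius = o$radius, variant = variant,
                  tree = NULL, r_base = 0, p_terminal_pa = 0,
                  n_generations = NA_integer_))
    }
    tree <- build_tree(
      o$radius, params = config$params, table = config$table,
      props = config$props,
      lambda = if (variant == "conventional_0d") "constant" else "table",
      lambda_constant = config$lambda_constant,
      is_ica = isTRUE(o$is_ica) && variant == "present_0d",
      mode = config$viscosity_mode
    )
    r_base <- compute_profile(tree, 0)$root_resistance
    list(name = o$name, radius = o$radius, variant = variant, tree = tree,
         r_base = r_base,
         p_terminal_pa = if (variant == "present_0d") p_term_pa else 0,
         n_generations = tree$n_generations)
  })
  structure(list(variant = variant, bcs = bcs, config = config),
            class = "outlet_bcs")
}

## lumped outlet resistance given the current outlet flow
lumped_resistance <- function(bc, q) {
  switch(bc$variant,
    zero_pressure = 0,
    conventional_0d = bc$r_base,
    present_0d = bc$r_base + bc$p_terminal_pa / q
  )
}

## ---- surrogate network solvers -------------------------------------------

## Per-edge Poiseuille resistance of the surrogate (Newtonian domain
## viscosity, as in the 3D solver it stands in for).
surrogate_edge_resistance <- function(segments, mu) {
  8 * mu * segments$length / (pi * segments$radius^4)
}

## Tree-reduction solve: downstream equivalent resistances bottom-up,
## then flow distribution top-down by conductance shares (shares at each
## junction sum to one, so mass is conserved to rounding).
solve_surrogate_tree <- function(surrogate, outlet_resistance, q_in, mu) {
  seg <- surrogate$segments
  r_edge <- surrogate_edge_resistance(seg, mu)
  children <- split(seq_len(nrow(seg)), seg$from)
  out_r <- stats::setNames(rep(NA_real_, nrow(surrogate$outlets)),
                           surrogate$outlets$name)
  out_r[names(outlet_resistance)] <- outlet_resistance

  req <- new.env(parent = emptyenv())
  req_of <- function(node) {
    if (!is.null(req[[node]])) return(req[[node]])
    kids <- children[[node]]
    val <- if (is.null(kids)) {
      r <- out_r[[node]]
      if (is.na(r)) stop_domain("leaf node without outlet model: ", node)
      r
    } else {
      branch <- vapply(kids, function(e) r_edge[e] + req_of(seg$to[e]),
                       numeric(1))
      1 / sum(1 / branch)
    }
    req[[node]] <- val
    val
  }

  p <- new.env(parent = emptyenv())
  q_node <- new.env(parent = emptyenv())
  distribute <- function(node, q_here) {
    q_node[[node]] <- q_here
    p_here <- p[[node]]
    kids <- children[[node]]
    if (is.null(kids)) return(invisible())
    branch <- vapply(kids, function(e) r_edge[e] + req_of(seg$to[e]),
                     numeric(1))
    share <- (1 / branch) / sum(1 / branch)
    for (j in seq_along(kids)) {
      e <- kids[j]
      q_e <- q_here * share[j]
      child <- seg$to[e]
      ## leaf pressure is defined by its lumped outlet model (exact for
      ## zero-resistance outlets); internal nodes march down the drop
      p[[child]] <- if (is.null(children[[child]])) {
        q_e * out_r[[child]]
      } else {
        p_here - q_e * r_edge[e]
      }
      distribute(child, q_e)
    }
  }

  root <- surrogate$inlet$name
  p[[root]] <- q_in * req_of(root)
  distribute(root, q_in)

  onames <- surrogate$outlets$name
  list(
    outlet_flows = stats::setNames(
      vapply(onames, function(nm) q_node[[nm]], numeric(1)), onames),
    outlet_pressures = stats::setNames(
      vapply(onames, function(nm) p[[nm]], numeric(1)), onames),
    inlet_pressure = p[[root]],
    total_resistance = req_of(root)
  )
}

#' One-shot nodal-analysis solution of the surrogate network
#'
#' Independent reference solver for fixed outlet resistances: assembles
#' the full node-conductance matrix of the surrogate (outlet lumped
#' resistors to venous reference 0) and solves the linear system in one
#' shot.  Outlets with zero lumped resistance are clamped to the
#' reference pressure.  Used to validate the tree-reduction solver.
#'
#' @param surrogate a [domain_surrogate()].
#' @param outlet_resistance named vector of lumped outlet resistances
#'   (Pa s/m^3), one per outlet.
#' @param q_in inlet flow (m^3/s).
#' @param mu domain viscosity (Pa s).
#' @return list with `outlet_flows`, `outlet_pressures` (named, Pa) and
#'   `inlet_pressure`.
#' @export
solve_network_nodal <- function(surrogate, outlet_resistance, q_in,
                                mu = blood_properties()$mu_newtonian) {
  stopifnot(inherits(surrogate, "domain_surrogate"))
  seg <- surrogate$segments
  r_edge <- surrogate_edge_resistance(seg, mu)
  onames <- surrogate$outlets$name
  out_r <- stats::setNames(rep(NA_real_, length(onames)), onames)
  out_r[names(outlet_resistance)] <- outlet_resistance
  if (any(is.na(out_r))) stop_domain("missing outlet resistance(s)")

  clamped <- onames[out_r == 0]                # held at reference pressure
  nodes <- setdiff(unique(c(surrogate$inlet$name, seg$from, seg$to)), clamped)
  ni <- stats::setNames(seq_along(nodes), nodes)
  G <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  add_edge <- function(a, b, g) {
    ## b may be the reference (ground or a clamped outlet)
    ia <- ni[[a]]
    G[ia, ia] <<- G[ia, ia] + g
    if (b %in% names(ni)) {
      ib <- ni[[b]]
      G[ia, ib] <<- G[ia, ib] - g
      G[ib, ia] <<- G[ib, ia] - g
      G[ib, ib] <<- G[ib, ib] + g
    }
  }
  for (e in seq_len(nrow(seg))) {
    if (seg$to[e] %in% clamped) {
      add_edge(seg$from[e], "<ref>", 1 / r_edge[e])
    } else {
      add_edge(seg$from[e], seg$to[e], 1 / r_edge[e])
    }
  }
  for (nm in setdiff(onames, clamped)) add_edge(nm, "<ref>", 1 / out_r[[nm]])

  b <- rep(0, length(nodes))
  b[ni[[surrogate$inlet$name]]] <- q_in
  pr <- solve(G, b)

  out_p <- stats::setNames(rep(0, length(onames)), onames)
  out_p[setdiff(onames, clamped)] <- pr[setdiff(onames, clamped)]
  out_q <- stats::setNames(numeric(length(onames)), onames)
  for (nm in onames) {
    if (nm %in% clamped) {
      e <- which(seg$to == nm)
      out_q[nm] <- pr[[seg$from[e]]] / r_edge[e]
    } else {
      out_q[nm] <- out_p[[nm]] / out_r[[nm]]
    }
  }
  list(outlet_flows = out_q, outlet_pressures = out_p,
       inlet_pressure = pr[[surrogate$inlet$name]])
}

## ---- coupled solve --------------------------------------------------------

#' Solve the surrogate domain coupled to its outflow models
#'
#' Successive-substitution exchange: (a) solve the resistive surrogate
#' network with the current lumped outlet resistances, (b) update each
#' flow-dependent outlet model (the terminal-pressure variant) from the
#' new outlet flows, until the maximum relative change of any outlet
#' flow drops below `config$coupling_tol`.  If the residual grows
#' between iterations the resistance update is under-relaxed by 0.5.
#' Mass is conserved at every iteration by construction of the
#' tree-reduction solve.
#'
#' @param surrogate a [domain_surrogate()].
#' @param variant outflow variant, see [attach_boundary_conditions()].
#' @param config a [run_config()].
#' @return an object of class `coupled_solution`: `variant`, `outlets`
#'   (data frame with flow, pressures in Pa and mmHg, mean velocity and
#'   per-outlet lumped/terminal resistance), `inlet_flow`,
#'   `inlet_pressure`, `iterations`, `converged`, `residual` and the
#'   full `residual_history`.
#' @export
#' @examples
#' fx <- fixture_config(seed = 7, n_branches = 7)
#' sg <- make_surrogate(make_outlet_set(fx), fx)
#' solve_coupled(sg, "present_0d")
solve_coupled <- function(surrogate,
                          variant = c("present_0d", "conventional_0d",
                                      "zero_pressure"),
                          config = run_config()) {
  stopifnot(inherits(surrogate, "domain_surrogate"))
  variant <- match.arg(variant)
  bcs <- attach_boundary_conditions(surrogate$outlets, variant, config)
  q_in <- inlet_flow_from_velocity(surrogate$inlet$radius,
                                   surrogate$inlet$velocity)
  if (q_in <= 0) stop_domain("inlet flow must be positive")
  mu <- config$props$mu_newtonian
  onames <- surrogate$outlets$name
  r_lumped <- stats::setNames(
    vapply(bcs$bcs, function(b) b$r_base, numeric(1)), onames)

  q_prev <- NULL
  residual <- Inf
  history <- numeric(0)
  converged <- FALSE
  iter <- 0L
  sol <- NULL
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    sol <- solve_surrogate_tree(surrogate, r_lumped, q_in, mu)
    q <- sol$outlet_flows
    if (!is.null(q_prev)) {
      res_new <- max(abs(q - q_prev) / q)
      relax <- length(history) > 0 && res_new > history[length(history)]
      history <- c(history, res_new)
      if (res_new < config$coupling_tol) {
        residual <- res_new
        converged <- TRUE
        break
      }
      residual <- res_new
    } else {
      relax <- FALSE
    }
    q_prev <- q
    r_new <- stats::setNames(
      mapply(lumped_resistance, bcs$bcs, q[onames]), onames)
    r_lumped <- if (relax) 0.5 * (r_new + r_lumped) else r_new
  }
  if (!converged) {
    stop(structure(
      class = c("peritree_no_convergence", "error", "condition"),
      list(message = sprintf(
             "coupled solve did not converge in %d iterations (residual %g)",
             iter, residual),
           call = sys.call(-1), residual_history = history)))
  }

  q <- sol$outlet_flows
  p <- sol$outlet_pressures
  term_res <- vapply(seq_along(onames), function(i) {
    b <- bcs$bcs[[i]]
    if (b$variant != "present_0d") 0
    else terminal_resistance(b$p_terminal_pa, q[i] / 2^b$n_generations)
  }, numeric(1))
  out <- data.frame(
    name = onames,
    radius = surrogate$outlets$radius,
    flow = as.numeric(q),
    pressure_pa = as.numeric(p),
    pressure_mmhg = pa_to_mmhg(as.numeric(p)),
    velocity = velocity_from_flow(as.numeric(q), surrogate$outlets$radius),
    lumped_resistance = as.numeric(r_lumped),
    terminal_resistance = term_res,
    stringsAsFactors = FALSE
  )
  structure(
    list(variant = variant, outlets = out, inlet_flow = q_in,
         inlet_pressure = sol$inlet_pressure, iterations = iter,
         converged = converged, residual = residual,
         residual_history = history),
    class = "coupled_solution"
  )
}

#' @export
print.coupled_solution <- function(x, ...) {
  cat(sprintf("<coupled_solution> variant = %s\n", x$variant))
  cat(sprintf("  inlet flow : %.4g mL/s, inlet pressure %.4g mmHg\n",
              x$inlet_flow * 1e6, pa_to_mmhg(x$inlet_pressure)))
  cat(sprintf("  iterations : %d (converged: %s, residual %.3g)\n",
              x$iterations, x$converged, x$residual))
  df <- x$outlets
  df$flow <- df$flow * 1e6
  df$velocity <- df$velocity * 1e2
  print(format(df[, c("name", "flow", "pressure_mmhg", "velocity")],
               digits = 4), row.names = FALSE)
  cat("  (flow in mL/s, velocity in cm/s)\n")
  invisible(x)
}

## relative velocity errors of a solution against measured velocities
velocity_errors <- function(solution, outlets) {
  stopifnot(inherits(solution, "coupled_solution"),
            inherits(outlets, "outlet_set"))
  m <- outlets$measured_velocity[match(solution$outlets$name, outlets$name)]
  abs(solution$outlets$velocity - m) / m
}

#' Compare the three outflow variants on one surrogate
#'
#' Solves the surrogate under the zero-pressure, conventional and
#' terminal-pressure variants and tabulates per-outlet velocities and
#' pressures.  Where outlets carry measured velocities, per-outlet
#' relative errors \eqn{|v_{sim} - v_{meas}| / v_{meas}} and their mean
#' and standard deviation per variant are reported (in percent).
#'
#' @param surrogate a [domain_surrogate()].
#' @param config a [run_config()].
#' @param variants character vector of variants to run.
#' @return an object of class `variant_comparison`: `table` (long per
#'   outlet x variant), `summary` (per variant mean/sd error, percent;
#'   `NA` without measurements) and the named list of `solutions`.
#' @export
compare_variants <- function(surrogate, config = run_config(),
                             variants = c("zero_pressure",
                                          "conventional_0d",
                                          "present_0d")) {
  stopifnot(inherits(surrogate, "domain_surrogate"))
  sols <- lapply(variants, function(v) solve_coupled(surrogate, v, config))
  names(sols) <- variants
  tab <- do.call(rbind, lapply(variants, function(v) {
    s <- sols[[v]]
    err <- velocity_errors(s, surrogate$outlets)
    data.frame(
      variant = v,
      name = s$outlets$name,
      flow = s$outlets$flow,
      velocity = s$outlets$velocity,
      velocity_cm_s = s$outlets$velocity * 1e2,
      pressure_mmhg = s$outlets$pressure_mmhg,
      measured_velocity = surrogate$outlets$measured_velocity[
        match(s$outlets$name, surrogate$outlets$name)],
      rel_error = err,
      stringsAsFactors = FALSE
    )
  }))
  summary <- do.call(rbind, lapply(variants, function(v) {
    err <- tab$rel_error[tab$variant == v]
    err <- err[is.finite(err)]
    data.frame(
      variant = v,
      n_measured = length(err),
      mean_error_pct = if (length(err)) mean(err) * 100 else NA_real_,
      sd_error_pct = if (length(err) > 1) stats::sd(err) * 100 else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  structure(list(table = tab, summary = summary, solutions = sols),
            class = "variant_comparison")
}

#' @export
print.variant_comparison <- function(x, ...) {
  cat("<variant_comparison>\n")
  print(format(x$summary, digits = 4), row.names = FALSE)
  wide <- stats::reshape(
    x$table[, c("variant", "name", "velocity_cm_s")],
    idvar = "name", timevar = "variant", direction = "wide")
  print(format(wide, digits = 4), row.names = FALSE)
  cat("  (velocities in cm/s)\n")
  invisible(x)
}
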