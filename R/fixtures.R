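## Seeded generators of carotid-like outlet sets and domain surrogates.
##
## No imaging or Doppler data ship with the package; these synthetic
## fixtures emulate the anatomy of the carotid analysis region (an ICA
## plus 7-9 external-carotid branches) so that every pipeline stage is
## testable.  They are labelled synthetic throughout: branch diameters
## are drawn uniformly within vessel-group intervals, not from patient
## statistics.

## ECA branch name pool in rough anatomical order; seven-branch sets
## drop the two branches most often unresolved in imaging.
ECA_BRANCH_NAMES <- c("SThA", "LA", "FA", "OA", "MA", "STA", "MMA",
                      "PAA", "TFA")
ICA_AVG_DIAMETER_MM <- 5.4834

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Configuration of the synthetic-fixture generator
#'
#' @param seed integer RNG seed; all generator output is a deterministic
#'   function of it.
#' @param n_branches number of external-carotid branch outlets in
#'   addition to the ICA (7 or 9 in the imaged models, depending on
#'   resolution).
#' @param diameter_jitter relative spread applied to the ICA and inlet
#'   diameters.
#' @param inlet_velocity mean common-carotid inlet velocity (m/s).
#' @param inlet_radius common-carotid inlet radius (m).
#' @param noise_sd relative standard deviation of the Gaussian noise on
#'   pseudo-measured velocities.
#' @return an object of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L, n_branches = 9L,
                           diameter_jitter = 0.05, inlet_velocity = 0.3,
                           inlet_radius = 3.5e-3, noise_sd = 0.05) {
  stopifnot(n_branches >= 1, diameter_jitter >= 0, noise_sd >= 0)
  check_positive(inlet_velocity, "inlet_velocity")
  check_positive(inlet_radius, "inlet_radius")
  structure(
    list(seed = as.integer(seed), n_branches = as.integer(n_branches),
         diameter_jitter = diameter_jitter, inlet_velocity = inlet_velocity,
         inlet_radius = inlet_radius, noise_sd = noise_sd),
    class = "fixture_config"
  )
}

#' Generate a synthetic carotid-like outlet set
#'
#' One ICA outlet with diameter near the anatomical mean (5.4834 mm,
#' jittered) plus `n_branches` external-carotid branch outlets.  Each
#' branch is assigned to the main-artery-branch or terminal-artery-
#' branch group at random and its diameter is drawn uniformly within
#' that group's classification interval, so generated diameters always
#' classify back into their declared group.
#'
#' @param config a [fixture_config()].
#' @param table a [vessel_group_table()].
#' @return an [outlet_set()] with an extra `group` column.
#' @export
#' @examples
#' make_outlet_set(fixture_config(seed = 42, n_branches = 7))
make_outlet_set <- function(config = fixture_config(),
                            table = vessel_group_table()) {
  stopifnot(inherits(config, "fixture_config"))
  nb <- config$n_branches
  nm <- if (nb <= length(ECA_BRANCH_NAMES)) {
    if (nb == 7L) setdiff(ECA_BRANCH_NAMES, c("PAA", "TFA"))
    else ECA_BRANCH_NAMES[seq_len(nb)]
  } else {
    c(ECA_BRANCH_NAMES,
      sprintf("BR%02d", seq_len(nb - length(ECA_BRANCH_NAMES))))
  }
  bounds <- function(grp) {
    i <- match(grp, table$group)
    o <- table[table$group != "ica", ]
    o <- o[order(o$min_diameter_mm), ]
    j <- match(grp, o$group)
    upper <- if (j < nrow(o)) o$min_diameter_mm[j + 1L] else Inf
    c(o$min_diameter_mm[j], upper)
  }
  with_seed(config$seed, {
    ica_d <- ICA_AVG_DIAMETER_MM *
      (1 + stats::runif(1, -config$diameter_jitter, config$diameter_jitter))
    grp <- sample(c("main_artery_branches", "terminal_artery_branches"),
                  nb, replace = TRUE)
    d <- vapply(grp, function(g) {
      b <- bounds(g)
      stats::runif(1, b[1], b[2])
    }, numeric(1))
    out <- outlet_set(
      name = c("ICA", nm),
      radius = c(ica_d, d) / 2 * 1e-3,
      is_ica = c(TRUE, rep(FALSE, nb))
    )
    out$group <- c(classify_vessel_group(ica_d, table), grp)
    out
  })
}

#' Build a synthetic surrogate domain over an outlet set
#'
#' Recursive binary splitting of the outlet list yields a branching tree
#' of Poiseuille segments from a common-carotid inlet to every outlet.
#' Junction radii follow the cube-law parent rule
#' \eqn{r_p = (r_1^3 + r_2^3)^{1/3}} bottom-up; every segment length is
#' 5 diameters (the branch-truncation rule of the imaged models).
#'
#' @param outlets an [outlet_set()].
#' @param config a [fixture_config()] (inlet radius/velocity + seed).
#' @return a [domain_surrogate()].
#' @export
make_surrogate <- function(outlets, config = fixture_config()) {
  stopifnot(inherits(outlets, "outlet_set"),
            inherits(config, "fixture_config"))
  with_seed(config$seed + 1L, {
    inlet_radius <- config$inlet_radius *
      (1 + stats::runif(1, -config$diameter_jitter, config$diameter_jitter))
    edges <- list()
    counter <- 0L
    new_junction <- function() {
      counter <<- counter + 1L
      sprintf("J%02d", counter)
    }
    ## returns list(node, radius) of the subtree root over outlet rows ix
    grow <- function(ix) {
      if (length(ix) == 1L) {
        return(list(node = outlets$name[ix], radius = outlets$radius[ix]))
      }
      half <- ceiling(length(ix) / 2)
      left <- grow(ix[seq_len(half)])
      right <- grow(ix[-seq_len(half)])
      node <- new_junction()
      for (child in list(left, right)) {
        edges[[length(edges) + 1L]] <<- data.frame(
          from = node, to = child$node, radius = child$radius,
          length = 5 * 2 * child$radius, stringsAsFactors = FALSE)
      }
      list(node = node,
           radius = (left$radius^3 + right$radius^3)^(1 / 3))
    }
    top <- grow(seq_len(nrow(outlets)))
    inlet <- list(name = "CCA", radius = inlet_radius,
                  velocity = config$inlet_velocity)
    if (top$node != inlet$name) {
      edges[[length(edges) + 1L]] <- data.frame(
        from = inlet$name, to = top$node, radius = inlet_radius,
        length = 5 * 2 * inlet_radius, stringsAsFactors = FALSE)
    }
    domain_surrogate(inlet, do.call(rbind, edges), outlets)
  })
}

#' Pseudo-measured velocities from a solved surrogate
#'
#' Stands in for Doppler measurements: each outlet's simulated mean
#' velocity is perturbed by multiplicative Gaussian noise,
#' \eqn{v_{meas} = v_{sim}(1 + N(0, \sigma))} with
#' \eqn{\sigma =} `config$noise_sd`, seeded for reproducibility.
#'
#' @param solution a converged [solve_coupled()] result.
#' @param config a [fixture_config()] (`noise_sd`, `seed`).
#' @param seed optional seed overriding `config$seed + 2`.
#' @return an [outlet_set()] carrying `measured_velocity`.
#' @export
make_pseudo_measurements <- function(solution, config = fixture_config(),
                                     seed = NULL) {
  stopifnot(inherits(solution, "coupled_solution"),
            inherits(config, "fixture_config"))
  if (!solution$converged) stop_domain("solution has not converged")
  if (is.null(seed)) seed <- config$seed + 2L
  out <- solution$outlets
  with_seed(seed, {
    noise <- stats::rnorm(nrow(out), 0, config$noise_sd)
    outlet_set(
      name = out$name,
      radius = out$radius,
      is_ica = out$name == "ICA",
      measured_velocity = out$velocity * (1 + noise)
    )
  })
}
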