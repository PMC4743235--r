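## Vessel-group table: anatomical averages for the peripheral network.
##
## Six groups cover the arterial side from large arteries down to
## capillaries; each carries an average diameter, a minimum diameter (the
## lower bound of its diameter interval), a representative length and the
## length-to-radius ratio lambda = length / (avg_diameter / 2).  The `ica`
## row is special: the internal carotid does not branch before entering
## the skull, so its lambda comes from measured length/diameter data and
## is applied to the measured outlet radius directly instead of a group
## lookup.  Note the printed ICA lambda is retained verbatim even though
## it is not reproducible from the printed length and mean diameter.

#' Vessel-group table of diameters, lengths and length-to-radius ratios
#'
#' Loads (or validates) the table of peripheral vessel groups used for
#' classifying tree generations and assigning their length-to-radius
#' ratio \eqn{\lambda = l/r}.  The packaged default covers: large
#' arteries, main artery branches, terminal artery branches, arterioles
#' and capillaries, plus the special `ica` entry.
#'
#' Classification boundaries come from the `min_diameter_mm` column:
#' each group spans from its printed minimum diameter up to the next
#' larger group's bound, boundary points belonging to the larger-vessel
#' group.  One exception keeps the table self-consistent: where a
#' group's printed average diameter exceeds the larger group's lower
#' bound (the anatomical categories overlap there — main artery
#' branches average 2.4 mm while large arteries extend down to 2 mm),
#' the boundary is raised to that average and the boundary point stays
#' with the smaller group, so every interior group average classifies
#' into its own row.  Diameters above all bounds map to
#' `large_arteries`, below the smallest to `capillaries`.
#'
#' @param path optional path to a user CSV with columns `group`,
#'   `avg_diameter_mm`, `min_diameter_mm`, `length_mm`, `lambda`; the
#'   packaged table is used when `NULL`.
#' @return a data frame of class `vessel_group_table`.
#' @export
#' @examples
#' vessel_group_table()
vessel_group_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vessel_groups.csv", package = "peritree",
                        mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_vessel_group_table(tab)
}

validate_vessel_group_table <- function(tab) {
  needed <- c("group", "avg_diameter_mm", "min_diameter_mm", "length_mm",
              "lambda")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop_domain("vessel group table is missing column(s): ",
                paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab$group)) stop_domain("duplicate group names")
  check_positive(tab$avg_diameter_mm, "avg_diameter_mm")
  check_positive(tab$min_diameter_mm, "min_diameter_mm")
  check_positive(tab$length_mm, "length_mm")
  check_positive(tab$lambda, "lambda")

  ord <- tab[tab$group != "ica", , drop = FALSE]
  if (is.unsorted(rev(ord$avg_diameter_mm), strictly = TRUE)) {
    stop_domain("non-special groups must be strictly ordered by decreasing ",
                "average diameter")
  }
  ## lambda must be consistent with length / (avg diameter / 2) for every
  ## non-special row; the ica row is measured data and exempt
  lam <- ord$length_mm / (ord$avg_diameter_mm / 2)
  bad <- abs(lam - ord$lambda) / ord$lambda > 1e-3
  if (any(bad)) {
    stop_domain("lambda inconsistent with length/(avg_diameter/2) for: ",
                paste(ord$group[bad], collapse = ", "))
  }
  structure(tab, class = c("vessel_group_table", "data.frame"))
}

#' Classify a vessel diameter into its peripheral group
#'
#' @param diameter_mm vessel diameter in millimetres (vectorised).
#' @param table a [vessel_group_table()].
#' @return character vector of group names.
#' @export
#' @examples
#' classify_vessel_group(2.4)  # main artery branch
#' classify_vessel_group(1.2)  # boundary: larger-vessel group wins
classify_vessel_group <- function(diameter_mm, table = vessel_group_table()) {
  check_positive(diameter_mm, "diameter_mm")
  groups <- table[table$group != "ica", , drop = FALSE]
  groups <- groups[order(groups$avg_diameter_mm, decreasing = TRUE), ,
                   drop = FALSE]
  n <- nrow(groups)
  ## boundary below group k; printed bounds belong to the larger group,
  ## raised bounds (overlapping averages) stay with the smaller one
  b <- groups$min_diameter_mm[-n]
  closed_larger <- rep(TRUE, n - 1L)
  raise <- groups$avg_diameter_mm[-1L] > b
  b[raise] <- groups$avg_diameter_mm[-1L][raise]
  closed_larger[raise] <- FALSE
  vapply(diameter_mm, function(d) {
    for (k in seq_len(n - 1L)) {
      if (d > b[k] || (d == b[k] && closed_larger[k])) {
        return(groups$group[k])
      }
    }
    groups$group[n]
  }, character(1))
}

#' Length-to-radius ratio for a vessel diameter or tree level
#'
#' `lambda_for_diameter()` classifies the diameter and returns the
#' group's \eqn{\lambda}; `lambda_for_level()` is the same lookup keyed
#' by vessel radius in metres (as stored on tree levels).
#'
#' @inheritParams classify_vessel_group
#' @return numeric \eqn{\lambda} value(s).
#' @export
#' @examples
#' lambda_for_diameter(6.5)    # large arteries
#' lambda_for_diameter(0.008)  # capillaries
lambda_for_diameter <- function(diameter_mm, table = vessel_group_table()) {
  grp <- classify_vessel_group(diameter_mm, table)
  table$lambda[match(grp, table$group)]
}

#' @rdname lambda_for_diameter
#' @param radius_m vessel radius in metres.
#' @export
lambda_for_level <- function(radius_m, table = vessel_group_table()) {
  check_positive(radius_m, "radius_m")
  lambda_for_diameter(2 * radius_m * 1e3, table)
}
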