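#' Outlet specification set
#'
#' A set of model outlets: vessel name, radius, an optional internal-
#' carotid flag (the ICA is handled specially in the peripheral model)
#' and an optional measured mean velocity used for validation
#' comparisons.
#'
#' @param name character vector of unique outlet names (e.g. ICA, SThA,
#'   LA, FA, OA, MA, STA).
#' @param radius outlet radii in metres, positive.
#' @param is_ica logical vector flagging the internal carotid outlet(s).
#' @param measured_velocity optional measured mean velocities (m/s), `NA`
#'   where absent.
#' @return a data frame of class `outlet_set`.
#' @export
#' @examples
#' outlet_set(c("ICA", "STA"), c(2.74e-3, 1.0e-3), is_ica = c(TRUE, FALSE))
outlet_set <- function(name, radius, is_ica = FALSE,
                       measured_velocity = NA_real_) {
  if (anyDuplicated(name)) stop_domain("outlet names must be unique")
  check_positive(radius, "radius")
  df <- data.frame(
    name = as.character(name),
    radius = radius,
    is_ica = rep_len(as.logical(is_ica), length(name)),
    measured_velocity = rep_len(as.numeric(measured_velocity), length(name)),
    stringsAsFactors = FALSE
  )
  bad <- !is.na(df$measured_velocity) & df$measured_velocity < 0
  if (any(bad)) stop_domain("measured velocities must be non-negative")
  structure(df, class = c("outlet_set", "data.frame"))
}

#' Lumped Poiseuille surrogate of the imaged carotid domain
#'
#' Stand-in for the 3D imaged domain: a tree of Poiseuille segments from
#' a common-carotid inlet to each outlet.  This surrogate deliberately
#' replaces the finite-volume domain so that the outflow boundary-
#' condition machinery can be exercised end to end at desk scale; it
#' reproduces the coupling contract, not patient-specific 3D velocities.
#' Segment lengths default to 5 diameters, the same truncation rule used
#' when cutting imaged branches.
#'
#' @param inlet list with `name`, `radius` (m) and `velocity` (mean
#'   inlet velocity, m/s).
#' @param segments data frame with columns `from`, `to`, `radius` (m)
#'   and optionally `length` (m; missing entries filled with
#'   `5 * 2 * radius`).
#' @param outlets an [outlet_set()]; every outlet name must be a leaf
#'   node of the segment tree.
#' @return an object of class `domain_surrogate`.
#' @export
domain_surrogate <- function(inlet, segments, outlets) {
  stopifnot(is.list(inlet), inherits(outlets, "outlet_set"))
  for (f in c("name", "radius", "velocity")) {
    if (is.null(inlet[[f]])) stop_domain("inlet is missing `", f, "`")
  }
  check_positive(inlet$radius, "inlet$radius")
  if (inlet$velocity < 0) stop_domain("inlet velocity must be non-negative")
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  for (f in c("from", "to", "radius")) {
    if (is.null(segments[[f]])) stop_domain("segments are missing `", f, "`")
  }
  check_positive(segments$radius, "segments$radius")
  if (is.null(segments$length)) segments$length <- NA_real_
  fill <- is.na(segments$length)
  segments$length[fill] <- 5 * 2 * segments$radius[fill]
  check_positive(segments$length, "segments$length")

  nodes <- unique(c(inlet$name, segments$from, segments$to))
  if (nrow(segments) != length(nodes) - 1L) {
    stop_domain("segment graph is not a tree: |edges| != |nodes| - 1")
  }
  incoming <- table(segments$to)
  if (inlet$name %in% segments$to) {
    stop_domain("inlet node must have no incoming segment")
  }
  if (any(incoming != 1L)) {
    stop_domain("every non-inlet node needs exactly one incoming segment")
  }
  ## reachability from the inlet (tree + unique parents => check cover)
  reach <- inlet$name
  repeat {
    nxt <- segments$to[segments$from %in% reach & !(segments$to %in% reach)]
    if (!length(nxt)) break
    reach <- c(reach, nxt)
  }
  if (!setequal(reach, nodes)) {
    stop_domain("disconnected node(s): ",
                paste(setdiff(nodes, reach), collapse = ", "))
  }
  leaves <- setdiff(nodes, segments$from)
  missing <- setdiff(outlets$name, leaves)
  if (length(missing)) {
    stop_domain("outlet(s) not leaf nodes of the surrogate: ",
                paste(missing, collapse = ", "))
  }
  structure(
    list(inlet = inlet, segments = segments, outlets = outlets),
    class = "domain_surrogate"
  )
}

#' @export
print.domain_surrogate <- function(x, ...) {
  cat("<domain_surrogate>\n")
  cat(sprintf("  inlet   : %s, radius %.3g mm, velocity %.3g m/s\n",
              x$inlet$name, x$inlet$radius * 1e3, x$inlet$velocity))
  cat(sprintf("  segments: %d\n", nrow(x$segments)))
  cat(sprintf("  outlets : %s\n", paste(x$outlets$name, collapse = ", ")))
  invisible(x)
}
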