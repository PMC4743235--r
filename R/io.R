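## Readers and writers.  Files use mm / cm/s at the boundary (the units
## clinicians record); everything is converted to SI on the way in and
## written back in both SI and conventional units on the way out.

#' Read an outlet specification file
#'
#' Accepts CSV or JSON (by extension).  Required fields: `name` and one
#' of `diameter_mm` / `radius_mm`; optional: `measured_velocity_cm_s`
#' and `is_ica`.  Validation errors name the offending row and field.
#'
#' @param path file path (`.csv` or `.json`).
#' @return an [outlet_set()] in SI units.
#' @export
read_outlet_spec <- function(path) {
  if (!file.exists(path)) stop_domain("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    csv = utils::read.csv(path, stringsAsFactors = FALSE,
                          comment.char = "#"),
    json = as.data.frame(jsonlite::fromJSON(path),
                         stringsAsFactors = FALSE),
    stop_domain("unsupported outlet-spec format: .", ext)
  )
  if (is.null(df$name)) stop_domain("outlet spec is missing column `name`")
  if (anyDuplicated(df$name)) {
    stop_domain("duplicate outlet name(s): ",
                paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  }
  if (!is.null(df$radius_mm)) {
    radius_mm <- df$radius_mm
  } else if (!is.null(df$diameter_mm)) {
    radius_mm <- df$diameter_mm / 2
  } else {
    stop_domain("outlet spec needs a `diameter_mm` or `radius_mm` column")
  }
  if (!is.numeric(radius_mm) || any(is.na(radius_mm))) {
    stop_domain("non-numeric diameter/radius in row(s): ",
                paste(which(!is.finite(suppressWarnings(
                  as.numeric(radius_mm)))), collapse = ", "))
  }
  bad <- radius_mm <= 0
  if (any(bad)) {
    stop_domain("non-positive diameter/radius in row(s): ",
                paste(which(bad), collapse = ", "),
                " (", paste(df$name[bad], collapse = ", "), ")")
  }
  mv <- if (!is.null(df$measured_velocity_cm_s)) {
    df$measured_velocity_cm_s / 100
  } else {
    NA_real_
  }
  is_ica <- if (!is.null(df$is_ica)) as.logical(df$is_ica) else FALSE
  outlet_set(df$name, radius_mm * 1e-3, is_ica = is_ica,
             measured_velocity = mv)
}

#' Write an outlet set to CSV
#'
#' Inverse of [read_outlet_spec()]: columns `name`, `diameter_mm`,
#' `measured_velocity_cm_s`, `is_ica`.
#'
#' @param outlets an [outlet_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_outlet_spec <- function(outlets, path) {
  stopifnot(inherits(outlets, "outlet_set"))
  df <- data.frame(
    name = outlets$name,
    diameter_mm = 2 * outlets$radius * 1e3,
    measured_velocity_cm_s = outlets$measured_velocity * 100,
    is_ica = outlets$is_ica,
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Standalone boundary-condition table for an outlet set
#'
#' Builds, per outlet, the quantities a flow solver needs to impose the
#' chosen outflow variant: the lumped resistance seen at the outlet, the
#' corresponding outlet pressure at a reference flow, and the terminal
#' resistance of the peripheral tree.  The reference flow per outlet
#' comes from its measured velocity when available, otherwise from
#' `config$reference_velocity`.
#'
#' @param outlets an [outlet_set()].
#' @param variant outflow variant, see [attach_boundary_conditions()].
#' @param config a [run_config()].
#' @return data frame of class `bc_table`: `name`, `variant`,
#'   `resistance_pa_s_m3`, `terminal_resistance_pa_s_m3`,
#'   `reference_flow_m3_s`, `pressure_pa`, `pressure_mmhg`.
#' @export
boundary_condition_table <- function(outlets,
                                     variant = c("present_0d",
                                                 "conventional_0d",
                                                 "zero_pressure"),
                                     config = run_config()) {
  variant <- match.arg(variant)
  bcs <- attach_boundary_conditions(outlets, variant, config)
  rows <- lapply(seq_len(nrow(outlets)), function(i) {
    b <- bcs$bcs[[i]]
    v_ref <- outlets$measured_velocity[i]
    if (is.na(v_ref) || v_ref <= 0) v_ref <- config$reference_velocity
    q_ref <- inlet_flow_from_velocity(outlets$radius[i], v_ref)
    r <- lumped_resistance(b, q_ref)
    r_term <- if (variant == "present_0d") {
      terminal_resistance(b$p_terminal_pa, q_ref / 2^b$n_generations)
    } else {
      0
    }
    data.frame(
      name = b$name, variant = variant,
      resistance_pa_s_m3 = r,
      terminal_resistance_pa_s_m3 = r_term,
      reference_flow_m3_s = q_ref,
      pressure_pa = q_ref * r,
      pressure_mmhg = pa_to_mmhg(q_ref * r),
      stringsAsFactors = FALSE
    )
  })
  structure(do.call(rbind, rows), class = c("bc_table", "data.frame"))
}

#' Write a boundary-condition file
#'
#' Serialises a [boundary_condition_table()] to CSV (default) or JSON,
#' chosen by extension, with provenance (package version, seed, config
#' hash) in `#`-prefixed comment lines (CSV) or a `provenance` object
#' (JSON).  Column order is stable and mmHg pressures are Pa / 133.322,
#' so re-runs with identical inputs are byte-identical.
#'
#' @param bc a `bc_table`.
#' @param path output path (`.csv` or `.json`).
#' @param config the [run_config()] used to build `bc`.
#' @return `path`, invisibly.
#' @export
write_bc_file <- function(bc, path, config = run_config()) {
  stopifnot(inherits(bc, "bc_table"))
  provenance <- list(
    package = paste("peritree",
                    as.character(utils::packageVersion("peritree"))),
    seed = if (is.null(config$seed)) "none" else config$seed,
    config = unname(config_hash(config))
  )
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(
      list(provenance = provenance, outlets = as.data.frame(bc)),
      path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c(
    sprintf("# %s boundary conditions", provenance$package),
    sprintf("# seed: %s", provenance$seed),
    sprintf("# config: %s", provenance$config)
  ), con)
  utils::write.csv(as.data.frame(bc), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a boundary-condition file
#'
#' @param path a file written by [write_bc_file()].
#' @return the `bc_table` (provenance header lines are skipped).
#' @export
read_bc_file <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("name", "variant", "resistance_pa_s_m3",
              "terminal_resistance_pa_s_m3", "reference_flow_m3_s",
              "pressure_pa", "pressure_mmhg")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop_domain("boundary-condition file is missing column(s): ",
                paste(missing, collapse = ", "))
  }
  structure(df, class = c("bc_table", "data.frame"))
}
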