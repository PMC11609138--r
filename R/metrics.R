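# Distalization efficiency, molar anchorage loss, between-design improvement
# and the comparison report at the space-closed step.

#' Distalization efficiency
#'
#' Percentage of the prescribed distal movement actually achieved,
#' `100 * max(0, -md_displacement) / prescribed` (distal displacement is
#' negative under the reporting sign convention). Wrong-direction motion is
#' clamped to 0 unless `signed = TRUE`.
#'
#' @param md_displacement signed mesio-distal displacement, mm (mesial +).
#' @param prescribed prescribed distal movement, mm (> 0).
#' @param signed report unclamped signed values.
#' @return efficiency, percent.
#' @export
#' @examples
#' efficiency(-1.93, 2.0) # 96.5
#' efficiency(-1.70, 2.0) # 85.0
efficiency <- function(md_displacement, prescribed, signed = FALSE) {
  if (any(prescribed <= 0)) stop("prescribed must be > 0", call. = FALSE)
  raw <- 100 * (-md_displacement) / prescribed
  if (signed) raw else pmax(0, raw)
}

#' Molar anchorage loss
#'
#' Unwanted mesial drift of an anchor tooth as a percentage of the prescribed
#' movement, `100 * max(0, +md_displacement) / prescribed` (mesial
#' displacement is positive). Distal drift is not anchorage loss and clamps
#' to 0 unless `signed = TRUE`.
#'
#' @inheritParams efficiency
#' @return anchorage loss, percent.
#' @export
#' @examples
#' anchorage_loss(0.41, 2.0) # 20.5
#' anchorage_loss(0.17, 2.0) # 8.5
anchorage_loss <- function(md_displacement, prescribed, signed = FALSE) {
  if (any(prescribed <= 0)) stop("prescribed must be > 0", call. = FALSE)
  raw <- 100 * md_displacement / prescribed
  if (signed) raw else pmax(0, raw)
}

#' Improvement between two designs
#'
#' Difference in percentage points, `loss_a - loss_b` (positive when design
#' `b` loses less anchorage than design `a`).
#'
#' @param loss_a,loss_b percentages.
#' @return percentage points.
#' @export
#' @examples
#' improvement(20.5, 8.5) # 12
improvement <- function(loss_a, loss_b) loss_a - loss_b

#' Per-design efficiency and anchorage metrics from a displacement table
#'
#' @param displacements long tibble with columns `design`, `tooth`,
#'   `quantity`, `value` (as produced by [read_displacement_table()] or
#'   [tidy()] of a report); only `quantity == "md_displacement"` rows are
#'   used.
#' @param prescribed prescribed distal movement, mm.
#' @return tibble with one row per design: premolar efficiencies (positions
#'   4, 5) and molar anchorage losses (positions 6, 7), percent.
#' @export
design_metrics <- function(displacements, prescribed = 2.0) {
  md <- dplyr::filter(displacements, .data$quantity == "md_displacement")
  need <- c("design", "tooth", "value")
  if (!all(need %in% names(md))) {
    stop("displacement table needs columns design, tooth, quantity, value",
         call. = FALSE)
  }
  pick <- function(d, t) md$value[md$design == d & md$tooth == t]
  purrr::map_dfr(unique(md$design), function(d) {
    tibble::tibble(
      design = d,
      efficiency_p1 = efficiency(pick(d, 4), prescribed),
      efficiency_p2 = efficiency(pick(d, 5), prescribed),
      anchorage_loss_m1 = anchorage_loss(pick(d, 6), prescribed),
      anchorage_loss_m2 = anchorage_loss(pick(d, 7), prescribed)
    )
  })
}

#' Read a displacement/rotation table from CSV
#'
#' Long format: `design, quantity, tooth, value` with quantities
#' `md_displacement, bl_displacement, axial_displacement` (mm) and
#' `bl_torque, md_tipping, axial_rotation` (degrees) under the standard sign
#' conventions.
#'
#' @param path CSV file.
#' @return tibble.
#' @export
read_displacement_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         design = readr::col_character(),
                         quantity = readr::col_character(),
                         tooth = readr::col_integer(),
                         value = readr::col_double()))
  need <- c("design", "quantity", "tooth", "value")
  if (!all(need %in% names(x))) {
    stop("expected columns design, quantity, tooth, value", call. = FALSE)
  }
  x
}

DISPLACEMENT_QUANTITIES <- c("md_displacement", "bl_displacement",
                             "axial_displacement", "bl_torque",
                             "md_tipping", "axial_rotation")

#' Build the cross-design comparison report
#'
#' Extracts, for each design, the displacement records of all seven teeth at
#' the final remodeling iteration of that design's space-closed step, and
#' attaches the efficiency and anchorage-loss metrics.
#'
#' @param trajectories named list of `alignersim_trajectory` objects (as from
#'   [compare_designs()]); a partial set produces a partial report with a
#'   warning.
#' @param prescribed prescribed distal movement, mm.
#' @return object of class `alignersim_report` with `displacements` (long
#'   tibble), `metrics` (per design) and `space_closed_steps`.
#' @export
build_report <- function(trajectories, prescribed = 2.0) {
  if (is.null(names(trajectories))) {
    names(trajectories) <- vapply(trajectories, `[[`, character(1), "design")
  }
  missing <- setdiff(TRIM_DESIGNS, names(trajectories))
  if (length(missing) > 0) {
    warning("partial report; missing designs: ",
            paste(missing, collapse = ", "))
  }
  long <- purrr::map_dfr(trajectories, function(tr) {
    final_it <- max(tr$records$iteration[tr$records$step == tr$space_closed_step])
    tr$records |>
      dplyr::filter(.data$step == tr$space_closed_step,
                    .data$iteration == final_it) |>
      dplyr::select("design", "tooth",
                    dplyr::all_of(DISPLACEMENT_QUANTITIES)) |>
      tidyr::pivot_longer(dplyr::all_of(DISPLACEMENT_QUANTITIES),
                          names_to = "quantity", values_to = "value")
  })
  metrics <- design_metrics(long, prescribed)
  steps <- tibble::tibble(
    design = names(trajectories),
    space_closed_step = vapply(trajectories, `[[`, integer(1),
                               "space_closed_step"))
  structure(list(displacements = long, metrics = metrics,
                 space_closed_steps = steps, prescribed = prescribed),
            class = "alignersim_report")
}

#' Write a report as CSV
#'
#' `wide = TRUE` writes the quantity-by-design rows vs teeth 1..7 layout used
#' in clinical reporting; otherwise the long format.
#'
#' @param report an `alignersim_report`.
#' @param path output CSV.
#' @param wide layout flag.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path, wide = TRUE) {
  if (wide) {
    wide_tbl <- report$displacements |>
      dplyr::mutate(quantity = factor(.data$quantity,
                                      levels = DISPLACEMENT_QUANTITIES)) |>
      dplyr::arrange(.data$quantity, .data$design, .data$tooth) |>
      tidyr::pivot_wider(names_from = "tooth", names_prefix = "tooth_",
                         values_from = "value")
    readr::write_csv(wide_tbl, path)
  } else {
    readr::write_csv(report$displacements, path)
  }
  invisible(path)
}

#' @export
print.alignersim_report <- function(x, ...) {
  cat("<alignersim_report> space-closed-step comparison\n")
  print(x$space_closed_steps)
  print(x$metrics)
  invisible(x)
}
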