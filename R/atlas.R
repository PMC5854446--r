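#' Dimensionless speed group for a real cell
#'
#' `beta = v / (d * l_BC)`: cell speed over the product of cell diameter
#' and signaling rate. `beta` is unit-invariant as long as `v` and `d` use
#' the same length unit and `l_BC` the matching inverse time.
#'
#' @param v cell speed (um/s).
#' @param d cell diameter (um, > 0).
#' @param l_BC signaling (output deactivation) rate (1/s, > 0; default 1).
#' @return Dimensionless `beta` (vectorized).
#' @examples
#' beta_value(v = 20, d = 2, l_BC = 2.2)  # E. coli: ~4.5
#' @export
beta_value <- function(v, d, l_BC = 1) {
  if (any(d <= 0) || any(l_BC <= 0)) stop("need d > 0 and l_BC > 0")
  if (any(v < 0)) stop("need v >= 0")
  v / (d * l_BC)
}

#' Classify a cell against the temporal/spatial decision band
#'
#' The simulated decision boundary sits at `beta = 1`. Since the signaling
#' rate is rarely measured, a cell is called `"temporal"` only when
#' `beta > 1` for every `l_BC` in `[l_BC_low, l_BC_high]` (i.e.
#' `v/d > l_BC_high`), `"spatial_candidate"` when `beta < 1` throughout
#' the band (`v/d < l_BC_low`), and `"boundary_band"` otherwise. The label
#' is "candidate" because spatial sensing additionally requires a
#' slow-diffusing activator, fast-diffusing inactivator and a
#' non-diffusing output.
#'
#' @param v cell speed (um/s); `d` diameter (um). Vectorized.
#' @param d cell diameter (um).
#' @param l_BC_low,l_BC_high plausible signaling-rate band (1/s; default
#'   0.2 to 5).
#' @return Character vector: `"temporal"`, `"spatial_candidate"` or
#'   `"boundary_band"`.
#' @export
classify_cell <- function(v, d, l_BC_low = 0.2, l_BC_high = 5) {
  stopifnot(l_BC_low > 0, l_BC_high >= l_BC_low)
  ratio <- v / d
  ifelse(ratio > l_BC_high, "temporal",
         ifelse(ratio < l_BC_low, "spatial_candidate", "boundary_band"))
}

#' Classify a table of cell records
#'
#' Accepts a data frame (or CSV path) with columns `name`, `diameter_um`,
#' `speed_um_s` and optionally `l_bc_per_s` (default 1) and
#' `motility_class`; returns it with `beta` and `classification` columns
#' appended. A small demo table with the E. coli row ships with the
#' package:
#' `system.file("extdata", "cells_demo.csv", package = "chemosense")`.
#'
#' @param cells data frame or path to a CSV file.
#' @param l_BC_low,l_BC_high band passed to [classify_cell()].
#' @return The input data frame with `beta` (at `l_bc_per_s`) and
#'   `classification` columns.
#' @export
classify_cells <- function(cells, l_BC_low = 0.2, l_BC_high = 5) {
  if (is.character(cells))
    cells <- utils::read.csv(cells, stringsAsFactors = FALSE)
  need <- c("name", "diameter_um", "speed_um_s")
  if (!all(need %in% names(cells)))
    stop("cell table needs columns: ", paste(need, collapse = ", "))
  if (is.null(cells$l_bc_per_s)) cells$l_bc_per_s <- 1
  cells$beta <- beta_value(cells$speed_um_s, cells$diameter_um,
                           cells$l_bc_per_s)
  cells$classification <- classify_cell(cells$speed_um_s,
                                        cells$diameter_um,
                                        l_BC_low, l_BC_high)
  cells
}

#' Diffusive traversal time across a cell
#'
#' `t = L^2 / D`: the time a protein with diffusivity `D` needs to cover a
#' distance `L`. For cytoplasmic CheY (`D = 4.6 um^2/s`) crossing a 2 um
#' bacterium this is about 0.9 s.
#'
#' @param L distance (um, >= 0).
#' @param D diffusivity (um^2/s, > 0).
#' @return Time in seconds (vectorized).
#' @export
traversal_time <- function(L, D) {
  if (any(D <= 0)) stop("need D > 0")
  if (any(L < 0)) stop("need L >= 0")
  L^2 / D
}

#' Diffusivity ratio estimated from molecular weights
#'
#' With diffusivity inversely proportional to the square root of molecular
#' weight, the ratio of two proteins' diffusivities is
#' `sqrt(mw_num / mw_den)` (the heavier protein in the numerator gives the
#' slower protein's weight ratio).
#'
#' @param mw_num,mw_den molecular weights in Da (> 0).
#' @return Dimensionless ratio (vectorized).
#' @export
mw_diffusion_ratio <- function(mw_num, mw_den) {
  if (any(mw_num <= 0) || any(mw_den <= 0))
    stop("molecular weights must be > 0")
  sqrt(mw_num / mw_den)
}
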