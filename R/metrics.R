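trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Temporal sensing output
#'
#' Time integral of the relative deviation of the output from its baseline,
#' averaged over compartments:
#' \deqn{O_T = \frac{1}{N}\int_0^{\tau_{end}} \sum_i
#'   \left(\frac{C_i(\tau)}{C_i(0)} - 1\right) d\tau,}
#' evaluated by the trapezoidal rule on the stored times. A cell using
#' temporal sensing accumulates the net rise of its whole-cell output above
#' the adapted baseline as it moves up the gradient.
#'
#' @param traj a `ring_trajectory` from [simulate_ring()].
#' @return Dimensionless `O_T` (positive for a net up-gradient response).
#' @export
temporal_output <- function(traj) {
  stopifnot(inherits(traj, "ring_trajectory"))
  if (any(traj$C0 <= 0)) stop("undefined baseline: some C_i(0) are 0")
  rel <- sweep(traj$C, 2, traj$C0, "/") - 1
  trapz(traj$times, rowSums(rel)) / traj$grid$N
}

#' Spatial sensing output
#'
#' Time integral of the front/back output asymmetry:
#' \deqn{O_S = \int_0^{\tau_{end}}
#'   \left(\frac{\sum_{i \in front} C_i(\tau)}{\sum_{i \in back} C_i(\tau)}
#'   - 1\right) d\tau.}
#' Negative values (output higher at the back than the front) make spatial
#' sensing inviable.
#'
#' @param traj a `ring_trajectory`.
#' @param grid grid supplying the masks; defaults to the trajectory's.
#' @return Dimensionless `O_S`.
#' @export
spatial_output <- function(traj, grid = traj$grid) {
  stopifnot(inherits(traj, "ring_trajectory"))
  front <- rowSums(traj$C[, grid$front, drop = FALSE])
  back <- rowSums(traj$C[, grid$back, drop = FALSE])
  if (any(back <= 0)) stop("degenerate front/back ratio: back_C reached 0")
  trapz(traj$times, front / back - 1)
}

#' Ratio of temporal to spatial output
#'
#' `O_TS = O_T / O_S`, defined only when both outputs are positive;
#' otherwise `NA` (the ratio is not meaningful when either strategy yields
#' no net signal).
#'
#' @param O_T,O_S sensing outputs.
#' @return `O_T / O_S`, or `NA_real_` when undefined.
#' @export
output_ratio <- function(O_T, O_S) {
  if (is.na(O_T) || is.na(O_S) || O_T <= 0 || O_S <= 0) return(NA_real_)
  O_T / O_S
}

#' Sensing strategy decision
#'
#' The strategy yielding the higher positive output is adopted: both
#' outputs non-positive gives `"failure"`; if exactly one is positive that
#' strategy wins; if both are positive, temporal sensing is chosen when
#' `O_TS >= 1` (ties go to temporal) and spatial otherwise.
#'
#' @param O_T,O_S sensing outputs.
#' @return `"temporal"`, `"spatial"` or `"failure"`.
#' @export
decide <- function(O_T, O_S) {
  if (O_T <= 0 && O_S <= 0) return("failure")
  if (O_T > 0 && O_S <= 0) return("temporal")
  if (O_S > 0 && O_T <= 0) return("spatial")
  if (O_T / O_S >= 1) "temporal" else "spatial"
}

#' Sensing outputs and decision for a ring trajectory
#'
#' @param traj a `ring_trajectory`.
#' @return Object of class `sensing_outputs`: list with `O_T`, `O_S`,
#'   `O_TS` (possibly `NA`) and `decision`.
#' @export
sensing_outputs <- function(traj) {
  O_T <- temporal_output(traj)
  O_S <- spatial_output(traj)
  structure(list(O_T = O_T, O_S = O_S, O_TS = output_ratio(O_T, O_S),
                 decision = decide(O_T, O_S)),
            class = "sensing_outputs")
}

#' @export
print.sensing_outputs <- function(x, ...) {
  cat(sprintf("O_T = %.5g, O_S = %.5g, O_TS = %s -> %s sensing\n",
              x$O_T, x$O_S,
              if (is.na(x$O_TS)) "undefined" else signif(x$O_TS, 5),
              x$decision))
  invisible(x)
}
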