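#' Define a factorial sweep over the dimensionless groups
#'
#' One ring simulation per combination of (parameter set, beta, D'_A, D'_B,
#' alpha). Parameter sets carry their own topology, so a mixed NFB/IFF list
#' sweeps both circuits; summaries are always per topology.
#'
#' @param param_sets list of screened [circuit_params()] objects.
#' @param beta_values speed-group grid (default the seven octave-spaced
#'   values 0.125..8).
#' @param DA_values,DB_values dimensionless diffusivity grids (default the
#'   five-decade grid 0.1..1000).
#' @param alpha_values slope-group grid (default 0.001).
#' @param D_C output-protein diffusivity (default 0).
#' @param shape gradient profile shape.
#' @param I_L baseline concentration.
#' @param I_H plateau for the step profile (ignored otherwise; default
#'   derived from the largest alpha so step sweeps are comparable).
#' @param T_s gradient exposure time; `T_post` the post-exposure window.
#' @param N ring compartment count.
#' @return Object of class `sweep_grid`.
#' @export
sweep_grid <- function(param_sets,
                       beta_values = c(0.125, 0.25, 0.5, 1, 2, 4, 8),
                       DA_values = c(0.1, 1, 10, 100, 1000),
                       DB_values = c(0.1, 1, 10, 100, 1000),
                       alpha_values = 0.001, D_C = 0,
                       shape = c("linear", "exponential", "step"),
                       I_L = 0.5, I_H = NULL, T_s = 10, T_post = 20,
                       N = 20) {
  shape <- match.arg(shape)
  stopifnot(length(param_sets) > 0, all(beta_values > 0),
            all(DA_values >= 0), all(DB_values >= 0), D_C >= 0,
            length(alpha_values) > 0)
  structure(list(param_sets = param_sets, beta_values = beta_values,
                 DA_values = DA_values, DB_values = DB_values,
                 alpha_values = alpha_values, D_C = D_C, shape = shape,
                 I_L = I_L, I_H = I_H, T_s = T_s, T_post = T_post, N = N),
            class = "sweep_grid")
}

sweep_profile <- function(grid, alpha) {
  if (grid$shape == "step") {
    I_H <- if (!is.null(grid$I_H)) grid$I_H
           else grid$I_L + max(grid$alpha_values) * grid$T_s
    gradient_profile("step", I_L = grid$I_L, T_s = grid$T_s, I_H = I_H)
  } else {
    gradient_profile(grid$shape, I_L = grid$I_L, alpha = alpha,
                     T_s = grid$T_s)
  }
}

#' Run a factorial sensing sweep
#'
#' One deterministic ring simulation per grid cell and parameter set;
#' integration failures are recorded as `"failure"` decisions with
#' `ok = FALSE`, never dropped. With a `cache_dir`, each record is written
#' to a JSON file keyed by its full coordinates as soon as it completes,
#' and existing files are reused, so interrupted sweeps resume.
#'
#' @param grid a [sweep_grid()].
#' @param cache_dir optional directory for per-record JSON caching.
#' @param ... passed to [simulate_ring()] (tolerances, `dt_store`).
#' @return Data frame with one row per (set, beta, D_A, D_B, alpha):
#'   coordinates, `O_T`, `O_S`, `O_TS`, `decision`, `ok`.
#' @export
run_sweep <- function(grid, cache_dir = NULL, ...) {
  stopifnot(inherits(grid, "sweep_grid"))
  if (!is.null(cache_dir) && !dir.exists(cache_dir))
    dir.create(cache_dir, recursive = TRUE)
  cells <- expand.grid(set = seq_along(grid$param_sets),
                       beta = grid$beta_values, D_A = grid$DA_values,
                       D_B = grid$DB_values, alpha = grid$alpha_values,
                       KEEP.OUT.ATTRS = FALSE)
  ring <- ring_grid(grid$N)
  rows <- lapply(seq_len(nrow(cells)), function(r) {
    cell <- cells[r, ]
    params <- grid$param_sets[[cell$set]]
    idx <- attr(params, "seed_index")
    key <- sprintf("%s_set%s_b%g_da%g_db%g_a%g_%s_Ts%g_N%d",
                   params$topology, if (is.null(idx)) cell$set else idx,
                   cell$beta, cell$D_A, cell$D_B, cell$alpha, grid$shape,
                   grid$T_s, grid$N)
    cache <- if (!is.null(cache_dir))
      file.path(cache_dir, paste0(gsub("[^A-Za-z0-9_.-]", "-", key), ".json"))
    if (!is.null(cache_dir) && file.exists(cache))
      return(as.data.frame(jsonlite::read_json(cache),
                           stringsAsFactors = FALSE))
    o <- tryCatch({
      traj <- simulate_ring(
        params,
        ring_transport(cell$beta, cell$D_A, cell$D_B, grid$D_C),
        sweep_profile(grid, cell$alpha), ring, T_post = grid$T_post, ...)
      c(sensing_outputs(traj), ok = TRUE)
    }, error = function(e)
      list(O_T = NA_real_, O_S = NA_real_, O_TS = NA_real_,
           decision = "failure", ok = FALSE))
    rec <- data.frame(topology = params$topology, set = cell$set,
                      beta = cell$beta, D_A = cell$D_A, D_B = cell$D_B,
                      alpha = cell$alpha, O_T = o$O_T, O_S = o$O_S,
                      O_TS = o$O_TS, decision = o$decision, ok = o$ok,
                      stringsAsFactors = FALSE)
    if (!is.null(cache_dir))
      jsonlite::write_json(as.list(rec), cache, auto_unbox = TRUE,
                           digits = NA, na = "null")
    rec
  })
  records <- do.call(rbind, rows)
  if (all(!records$ok)) stop("every run in the sweep failed")
  records
}

#' Decision fractions per sweep cell
#'
#' Aggregates sweep records into per-cell decision fractions and mean
#' outputs. The default cell is (topology, beta, D_A, D_B, alpha);
#' marginal summaries (e.g. per beta, or per (D_A, D_B) at fixed beta)
#' are obtained by passing a shorter `by`.
#'
#' @param records a [run_sweep()] data frame.
#' @param by character vector of coordinate columns defining a cell.
#' @return Data frame with `n_runs`, `fraction_temporal`,
#'   `fraction_spatial`, `fraction_failure`, `mean_O_T`, `mean_O_S` per
#'   cell; the three fractions sum to 1.
#' @export
fraction_favoring <- function(records,
                              by = c("topology", "beta", "D_A", "D_B",
                                     "alpha")) {
  stopifnot(nrow(records) > 0, all(by %in% names(records)))
  key <- interaction(records[by], drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(g) {
    cbind(g[1, by, drop = FALSE],
          data.frame(
            n_runs = nrow(g),
            fraction_temporal = mean(g$decision == "temporal"),
            fraction_spatial = mean(g$decision == "spatial"),
            fraction_failure = mean(g$decision == "failure"),
            mean_O_T = mean(g$O_T, na.rm = TRUE),
            mean_O_S = mean(g$O_S, na.rm = TRUE)))
  }))
  rownames(out) <- NULL
  out
}
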