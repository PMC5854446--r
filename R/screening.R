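#' Sample circuit parameter sets log-uniformly
#'
#' Each of the six rate constants (`k_IA`, `k_IB`, `k_CB`, `k_AC`, `l_FA`,
#' `l_FB`) is drawn log-uniformly over `10^rate_range` and each equilibrium
#' constant (`K_AC`, `L_BC`) log-uniformly over `10^eq_const_range`; the
#' reference rate `l_BC` is 1 by construction. Both topology branches'
#' constants are drawn for every set so NFB and IFF screens at the same seed
#' see identical numbers.
#'
#' @param n_samples number of sets to draw.
#' @param topology `"NFB"` or `"IFF"`, attached to every set.
#' @param rate_range log10 bounds for rate constants (default `c(-1, 3)`,
#'   four orders of magnitude).
#' @param eq_const_range log10 bounds for equilibrium constants
#'   (default `c(-3, 1)`).
#' @param seed integer RNG seed; identical seed gives identical sets.
#' @return List of [circuit_params()] objects; each carries a `seed_index`
#'   attribute giving its position in the sampling stream.
#' @export
sample_parameter_sets <- function(n_samples, topology = c("NFB", "IFF"),
                                  rate_range = c(-1, 3),
                                  eq_const_range = c(-3, 1),
                                  seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(n_samples >= 0, rate_range[1] < rate_range[2],
            eq_const_range[1] < eq_const_range[2])
  if (n_samples == 0) return(list())
  rng <- local({ set.seed(seed)
    matrix(stats::runif(n_samples * 8L), ncol = 8L) })
  rate <- function(u) 10^(rate_range[1] + u * diff(rate_range))
  eqc <- function(u) 10^(eq_const_range[1] + u * diff(eq_const_range))
  lapply(seq_len(n_samples), function(i) {
    p <- circuit_params(topology,
                        k_IA = rate(rng[i, 1]), k_IB = rate(rng[i, 2]),
                        k_CB = rate(rng[i, 3]), k_AC = rate(rng[i, 4]),
                        l_FA = rate(rng[i, 5]), l_FB = rate(rng[i, 6]),
                        K_AC = eqc(rng[i, 7]), L_BC = eqc(rng[i, 8]))
    attr(p, "seed_index") <- i
    p
  })
}

#' Score one parameter set on the step-response assay
#'
#' Runs [simulate_point()] and computes sensitivity and precision. A set
#' whose steady state does not exist (non-adaptive NFB ratio) or whose
#' integration fails is recorded as failed with `S = P = 0`, never raised.
#' The step budget is deliberately modest (5,000 steps for a three-variable
#' system over fifty time units): sets too stiff or oscillatory to integrate
#' within it are discarded by the screen rather than pursued.
#'
#' @param params a [circuit_params()] object.
#' @param stimulus the screening [step_stimulus()].
#' @param s_min,p_min pass thresholds on sensitivity and precision.
#' @param ... passed to [simulate_point()].
#' @return List with `params`, `S`, `P`, `passed`, `ok` (did the simulation
#'   run).
#' @export
evaluate_set <- function(params, stimulus = step_stimulus(),
                         s_min = 1, p_min = 10, ...) {
  res <- tryCatch({
    traj <- simulate_point(params, stimulus, maxsteps = 5e3, ...)
    list(S = sensitivity(traj), P = precision(traj), ok = TRUE)
  }, error = function(e) list(S = 0, P = 0, ok = FALSE))
  list(params = params, S = res$S, P = res$P, ok = res$ok,
       passed = res$ok && res$S >= s_min && res$P >= p_min)
}

#' Select passing parameter sets in sampling order
#'
#' The screen is a filter, not a ranking: the first `n_keep` sets with
#' `S >= s_min` and `P >= p_min` are kept in sampling order. If fewer pass,
#' all passing sets are returned with a warning.
#'
#' @param results list of [evaluate_set()] results.
#' @param s_min,p_min thresholds (> 0).
#' @param n_keep number of sets to keep (>= 1).
#' @return List of [circuit_params()] with attributes `S` and `P` attached
#'   to each element.
#' @export
select_passing <- function(results, s_min = 1, p_min = 10, n_keep = 100) {
  stopifnot(s_min > 0, p_min > 0, n_keep >= 1)
  if (length(results) == 0) {
    warning("no screening results to select from")
    return(list())
  }
  pass <- vapply(results, function(r)
    isTRUE(r$ok) && r$S >= s_min && r$P >= p_min, logical(1))
  sel <- results[pass]
  if (length(sel) < n_keep)
    warning("only ", length(sel), " of the requested ", n_keep,
            " parameter sets passed the screen")
  sel <- sel[seq_len(min(n_keep, length(sel)))]
  lapply(sel, function(r) {
    p <- r$params; attr(p, "S") <- r$S; attr(p, "P") <- r$P; p
  })
}

#' Screen sampled parameter sets for sensitivity and adaptation precision
#'
#' Convenience pipeline: sample, score every set on the step response, and
#' keep the first `n_keep` sets passing both thresholds.
#'
#' @inheritParams sample_parameter_sets
#' @inheritParams select_passing
#' @param stimulus the screening [step_stimulus()].
#' @param ... passed to [simulate_point()].
#' @return Object of class `screen_result`: list with `selected` (list of
#'   passing [circuit_params()]), `table` (data frame of S, P, passed per
#'   sampled set) and the screen settings.
#' @export
screen_parameters <- function(n_samples, topology = c("NFB", "IFF"),
                              seed = 1L, s_min = 1, p_min = 10,
                              n_keep = 100, stimulus = step_stimulus(),
                              rate_range = c(-1, 3),
                              eq_const_range = c(-3, 1), ...) {
  topology <- match.arg(topology)
  sets <- sample_parameter_sets(n_samples, topology, rate_range,
                                eq_const_range, seed)
  results <- lapply(sets, evaluate_set, stimulus = stimulus,
                    s_min = s_min, p_min = p_min, ...)
  tab <- data.frame(
    seed_index = seq_along(results),
    S = vapply(results, `[[`, numeric(1), "S"),
    P = vapply(results, `[[`, numeric(1), "P"),
    ok = vapply(results, `[[`, logical(1), "ok"),
    passed = vapply(results, `[[`, logical(1), "passed"))
  selected <- suppressWarnings(select_passing(results, s_min, p_min, n_keep))
  structure(list(selected = selected, table = tab, topology = topology,
                 seed = seed, s_min = s_min, p_min = p_min,
                 stimulus = stimulus),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Adaptation screen (", x$topology, "): ", nrow(x$table),
      " sampled, ", sum(x$table$passed), " passed (S >= ", x$s_min,
      ", P >= ", x$p_min, "), ", length(x$selected), " kept\n", sep = "")
  invisible(x)
}

#' Write or read parameter sets as JSON records
#'
#' Records carry `{topology, k_IA, k_IB, k_CB, k_AC, l_FA, l_FB, K_AC,
#' L_BC, seed_index}` and round-trip through [read_params_json()].
#'
#' @param params list of [circuit_params()] objects.
#' @param path file path.
#' @return `write_params_json()` returns `path` invisibly;
#'   `read_params_json()` returns a list of [circuit_params()].
#' @export
write_params_json <- function(params, path) {
  recs <- lapply(params, function(p) {
    r <- p[c("topology", "k_IA", "k_IB", "k_CB", "k_AC",
             "l_FA", "l_FB", "K_AC", "L_BC")]
    r$seed_index <- attr(p, "seed_index")
    r
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  recs <- jsonlite::read_json(path)
  lapply(recs, function(r) {
    p <- circuit_params(r$topology, k_IA = r$k_IA, k_IB = r$k_IB,
                        k_CB = r$k_CB, k_AC = r$k_AC, l_FA = r$l_FA,
                        l_FB = r$l_FB, K_AC = r$K_AC, L_BC = r$L_BC)
    attr(p, "seed_index") <- r$seed_index
    p
  })
}
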