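# evaluate expr under a local RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# zero-mean draws truncated at +/- 3 sd of a unit normal
rtrunc3 <- function(n) {
  stats::qnorm(stats::runif(n, stats::pnorm(-3), stats::pnorm(3)))
}

#' External chemoattractant noise specification
#'
#' Multiplicative noise on the input field: the deterministic input is
#' scaled by `1 + eta * u(x')`, where `u` is a frozen random field with
#' correlation length `patch_length` (in units of the cell diameter):
#' independent zero-mean draws at axial nodes spaced `patch_length` apart,
#' interpolated linearly between nodes and fixed for the whole run. Because
#' the field is frozen in space, a slowly moving cell experiences slowly
#' varying noise: externally driven fluctuations of the output are
#' concentrated at low frequencies. The continuous interpolation keeps the
#' forcing integrable by an adaptive stiff solver.
#'
#' @param eta fractional noise amplitude (>= 0).
#' @param patch_length spatial correlation length in units of the cell
#'   diameter (default 1).
#' @param distribution `"truncnorm"` (unit normal truncated at 3 sd) or
#'   `"uniform"` (zero-mean unit-variance uniform).
#' @param seed integer seed for the field realization.
#' @return Object of class `external_noise`.
#' @export
external_noise <- function(eta, patch_length = 1,
                           distribution = c("truncnorm", "uniform"),
                           seed = 1L) {
  distribution <- match.arg(distribution)
  if (eta < 0 || patch_length <= 0)
    stop("need eta >= 0 and patch_length > 0")
  structure(list(eta = eta, patch_length = patch_length,
                 distribution = distribution, seed = as.integer(seed)),
            class = "external_noise")
}

# draw the frozen node field covering the whole axial range of a run;
# returns a function x' -> multiplicative factor (1 + eta * u)
realize_external_field <- function(noise, beta, tau_end, grid) {
  stopifnot(inherits(noise, "external_noise"))
  L <- noise$patch_length
  j_lo <- floor((min(grid$p) - L) / L)
  j_hi <- ceiling((beta * tau_end + max(grid$p) + L) / L)
  n <- j_hi - j_lo + 1L
  u <- with_seed(noise$seed, switch(noise$distribution,
    truncnorm = rtrunc3(n),
    uniform = stats::runif(n, -sqrt(3), sqrt(3))))
  eta <- noise$eta
  f <- stats::approxfun((j_lo:j_hi) * L, 1 + eta * u, rule = 2)
  function(x) f(x)
}

#' Evaluate the noisy per-compartment input
#'
#' Deterministic [input_profile()] multiplied by the frozen random field of
#' an [external_noise()] spec, truncated below at 0. Two evaluations with
#' the same spec, time and compartment give identical values.
#'
#' @inheritParams input_profile
#' @param noise an [external_noise()] spec.
#' @param tau_end end of the window the field must cover (default: the
#'   evaluation time).
#' @return Numeric vector of length `grid$N`.
#' @export
noisy_input_profile <- function(profile, noise, tau, grid, beta,
                                tau_end = max(tau, profile$T_s)) {
  fac <- realize_external_field(noise, beta, tau_end, grid)
  pmax(input_profile(profile, tau, grid, beta) * fac(beta * tau + grid$p), 0)
}

#' Internal kinetic-parameter noise specification
#'
#' All seven kinetic rate constants (`k_IA`, `k_IB`, `k_CB`, `k_AC`,
#' `l_FA`, `l_FB`, `l_BC`) are redrawn independently every
#' `resample_interval` time units as normal deviates with mean equal to
#' their noiseless values, truncated at 0. The variance level `nu` is
#' fractional by default (variance `nu * p0^2`, coefficient of variation
#' `sqrt(nu)`); `fractional = FALSE` uses absolute variance `nu`. The
#' equilibrium constants `K_AC` and `L_BC` are not perturbed.
#'
#' @param nu variance level (>= 0).
#' @param resample_interval time between redraws (default 0.1).
#' @param fractional interpret `nu` as fractional variance (default TRUE).
#' @param seed integer seed for the parameter path.
#' @return Object of class `internal_noise`.
#' @export
internal_noise <- function(nu, resample_interval = 0.1, fractional = TRUE,
                           seed = 1L) {
  if (nu < 0 || resample_interval <= 0)
    stop("need nu >= 0 and resample_interval > 0")
  structure(list(nu = nu, resample_interval = resample_interval,
                 fractional = fractional, seed = as.integer(seed)),
            class = "internal_noise")
}

noisy_rate_names <- c("k_IA", "k_IB", "k_CB", "k_AC", "l_FA", "l_FB", "l_BC")

# pre-draw the piecewise-constant parameter path; returns tau -> named rates
realize_internal_path <- function(noise, params, tau_end) {
  stopifnot(inherits(noise, "internal_noise"))
  dt <- noise$resample_interval
  n <- as.integer(ceiling(tau_end / dt)) + 1L
  p0 <- unlist(params[noisy_rate_names])
  sd <- if (noise$fractional) sqrt(noise$nu) * p0
        else rep(sqrt(noise$nu), length(p0))
  path <- with_seed(noise$seed, {
    m <- matrix(stats::rnorm(n * length(p0), mean = rep(p0, each = n),
                             sd = rep(sd, each = n)), nrow = n)
    m[m < 0] <- 0
    colnames(m) <- noisy_rate_names
    m
  })
  function(t) path[min(floor(t / dt) + 1L, n), ]
}

#' Draw one noisy realization of the kinetic constants
#'
#' Single redraw of the seven rate constants under an [internal_noise()]
#' spec (normal around the noiseless values, truncated at 0); equilibrium
#' constants are untouched. Used for testing the sampler; during a
#' simulation the redraw happens every `resample_interval` via
#' [simulate_ring()]'s `internal` argument.
#'
#' @param params a [circuit_params()] object.
#' @param noise an [internal_noise()] spec.
#' @return A `circuit_params` object with perturbed rates.
#' @export
perturb_params <- function(params, noise) {
  assert_params(params)
  stopifnot(inherits(noise, "internal_noise"))
  p0 <- unlist(params[noisy_rate_names])
  sd <- if (noise$fractional) sqrt(noise$nu) * p0
        else rep(sqrt(noise$nu), length(p0))
  draw <- pmax(stats::rnorm(length(p0), p0, sd), 0)
  out <- unclass(params)
  out[noisy_rate_names] <- as.list(draw)
  structure(out, class = "circuit_params")
}

# deterministic replicate-seed derivation, kept inside 32-bit integer range
derive_seed <- function(base_seed, index, stream = 0L) {
  as.integer((as.double(base_seed) * 7919 + index * 104729 +
                stream * 611953) %% 2147483629)
}

#' Run a stochastic ensemble of ring simulations
#'
#' `n_replicates` independent [simulate_ring()] runs with fresh noise
#' realizations per replicate (seeds derived deterministically from
#' `base_seed`), recording the temporal and spatial outputs of each. A
#' replicate whose integration fails records `(O_T, O_S) = (0, 0)`.
#'
#' @inheritParams simulate_ring
#' @param external optional [external_noise()] spec (its `seed` field is
#'   overridden per replicate).
#' @param internal optional [internal_noise()] spec (likewise).
#' @param n_replicates ensemble size (default 10).
#' @param base_seed integer seed the replicate seeds derive from.
#' @param rtol,atol integrator tolerances; ensembles default to slightly
#'   looser values than deterministic runs because the noise amplitude
#'   dominates the truncation error.
#' @return Object of class `ensemble_result`: `replicates` data frame
#'   (`replicate`, `O_T`, `O_S`, `decision`), viability flags
#'   `viable_temporal` / `viable_spatial` (all replicates strictly
#'   positive), and the ensemble `decision`.
#' @export
run_ensemble <- function(params, transport, profile, grid = ring_grid(),
                         external = NULL, internal = NULL,
                         n_replicates = 10, base_seed = 1L, T_post = 20,
                         rtol = 1e-5, atol = 1e-8, ...) {
  stopifnot(n_replicates >= 1)
  # at zero noise every replicate is the deterministic run: simulate once
  if ((is.null(external) || external$eta == 0) &&
      (is.null(internal) || internal$nu == 0)) {
    o <- tryCatch({
      traj <- simulate_ring(params, transport, profile, grid,
                            T_post = T_post, rtol = rtol, atol = atol, ...)
      sensing_outputs(traj)
    }, error = function(e) list(O_T = 0, O_S = 0, decision = "failure"))
    reps <- data.frame(replicate = seq_len(n_replicates), O_T = o$O_T,
                       O_S = o$O_S, decision = o$decision)
    res <- structure(list(replicates = reps,
                          viable_temporal = all(reps$O_T > 0),
                          viable_spatial = all(reps$O_S > 0),
                          n_replicates = n_replicates,
                          base_seed = base_seed),
                     class = "ensemble_result")
    res$decision <- noise_decision(res)
    return(res)
  }
  rows <- lapply(seq_len(n_replicates), function(r) {
    ext <- external
    if (!is.null(ext)) ext$seed <- derive_seed(base_seed, r, 1L)
    int <- internal
    if (!is.null(int)) int$seed <- derive_seed(base_seed, r, 2L)
    o <- tryCatch({
      traj <- simulate_ring(params, transport, profile, grid,
                            T_post = T_post, external = ext,
                            internal = int, rtol = rtol, atol = atol, ...)
      sensing_outputs(traj)
    }, error = function(e) list(O_T = 0, O_S = 0, decision = "failure"))
    data.frame(replicate = r, O_T = o$O_T, O_S = o$O_S,
               decision = o$decision)
  })
  reps <- do.call(rbind, rows)
  res <- structure(list(replicates = reps,
                        viable_temporal = all(reps$O_T > 0),
                        viable_spatial = all(reps$O_S > 0),
                        n_replicates = n_replicates,
                        base_seed = base_seed),
                   class = "ensemble_result")
  res$decision <- noise_decision(res)
  res
}

#' Viability of a sensing strategy under noise
#'
#' A strategy is viable for a parameter set when every stochastic replicate
#' yields strictly positive output for it.
#'
#' @param ensemble an [run_ensemble()] result.
#' @param strategy `"temporal"` or `"spatial"`.
#' @return Logical.
#' @export
viability <- function(ensemble, strategy = c("temporal", "spatial")) {
  stopifnot(inherits(ensemble, "ensemble_result"))
  strategy <- match.arg(strategy)
  if (strategy == "temporal") ensemble$viable_temporal
  else ensemble$viable_spatial
}

#' Ensemble-level sensing decision
#'
#' Neither strategy viable gives `"failure"`; exactly one viable wins; when
#' both are viable, [decide()] is applied to the replicate-mean outputs.
#'
#' @param ensemble an [run_ensemble()] result.
#' @return `"temporal"`, `"spatial"` or `"failure"`.
#' @export
noise_decision <- function(ensemble) {
  stopifnot(inherits(ensemble, "ensemble_result"))
  vt <- ensemble$viable_temporal; vs <- ensemble$viable_spatial
  if (!vt && !vs) return("failure")
  if (vt && !vs) return("temporal")
  if (vs && !vt) return("spatial")
  decide(mean(ensemble$replicates$O_T), mean(ensemble$replicates$O_S))
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf(
    "Stochastic ensemble (%d replicates): temporal %sviable, spatial %sviable -> %s\n",
    x$n_replicates, if (x$viable_temporal) "" else "not ",
    if (x$viable_spatial) "" else "not ", x$decision))
  cat(sprintf("  mean O_T = %.4g, mean O_S = %.4g\n",
              mean(x$replicates$O_T), mean(x$replicates$O_S)))
  invisible(x)
}
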