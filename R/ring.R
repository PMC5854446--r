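#' Discretized ring-cell geometry
#'
#' The cell membrane is a one-dimensional ring of diameter 1 (lengths in
#' units of the cell diameter `d`) split into `N` equal compartments at
#' half-offset angles `theta_i = 2 pi (i - 1/2) / N`. The axial offset of a
#' compartment along the direction of motion is `p_i = cos(theta_i) / 2`,
#' spanning the full diameter; arclength spacing is `pi / N` (the ring
#' circumference is `pi d`). Half-offset angles guarantee no compartment
#' sits exactly on the front/back boundary, so the front (`p > 0`) and back
#' (`p < 0`) halves contain exactly `N/2` compartments each.
#'
#' @param N even compartment count (default 20).
#' @return Object of class `ring_grid` with fields `N`, `theta`, `p`,
#'   `delta`, `front`, `back` (logical masks).
#' @export
ring_grid <- function(N = 20) {
  if (N < 4 || N %% 2 != 0) stop("N must be even and >= 4")
  theta <- 2 * pi * (seq_len(N) - 0.5) / N
  p <- cos(theta) / 2
  structure(list(N = N, theta = theta, p = p, delta = pi / N,
                 front = p > 0, back = p < 0),
            class = "ring_grid")
}

#' Chemoattractant gradient profile
#'
#' The cell travels at dimensionless speed `beta` through a stationary
#' profile. For `tau` in `[0, T_s]` the cell center is inside the gradient
#' region; afterwards the input plateaus at `I_H`. The slope group
#' `alpha = v k / l_BC` sets the rate of input change seen by the moving
#' cell. Plateau levels: linear `I_H = I_L + alpha T_s`; exponential
#' `I_H = I_L exp(alpha T_s / I_L)` (its initial logarithmic slope matches
#' the linear profile's relative slope at `I_L`); for a step, `I_H` is given
#' directly and `alpha` is unused.
#'
#' @param shape `"linear"`, `"exponential"` or `"step"`.
#' @param I_L baseline concentration (> 0).
#' @param alpha dimensionless slope group (may be negative for a
#'   down-gradient run).
#' @param T_s dimensionless gradient exposure time.
#' @param I_H plateau concentration; required for `"step"`, derived
#'   otherwise.
#' @return Object of class `gradient_profile`.
#' @export
gradient_profile <- function(shape = c("linear", "exponential", "step"),
                             I_L = 0.5, alpha = 0.001, T_s = 10,
                             I_H = NULL) {
  shape <- match.arg(shape)
  if (I_L <= 0) stop("I_L must be > 0")
  if (T_s <= 0) stop("T_s must be > 0")
  I_H <- switch(shape,
    linear = I_L + alpha * T_s,
    exponential = I_L * exp(alpha * T_s / I_L),
    step = {
      if (is.null(I_H) || I_H <= I_L)
        stop("step profile requires I_H > I_L")
      I_H
    })
  structure(list(shape = shape, I_L = I_L, alpha = alpha, T_s = T_s,
                 I_H = I_H), class = "gradient_profile")
}

#' Dimensionless transport coefficients
#'
#' `beta = v / (d l_BC)` compares the cell speed to the product of diameter
#' and signaling rate; `D'_X = D_X / (d^2 l_BC)` compares the signaling
#' time to the time protein `X` needs to diffuse across the cell. The
#' output protein's diffusivity defaults to 0 (a non-diffusing readout).
#'
#' @param beta speed group (> 0).
#' @param D_A,D_B,D_C dimensionless diffusivities (>= 0).
#' @return Object of class `ring_transport`.
#' @export
ring_transport <- function(beta, D_A = 0, D_B = 0, D_C = 0) {
  vals <- c(beta = beta, D_A = D_A, D_B = D_B, D_C = D_C)
  if (any(!is.finite(vals)) || beta <= 0 || any(vals[-1] < 0))
    stop("need finite beta > 0 and diffusivities >= 0")
  structure(as.list(vals), class = "ring_transport")
}

#' Per-compartment chemoattractant input
#'
#' Compartment `i` sits at axial position `x'_i(tau) = beta tau + p_i` (the
#' cell center crosses the gradient's start, `x' = 0`, at `tau = 0`, so the
#' front half is already inside the gradient at entry). The gradient region
#' spans `x'` in `[0, beta T_s]`:
#' linear `I = I_L + (alpha/beta) clamp(x', 0, beta T_s)`; exponential
#' `I = I_L exp((alpha/(beta I_L)) clamp(x', 0, beta T_s))`; step
#' `I = I_L` for `x' < 0` else `I_H`.
#'
#' @param profile a [gradient_profile()].
#' @param tau dimensionless time (negative allowed: pre-entry).
#' @param grid a [ring_grid()].
#' @param beta speed group (> 0).
#' @return Numeric vector of length `grid$N`.
#' @export
input_profile <- function(profile, tau, grid, beta) {
  stopifnot(inherits(profile, "gradient_profile"), inherits(grid, "ring_grid"),
            beta > 0)
  x <- beta * tau + grid$p
  xc <- pmin(pmax(x, 0), beta * profile$T_s)
  switch(profile$shape,
    linear = profile$I_L + (profile$alpha / beta) * xc,
    exponential = profile$I_L *
      exp((profile$alpha / (beta * profile$I_L)) * xc),
    step = ifelse(x < 0, profile$I_L, profile$I_H))
}

#' Discrete diffusion operator on the ring
#'
#' Second-order central difference with periodic wraparound on arclength
#' spacing `pi / N`: `D' (v[i-1] - 2 v[i] + v[i+1]) / (pi/N)^2`. The
#' compartment sum of the result is zero to machine precision (discrete
#' conservation).
#'
#' @param values per-compartment field.
#' @param D_prime dimensionless diffusivity (>= 0).
#' @param grid a [ring_grid()].
#' @return Numeric vector of length `grid$N`.
#' @export
ring_laplacian <- function(values, D_prime, grid) {
  stopifnot(inherits(grid, "ring_grid"), D_prime >= 0)
  N <- grid$N
  if (N < 3) stop("need at least 3 compartments")
  ip1 <- c(2:N, 1); im1 <- c(N, 1:(N - 1))
  D_prime * (values[im1] - 2 * values + values[ip1]) / grid$delta^2
}

#' Simulate the circuit on a moving ring cell
#'
#' Method-of-lines integration of the three species on the ring: per
#' compartment the circuit kinetics driven by the local input
#' [input_profile()], plus diffusion [ring_laplacian()] for each species.
#' The initial condition is the spatially uniform steady state at `I_L` and
#' the window runs from entry (`tau = 0`) to `T_s + T_post`, covering
#' transit and re-adaptation at the plateau. Integration uses adaptive
#' stiff [deSolve::lsoda()].
#'
#' Optional noise: `external` multiplies the input by a frozen spatial
#' random field (see [external_noise()]); `internal` makes the kinetic
#' constants follow a pre-drawn piecewise-constant path in time (see
#' [internal_noise()]). Both realizations are drawn up-front, so results
#' are reproducible and independent of the solver's step-size control.
#'
#' @param params a [circuit_params()] object.
#' @param transport a [ring_transport()] object.
#' @param profile a [gradient_profile()] object.
#' @param grid a [ring_grid()] object.
#' @param T_post time simulated past the gradient exposure (default 20).
#' @param external optional [external_noise()] spec.
#' @param internal optional [internal_noise()] spec.
#' @param rtol,atol integrator tolerances.
#' @param dt_store spacing of stored times.
#' @return Object of class `ring_trajectory`: `times`, matrices `A`, `B`,
#'   `C` (time x compartment), derived series `mean_C`, `front_C`,
#'   `back_C`, baseline `C0`, and the inputs that produced it.
#' @export
simulate_ring <- function(params, transport, profile, grid = ring_grid(),
                          T_post = 20, external = NULL, internal = NULL,
                          rtol = 1e-6, atol = 1e-9, dt_store = 0.05) {
  assert_params(params)
  stopifnot(inherits(transport, "ring_transport"),
            inherits(profile, "gradient_profile"),
            inherits(grid, "ring_grid"))
  N <- grid$N
  tau_end <- profile$T_s + T_post
  beta <- transport$beta
  y0 <- rep(steady_state(params, profile$I_L), each = N)
  iA <- 1:N; iB <- N + 1:N; iC <- 2 * N + 1:N
  noise_factor <- if (!is.null(external))
    realize_external_field(external, beta, tau_end, grid) else NULL
  if (!is.null(noise_factor)) {
    # a cell that has been sitting in the frozen noisy field is adapted to
    # its local input at entry: pre-equilibrate each compartment at its own
    # tau = 0 input (the adapted C component is input-independent anyway),
    # so the functionals measure the traversal response, not an onset shock
    I0 <- pmax(input_profile(profile, 0, grid, beta) *
                 noise_factor(grid$p), 0)
    st0 <- vapply(pmax(I0, 1e-12), function(I) steady_state(params, I),
                  numeric(3))
    y0 <- c(st0[1, ], st0[2, ], st0[3, ])
  }
  ip1 <- c(2:N, 1); im1 <- c(N, 1:(N - 1))
  inv_d2 <- 1 / grid$delta^2
  nfb <- params$topology == "NFB"

  rates_at <- if (!is.null(internal))
    realize_internal_path(internal, params, tau_end) else NULL
  base_rates <- unlist(params[c("k_IA", "k_IB", "k_CB", "k_AC",
                                "l_FA", "l_FB", "l_BC")])

  # input computation inlined (input_profile() minus its argument checks):
  # the rhs is called tens of thousands of times per run
  x_hi <- beta * profile$T_s
  slope <- if (profile$shape == "linear") profile$alpha / beta else
    if (profile$shape == "exponential") profile$alpha / (beta * profile$I_L)
  input_at <- function(t) {
    x <- beta * t + grid$p
    switch(profile$shape,
      linear = profile$I_L + slope * pmin(pmax(x, 0), x_hi),
      exponential = profile$I_L * exp(slope * pmin(pmax(x, 0), x_hi)),
      step = ifelse(x < 0, profile$I_L, profile$I_H))
  }
  rhs <- function(t, y, r) {
    A <- y[iA]; B <- y[iB]; C <- y[iC]
    I <- input_at(t)
    if (!is.null(noise_factor)) I <- pmax(I * noise_factor(beta * t + grid$p), 0)
    dA <- r[["k_IA"]] * I - r[["l_FA"]] * A +
      transport$D_A * (A[im1] - 2 * A + A[ip1]) * inv_d2
    if (nfb) {
      dB <- r[["k_CB"]] * C - r[["l_FB"]] +
        transport$D_B * (B[im1] - 2 * B + B[ip1]) * inv_d2
      dB[B <= 0 & dB < 0] <- 0
    } else {
      dB <- r[["k_IB"]] * I - r[["l_FB"]] * B +
        transport$D_B * (B[im1] - 2 * B + B[ip1]) * inv_d2
    }
    dC <- r[["k_AC"]] * A * (1 - C) / (params$K_AC + 1 - C) -
      r[["l_BC"]] * pmax(B, 0) * C / (params$L_BC + C) +
      transport$D_C * (C[im1] - 2 * C + C[ip1]) * inv_d2
    list(c(dA, dB, dC))
  }

  # analytic Jacobian (clamps ignored: lsoda only needs it approximately)
  lap_mat <- function(D) {
    M <- diag(-2, N)
    M[cbind(1:N, ip1)] <- 1
    M[cbind(1:N, im1)] <- 1
    M * D * inv_d2
  }
  LA <- lap_mat(transport$D_A)
  LB <- lap_mat(transport$D_B)
  LC <- lap_mat(transport$D_C)
  jac <- function(t, y, r) {
    A <- y[iA]; B <- y[iB]; C <- y[iC]
    J <- matrix(0, 3 * N, 3 * N)
    J[iA, iA] <- LA - diag(r[["l_FA"]], N)
    if (nfb) {
      J[iB, iB] <- LB
      J[cbind(iB, iC)] <- r[["k_CB"]]
    } else {
      J[iB, iB] <- LB - diag(r[["l_FB"]], N)
    }
    J[cbind(iC, iA)] <- r[["k_AC"]] * (1 - C) / (params$K_AC + 1 - C)
    J[cbind(iC, iB)] <- -r[["l_BC"]] * C / (params$L_BC + C)
    J[iC, iC] <- LC +
      diag(-r[["k_AC"]] * A * params$K_AC / (params$K_AC + 1 - C)^2 -
             r[["l_BC"]] * pmax(B, 0) * params$L_BC / (params$L_BC + C)^2, N)
    J
  }

  times <- seq(0, tau_end, by = dt_store)
  fail <- function() stop(sprintf(
    "ring integration failed (%s, beta=%g, D'_A=%g, D'_B=%g)",
    params$topology, beta, transport$D_A, transport$D_B))
  if (is.null(rates_at)) {
    out <- suppressWarnings(
      deSolve::lsoda(y = y0, times = times, func = rhs,
                     parms = base_rates, jacfunc = jac,
                     jactype = "fullusr", rtol = rtol, atol = atol,
                     maxsteps = 1e5))
    if (attr(out, "istate")[1] < 0 || nrow(out) < length(times)) fail()
  } else {
    # kinetic constants are piecewise constant on the resample grid:
    # integrate each smooth segment separately so the adaptive solver
    # never straddles a parameter jump
    dt_r <- internal$resample_interval
    bounds <- unique(c(seq(0, tau_end, by = dt_r), tau_end))
    out <- matrix(NA_real_, length(times), 1 + 3 * N)
    out[1, ] <- c(0, y0)
    y <- y0
    for (j in seq_len(length(bounds) - 1)) {
      t0 <- bounds[j]; t1 <- bounds[j + 1]
      seg_store <- times[times > t0 & times <= t1]
      seg_times <- unique(c(t0, seg_store, t1))
      r <- rates_at(t0 + dt_r / 2)
      seg <- suppressWarnings(
        deSolve::lsoda(y = y, times = seg_times, func = rhs,
                       parms = r, jacfunc = jac, jactype = "fullusr",
                       rtol = rtol, atol = atol, maxsteps = 1e5))
      if (attr(seg, "istate")[1] < 0 || nrow(seg) < length(seg_times)) fail()
      y <- seg[nrow(seg), -1]
      if (length(seg_store))
        out[match(seg_store, times), ] <-
          seg[match(seg_store, seg[, 1]), , drop = FALSE]
    }
  }
  Cm <- out[, 1 + iC, drop = FALSE]
  structure(list(
    times = out[, 1],
    A = out[, 1 + iA, drop = FALSE],
    B = out[, 1 + iB, drop = FALSE],
    C = Cm,
    C0 = Cm[1, ],
    mean_C = rowMeans(Cm),
    front_C = rowSums(Cm[, grid$front, drop = FALSE]),
    back_C = rowSums(Cm[, grid$back, drop = FALSE]),
    grid = grid, profile = profile, transport = transport,
    params = params),
    class = "ring_trajectory")
}

#' Mean, front and back output series of a ring trajectory
#'
#' @param traj a `ring_trajectory` from [simulate_ring()].
#' @param grid the grid to use for the masks; defaults to the trajectory's.
#' @return Data frame with columns `tau`, `mean_C` (compartment mean),
#'   `front_C` and `back_C` (sums over the front/back halves).
#' @export
summarize_traj <- function(traj, grid = traj$grid) {
  stopifnot(inherits(traj, "ring_trajectory"))
  data.frame(tau = traj$times,
             mean_C = rowMeans(traj$C),
             front_C = rowSums(traj$C[, grid$front, drop = FALSE]),
             back_C = rowSums(traj$C[, grid$back, drop = FALSE]))
}

#' @export
print.ring_trajectory <- function(x, ...) {
  cat(sprintf(
    "Ring-cell trajectory: %s circuit, N = %d, beta = %g, D' = (%g, %g, %g)\n",
    x$params$topology, x$grid$N, x$transport$beta,
    x$transport$D_A, x$transport$D_B, x$transport$D_C))
  cat(sprintf("  %s profile, I_L = %g -> I_H = %g, tau in [0, %g]\n",
              x$profile$shape, x$profile$I_L, x$profile$I_H,
              max(x$times)))
  o <- sensing_outputs(x)
  cat(sprintf("  O_T = %.4g, O_S = %.4g -> %s sensing\n",
              o$O_T, o$O_S, o$decision))
  invisible(x)
}

#' @export
plot.ring_trajectory <- function(x, ...) {
  s <- summarize_traj(x)
  half <- x$grid$N / 2
  graphics::matplot(s$tau, cbind(s$mean_C, s$front_C / half, s$back_C / half),
                    type = "l", lty = 1, col = c("red", "darkgreen", "blue"),
                    xlab = expression(tau), ylab = "C (per-compartment mean)",
                    ...)
  graphics::legend("topright", c("mean", "front", "back"), lty = 1,
                   col = c("red", "darkgreen", "blue"), bty = "n")
  invisible(x)
}

#' @export
as.data.frame.ring_trajectory <- function(x, ...) {
  N <- x$grid$N
  data.frame(tau = rep(x$times, N),
             compartment = rep(seq_len(N), each = length(x$times)),
             A = as.vector(x$A), B = as.vector(x$B), C = as.vector(x$C))
}
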