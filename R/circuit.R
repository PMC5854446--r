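#' Construct a three-node circuit parameter set
#'
#' The two adaptive circuit topologies share three species: an activator
#' \eqn{A} driven by the chemoattractant input \eqn{I}, an inactivator
#' \eqn{B}, and an output \eqn{C}. Their dimensionless dynamics are
#' \deqn{dA/d\tau = k_{IA} I - l_{FA} A}
#' \deqn{dB/d\tau = k_{CB} C - l_{FB} \quad \mathrm{(NFB)}, \qquad
#'       dB/d\tau = k_{IB} I - l_{FB} B \quad \mathrm{(IFF)}}
#' \deqn{dC/d\tau = k_{AC} A (1-C)/(K_{AC}+1-C) - l_{BC} B C/(L_{BC}+C)}
#' In the negative-integral-feedback (NFB) circuit the inactivator decay is
#' zero-order, which makes the feedback integral and the adaptation of
#' \eqn{C} exact; \eqn{B} is clamped at zero. In the incoherent feedforward
#' (IFF) circuit both \eqn{A} and \eqn{B} scale proportionally with the
#' input, so the steady state of \eqn{C} is input-independent.
#'
#' Time is measured in units of \eqn{1/l_{BC}} (the deactivation rate of the
#' output is the reference rate), so internally `l_BC` is always 1: if a
#' different physical `l_BC` is supplied, all other rates are divided by it.
#'
#' @param topology `"NFB"` or `"IFF"`.
#' @param k_IA input-to-activator rate.
#' @param k_IB input-to-inactivator rate (used by IFF only).
#' @param k_CB output-to-inactivator rate (used by NFB only).
#' @param k_AC activator-to-output rate.
#' @param l_FA,l_FB decay rates of activator and inactivator.
#' @param l_BC deactivation rate of the output; the reference rate.
#' @param K_AC,L_BC dimensionless Michaelis constants of the output
#'   production and removal terms.
#' @return An object of class `circuit_params`.
#' @examples
#' p <- circuit_params("IFF", K_AC = 0.1, L_BC = 0.1)
#' steady_state(p, input_level = 1)
#' @export
circuit_params <- function(topology = c("NFB", "IFF"),
                           k_IA = 1, k_IB = 1, k_CB = 1, k_AC = 1,
                           l_FA = 1, l_FB = 1, l_BC = 1,
                           K_AC = 0.1, L_BC = 0.1) {
  topology <- match.arg(topology)
  vals <- c(k_IA = k_IA, k_IB = k_IB, k_CB = k_CB, k_AC = k_AC,
            l_FA = l_FA, l_FB = l_FB, l_BC = l_BC,
            K_AC = K_AC, L_BC = L_BC)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all circuit rate and equilibrium constants must be finite and > 0")
  # nondimensionalize: time in units of 1/l_BC
  rates <- c("k_IA", "k_IB", "k_CB", "k_AC", "l_FA", "l_FB")
  if (l_BC != 1) vals[rates] <- vals[rates] / l_BC
  vals["l_BC"] <- 1
  structure(c(list(topology = topology), as.list(vals)),
            class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("Three-node adaptive circuit (", x$topology, ")\n", sep = "")
  branch <- if (x$topology == "NFB") "k_CB" else "k_IB"
  keep <- c("k_IA", branch, "k_AC", "l_FA", "l_FB", "K_AC", "L_BC")
  cat(paste0("  ", keep, " = ", signif(unlist(x[keep]), 4), collapse = "\n"),
      "\n  (l_BC = 1: rates in units of the output deactivation rate)\n",
      sep = "")
  invisible(x)
}

assert_params <- function(params) {
  if (!inherits(params, "circuit_params"))
    stop("`params` must be created by circuit_params()")
  invisible(params)
}

#' Circuit right-hand side
#'
#' Time derivative of `(A, B, C)` at a given input level. For the NFB branch
#' the inactivator decay is zero-order; when `B` is at zero and its raw
#' derivative is negative, the returned derivative is clamped to zero so the
#' state stays non-negative.
#'
#' @param state numeric vector `c(A, B, C)`.
#' @param input_level chemoattractant input `I >= 0`.
#' @param params a [circuit_params()] object.
#' @return Named numeric vector `c(A =, B =, C =)` of derivatives.
#' @export
circuit_rhs <- function(state, input_level, params) {
  assert_params(params)
  if (any(!is.finite(state)) || !is.finite(input_level) || input_level < 0)
    stop("state and input must be finite and input non-negative")
  A <- state[[1]]; B <- state[[2]]; C <- state[[3]]
  dA <- params$k_IA * input_level - params$l_FA * A
  if (params$topology == "NFB") {
    dB <- params$k_CB * C - params$l_FB
    if (B <= 0 && dB < 0) dB <- 0
  } else {
    dB <- params$k_IB * input_level - params$l_FB * B
  }
  dC <- params$k_AC * A * (1 - C) / (params$K_AC + 1 - C) -
    params$l_BC * max(B, 0) * C / (params$L_BC + C)
  c(A = dA, B = dB, C = dC)
}

#' Pre-stimulus steady state of a circuit
#'
#' For NFB the fixed point of the zero-order inactivator equation pins the
#' output at `C* = l_FB / k_CB`, independent of the input; the set is
#' non-adaptive (error) if that ratio is not inside (0, 1). For IFF,
#' `A* = k_IA I / l_FA` and `B* = k_IB I / l_FB` both scale with the input,
#' so the root of the output balance in (0, 1) is input-independent; it is
#' found by bisection to near machine precision.
#'
#' @inheritParams circuit_rhs
#' @return Named numeric vector `c(A, B, C)` with `circuit_rhs()` residual
#'   at solver tolerance.
#' @export
steady_state <- function(params, input_level) {
  assert_params(params)
  if (!is.finite(input_level) || input_level <= 0)
    stop("input_level must be finite and > 0")
  A <- params$k_IA * input_level / params$l_FA
  if (params$topology == "NFB") {
    C <- params$l_FB / params$k_CB
    if (C >= 1)
      stop("non-adaptive NFB parameter set: l_FB/k_CB = ",
           signif(C, 4), " is not below 1")
    # B* balances output production against removal at C*
    B <- params$k_AC * A * (1 - C) / (params$K_AC + 1 - C) *
      (params$L_BC + C) / (params$l_BC * C)
  } else {
    B <- params$k_IB * input_level / params$l_FB
    g <- function(C) {
      params$k_AC * A * (1 - C) / (params$K_AC + 1 - C) -
        params$l_BC * B * C / (params$L_BC + C)
    }
    # g(0) > 0 and g(1) < 0 always, so a root exists in (0, 1)
    C <- stats::uniroot(g, c(0, 1), tol = .Machine$double.eps^0.75)$root
  }
  c(A = A, B = B, C = C)
}

#' Step stimulus for the point-cell adaptation assay
#'
#' @param I_L baseline input concentration (> 0).
#' @param I_H post-step input concentration (`>= I_L`).
#' @param tau_step dimensionless time of the step.
#' @param tau_end end of the simulated window (`> tau_step`).
#' @return An object of class `step_stimulus`.
#' @export
step_stimulus <- function(I_L = 0.5, I_H = 0.6, tau_step = 0, tau_end = 50) {
  if (I_L <= 0 || I_H < I_L) stop("need I_H >= I_L > 0")
  if (tau_step < 0 || tau_end <= tau_step) stop("need tau_end > tau_step >= 0")
  structure(list(I_L = I_L, I_H = I_H, tau_step = tau_step,
                 tau_end = tau_end), class = "step_stimulus")
}

#' Simulate the well-mixed (point-cell) circuit through a step input
#'
#' The circuit is pre-equilibrated at `I_L` (initial state from
#' [steady_state()]) and integrated over `[0, tau_end]` with the input
#' switching to `I_H` at `tau_step`, using the adaptive stiff solver
#' [deSolve::lsoda()]. The stored grid is refined just after the step so
#' that sharp response peaks of fast parameter sets are resolved.
#'
#' @inheritParams circuit_rhs
#' @param stimulus a [step_stimulus()] object.
#' @param rtol,atol relative and absolute integrator tolerances.
#' @param dt_store spacing of the stored time grid.
#' @param maxsteps integrator step budget; exceeding it is an error.
#' @return A `point_trajectory`: data frame columns `tau, A, B, C` plus
#'   attributes `C_initial` (pre-step steady state), `C_max` (maximum of C
#'   after the step), `C_final` (C at `tau_end`) and the stimulus.
#' @export
simulate_point <- function(params, stimulus = step_stimulus(),
                           rtol = 1e-6, atol = 1e-9, dt_store = 0.05,
                           maxsteps = 1e5) {
  assert_params(params)
  stopifnot(inherits(stimulus, "step_stimulus"))
  y0 <- steady_state(params, stimulus$I_L)
  ts <- stimulus$tau_step
  times <- sort(unique(c(
    seq(0, stimulus$tau_end, by = dt_store),
    # fine grid for two time units after the step to catch fast peaks
    seq(ts, min(ts + 2, stimulus$tau_end), by = dt_store / 25),
    stimulus$tau_end)))
  rhs <- function(t, y, parms) {
    I <- if (t < ts) stimulus$I_L else stimulus$I_H
    list(unname(circuit_rhs(y, I, params)))
  }
  out <- suppressWarnings(
    deSolve::lsoda(y = y0, times = times, func = rhs, parms = NULL,
                   rtol = rtol, atol = atol, maxsteps = maxsteps))
  if (attr(out, "istate")[1] < 0 || nrow(out) < length(times))
    stop("integration failed for ", params$topology, " parameter set")
  df <- as.data.frame(out)
  names(df) <- c("tau", "A", "B", "C")
  post <- df$tau > ts
  structure(df,
            C_initial = unname(y0[["C"]]),
            C_max = max(df$C[post]),
            C_final = df$C[nrow(df)],
            stimulus = stimulus,
            params = params,
            class = c("point_trajectory", "data.frame"))
}

#' @export
print.point_trajectory <- function(x, ...) {
  st <- attr(x, "stimulus")
  cat("Point-cell step response:", attr(x, "params")$topology,
      sprintf("circuit, I %.3g -> %.3g over tau [0, %g]\n",
              st$I_L, st$I_H, st$tau_end))
  cat(sprintf("  C_initial = %.5g, C_max = %.5g, C_final = %.5g\n",
              attr(x, "C_initial"), attr(x, "C_max"), attr(x, "C_final")))
  sp <- tryCatch(
    sprintf("  S = %.4g, P = %s\n", sensitivity(x),
            format(precision(x), digits = 4)),
    error = function(e) "  S, P undefined for this stimulus\n")
  cat(sp)
  invisible(x)
}

#' Sensitivity of a step response
#'
#' Relative peak response normalized by the relative input change:
#' \deqn{S = \frac{(C_{max}-C_{initial})/C_{initial}}{(I_H-I_L)/I_L}.}
#'
#' @param traj a `point_trajectory` from [simulate_point()].
#' @param stimulus the stimulus; defaults to the one stored in `traj`.
#' @return Non-negative dimensionless sensitivity.
#' @export
sensitivity <- function(traj, stimulus = attr(traj, "stimulus")) {
  Ci <- attr(traj, "C_initial"); Cm <- attr(traj, "C_max")
  if (stimulus$I_H == stimulus$I_L)
    stop("sensitivity undefined for a null step (I_H == I_L)")
  if (Ci == 0) stop("sensitivity undefined: C_initial is 0")
  ((Cm - Ci) / Ci) / ((stimulus$I_H - stimulus$I_L) / stimulus$I_L)
}

#' Adaptation precision of a step response
#'
#' Inverse of the relative steady-state error normalized by the relative
#' input change:
#' \deqn{P = \frac{C_{initial}/|C_{final}-C_{initial}|}{I_L/(I_H-I_L)}.}
#' Perfect adaptation (`C_final == C_initial` to machine precision) returns
#' `Inf`, which passes any finite precision threshold downstream.
#'
#' @inheritParams sensitivity
#' @return Positive precision, possibly `Inf`.
#' @export
precision <- function(traj, stimulus = attr(traj, "stimulus")) {
  Ci <- attr(traj, "C_initial"); Cf <- attr(traj, "C_final")
  if (stimulus$I_H == stimulus$I_L)
    stop("precision undefined for a null step (I_H == I_L)")
  dev <- abs(Cf - Ci)
  if (dev <= .Machine$double.eps * max(1, Ci)) return(Inf)
  (Ci / dev) / (stimulus$I_L / (stimulus$I_H - stimulus$I_L))
}
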