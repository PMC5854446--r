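test_that("the ring grid splits evenly into front and back halves", {
  g <- ring_grid(20)
  expect_equal(sum(g$front), 10)
  expect_equal(sum(g$back), 10)
  expect_true(all(g$p != 0))
  expect_equal(g$delta, pi / 20)
  expect_equal(range(g$p), c(-1, 1) * cos(pi / 20) / 2)
  expect_error(ring_grid(15), "even")
})

test_that("the input profile clamps to the gradient region", {
  g <- ring_grid(20)
  # zero slope: baseline everywhere, any time
  flat <- gradient_profile("linear", I_L = 0.5, alpha = 0, T_s = 10)
  for (tau in c(-5, 0, 7, 100))
    expect_equal(input_profile(flat, tau, g, beta = 0.5), rep(0.5, 20))
  # hand evaluation at tau = 2, beta = 0.5, alpha = 0.001
  prof <- gradient_profile("linear", I_L = 0.5, alpha = 0.001, T_s = 10)
  I <- input_profile(prof, 2, g, beta = 0.5)
  expect_equal(I, 0.5 + 0.002 * pmin(pmax(1 + g$p, 0), 5), tolerance = 1e-14)
  expect_equal(max(I), 0.5 + 0.002 * (1 + max(g$p)))
  # whole cell past the gradient region sits at the plateau
  I_end <- input_profile(prof, (0.5 * 10 + 0.5) / 0.5 + 1, g, beta = 0.5)
  expect_equal(I_end, rep(prof$I_H, 20))
  expect_equal(prof$I_H, 0.51)
  # step: front half sees the plateau immediately
  st <- gradient_profile("step", I_L = 0.5, I_H = 0.7, T_s = 10)
  I0 <- input_profile(st, 0, g, beta = 1)
  expect_equal(I0[g$front], rep(0.7, 10))
  expect_equal(I0[g$back], rep(0.5, 10))
  # exponential plateau matches the matched-relative-slope construction
  ex <- gradient_profile("exponential", I_L = 0.5, alpha = 0.001, T_s = 10)
  expect_equal(ex$I_H, 0.5 * exp(0.001 * 10 / 0.5))
})

test_that("the discrete ring Laplacian conserves mass and has the right spectrum", {
  g <- ring_grid(64)
  expect_equal(ring_laplacian(rep(2.3, 64), 1.7, g), rep(0, 64))
  set.seed(1)
  v <- runif(64)
  expect_lt(abs(sum(ring_laplacian(v, 5, g))), 1e-11)
  # slowest eigenmode decays at the discrete rate, within 0.2% of -4 D'
  mode <- cos(g$theta)
  lam <- -(2 / g$delta^2) * (1 - cos(2 * pi / 64))
  out <- ring_laplacian(mode, 1, g)
  expect_equal(out, lam * mode, tolerance = 1e-12)
  expect_lt(abs(lam - (-4)) / 4, 0.002)
})

test_that("a uniform input preserves spatial symmetry exactly", {
  p <- demo_params("IFF")
  flat <- gradient_profile("linear", I_L = 0.5, alpha = 0, T_s = 10)
  tr <- simulate_ring(p, ring_transport(1, 1, 100, 0), flat, ring_grid(20),
                      T_post = 5)
  expect_equal(max(abs(sweep(tr$C, 1, tr$C[, 1], "-"))), 0)
  expect_lt(max(abs(tr$C - tr$C[1, 1])), 1e-6)  # stays at steady state
})

test_that("with no diffusion each compartment reproduces the point model", {
  p <- screened_sets("IFF", 1)[[1]]
  g <- ring_grid(20)
  beta <- 2
  st <- gradient_profile("step", I_L = 0.5, I_H = 0.6, T_s = 10)
  tr <- simulate_ring(p, ring_transport(beta, 0, 0, 0), st, g, T_post = 10)
  for (i in c(which.max(g$p), which.min(g$p))) {
    # compartment i crosses the step at tau = -p_i / beta (0 if already past)
    ts <- max(-g$p[i] / beta, 0)
    stim <- step_stimulus(0.5, 0.6, tau_step = ts, tau_end = 20)
    pt <- simulate_point(p, stim, dt_store = 0.05)
    shared <- match(round(tr$times, 10), round(pt$tau, 10))
    expect_lt(max(abs(tr$C[, i] - pt$C[shared])), 1e-5)
  }
})

test_that("sensing outputs converge in the compartment count", {
  p <- screened_sets("IFF", 1)[[1]]
  prof <- default_profile()
  tp <- ring_transport(0.125, 1, 100, 0)
  o20 <- sensing_outputs(simulate_ring(p, tp, prof, ring_grid(20)))
  o40 <- sensing_outputs(simulate_ring(p, tp, prof, ring_grid(40)))
  expect_lt(abs(o40$O_T / o20$O_T - 1), 0.01)
  expect_lt(abs(o40$O_S / o20$O_S - 1), 0.01)
})

test_that("results depend on compartment positions, not their labels", {
  # negating every axial offset relabels the ring (the position multiset is
  # symmetric); all physical summaries must be unchanged
  p <- screened_sets("NFB", 1)[[1]]
  g <- ring_grid(20)
  relabeled <- g
  relabeled$p <- -g$p
  relabeled$front <- relabeled$p > 0
  relabeled$back <- relabeled$p < 0
  prof <- default_profile()
  tp <- ring_transport(0.5, 1, 10, 0)
  a <- simulate_ring(p, tp, prof, g, T_post = 10)
  b <- simulate_ring(p, tp, prof, relabeled, T_post = 10)
  expect_gt(max(abs(a$front_C - a$back_C)), 0)  # genuine asymmetry present
  expect_equal(a$front_C, b$front_C, tolerance = 1e-5)
  expect_equal(a$back_C, b$back_C, tolerance = 1e-5)
  expect_equal(a$mean_C, b$mean_C, tolerance = 1e-5)
})

test_that("a down-gradient run reverses both sensing outputs", {
  p <- screened_sets("NFB", 1)[[1]]
  tp <- ring_transport(0.5, 1, 10, 0)
  g <- ring_grid(20)
  up <- sensing_outputs(simulate_ring(p, tp, default_profile(0.001), g))
  dn_traj <- simulate_ring(p, tp, default_profile(-0.001), g)
  dn <- sensing_outputs(dn_traj)
  # linear response: outputs negate (to within the small quadratic part)
  expect_equal(dn$O_T, -up$O_T, tolerance = 0.05)
  expect_equal(dn$O_S, -up$O_S, tolerance = 0.05)
  expect_identical(dn$decision, "failure")
})

test_that("a fast-diffusing output homogenizes the spatial signal", {
  # homogenization compares D'_C with the kinetic relaxation rate, so use
  # a set with O(1) rates; a stiff set would need correspondingly larger D'_C
  p <- demo_params("IFF")
  prof <- default_profile()
  g <- ring_grid(20)
  asym <- function(D_C) {
    tr <- simulate_ring(p, ring_transport(0.125, 1, 100, D_C), prof, g)
    max(abs(tr$front_C - tr$back_C) / (g$N * tr$mean_C))
  }
  a0 <- asym(0)
  a_hom <- asym(100)
  expect_lt(a_hom, a0 / 20)
  expect_lt(a_hom, 1e-3)
})

test_that("at low beta the back output rises only after the front peaks", {
  p <- screened_sets("IFF", 1)[[1]]
  tr <- simulate_ring(p, ring_transport(0.125, 1, 1, 0), default_profile(),
                      ring_grid(20))
  front <- tr$front_C
  back <- tr$back_C
  t_front_peak <- tr$times[which.max(front)]
  # the back half reaches a quarter of its own rise only after the front
  # has peaked, and its peak comes later still
  rise <- 0.25 * (max(back) - back[1])
  t_back_rise <- tr$times[min(which(back - back[1] > rise))]
  expect_gt(t_back_rise, t_front_peak)
  expect_gt(tr$times[which.max(back)], t_front_peak)
})

test_that("trajectory export has one row per time and compartment", {
  p <- demo_params("IFF")
  tr <- simulate_ring(p, ring_transport(1, 0, 0, 0), default_profile(),
                      ring_grid(6), T_post = 2, dt_store = 0.5)
  df <- as.data.frame(tr)
  expect_equal(nrow(df), length(tr$times) * 6)
  expect_named(df, c("tau", "compartment", "A", "B", "C"))
  expect_equal(df$C[df$compartment == 3], unname(tr$C[, 3]))
})
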