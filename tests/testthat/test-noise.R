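test_that("zero external noise reduces to the deterministic input", {
  g <- ring_grid(20)
  prof <- default_profile()
  I0 <- input_profile(prof, 3, g, beta = 0.5)
  In <- noisy_input_profile(prof, external_noise(0, seed = 4), 3, g,
                            beta = 0.5, tau_end = 30)
  expect_equal(In, I0)
})

test_that("the frozen noise field is reproducible and bounded below", {
  g <- ring_grid(20)
  prof <- default_profile()
  spec <- external_noise(0.5, seed = 99)
  a <- noisy_input_profile(prof, spec, 3, g, beta = 0.5, tau_end = 30)
  b <- noisy_input_profile(prof, spec, 3, g, beta = 0.5, tau_end = 30)
  expect_identical(a, b)
  expect_true(any(a != input_profile(prof, 3, g, 0.5)))
  big <- noisy_input_profile(prof, external_noise(5, seed = 99), 3, g,
                             beta = 0.5, tau_end = 30)
  expect_true(all(big >= 0))  # truncated at zero
})

test_that("at large eta the noise deviations rival the signal itself", {
  g <- ring_grid(20)
  prof <- default_profile()
  I0 <- input_profile(prof, 3, g, beta = 0.5)
  In <- noisy_input_profile(prof, external_noise(1, seed = 12), 3, g,
                            beta = 0.5, tau_end = 30)
  expect_gt(max(abs(In - I0) / I0), 0.25)
})

test_that("the kinetic-noise sampler is unbiased and truncated at zero", {
  p <- demo_params("IFF")
  spec <- internal_noise(0.25)
  expect_equal(perturb_params(p, internal_noise(0)), p,
               ignore_attr = TRUE)
  set.seed(5)
  draws <- replicate(1e4, perturb_params(p, spec)$k_AC)
  expect_true(all(draws >= 0))
  # sample mean within 3 standard errors of the noiseless value
  # (truncation bias at cv = 0.5 is well below that)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - p$k_AC), 3 * se + 0.01 * p$k_AC)
  # equilibrium constants are never perturbed
  expect_equal(perturb_params(p, spec)$K_AC, p$K_AC)
})

test_that("ensembles are reproducible and zero noise equals deterministic", {
  p <- screened_sets("IFF", 1)[[1]]
  tp <- ring_transport(1, 1, 100, 0)
  prof <- default_profile()
  g <- ring_grid(20)
  e1 <- run_ensemble(p, tp, prof, g, external = external_noise(0.25),
                     n_replicates = 3, base_seed = 21)
  e2 <- run_ensemble(p, tp, prof, g, external = external_noise(0.25),
                     n_replicates = 3, base_seed = 21)
  expect_equal(e1$replicates, e2$replicates)
  expect_equal(nrow(e1$replicates), 3)
  # replicates differ from each other under nonzero noise
  expect_gt(diff(range(e1$replicates$O_T)), 0)
  # zero noise: every replicate equals the deterministic run
  det <- sensing_outputs(simulate_ring(p, tp, prof, g, rtol = 1e-5,
                                       atol = 1e-8))
  e0 <- run_ensemble(p, tp, prof, g, external = external_noise(0),
                     n_replicates = 4, base_seed = 21)
  expect_equal(unique(e0$replicates$O_T), det$O_T)
  expect_equal(unique(e0$replicates$O_S), det$O_S)
  expect_identical(e0$decision, det$decision)
})

test_that("viability requires every replicate to be strictly positive", {
  fake <- function(O_T, O_S) {
    r <- structure(list(replicates = data.frame(
      replicate = seq_along(O_T), O_T = O_T, O_S = O_S,
      decision = mapply(decide, O_T, O_S)),
      viable_temporal = all(O_T > 0), viable_spatial = all(O_S > 0),
      n_replicates = length(O_T), base_seed = 1),
      class = "ensemble_result")
    r$decision <- noise_decision(r)
    r
  }
  all_pos <- fake(O_T = rep(1, 10), O_S = rep(0.5, 10))
  expect_true(viability(all_pos, "temporal"))
  expect_true(viability(all_pos, "spatial"))
  expect_identical(all_pos$decision, "temporal")  # larger mean output

  one_bad <- fake(O_T = rep(1, 10), O_S = c(rep(2, 9), -0.1))
  expect_false(viability(one_bad, "spatial"))
  expect_identical(one_bad$decision, "temporal")  # only viable strategy

  neither <- fake(O_T = c(-1, rep(1, 9)), O_S = c(rep(2, 9), -0.1))
  expect_identical(neither$decision, "failure")

  spatial_wins <- fake(O_T = rep(0.2, 10), O_S = rep(1, 10))
  expect_identical(spatial_wins$decision, "spatial")
})

test_that("external noise drives slower output fluctuations than internal", {
  p <- screened_sets("IFF", 2)[[2]]
  tp <- ring_transport(1, 1, 100, 0)
  prof <- default_profile()
  g <- ring_grid(20)
  base <- simulate_ring(p, tp, prof, g, rtol = 1e-5, atol = 1e-8)
  ext <- simulate_ring(p, tp, prof, g, external = external_noise(1, seed = 8),
                       rtol = 1e-5, atol = 1e-8)
  int <- simulate_ring(p, tp, prof, g,
                       internal = internal_noise(0.25, seed = 8),
                       rtol = 1e-5, atol = 1e-8)
  centroid <- function(tr) {
    x <- tr$mean_C - base$mean_C
    sp <- stats::spec.pgram(stats::ts(x, deltat = 0.05), plot = FALSE,
                            taper = 0.1, detrend = TRUE)
    sum(sp$freq * sp$spec) / sum(sp$spec)
  }
  expect_lt(centroid(ext), centroid(int))
})
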