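# shared fixtures, computed once per test run
.fixtures <- new.env(parent = emptyenv())

# first n parameter sets passing the adaptation screen (fixed seed);
# one screen per topology, sliced on demand
screened_sets <- function(topology, n = 10) {
  if (is.null(.fixtures[[topology]]))
    .fixtures[[topology]] <- suppressWarnings(
      screen_parameters(500, topology, seed = 7, n_keep = 10)$selected)
  .fixtures[[topology]][seq_len(n)]
}

# a hand-specified responsive set used where screening would be overkill
demo_params <- function(topology = "IFF") {
  circuit_params(topology, k_IA = 1, k_IB = 1, k_CB = 2, k_AC = 1,
                 l_FA = 1, l_FB = 1, K_AC = 0.1, L_BC = 0.1)
}

# minimal ring_trajectory for testing the output functionals in isolation
make_traj <- function(times, C, grid) {
  structure(list(times = times, C = C, C0 = C[1, ],
                 mean_C = rowMeans(C),
                 front_C = rowSums(C[, grid$front, drop = FALSE]),
                 back_C = rowSums(C[, grid$back, drop = FALSE]),
                 grid = grid),
            class = "ring_trajectory")
}

default_profile <- function(alpha = 0.001)
  gradient_profile("linear", I_L = 0.5, alpha = alpha, T_s = 10)
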