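# shared helpers for the simulation-heavy tests

baseline_params <- function(alpha = 1, steps = 5000, seed = 1,
                            lambda = NULL, ...) {
  sim_params(N = 60, k = 10, alpha = alpha, q = 0.9, eps = 0.05,
             steps = steps, burn_in = 0.1, seed = seed, ...)
}

# fixation probability of `mutant` into `resident` (and the reverse) from a
# fresh behaviour sweep at the given payoff parameter
fixation_both <- function(mutant, resident, alpha, steps, seed,
                          N = 60, k = 10, s = 1) {
  p <- sim_params(N = N, k = k, alpha = alpha, q = 0.9, eps = 0.05,
                  steps = steps, burn_in = 0.1, seed = seed)
  cb <- composition_behaviour(mutant, resident, p)
  cp <- composition_payoffs(cb, params = p)
  rev_idx <- rev(seq_len(N - 1))
  c(mut_into_res = fixation_probability(cp$pi_mut, cp$pi_res, s, N),
    res_into_mut = fixation_probability(cp$pi_res[rev_idx],
                                        cp$pi_mut[rev_idx], s, N))
}

# equilibrium of one {norm, ALLC, ALLD} cell at (alpha, lambda)
norm_cell_equilibrium <- function(strategy, alpha, lambda, steps, seed,
                                  N = 60, k = 10, s = 1) {
  cfg <- scenario_config("phase_grid", strategy = strategy,
                         alpha_grid = alpha, lambdas = lambda,
                         N = N, k = k, steps = steps, burn_in = 0.2,
                         s = s, seed = seed)
  run_phase_grid(cfg)
}
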