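test_that("Fermi imitation probability has the right shape", {
  expect_equal(fermi_prob(2, 2, 1), 0.5)
  expect_equal(fermi_prob(5, -3, 0), 0.5)
  expect_equal(fermi_prob(0, 1, 1), 1 / (1 + exp(-1)))
  expect_equal(fermi_prob(0, 1, 1), 0.73106, tolerance = 1e-5)
  deltas <- seq(-3, 3, by = 0.5)
  probs <- fermi_prob(0, deltas, 2)
  expect_true(all(diff(probs) > 0))
  expect_true(all(probs > 0 & probs < 1))
})

test_that("fixation probability closed form matches its exact special cases", {
  N <- 40
  # neutral mutant: exactly 1/N
  pi0 <- rep(1.3, N - 1)
  expect_equal(fixation_probability(pi0, pi0, 1, N), 1 / N)
  expect_equal(fixation_probability(pi0, pi0, 0, N), 1 / N)
  # N = 2: single term reduces to the Fermi probability
  pm <- 0.8; pr <- 0.2; s <- 1.7
  expect_equal(fixation_probability(pm, pr, s, 2), fermi_prob(pr, pm, s))
  # constant payoff difference: geometric series (1 - g) / (1 - g^N)
  for (delta in c(0.3, -0.4)) {
    s <- 1.2
    g <- exp(-s * delta)
    rho <- fixation_probability(rep(delta, N - 1), rep(0, N - 1), s, N)
    expect_equal(rho, (1 - g) / (1 - g^N))
  }
})

test_that("fixation probability is monotone in the mutant payoffs and overflow-safe", {
  set.seed(3)
  N <- 25
  pi_res <- runif(N - 1)
  pi_mut <- pi_res + rnorm(N - 1, 0, 0.2)
  rho1 <- fixation_probability(pi_mut, pi_res, 1, N)
  rho2 <- fixation_probability(pi_mut + 0.1, pi_res, 1, N)
  expect_gte(rho2, rho1)
  # strong selection against the mutant: underflows gracefully, never NaN
  rho_tiny <- fixation_probability(rep(-50, N - 1), rep(50, N - 1), 10, N)
  expect_true(is.finite(rho_tiny))
  expect_gte(rho_tiny, 0)
  expect_lt(rho_tiny, 1e-100)
  rho_sure <- fixation_probability(rep(50, N - 1), rep(-50, N - 1), 10, N)
  expect_equal(rho_sure, 1, tolerance = 1e-12)
})

test_that("closed-form fixation agrees with direct simulation of the imitation chain", {
  # two states with a composition-dependent payoff rule, N = 10, s = 1
  N <- 10; s <- 1
  payoff_of_m <- function(m) c(0.1 + 0.03 * m, 0.25 - 0.01 * m)
  cp_mut <- vapply(1:(N - 1), function(m) payoff_of_m(m)[1], numeric(1))
  cp_res <- vapply(1:(N - 1), function(m) payoff_of_m(m)[2], numeric(1))
  rho <- fixation_probability(cp_mut, cp_res, s, N)
  payoff_fn <- function(counts) payoff_of_m(counts[1])
  set.seed(11)
  runs <- 1500
  fixed <- vapply(seq_len(runs), function(r) {
    out <- agent_based_evolution(
      list(player_state("ALLC", 0.5), player_state("ALLD", 0.5)),
      init_counts = c(1, N - 1), n_steps = 50000, s = s, mu = 0,
      payoff_fn = payoff_fn, record_every = 1e9, stop_when_absorbed = TRUE)
    identical(out$absorbed_state, 1L)
  }, logical(1))
  phat <- mean(fixed)
  se <- sqrt(phat * (1 - phat) / runs)
  expect_lt(abs(phat - rho), 3 * se + 1e-6)
})

test_that("neutral agent-based evolution fixes proportionally to its start", {
  set.seed(21)
  N <- 8; m0 <- 3
  runs <- 600
  fixed <- vapply(seq_len(runs), function(r) {
    out <- agent_based_evolution(
      list(player_state("L1", 0.5), player_state("L1", 0.6)),
      init_counts = c(m0, N - m0), n_steps = 30000, s = 0, mu = 0,
      payoff_fn = function(counts) c(0, 0), record_every = 1e9,
      stop_when_absorbed = TRUE)
    identical(out$absorbed_state, 1L)
  }, logical(1))
  phat <- mean(fixed)
  se <- sqrt(phat * (1 - phat) / runs)
  expect_lt(abs(phat - m0 / N), 3 * se + 1e-6)
})

test_that("mu = 0 keeps a homogeneous population homogeneous; mu = 1 mixes", {
  out <- agent_based_evolution(
    list(player_state("L2", 0.4), player_state("ALLD", 0.4)),
    init_counts = c(6, 0), n_steps = 500, s = 1, mu = 0,
    payoff_fn = function(counts) c(1, 0), record_every = 100)
  expect_true(all(out$trajectory[, 1] == 6))
  set.seed(2)
  out1 <- agent_based_evolution(
    list(player_state("L2", 0.4), player_state("ALLD", 0.4)),
    init_counts = c(6, 0), n_steps = 4000, s = 1, mu = 1,
    payoff_fn = function(counts) c(1, 0), record_every = 1)
  means <- colMeans(out1$trajectory[-(1:500), ])
  expect_lt(abs(means[1] - 3), 0.6)  # uniform mutation: ~half and half
})

test_that("embedded chain and stationary distribution behave as advertised", {
  fix <- matrix(0.2, 3, 3); diag(fix) <- 0
  T <- embedded_chain(fix)
  expect_equal(rowSums(T), rep(1, 3))
  expect_true(all(T[row(T) != col(T)] == 0.1))
  ab <- stationary_distribution(T)
  expect_equal(unname(ab), rep(1 / 3, 3))

  # 2-state balance: x_A = rho(A into B) / (rho(A into B) + rho(B into A))
  rab <- 0.3; rba <- 0.1
  # fix[resident, mutant]: row B column A = rho(A into B)
  fix2 <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  fix2["B", "A"] <- rab  # A invades B
  fix2["A", "B"] <- rba  # B invades A
  ab2 <- stationary_distribution(embedded_chain(fix2))
  expect_equal(unname(ab2["A"]), rab / (rab + rba))

  # left fixed vector property and invariance under common rescaling
  set.seed(5)
  fix3 <- matrix(runif(16, 0.01, 0.9), 4, 4); diag(fix3) <- 0
  T3 <- embedded_chain(fix3)
  ab3 <- stationary_distribution(T3)
  expect_equal(as.numeric(ab3 %*% T3), as.numeric(ab3), tolerance = 1e-10)
  ab3s <- stationary_distribution(embedded_chain(fix3 * 0.37))
  expect_equal(ab3, ab3s, tolerance = 1e-9)

  # reducible chains are rejected
  fix_red <- matrix(0, 3, 3); fix_red[2, 1] <- 0.5
  expect_error(stationary_distribution(embedded_chain(fix_red)), "reducible")
})

test_that("equilibrium cooperation rate is the abundance-weighted mean", {
  expect_equal(equilibrium_cooperation_rate(c(0, 0, 1), c(0.7, 1, 0)), 0)
  expect_equal(equilibrium_cooperation_rate(c(0, 1, 0), c(0.7, 1, 0)), 1)
  expect_equal(equilibrium_cooperation_rate(c(0.5, 0.5), c(1, 0)), 0.5)
})

test_that("the critical payoff parameter matches the brute-force expectation", {
  expect_equal(critical_alpha(60, 10), 1.18)
  expect_equal(critical_alpha(1e7, 10), 1, tolerance = 1e-5)
  expect_error(critical_alpha(10, 10), "k < N")
  # exact: the brute-force cooperator/defector difference vanishes at
  # alpha_c and flips sign around it, at every composition
  for (N in c(12, 60)) for (k in c(3, 10)) {
    ac <- critical_alpha(N, k)
    for (m in c(1, N %/% 2, N - 1)) {
      expect_equal(payoff_difference_bruteforce(N, k, m, ac), 0,
                   tolerance = 1e-12)
      expect_gt(payoff_difference_bruteforce(N, k, m, ac + 0.05), 0)
      expect_lt(payoff_difference_bruteforce(N, k, m, ac - 0.05), 0)
    }
  }
})

test_that("composition payoffs recover the ALLC/ALLD closed form", {
  N <- 12; k <- 4
  params <- sim_params(N = N, k = k, alpha = 1.1, q = 0.9, eps = 0.05,
                       steps = 8000, burn_in = 0.1, seed = 31)
  cb <- composition_behaviour(player_state("ALLC", 0.5),
                              player_state("ALLD", 0.5), params)
  cp <- composition_payoffs(cb, params = params)
  target <- 1.1 * (N - k) / (N - 1) - 1
  expect_true(all(abs((cp$pi_mut - cp$pi_res) - target) < 0.05))
  # at the critical alpha the difference is ~0 at every composition
  pc <- params; pc$alpha <- critical_alpha(N, k); pc$R <- pc$alpha * k
  cpc <- composition_payoffs(cb, params = pc)
  expect_true(all(abs(cpc$pi_mut - cpc$pi_res) < 0.05))
})

test_that("composition sweeps match a naive per-composition oracle", {
  N <- 6; k <- 3
  params <- sim_params(N = N, k = k, alpha = 1.2, q = 0.8, eps = 0.1,
                       steps = 40, burn_in = 0, seed = 19)
  cb <- composition_behaviour(player_state("L3", 0.7),
                              player_state("ALLD", 0.7), params,
                              m_values = c(2, 4))
  for (row in seq_len(nrow(cb))) {
    m <- cb$m[row]
    pl <- make_players(c(rep("L3", m), rep("ALLD", N - m)), 0.7)
    p <- params; p$seed <- params$seed + m
    st <- simulate_reputation_dynamics(pl, p, engine = "r")
    expect_equal(cb$coop_mut[row],
                 st$classes$coop_freq[st$classes$strategy == "L3"])
    expect_equal(cb$nc_res[row],
                 st$classes$mean_nc[st$classes$strategy == "ALLD"])
  }
})

test_that("find_lambda_c follows its operational definition", {
  grid <- expand.grid(alpha = c(0.4, 0.8, 1.2), lambda = c(0.1, 0.4, 0.7))
  grid$coop_rate <- 0
  grid$coop_rate[grid$lambda == 0.4 & grid$alpha >= 0.8] <- 0.9
  grid$coop_rate[grid$lambda == 0.7 & grid$alpha >= 1.2] <- 0.8
  res <- find_lambda_c(grid)
  expect_equal(res$lambda_c, 0.4)
  expect_equal(res$alpha_min, 0.8)
  # ties break toward the smaller lambda
  grid$coop_rate[grid$lambda == 0.7 & grid$alpha >= 0.8] <- 0.8
  expect_equal(find_lambda_c(grid)$lambda_c, 0.4)
  # nothing cooperates -> undefined
  grid$coop_rate <- 0
  expect_true(is.na(find_lambda_c(grid)$lambda_c))
})
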