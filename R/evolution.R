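#' Fermi imitation probability
#'
#' Probability that a player with payoff `pi_i` imitates a role model with
#' payoff `pi_j` under the pairwise-comparison rule
#' \eqn{P = \{1 + \exp[-s(\pi_j - \pi_i)]\}^{-1}}.
#'
#' @param pi_i focal player's payoff.
#' @param pi_j role model's payoff.
#' @param s selection strength, `s >= 0`.
#' @return probability in (0, 1); vectorized.
#' @export
fermi_prob <- function(pi_i, pi_j, s) {
  stopifnot(all(s >= 0))
  stats::plogis(s * (pi_j - pi_i))
}

#' Describe a strategy state
#'
#' A (strategy, criterion) pair, the unit of the evolutionary state space.
#'
#' @param strategy strategy id (see [norm_ids()]) or alias.
#' @param lambda assessment criterion in (0, 1].
#' @return list of class `player_state`.
#' @export
player_state <- function(strategy, lambda) {
  strategy <- leading_eight_table(strategy)$id
  if (lambda <= 0 || lambda > 1) stop("lambda must lie in (0, 1]")
  structure(list(strategy = strategy, lambda = lambda), class = "player_state")
}

.state_label <- function(st) paste0(st$strategy, "|", format(st$lambda))

#' Composition-dependent behaviour of a mutant/resident pair
#'
#' For every mutant count `m` in `m_values`, simulates the reputation
#' dynamics of the population holding `m` copies of `mutant` and `N - m`
#' copies of `resident`, and records the behaviour statistics that determine
#' payoffs: each class's cooperation frequency and the mean number of
#' cooperators in the games its members played.  These statistics do not
#' depend on the payoff parameter (actions depend on reputations only while
#' strategies are fixed), so one sweep serves any value of `alpha` via
#' [composition_payoffs()].
#'
#' @param mutant,resident `player_state` objects (must differ).
#' @param params a `sim_params` object (its `alpha`/`R` is irrelevant here;
#'   its `seed` seeds composition `m` with `seed + m`).
#' @param m_values mutant counts to evaluate (default `1:(N-1)`).
#' @param cache_dir optional directory; sweeps are cached as CSV keyed by
#'   (pair, lambdas, N, k, q, eps, steps, seed).
#' @return data.frame of class `composition_behaviour` with columns `m`,
#'   `coop_mut`, `nc_mut`, `coop_res`, `nc_res` and the pair metadata as
#'   attributes.
#' @export
composition_behaviour <- function(mutant, resident, params,
                                  m_values = NULL, cache_dir = NULL) {
  stopifnot(inherits(mutant, "player_state"), inherits(resident, "player_state"))
  if (identical(unclass(mutant), unclass(resident)))
    stop("mutant and resident must be distinct (strategy, lambda) states")
  N <- params$N
  if (is.null(m_values)) m_values <- seq_len(N - 1L)
  key <- paste("cb", mutant$strategy, mutant$lambda, resident$strategy,
               resident$lambda, N, params$k, params$q, params$eps,
               params$steps, params$burn_in, params$seed, sep = "_")
  cache_file <- if (!is.null(cache_dir)) file.path(cache_dir, paste0(key, ".csv"))
  if (!is.null(cache_file) && file.exists(cache_file)) {
    out <- utils::read.csv(cache_file)
    if (identical(as.integer(out$m), as.integer(m_values)))
      return(.as_cb(out, mutant, resident))
  }
  rows <- lapply(m_values, function(m) {
    pl <- make_players(c(rep(mutant$strategy, m), rep(resident$strategy, N - m)),
                       c(rep(mutant$lambda, m), rep(resident$lambda, N - m)))
    p <- params
    p$seed <- if (is.null(params$seed)) NULL else params$seed + m
    st <- simulate_reputation_dynamics(pl, p)
    cl <- st$classes
    mut_row <- cl[cl$label == .state_label(mutant), ]
    res_row <- cl[cl$label == .state_label(resident), ]
    data.frame(m = m,
               coop_mut = mut_row$coop_freq, nc_mut = mut_row$mean_nc,
               coop_res = res_row$coop_freq, nc_res = res_row$mean_nc)
  })
  out <- do.call(rbind, rows)
  if (!is.null(cache_file)) {
    dir.create(dirname(cache_file), showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, cache_file, row.names = FALSE)
  }
  .as_cb(out, mutant, resident)
}

.as_cb <- function(df, mutant, resident) {
  structure(df, class = c("composition_behaviour", "data.frame"),
            mutant = mutant, resident = resident)
}

#' Expected per-game payoffs at each composition
#'
#' Converts a behaviour sweep into expected per-game payoffs (conditional on
#' participation): \eqn{\pi = R c \bar n_C / k - c \bar a}, with
#' \eqn{R = \alpha k} when `alpha` is given.  Called with `player_state`
#' arguments it runs the sweep itself.
#'
#' @param mutant either a `composition_behaviour` sweep or a `player_state`.
#' @param resident `player_state` (when `mutant` is a state).
#' @param params `sim_params`; supplies `alpha`/`R`, `c` and `k`.
#' @param ... passed on to [composition_behaviour()].
#' @return data.frame with columns `m`, `pi_mut`, `pi_res`.
#' @export
composition_payoffs <- function(mutant, resident = NULL, params, ...) {
  cb <- if (inherits(mutant, "composition_behaviour")) mutant
        else composition_behaviour(mutant, resident, params, ...)
  data.frame(m = cb$m,
             pi_mut = params$R * params$c * cb$nc_mut / params$k -
                      params$c * cb$coop_mut,
             pi_res = params$R * params$c * cb$nc_res / params$k -
                      params$c * cb$coop_res)
}

#' Fixation probability of the imitation birth--death chain
#'
#' Closed form for the probability that a single mutant takes over a
#' population of `N - 1` residents under pairwise Fermi imitation:
#' \deqn{\rho = \left[1 + \sum_{m=1}^{N-1} \prod_{l=1}^{m}
#'   e^{-s(\pi_{mut}(l) - \pi_{res}(l))}\right]^{-1}.}
#' Evaluated in log space, so large `s`-weighted payoff differences cannot
#' overflow.
#'
#' @param pi_mut,pi_res numeric vectors of expected payoffs at mutant counts
#'   `1..N-1` (in that order), e.g. from [composition_payoffs()].
#' @param s selection strength.
#' @param N population size (`length(pi_mut) == N - 1`).
#' @return fixation probability in (0, 1).
#' @export
fixation_probability <- function(pi_mut, pi_res, s, N) {
  stopifnot(length(pi_mut) == N - 1, length(pi_res) == N - 1, s >= 0)
  l <- cumsum(-s * (pi_mut - pi_res))       # log of the partial products
  terms <- c(0, l)                          # the leading 1 contributes log 0
  mx <- max(terms)
  lse <- mx + log(sum(exp(terms - mx)))     # log(1 + sum of products)
  exp(-lse)
}

# Both fixation directions from one unordered-pair sweep: a composition with
# l mutants is a composition with N - l residents-as-mutants.
.fixation_pair <- function(cp, s, N) {
  rho_mut <- fixation_probability(cp$pi_mut, cp$pi_res, s, N)
  rev_idx <- rev(seq_len(N - 1))            # l residents <-> N - l mutants
  rho_res <- fixation_probability(cp$pi_res[rev_idx], cp$pi_mut[rev_idx], s, N)
  c(mut_into_res = rho_mut, res_into_mut = rho_res)
}

#' Embedded Markov chain over homogeneous states
#'
#' In the rare-mutation limit the population hops between homogeneous
#' states.  Given the table of fixation probabilities `fix[i, j]` (a single
#' `j`-mutant fixating in an `i`-resident population), the transition
#' probability is `T[i, j] = fix[i, j] / (n - 1)` for `j != i` (mutations
#' uniform over the other states), diagonal set to keep rows stochastic.
#'
#' @param fix square matrix of fixation probabilities; rows = resident state,
#'   columns = invading state; diagonal ignored.
#' @return row-stochastic transition matrix with `fix`'s dimnames.
#' @export
embedded_chain <- function(fix) {
  stopifnot(is.matrix(fix), nrow(fix) == ncol(fix), nrow(fix) >= 2)
  n <- nrow(fix)
  T <- fix / (n - 1)
  diag(T) <- 0
  diag(T) <- 1 - rowSums(T)
  if (any(diag(T) < 0)) stop("invalid fixation table: diagonal went negative")
  dimnames(T) <- dimnames(fix)
  T
}

#' Stationary distribution of a row-stochastic matrix
#'
#' The unique left fixed vector (selection--mutation equilibrium of the
#' embedded chain).  The chain must be irreducible; with Fermi imitation all
#' fixation probabilities are positive, which guarantees it.
#'
#' @param T row-stochastic matrix.
#' @param tol tolerance for validation.
#' @return nonnegative vector summing to 1, named like `T`'s rows.
#' @export
stationary_distribution <- function(T, tol = 1e-9) {
  stopifnot(is.matrix(T), nrow(T) == ncol(T))
  if (any(T < -tol) || any(abs(rowSums(T) - 1) > 1e-8))
    stop("T must be row-stochastic")
  n <- nrow(T)
  # irreducibility check on the off-diagonal support (any strictly positive
  # rate counts: Fermi fixation probabilities can be tiny but never zero)
  reach <- (T > 0) | diag(n) > 0
  paths <- reach
  for (i in seq_len(n)) paths <- (paths %*% reach) > 0
  if (!all(paths)) stop("transition matrix is reducible; ",
                        "stationary distribution not unique")
  # solve x (T - I) = 0 with sum(x) = 1
  A <- rbind(t(T) - diag(n), rep(1, n))
  b <- c(rep(0, n), 1)
  x <- qr.solve(A, b)
  x[x < 0 & x > -tol] <- 0
  if (any(x < 0)) stop("negative stationary probabilities; matrix invalid")
  x <- x / sum(x)
  names(x) <- rownames(T)
  x
}

#' Equilibrium cooperation rate
#'
#' Abundance-weighted average of the homogeneous-state cooperation
#' frequencies (`ALLC` contributes 1, `ALLD` 0, a norm its simulated
#' homogeneous cooperation frequency).
#'
#' @param abundance stationary probabilities over states.
#' @param coop_rates homogeneous cooperation rates, same order.
#' @return cooperation rate in `[0, 1]`.
#' @export
equilibrium_cooperation_rate <- function(abundance, coop_rates) {
  stopifnot(length(abundance) == length(coop_rates),
            abs(sum(abundance) - 1) < 1e-6)
  sum(abundance * coop_rates)
}

#' Critical payoff parameter for unconditional cooperation
#'
#' With synergy \eqn{R(k) = \alpha k} and groups of size `k` sampled without
#' replacement from `N` players, a focal cooperator's and defector's expected
#' per-game payoffs differ by \eqn{\alpha c (N-k)/(N-1) - c} at every
#' ALLC/ALLD mixture; they coincide at
#' \deqn{\alpha_c = \frac{N-1}{N-k}.}
#' Above `alpha_c` unconditional cooperation is favoured, below it defection.
#'
#' @param N population size.
#' @param k group size, `2 <= k < N` (at `k = N` a defector always shares a
#'   group with every cooperator and no threshold exists).
#' @return the critical payoff parameter.
#' @examples
#' critical_alpha(60, 10)  # 1.18
#' @export
critical_alpha <- function(N, k) {
  stopifnot(N >= 2, k >= 2)
  if (k >= N) stop("critical alpha requires k < N (no sampling asymmetry at k = N)")
  (N - 1) / (N - k)
}

#' Brute-force cooperator/defector payoff difference
#'
#' Independent check of [critical_alpha()]: the exact expected per-game
#' payoff difference between a focal ALLC and a focal ALLD player in a
#' population with `m` cooperators, obtained by summing the hypergeometric
#' distribution of co-players over all compositions (no closed-form
#' shortcut).
#'
#' @param N,k population and group size.
#' @param m number of ALLC players, `1 <= m <= N - 1`.
#' @param alpha payoff parameter.
#' @param c contribution cost.
#' @return expected `pi_C - pi_D` (focal cooperator minus focal defector).
#' @export
payoff_difference_bruteforce <- function(N, k, m, alpha, c = 1) {
  stopifnot(m >= 1, m <= N - 1, k >= 2, k <= N)
  R <- alpha * k
  j <- 0:(k - 1)  # cooperators among the k - 1 co-players
  # focal cooperator: co-players drawn from m - 1 ALLC, N - m ALLD
  pC <- stats::dhyper(j, m - 1, N - m, k - 1)
  eC <- sum(pC * vapply(j, function(x) pg_payoffs(k, x + 1, c, R)[["pi_C"]],
                        numeric(1)))
  # focal defector: co-players drawn from m ALLC, N - 1 - m ALLD
  pD <- stats::dhyper(j, m, N - 1 - m, k - 1)
  eD <- sum(pD * vapply(j, function(x) pg_payoffs(k, x, c, R)[["pi_D"]],
                        numeric(1)))
  eC - eD
}

#' Locate the cooperation-optimal assessment criterion on a phase grid
#'
#' Operational definition: for each criterion `lambda` on the grid, find the
#' smallest payoff parameter `alpha` whose equilibrium cooperation rate
#' reaches `threshold`; `lambda_c` is the criterion minimizing that smallest
#' `alpha`, ties broken toward the smaller (more relaxed) criterion.
#'
#' @param grid data.frame with columns `alpha`, `lambda`, `coop_rate`
#'   (long-format phase grid, e.g. from [run_phase_grid()]).
#' @param threshold cooperation rate counting as "cooperation maintained".
#' @return list with `lambda_c` (NA if no cell reaches the threshold),
#'   `alpha_min` (that criterion's smallest cooperating alpha) and
#'   `per_lambda` (data.frame `lambda`, `alpha_min`).
#' @export
find_lambda_c <- function(grid, threshold = 0.5) {
  stopifnot(all(c("alpha", "lambda", "coop_rate") %in% names(grid)))
  lambdas <- sort(unique(grid$lambda))
  amin <- vapply(lambdas, function(l) {
    ok <- grid$lambda == l & grid$coop_rate >= threshold
    if (!any(ok)) NA_real_ else min(grid$alpha[ok])
  }, numeric(1))
  per_lambda <- data.frame(lambda = lambdas, alpha_min = amin)
  if (all(is.na(amin)))
    return(list(lambda_c = NA_real_, alpha_min = NA_real_,
                per_lambda = per_lambda))
  best <- min(amin, na.rm = TRUE)
  lambda_c <- min(lambdas[!is.na(amin) & amin == best])  # ties -> smaller
  list(lambda_c = lambda_c, alpha_min = best, per_lambda = per_lambda)
}

#' Direct agent-based simulation of the imitation--mutation chain
#'
#' The slow-timescale strategy dynamics simulated explicitly: each step one
#' random player either mutates (probability `mu`, new state uniform over the
#' other states) or picks a random other player and imitates it with the
#' Fermi probability.  Payoffs are supplied by `payoff_fn(counts)`, a
#' function of the current composition returning one expected payoff per
#' state; by default they are estimated by running the reputation dynamics
#' at the current composition.
#'
#' Used for high-mutation scenarios and as a stochastic oracle for
#' [fixation_probability()].
#'
#' @param states list of `player_state`s.
#' @param init_counts starting composition (sums to `N`).
#' @param n_steps number of imitation/mutation events.
#' @param s selection strength.
#' @param mu mutation rate in `[0, 1]`.
#' @param payoff_fn function(counts) -> payoff per state; `NULL` estimates
#'   payoffs by simulation with `params`.
#' @param params `sim_params`, required when `payoff_fn` is `NULL`.
#' @param record_every store the composition every this many events.
#' @param stop_when_absorbed stop at homogeneity (fixation experiments).
#' @return list with `counts` (final composition), `absorbed_state` (index or
#'   NA) and `trajectory` (matrix of recorded compositions).
#' @export
agent_based_evolution <- function(states, init_counts, n_steps, s, mu,
                                  payoff_fn = NULL, params = NULL,
                                  record_every = 1L,
                                  stop_when_absorbed = FALSE) {
  n_states <- length(states)
  stopifnot(length(init_counts) == n_states, mu >= 0, mu <= 1, s >= 0)
  counts <- as.integer(init_counts)
  N <- sum(counts)
  if (is.null(payoff_fn)) {
    if (is.null(params)) stop("supply params when payoff_fn is NULL")
    payoff_fn <- function(cnt) .simulated_state_payoffs(states, cnt, params)
  }
  traj <- list(counts)
  for (step in seq_len(n_steps)) {
    i_state <- sample.int(n_states, 1, prob = counts)   # random focal player
    if (mu > 0 && stats::runif(1) < mu) {
      other <- setdiff(seq_len(n_states), i_state)
      new_state <- other[sample.int(length(other), 1)]
      counts[i_state] <- counts[i_state] - 1L
      counts[new_state] <- counts[new_state] + 1L
    } else {
      others <- counts; others[i_state] <- others[i_state] - 1L
      if (sum(others) > 0) {
        j_state <- sample.int(n_states, 1, prob = others)
        if (j_state != i_state) {
          pay <- payoff_fn(counts)
          if (stats::runif(1) < fermi_prob(pay[i_state], pay[j_state], s)) {
            counts[i_state] <- counts[i_state] - 1L
            counts[j_state] <- counts[j_state] + 1L
          }
        }
      }
    }
    if (step %% record_every == 0L) traj[[length(traj) + 1L]] <- counts
    if (stop_when_absorbed && any(counts == N)) break
  }
  absorbed <- if (any(counts == N)) which(counts == N) else NA_integer_
  list(counts = counts, absorbed_state = absorbed,
       trajectory = do.call(rbind, traj))
}

.simulated_state_payoffs <- function(states, counts, params) {
  pl <- make_players(
    unlist(lapply(seq_along(states),
                  function(i) rep(states[[i]]$strategy, counts[i]))),
    unlist(lapply(seq_along(states),
                  function(i) rep(states[[i]]$lambda, counts[i]))))
  st <- simulate_reputation_dynamics(pl, params)
  labels <- vapply(states, .state_label, character(1))
  st$classes$mean_payoff[match(labels, st$classes$label)]
}
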