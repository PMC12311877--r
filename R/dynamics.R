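#' Collective reputation of a group
#'
#' An observer deems a group good when the fraction of members it privately
#' considers good is at least the assessment criterion `lam`:
#' returns 1 iff \eqn{\sum_{j \in G'} M_{ij} \ge \lambda |G'|}
#' (inclusive comparison, no rounding).
#'
#' @param opinion_row binary vector: the observer's opinions of the whole
#'   population (its row of the image matrix).
#' @param group indices of the group members (nonempty).
#' @param lam assessment criterion in (0, 1].
#' @return binary reputation (integer 0/1).
#' @examples
#' collective_reputation(c(1, 1, 1, 0), 1:4, 0.7)   # 3 of 4 good -> good
#' collective_reputation(c(1, 1, 0, 0), 1:4, 0.5)   # boundary inclusive -> good
#' @export
collective_reputation <- function(opinion_row, group, lam) {
  if (length(group) == 0L) stop("empty group: collective reputation undefined")
  if (!is.numeric(lam) || length(lam) != 1L || lam <= 0 || lam > 1)
    stop("lam must be a single value in (0, 1]")
  vals <- opinion_row[group]
  if (anyNA(vals) || !all(vals %in% c(0, 1)))
    stop("opinion_row entries must be binary 0/1")
  as.integer(sum(vals) >= lam * length(group))
}

#' Public goods game payoffs
#'
#' With `n_C` contributors out of `k` players, each contribution `c` is
#' multiplied by the synergy factor `R` and shared equally:
#' \eqn{\pi_C = R c n_C / k - c}, \eqn{\pi_D = R c n_C / k}.
#' The defector premium is always exactly `c`.
#'
#' @param k group size.
#' @param n_C number of cooperators, `0 <= n_C <= k`.
#' @param c contribution cost (> 0).
#' @param R synergy factor.
#' @return named numeric vector `c(pi_C = , pi_D = )`.
#' @export
pg_payoffs <- function(k, n_C, c = 1, R) {
  stopifnot(k >= 2, n_C >= 0, n_C <= k, c > 0)
  share <- R * c * n_C / k
  c(pi_C = share - c, pi_D = share)
}

#' Construct simulation parameters
#'
#' Configuration for the reputation-dynamics engine.  Either a fixed synergy
#' factor `R` or the payoff parameter `alpha` (with \eqn{R(k) = \alpha k})
#' must be given; defaults mirror the baseline group-interaction setting
#' (N = 60, k = 10, q = 0.9, eps = 0.05).
#'
#' @param N population size.
#' @param k group size, `2 <= k <= N`.
#' @param c contribution cost.
#' @param alpha payoff parameter; synergy is `R = alpha * k`.
#' @param R fixed synergy factor (alternative to `alpha`).
#' @param q probability that a non-participant observes a round.
#' @param eps probability an observer misperceives a single action.
#' @param eps_scope who is subject to perception error: `"all"` (default;
#'   every observer, including a donor interpreting its own action --
#'   uniform noisy assessment), `"no-self"` (everyone but the donor itself)
#'   or `"out-group"` (outside observers only; participants perceive
#'   accurately).  With `"all"`, a leading-eight donor can occasionally come
#'   to view itself as bad, which is what lets norms that reward
#'   cooperation between bad parties re-seed cooperation in strict
#'   societies; the stricter scopes freeze self-images at good.
#' @param steps number of game rounds.
#' @param burn_in fraction of `steps` discarded before averaging.
#' @param seed RNG seed (or `NULL` to use the current RNG state).
#' @return object of class `sim_params`.
#' @export
sim_params <- function(N = 60, k = 10, c = 1, alpha = NULL, R = NULL,
                       q = 0.9, eps = 0.05,
                       eps_scope = c("all", "no-self", "out-group"),
                       steps = 1000, burn_in = 0.1, seed = NULL) {
  eps_scope <- match.arg(eps_scope)
  if (is.null(R)) {
    if (is.null(alpha)) stop("supply either alpha or R")
    R <- alpha * k
  }
  stopifnot(N >= 2, k >= 2, k <= N, c > 0,
            q >= 0, q <= 1, eps >= 0, eps <= 0.5,
            steps >= 1, burn_in >= 0, burn_in < 1)
  structure(list(N = as.integer(N), k = as.integer(k), c = c,
                 alpha = alpha, R = R, q = q, eps = eps,
                 eps_scope = eps_scope,
                 steps = as.integer(steps), burn_in = burn_in, seed = seed),
            class = "sim_params")
}

#' Construct a population of players
#'
#' @param strategies character vector of strategy ids (one per player).
#' @param lambda assessment criterion in (0, 1]; scalar (shared) or one per
#'   player.
#' @return data.frame of class `players` with columns `strategy`, `lambda`.
#' @export
make_players <- function(strategies, lambda) {
  strategies <- vapply(strategies,
                       function(s) leading_eight_table(s)$id, character(1))
  lambda <- rep_len(lambda, length(strategies))
  if (any(lambda <= 0 | lambda > 1)) stop("lambda must lie in (0, 1]")
  structure(data.frame(strategy = unname(strategies), lambda = lambda,
                       stringsAsFactors = FALSE),
            class = c("players", "data.frame"))
}

# Compile players into the flat arrays the engines consume.  Classes are the
# unique (strategy, lambda) states in order of first appearance; `cls` is the
# 1-based class index per player; `fixed` is 0 (norm), 1 (ALLC), 2 (ALLD).
.compile_players <- function(players) {
  stopifnot(inherits(players, "players") || is.data.frame(players))
  N <- nrow(players)
  key <- paste0(players$strategy, "|", format(players$lambda, digits = 12))
  ukey <- unique(key)
  cls <- match(key, ukey)
  first <- match(ukey, key)
  classes <- data.frame(label = ukey,
                        strategy = players$strategy[first],
                        lambda = players$lambda[first],
                        size = as.integer(table(cls)[as.character(seq_along(ukey))]),
                        stringsAsFactors = FALSE)
  A <- matrix(0L, N, 8)
  B <- matrix(0L, N, 4)
  fixed <- integer(N)
  for (i in seq_len(N)) {
    ct <- .compile_table(leading_eight_table(players$strategy[i]))
    A[i, ] <- ct$assessment
    B[i, ] <- ct$action
    fixed[i] <- switch(players$strategy[i], ALLC = 1L, ALLD = 2L, 0L)
  }
  list(A = A, B = B, lambda = players$lambda, fixed = fixed,
       cls = cls, classes = classes, N = N)
}

# Initial image matrix: all-good by default, with ALLC/ALLD rows pinned to
# their constants whatever `init` says.
.init_matrix <- function(comp, init = NULL) {
  N <- comp$N
  M <- if (is.null(init)) matrix(1L, N, N) else {
    stopifnot(is.matrix(init), nrow(init) == N, ncol(init) == N,
              all(init %in% c(0L, 1L)))
    matrix(as.integer(init), N, N)
  }
  M[comp$fixed == 1L, ] <- 1L
  M[comp$fixed == 2L, ] <- 0L
  M
}

#' Simulate reputation dynamics
#'
#' Iterates rounds of the public goods game with private reputation updates:
#' each round samples `k` players, each member acts on its own image row
#' (self-reputation and the collective reputation of the other members at its
#' own criterion), and every observer synchronously re-assesses every donor
#' using the pre-round image matrix.  Group members always observe;
#' outsiders observe the whole round with probability `q`; every observed
#' action is misperceived independently with probability `eps` by the
#' observers `eps_scope` designates (see [sim_params()]).  Opinion rows of
#' ALLC (all-good) and ALLD (all-bad) players are pinned constants.
#'
#' Statistics are time-averaged over the rounds after burn-in:
#' per-class cooperation frequency, mean number of cooperators in the games a
#' class member played (hence mean per-game payoffs), and the proportion of
#' good opinions between every ordered pair of classes.
#'
#' @param players a `players` data.frame (see [make_players()]).
#' @param params a `sim_params` object.
#' @param engine `"cpp"` (fast path) or `"r"` (pure-R reference loop built on
#'   [play_round()] and [update_reputations()]; consumes the identical RNG
#'   stream, so trajectories agree bit for bit).
#' @param init optional initial image matrix (default all-good).
#' @param return_matrix keep the final image matrix in the result.
#' @return object of class `rep_stats`: list with `classes` (data.frame:
#'   label, strategy, lambda, size, coop_freq, mean_nc, mean_payoff),
#'   `good_rep` (class x class matrix of time-averaged good-opinion
#'   proportions, observer in rows), `acc_steps`, `params`, and optionally
#'   `matrix`.
#' @export
simulate_reputation_dynamics <- function(players, params,
                                         engine = c("cpp", "r"),
                                         init = NULL, return_matrix = FALSE) {
  engine <- match.arg(engine)
  stopifnot(inherits(params, "sim_params"))
  comp <- .compile_players(players)
  if (comp$N != params$N)
    stop("players (", comp$N, ") and params$N (", params$N, ") disagree")
  if (!is.null(params$seed)) set.seed(params$seed)
  M0 <- .init_matrix(comp, init)
  burn <- floor(params$steps * params$burn_in)
  raw <- if (engine == "cpp") {
    sim_engine_cpp(M0, comp$A, comp$B, comp$lambda, comp$fixed,
                   comp$cls - 1L, nrow(comp$classes), params$k,
                   params$steps, burn, params$q, params$eps,
                   .eps_scope_code(params$eps_scope))
  } else {
    .sim_engine_r(M0, comp, params, burn)
  }
  .make_rep_stats(raw, comp, params, return_matrix)
}

.make_rep_stats <- function(raw, comp, params, return_matrix) {
  cl <- comp$classes
  games <- raw$games
  coop <- ifelse(games > 0, raw$coop / games, NA_real_)
  mean_nc <- ifelse(games > 0, raw$ncsum / games, NA_real_)
  # per-game payoff: R*c*nC/k - c*a
  payoff <- params$R * params$c * mean_nc / params$k - params$c * coop
  n_cls <- nrow(cl)
  pairs <- outer(cl$size, cl$size) - diag(cl$size, n_cls)
  good_rep <- raw$good_sum / (raw$acc_steps * pairs)
  good_rep[pairs == 0] <- NA_real_
  dimnames(good_rep) <- list(observer = cl$label, target = cl$label)
  cl$games <- games
  cl$coop_freq <- coop
  cl$mean_nc <- mean_nc
  cl$mean_payoff <- payoff
  out <- list(classes = cl, good_rep = good_rep, acc_steps = raw$acc_steps,
              params = params)
  if (return_matrix) out$matrix <- raw$M
  structure(out, class = "rep_stats")
}

#' @export
print.rep_stats <- function(x, ...) {
  cat("<rep_stats>", x$acc_steps, "accumulated rounds\n")
  print(x$classes[, c("label", "size", "coop_freq", "mean_nc", "mean_payoff")],
        row.names = FALSE)
  cat("good-opinion proportions (observer rows):\n")
  print(round(x$good_rep, 3))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Round-level R reference implementation.  RNG draw-order contract (shared
# with the C++ engine, all draws from R's uniform stream):
#   1. group sampling: partial Fisher-Yates, draw j in 0..k-1 picks
#      r = j + floor(u * (N - j));
#   2. actions: deterministic, no draws;
#   3. observation: one u < q draw per out-of-group player whose row is not
#      pinned (ascending index); in-group players always observe;
#   4. updates: donors in sampled order; for each donor, observers in
#      ascending index; one u < eps misperception draw per (observer, donor)
#      pair subject to error per eps_scope ("all": every observer incl. the
#      donor itself; "no-self": everyone but the donor; "out-group":
#      outside observers only); pairs outside the scope consume no draw.
# ---------------------------------------------------------------------------

.eps_scope_code <- function(scope) {
  switch(scope, "out-group" = 0L, "no-self" = 1L, "all" = 2L,
         stop("unknown eps_scope '", scope, "'"))
}

.sample_group <- function(N, k) {
  pool <- 0:(N - 1)
  grp <- integer(k)
  for (j in seq_len(k)) {
    r <- (j - 1L) + as.integer(floor(stats::runif(1) * (N - j + 1L)))
    if (r > N - 1L) r <- N - 1L
    tmp <- pool[j]; pool[j] <- pool[r + 1L]; pool[r + 1L] <- tmp
    grp[j] <- pool[j]
  }
  grp + 1L
}

#' Play one public goods round
#'
#' Samples a group of `k` distinct players, lets each member choose its
#' action from its own image row (self-reputation and collective reputation
#' of the other members), and computes payoffs.  Consumes only the group
#' sampling draws from the RNG.
#'
#' @param matrix current image matrix (N x N binary, rows = observers).
#' @inheritParams simulate_reputation_dynamics
#' @return list of class `round_record` with `group` (ordered indices),
#'   `actions`, `n_C` and `payoffs` (per member).
#' @export
play_round <- function(matrix, players, params) {
  comp <- if (is.list(players) && !is.null(players$A)) players
          else .compile_players(players)
  N <- comp$N; k <- params$k
  if (k > N) stop("group size k exceeds population size N")
  grp <- .sample_group(N, k)
  acts <- integer(k)
  for (j in seq_len(k)) {
    i <- grp[j]
    acts[j] <- if (comp$fixed[i] == 1L) 1L else if (comp$fixed[i] == 2L) 0L
    else {
      ra <- matrix[i, i]
      rp <- collective_reputation(matrix[i, ], setdiff(grp, i), comp$lambda[i])
      comp$B[i, ra * 2L + rp + 1L]
    }
  }
  n_C <- sum(acts)
  pay <- pg_payoffs(k, n_C, params$c, params$R)
  structure(list(group = grp, actions = acts, n_C = n_C,
                 payoffs = ifelse(acts == 1L, pay[["pi_C"]], pay[["pi_D"]])),
            class = "round_record")
}

#' Synchronously update reputations after a round
#'
#' Applies the observation model and every observer's assessment rule to
#' every donor of the round.  All assessments read the pre-round matrix
#' (synchronous updating); opinion rows of ALLC/ALLD players are pinned.
#'
#' @param matrix the image matrix the round was played on.
#' @param record the `round_record` from [play_round()].
#' @inheritParams simulate_reputation_dynamics
#' @return the post-round image matrix.
#' @export
update_reputations <- function(matrix, record, players, params) {
  comp <- if (is.list(players) && !is.null(players$A)) players
          else .compile_players(players)
  N <- comp$N; k <- params$k
  grp <- record$group
  in_group <- logical(N); in_group[grp] <- TRUE
  rowsum_g <- rowSums(matrix[, grp, drop = FALSE])
  observer <- logical(N)
  for (h in seq_len(N)) {
    if (comp$fixed[h] != 0L) next
    observer[h] <- if (in_group[h]) TRUE else stats::runif(1) < params$q
  }
  newM <- matrix
  for (j in seq_len(k)) {
    i <- grp[j]
    a <- record$actions[j]
    for (h in seq_len(N)) {
      if (!observer[h]) next
      perceived <- a
      scope <- .eps_scope_code(params$eps_scope)
      can_err <- (scope == 2L) || (scope == 1L && h != i) ||
                 (scope == 0L && !in_group[h])
      if (can_err && stats::runif(1) < params$eps) perceived <- 1L - perceived
      old <- matrix[h, i]
      rp <- as.integer((rowsum_g[h] - old) >= comp$lambda[h] * (k - 1L))
      newM[h, i] <- comp$A[h, old * 4L + rp * 2L + perceived + 1L]
    }
  }
  newM
}

# Pure-R engine: the naive loop the C++ engine is validated against.
.sim_engine_r <- function(M0, comp, params, burn) {
  N <- comp$N
  n_cls <- nrow(comp$classes)
  M <- M0
  games <- numeric(n_cls); coop <- numeric(n_cls); ncsum <- numeric(n_cls)
  good_sum <- matrix(0, n_cls, n_cls)
  offdiag <- matrix(TRUE, N, N); diag(offdiag) <- FALSE
  cls_f <- factor(comp$cls, levels = seq_len(n_cls))
  for (t in seq_len(params$steps)) {
    rec <- play_round(M, comp, params)
    M <- update_reputations(M, rec, comp, params)
    if (t > burn) {
      for (j in seq_len(params$k)) {
        i <- rec$group[j]; ci <- comp$cls[i]
        games[ci] <- games[ci] + 1
        coop[ci] <- coop[ci] + rec$actions[j]
        ncsum[ci] <- ncsum[ci] + rec$n_C
      }
      cur <- tapply((M * offdiag), list(cls_f[row(M)], cls_f[col(M)]), sum)
      cur[is.na(cur)] <- 0
      good_sum <- good_sum + cur
    }
  }
  list(M = M, games = games, coop = coop, ncsum = ncsum,
       good_sum = good_sum, acc_steps = params$steps - burn)
}
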