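#' Scenario configuration
#'
#' Bundles every knob of an experiment family.  Defaults are the baseline
#' group-interaction parameter set (N = 60, k = 10, s = 1, eps = 0.05,
#' q = 0.9, rare mutations), with desk-scale step counts.
#'
#' @param family one of `"reputation"` (fixed-strategy reputation dynamics
#'   across criteria), `"phase_grid"` (selection--mutation equilibrium over
#'   an alpha x lambda grid), `"criterion_evolution"` (one norm, three
#'   criteria competing), `"coevolution"` (norm with three criteria plus
#'   ALLC and ALLD).
#' @param strategy the leading-eight strategy id.
#' @param lambdas criterion grid (family-specific default).
#' @param alpha_grid payoff-parameter grid.
#' @param N,k,c,q,eps,eps_scope,steps,burn_in reputation-dynamics
#'   parameters, see [sim_params()].
#' @param reps replicates per cell (reputation family).
#' @param s selection strength.
#' @param mu mutation rate (0 means the rare-mutation embedded chain).
#' @param seed master seed.
#' @param threshold cooperation rate counting as cooperation maintained.
#' @param cache_dir optional sweep cache directory.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(family = c("reputation", "phase_grid",
                                       "criterion_evolution", "coevolution"),
                            strategy = "L1",
                            lambdas = NULL,
                            alpha_grid = seq(0.3, 1.2, by = 0.1),
                            N = 60, k = 10, c = 1, q = 0.9, eps = 0.05,
                            eps_scope = "all",
                            steps = 5000, burn_in = 0.2, reps = 10,
                            s = 1, mu = 0, seed = 1, threshold = 0.5,
                            cache_dir = NULL) {
  family <- match.arg(family)
  if (is.null(lambdas)) {
    lambdas <- switch(family,
      reputation = seq(0.1, 0.9, by = 0.1),
      phase_grid = c(0.1, 0.3, 0.5, 0.7, 0.9),
      criterion_evolution = c(0.1, 0.4, 0.7),
      coevolution = c(0.1, 0.4, 0.7))
  }
  strategy <- leading_eight_table(strategy)$id
  cfg <- list(family = family, strategy = strategy, lambdas = lambdas,
              alpha_grid = alpha_grid, N = N, k = k, c = c, q = q, eps = eps,
              eps_scope = eps_scope,
              steps = steps, burn_in = burn_in, reps = reps, s = s, mu = mu,
              seed = seed, threshold = threshold, cache_dir = cache_dir)
  stopifnot(all(cfg$lambdas > 0 & cfg$lambdas <= 1), s >= 0,
            mu >= 0, mu <= 1, reps >= 1)
  structure(cfg, class = "scenario_config")
}

#' Serialize / parse a scenario configuration
#'
#' `config_to_json()` and `config_from_json()` round-trip a
#' `scenario_config` through plain JSON (`parse(serialize(x)) == x`).
#'
#' @param config a `scenario_config`.
#' @param json JSON string or file path.
#' @return JSON string / `scenario_config`.
#' @export
config_to_json <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                   null = "null", pretty = TRUE)
}

#' @rdname config_to_json
#' @export
config_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  do.call(scenario_config, obj[!vapply(obj, is.null, logical(1))])
}

.sim_params_from_config <- function(cfg, alpha = 1, steps = cfg$steps,
                                    seed = cfg$seed) {
  sim_params(N = cfg$N, k = cfg$k, c = cfg$c, alpha = alpha, q = cfg$q,
             eps = cfg$eps, eps_scope = cfg$eps_scope,
             steps = steps, burn_in = cfg$burn_in, seed = seed)
}

# nearest equal-thirds split of N among (Li, ALLC, ALLD)
.thirds_split <- function(N) {
  base <- N %/% 3L
  rem <- N - 3L * base
  sizes <- c(base, base, base) + c(rem >= 1L, rem >= 2L, 0L)
  if (rem != 0L)
    warning("N = ", N, " not divisible by 3; using split ",
            paste(sizes, collapse = "/"))
  sizes
}

#' Reputation dynamics across assessment criteria
#'
#' The fixed-strategy experiment family: populations split (as equally as
#' possible) among one leading-eight norm, ALLC and ALLD, simulated across a
#' grid of assessment criteria with seeded replicates.  Emits long-format
#' rows for per-strategy cooperation frequencies and for every
#' (observer strategy, target strategy) good-opinion proportion.
#'
#' @param config a `scenario_config` (family `"reputation"`).
#' @return data.frame with columns `scenario`, `pair`, `lambda`, `alpha`,
#'   `statistic`, `value`, `seed`, `steps`.
#' @export
run_reputation_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  sizes <- .thirds_split(config$N)
  strategies <- c(rep(config$strategy, sizes[1]), rep("ALLC", sizes[2]),
                  rep("ALLD", sizes[3]))
  rows <- list()
  for (il in seq_along(config$lambdas)) {
    lam <- config$lambdas[il]
    players <- make_players(strategies, lam)
    for (r in seq_len(config$reps)) {
      seed_r <- config$seed + 1000L * (il - 1L) + r
      p <- .sim_params_from_config(config, alpha = 1, seed = seed_r)
      st <- simulate_reputation_dynamics(players, p)
      cl <- st$classes
      strat_of <- cl$strategy
      coop <- data.frame(pair = strat_of, statistic = "coop_freq",
                         value = cl$coop_freq)
      gr <- expand.grid(obs = seq_len(nrow(cl)), tgt = seq_len(nrow(cl)))
      good <- data.frame(
        pair = paste0(strat_of[gr$obs], "->", strat_of[gr$tgt]),
        statistic = "good_rep",
        value = st$good_rep[cbind(gr$obs, gr$tgt)])
      both <- rbind(coop, good)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = paste0("reputation_", config$strategy),
        pair = both$pair, lambda = lam, alpha = NA_real_,
        statistic = both$statistic, value = both$value,
        seed = seed_r, steps = config$steps)
    }
  }
  do.call(rbind, rows)
}

# the three pairwise sweeps + homogeneous norm cooperation for one
# {Li, ALLC, ALLD} cell at a given lambda; cb_ad may be reused across lambda
.norm_triplet_sweeps <- function(cfg, lam, cb_ad = NULL) {
  li <- player_state(cfg$strategy, lam)
  allc <- player_state("ALLC", lam)
  alld <- player_state("ALLD", lam)
  p <- .sim_params_from_config(cfg)
  cb_la <- composition_behaviour(li, allc, p, cache_dir = cfg$cache_dir)
  p2 <- p; p2$seed <- cfg$seed + 70000L
  cb_ld <- composition_behaviour(li, alld, p2, cache_dir = cfg$cache_dir)
  if (is.null(cb_ad)) {
    p3 <- p; p3$seed <- cfg$seed + 140000L
    cb_ad <- composition_behaviour(allc, alld, p3, cache_dir = cfg$cache_dir)
  }
  ph <- p; ph$seed <- cfg$seed + 210000L
  hom <- simulate_reputation_dynamics(
    make_players(rep(cfg$strategy, cfg$N), lam), ph)
  list(cb_la = cb_la, cb_ld = cb_ld, cb_ad = cb_ad,
       coop_norm = hom$classes$coop_freq[1])
}

# assemble the 3x3 fixation table (rows resident, cols mutant) for states
# (norm, ALLC, ALLD) at one alpha from the three sweeps
.norm_triplet_fixation <- function(sweeps, cfg, alpha) {
  p <- .sim_params_from_config(cfg, alpha = alpha)
  fx <- matrix(NA_real_, 3, 3,
               dimnames = list(resident = c(cfg$strategy, "ALLC", "ALLD"),
                               mutant = c(cfg$strategy, "ALLC", "ALLD")))
  pr_la <- .fixation_pair(composition_payoffs(sweeps$cb_la, params = p),
                          cfg$s, cfg$N)
  pr_ld <- .fixation_pair(composition_payoffs(sweeps$cb_ld, params = p),
                          cfg$s, cfg$N)
  pr_ad <- .fixation_pair(composition_payoffs(sweeps$cb_ad, params = p),
                          cfg$s, cfg$N)
  fx[2, 1] <- pr_la[["mut_into_res"]]; fx[1, 2] <- pr_la[["res_into_mut"]]
  fx[3, 1] <- pr_ld[["mut_into_res"]]; fx[1, 3] <- pr_ld[["res_into_mut"]]
  fx[3, 2] <- pr_ad[["mut_into_res"]]; fx[2, 3] <- pr_ad[["res_into_mut"]]
  diag(fx) <- 0
  fx
}

#' Selection--mutation equilibrium over a payoff x criterion grid
#'
#' For every (alpha, lambda) grid cell: composition-payoff sweeps for the
#' three strategy pairs among \{norm, ALLC, ALLD\}, closed-form fixation
#' probabilities, the rare-mutation embedded chain, its stationary
#' distribution and the abundance-weighted equilibrium cooperation rate.
#' Behaviour sweeps are reused across the whole alpha grid (they do not
#' depend on the payoff parameter), and the ALLC/ALLD sweep across lambda.
#'
#' @param config a `scenario_config` (family `"phase_grid"`).
#' @return data.frame with one row per grid cell: `strategy`, `alpha`,
#'   `lambda`, `coop_rate`, `ab_norm`, `ab_allc`, `ab_alld`, `seed`, `steps`.
#' @export
run_phase_grid <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  cb_ad <- NULL
  rows <- list()
  for (lam in config$lambdas) {
    sw <- .norm_triplet_sweeps(config, lam, cb_ad)
    cb_ad <- sw$cb_ad
    for (alpha in config$alpha_grid) {
      fx <- .norm_triplet_fixation(sw, config, alpha)
      ab <- stationary_distribution(embedded_chain(fx))
      coop <- equilibrium_cooperation_rate(ab, c(sw$coop_norm, 1, 0))
      rows[[length(rows) + 1L]] <- data.frame(
        strategy = config$strategy, alpha = alpha, lambda = lam,
        coop_rate = coop, ab_norm = ab[[1]], ab_allc = ab[[2]],
        ab_alld = ab[[3]], seed = config$seed, steps = config$steps)
    }
  }
  do.call(rbind, rows)
}

#' Evolution of the assessment criterion
#'
#' One leading-eight norm, three criterion states (default 0.1/0.4/0.7)
#' competing under rare mutations: for every alpha, the 3 x 3 fixation
#' table, the stationary abundances and the equilibrium cooperation rate.
#'
#' @param config a `scenario_config` (family `"criterion_evolution"`).
#' @return list with `abundance` (data.frame: alpha, one column per
#'   criterion, `coop_rate`, `neutral` = 1/N) and `fixation` (data.frame:
#'   alpha, mutant lambda, resident lambda, rho, neutral).
#' @export
run_criterion_evolution <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  lams <- config$lambdas
  stopifnot(length(lams) >= 2)
  states <- lapply(lams, function(l) player_state(config$strategy, l))
  out <- .states_equilibrium(states, paste0("lambda_", lams), config)
  names(out$fixation)[names(out$fixation) == "mutant"] <- "mutant_lambda"
  names(out$fixation)[names(out$fixation) == "resident"] <- "resident_lambda"
  out$fixation$mutant_lambda <-
    lams[match(out$fixation$mutant_lambda, paste0("lambda_", lams))]
  out$fixation$resident_lambda <-
    lams[match(out$fixation$resident_lambda, paste0("lambda_", lams))]
  out
}

#' Co-evolution of strategy and assessment criterion
#'
#' Five states compete under rare mutations: the configured leading-eight
#' norm with each of the configured criteria (default 0.1/0.4/0.7), plus
#' ALLC and ALLD.  Returns stationary abundances, the full fixation table
#' and the equilibrium cooperation rate per payoff parameter.
#'
#' @param config a `scenario_config` (family `"coevolution"`).
#' @return list with `abundance` and `fixation` data.frames as in
#'   [run_criterion_evolution()], with columns named by state label.
#' @export
run_coevolution <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  lams <- config$lambdas
  states <- c(lapply(lams, function(l) player_state(config$strategy, l)),
              list(player_state("ALLC", lams[1]),
                   player_state("ALLD", lams[1])))
  labels <- c(paste0(config$strategy, "_", lams), "ALLC", "ALLD")
  .states_equilibrium(states, labels, config)
}

# rare-mutation equilibrium over an arbitrary list of (strategy, lambda)
# states: pairwise behaviour sweeps -> fixation table -> embedded chain ->
# stationary abundance and cooperation rate, per alpha on the grid
.states_equilibrium <- function(states, labels, config) {
  n <- length(states)
  p <- .sim_params_from_config(config)
  pairs <- utils::combn(n, 2)
  sweeps <- lapply(seq_len(ncol(pairs)), function(ip) {
    pi_ <- p; pi_$seed <- config$seed + 30000L * ip
    composition_behaviour(states[[pairs[1, ip]]], states[[pairs[2, ip]]], pi_,
                          cache_dir = config$cache_dir)
  })
  hom_coop <- vapply(seq_len(n), function(i) {
    st <- states[[i]]
    if (st$strategy == "ALLC") return(1)
    if (st$strategy == "ALLD") return(0)
    ph <- p; ph$seed <- config$seed + 90000L + i
    out <- simulate_reputation_dynamics(
      make_players(rep(st$strategy, config$N), st$lambda), ph)
    out$classes$coop_freq[1]
  }, numeric(1))
  ab_rows <- list(); fx_rows <- list()
  for (alpha in config$alpha_grid) {
    pa <- .sim_params_from_config(config, alpha = alpha)
    fx <- matrix(0, n, n, dimnames = list(resident = labels, mutant = labels))
    for (ip in seq_len(ncol(pairs))) {
      a <- pairs[1, ip]; b <- pairs[2, ip]
      pr <- .fixation_pair(composition_payoffs(sweeps[[ip]], params = pa),
                           config$s, config$N)
      fx[b, a] <- pr[["mut_into_res"]]
      fx[a, b] <- pr[["res_into_mut"]]
    }
    ab <- stationary_distribution(embedded_chain(fx))
    ab_row <- data.frame(alpha = alpha, t(ab),
                         coop_rate = equilibrium_cooperation_rate(ab, hom_coop),
                         neutral = 1 / config$N)
    names(ab_row)[2:(n + 1)] <- labels
    ab_rows[[length(ab_rows) + 1L]] <- ab_row
    idx <- which(row(fx) != col(fx), arr.ind = TRUE)
    fx_rows[[length(fx_rows) + 1L]] <- data.frame(
      alpha = alpha, mutant = labels[idx[, "col"]],
      resident = labels[idx[, "row"]], rho = fx[idx],
      neutral = 1 / config$N)
  }
  list(abundance = do.call(rbind, ab_rows),
       fixation = do.call(rbind, fx_rows))
}

#' Write results with a reproducibility manifest
#'
#' Writes a results data.frame as CSV together with a JSON manifest (config
#' echo, seed, package version, per-file MD5 checksums) sufficient to
#' reproduce the CSV bit for bit.
#'
#' @param results data.frame (or named list of data.frames).
#' @param config the `scenario_config` that produced them.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
write_results <- function(results, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.data.frame(results)) results <- list(results = results)
  files <- character(0)
  for (nm in names(results)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(results[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  manifest <- list(
    config = unclass(config),
    package_version = as.character(utils::packageVersion("collrep")),
    files = basename(files),
    md5 = unname(tools::md5sum(files)))
  writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                           digits = NA, null = "null",
                                           pretty = TRUE)),
             file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

#' Build a small deterministic test instance
#'
#' @param kind `"tiny-population"` (an N = 6, k = 3 mixed population with a
#'   short simulated trajectory), `"worked-example"` (a five-player
#'   group where the donor and an outside observer disagree about the
#'   recipients: the donor counts 3 of 4 members good, the observer only 2,
#'   so at criterion 0.7 they reach opposite collective reputations), or
#'   `"oracle-pair"` (the C++ engine and the naive R loop run on the same
#'   seed for cross-validation).
#' @param seed RNG seed.
#' @return a list; contents depend on `kind`.
#' @export
make_fixture <- function(kind = c("tiny-population", "worked-example",
                                  "oracle-pair"), seed = 1) {
  kind <- match.arg(kind)
  if (kind == "worked-example") {
    group <- 1:5; donor <- 1L; recipients <- 2:5; lam <- 0.7
    donor_row <- c(1L, 1L, 1L, 1L, 0L)     # donor: 3 of 4 recipients good
    observer_row <- c(1L, 0L, 1L, 1L, 0L)  # observer disagrees on two members
    return(list(group = group, donor = donor, recipients = recipients,
                lam = lam, donor_row = donor_row, observer_row = observer_row,
                donor_view = collective_reputation(donor_row, recipients, lam),
                observer_view = collective_reputation(observer_row, recipients,
                                                      lam)))
  }
  players <- make_players(c("L3", "L6", "ALLC", "ALLC", "ALLD", "ALLD"),
                          lambda = 0.5)
  params <- sim_params(N = 6, k = 3, alpha = 1.2, q = 0.9, eps = 0.1,
                       steps = if (kind == "oracle-pair") 50 else 100,
                       burn_in = 0.1, seed = seed)
  if (kind == "tiny-population") {
    st <- simulate_reputation_dynamics(players, params, return_matrix = TRUE)
    return(list(players = players, params = params, stats = st,
                final_matrix = st$matrix))
  }
  cpp <- simulate_reputation_dynamics(players, params, engine = "cpp",
                                      return_matrix = TRUE)
  ref <- simulate_reputation_dynamics(players, params, engine = "r",
                                      return_matrix = TRUE)
  list(players = players, params = params, engine = cpp, oracle = ref,
       agree = identical(cpp$matrix, ref$matrix))
}
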