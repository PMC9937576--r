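#' Initialize an agent population
#'
#' Builds a roster of `N = k * n` agents in `k` equally sized groups, with
#' each agent's strategy drawn independently and uniformly from the
#' strategy space.
#'
#' @param params A [model_params()] object.
#' @param strategies Strategy-set `data.frame` ([core_strategies()] or
#'   [extended_strategies()]).
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `"coop_population"`: list with `group`
#'   (integer vector), `strategy` (integer indices into `strategies`),
#'   `strategies`, and `helped_prev` (logical, `NA` before the first round).
#' @export
init_population <- function(params, strategies = core_strategies(), seed = NULL) {
  pars <- as_coop_params(params, check = FALSE)
  if (pars$N %% pars$k != 0) stop("N must be divisible by k")
  if (!is.null(seed)) set.seed(seed)
  pop <- list(group = rep(seq_len(pars$k), each = pars$n),
              strategy = sample.int(nrow(strategies), pars$N, replace = TRUE),
              strategies = strategies,
              helped_prev = rep(NA, pars$N))
  class(pop) <- "coop_population"
  pop
}

#' @export
print.coop_population <- function(x, ...) {
  tab <- table(factor(x$strategies$name[x$strategy], levels = x$strategies$name))
  cat(sprintf("Agent population: N = %d in %d groups\n",
              length(x$group), max(x$group)))
  print(tab)
  invisible(x)
}

# counts view of a population: k x S matrix
population_counts <- function(pop) {
  S <- nrow(pop$strategies)
  k <- max(pop$group)
  m <- matrix(0L, k, S, dimnames = list(NULL, pop$strategies$name))
  for (i in seq_along(pop$group)) {
    m[pop$group[i], pop$strategy[i]] <- m[pop$group[i], pop$strategy[i]] + 1L
  }
  m
}

#' Random donor-to-receiver assignment for the helping stage
#'
#' Every agent acts once as a donor; its receiver is an in-group member
#' with probability `p` (uniform among the other group members) and an
#' out-group member with probability `1 - p` (uniform among all members of
#' other groups). Receivers may be drawn by several donors; a donor never
#' draws itself.
#'
#' @param pop A `"coop_population"`.
#' @param p In-group meeting probability.
#' @return Integer vector `receiver` of length `N`.
#' @export
pair_agents <- function(pop, p) {
  group <- pop$group
  N <- length(group)
  sizes <- tabulate(group)
  if (p > 0 && any(sizes < 2)) stop("p > 0 requires every group to have >= 2 members")
  if (p < 1 && length(sizes) < 2) stop("p < 1 requires an out-group to exist (k >= 2)")
  receiver <- integer(N)
  for (a in seq_len(N)) {
    if (stats::runif(1) < p) {
      cand <- setdiff(which(group == group[a]), a)
    } else {
      cand <- which(group != group[a])
    }
    receiver[a] <- cand[sample.int(length(cand), 1)]
  }
  receiver
}

#' One full iteration of the agent-based model
#'
#' Reference (plain R) implementation of a single iteration: stage-1
#' earnings via [stage1_earnings()], stage-2 realized pairing and helping
#' via [pair_agents()] and [helping_decision()], both endowments credited,
#' then one Moran event — the dying agent is uniform over agents (identical
#' to group-then-type sampling for equal group sizes), replaced by a
#' uniform-random strategy with probability `mu` or by global
#' fitness-proportional imitation on `exp(realized payoff)` otherwise.
#'
#' @param pop A `"coop_population"`.
#' @param params A [model_params()] object.
#' @param benefit_of_doubt Round-1 treatment of unknown helping history,
#'   see [helping_decision()].
#' @return List: `population` (updated, with `helped_prev` set to each
#'   agent's new standing), `payoffs` (realized per-agent), `helped`
#'   (logical per-agent), `standing` (logical per-agent), `dying`,
#'   `new_strategy`.
#' @export
abm_iterate <- function(pop, params, benefit_of_doubt = TRUE) {
  pars <- as_coop_params(params, check = FALSE)
  strategies <- pop$strategies
  N <- length(pop$group)
  actions <- strategies$contribution[pop$strategy]
  pay <- stage1_earnings(pars, actions, pop$group) + pars$e
  receiver <- pair_agents(pop, pars$p)
  helped <- logical(N)
  standing <- logical(N)
  for (a in seq_len(N)) {
    r <- receiver[a]
    info <- list(contribution = actions[r],
                 same_group = pop$group[r] == pop$group[a],
                 helped_last = pop$helped_prev[r])
    if (helping_decision(strategies[pop$strategy[a], ], info, benefit_of_doubt)) {
      helped[a] <- TRUE
      pay[a] <- pay[a] - pars$c_h
      pay[r] <- pay[r] + pars$b_h
    }
    # withholding keeps good standing only when justified: the receiver
    # contributed nothing in stage 1 or was itself in bad standing
    standing[a] <- helped[a] || actions[r] == "none" ||
      isFALSE(as.logical(pop$helped_prev[r]))
  }
  dying <- sample.int(N, 1)
  if (stats::runif(1) < pars$mu) {
    new_strategy <- sample.int(nrow(strategies), 1)
  } else {
    w <- fitness_weights(pay)
    new_strategy <- pop$strategy[sample.int(N, 1, prob = w)]
  }
  pop$strategy[dying] <- new_strategy
  pop$helped_prev <- standing
  list(population = pop, payoffs = pay, helped = helped, standing = standing,
       dying = dying, new_strategy = new_strategy)
}

#' Run one agent-based simulation
#'
#' Runs the compiled simulator until the population is homogeneous or a
#' maximum number of iterations is reached. When the cap is hit, the final
#' composition reported is the mean of the type shares over the last
#' `average_last` iterations; when the run converges it is the homogeneous
#' composition.
#'
#' @param params A [model_params()] object.
#' @param strategies Strategy-set `data.frame`.
#' @param seed Optional integer seed.
#' @param max_iter Iteration cap (default 2000).
#' @param average_last Number of trailing iterations averaged when capped
#'   (default 1000).
#' @param stop_at_homogeneous Stop when all agents share one strategy.
#' @param benefit_of_doubt Round-1 treatment of unknown helping history.
#' @param fitness_payoffs Use `"realized"` per-iteration payoffs (default)
#'   or closed-form `"expected"` payoffs (core three-strategy space only)
#'   as imitation weights.
#' @param neutral If `TRUE`, imitation is payoff-blind (uniform over
#'   agents): pure drift, for calibration tests.
#' @param record_every Thinning of the stored trajectory.
#' @param population Optional pre-built starting `"coop_population"`
#'   (overrides random initialization).
#' @return List of class `"coop_run"`: `converged`, `iterations`,
#'   `final_composition` (named shares summing to 1), `trajectory`
#'   (`data.frame` of per-strategy counts by iteration), `seed`.
#' @examples
#' \donttest{
#' run_simulation(model_params(b_h = 7, p = 0.5), seed = 1)$final_composition
#' }
#' @export
run_simulation <- function(params, strategies = core_strategies(), seed = NULL,
                           max_iter = 2000, average_last = 1000,
                           stop_at_homogeneous = TRUE,
                           benefit_of_doubt = TRUE,
                           fitness_payoffs = c("realized", "expected"),
                           neutral = FALSE, record_every = 1,
                           population = NULL) {
  pars <- as_coop_params(params, check = FALSE)
  fitness_payoffs <- match.arg(fitness_payoffs)
  if (fitness_payoffs == "expected" && nrow(strategies) != 3) {
    stop("expected-payoff fitness is defined for the core three-strategy space")
  }
  force(population)  # evaluate user-supplied rosters before seeding
  if (!is.null(seed)) set.seed(seed)
  if (is.null(population)) {
    population <- init_population(pars, strategies)
  }
  if (pars$p > 0 && pars$n < 2) stop("p > 0 requires group size >= 2")
  if (pars$p < 1 && pars$k < 2) stop("p < 1 requires k >= 2")
  res <- abm_run_cpp(population$group - 1L, population$strategy - 1L,
                     strategy_codes(strategies),
                     pars$e, pars$c_c, pars$c_h, pars$b_CG, pars$b_PG,
                     pars$b_h, pars$p, pars$mu,
                     as.integer(max_iter), stop_at_homogeneous,
                     benefit_of_doubt, neutral,
                     if (fitness_payoffs == "expected") 1L else 0L,
                     as.integer(record_every))
  N <- pars$N
  trace <- res$trace
  colnames(trace) <- strategies$name
  if (res$converged) {
    comp <- trace[nrow(trace), ] / N
  } else {
    keep <- res$trace_iter > res$iterations - average_last
    comp <- colMeans(trace[keep, , drop = FALSE]) / N
  }
  structure(list(converged = res$converged,
                 iterations = res$iterations,
                 final_composition = comp,
                 trajectory = data.frame(iteration = res$trace_iter, trace,
                                         check.names = FALSE),
                 final_strategies = res$final_strat + 1L,
                 final_payoffs = res$final_payoffs,
                 seed = seed),
            class = "coop_run")
}

#' @export
print.coop_run <- function(x, ...) {
  cat(sprintf("ABM run: %s after %d iterations\n",
              if (x$converged) "converged (homogeneous)" else "capped",
              x$iterations))
  print(round(x$final_composition, 4))
  invisible(x)
}

#' Long-run time-averaged composition of the agent-based model
#'
#' Runs independent replicate simulations without the homogeneity stopping
#' rule, discards a burn-in fraction of each, and reports time-averaged
#' type shares with Monte-Carlo standard errors computed across replicates.
#' Used to cross-validate the ABM against the exact stationary
#' distribution.
#'
#' @param params A [model_params()] object.
#' @param strategies Strategy set (core by default).
#' @param iterations Iterations per replicate.
#' @param replicates Number of independent replicates.
#' @param burn_frac Fraction of each replicate discarded as burn-in.
#' @param seed Base seed; replicate `r` uses `seed + r`.
#' @param record_every Trajectory thinning within each replicate.
#' @param fitness_payoffs Imitation-weight payoffs, see [run_simulation()];
#'   `"expected"` mirrors the exact engine's update and is the right mode
#'   for stationary cross-validation.
#' @return `data.frame` with one row per strategy: `share` (mean across
#'   replicates) and `se` (Monte-Carlo standard error of that mean).
#' @export
abm_time_average <- function(params, strategies = core_strategies(),
                             iterations = 2e6, replicates = 6,
                             burn_frac = 0.5, seed = 1, record_every = 10,
                             fitness_payoffs = c("expected", "realized")) {
  pars <- as_coop_params(params, check = FALSE)
  fitness_payoffs <- match.arg(fitness_payoffs)
  reps <- matrix(NA_real_, replicates, nrow(strategies))
  for (r in seq_len(replicates)) {
    run <- run_simulation(pars, strategies, seed = seed + r,
                          max_iter = iterations,
                          stop_at_homogeneous = FALSE,
                          fitness_payoffs = fitness_payoffs,
                          record_every = record_every)
    tr <- run$trajectory
    keep <- tr$iteration > burn_frac * iterations
    reps[r, ] <- colMeans(as.matrix(tr[keep, -1, drop = FALSE])) / pars$N
  }
  data.frame(strategy = strategies$name,
             share = colMeans(reps),
             se = apply(reps, 2, stats::sd) / sqrt(replicates))
}
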