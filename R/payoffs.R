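#' @useDynLib coopevo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Core strategy type labels
#'
#' The exact engine works on three types: universal cooperators (`"U"`,
#' contribute to the public good and help other universalists), parochial
#' cooperators (`"P"`, contribute to their group's club good and help
#' in-group parochialists), and free-riders (`"F"`, neither contribute nor
#' help).
#'
#' @format Character vector of length 3: `c("U", "P", "F")`.
#' @export
core_types <- c("U", "P", "F")

# Coerce a population state to a validated k x T count matrix (rows = groups,
# columns = types U, P, F for the core model).
as_state_matrix <- function(state, n_types = 3) {
  m <- as.matrix(state)
  if (ncol(m) != n_types) stop("state must have ", n_types, " type columns")
  if (any(m < 0) || any(m != round(m))) stop("state counts must be nonnegative integers")
  storage.mode(m) <- "integer"
  if (is.null(colnames(m)) && n_types == 3) colnames(m) <- core_types
  m
}

#' Stage-1 earnings from the nested contribution game
#'
#' Each agent either keeps the endowment `e`, invests it in the group's club
#' pool, or invests it in the population-wide public pool. An investment
#' costs `c_c`; every unit in the public pool yields `b_PG` shared equally
#' over all `N` agents, and every unit in a group's club pool yields `b_CG`
#' shared equally over that group's `n_i` members.
#'
#' @param params A [model_params()] object.
#' @param actions Character vector of length `N`, one of `"public"`,
#'   `"club"`, `"none"` per agent.
#' @param groups Integer vector of length `N` with each agent's group id in
#'   `1..k`. Defaults to `k` consecutive blocks of size `n`.
#' @return Numeric vector of per-agent stage-1 earnings (monetary units).
#' @examples
#' pars <- model_params()
#' stage1_earnings(pars, rep("public", 8))  # everyone earns 8 * 3 / 8 = 3
#' @export
stage1_earnings <- function(params, actions,
                            groups = rep(seq_len(params$k), each = params$n)) {
  pars <- as_coop_params(params, check = FALSE)
  if (length(actions) != pars$N) {
    stop(sprintf("expected %d actions, got %d", pars$N, length(actions)))
  }
  if (length(groups) != pars$N) stop("groups must have one entry per agent")
  bad <- setdiff(unique(actions), c("public", "club", "none"))
  if (length(bad)) stop("unknown action label(s): ", paste(bad, collapse = ", "))

  group_sizes <- tabulate(groups, nbins = pars$k)
  n_public <- sum(actions == "public")
  club_by_group <- vapply(seq_len(pars$k),
                          function(g) sum(actions == "club" & groups == g),
                          integer(1))
  contributes <- actions != "none"
  pars$e - pars$c_c * contributes +
    n_public * pars$b_PG / pars$N +
    club_by_group[groups] * pars$b_CG / group_sizes[groups]
}

# p * x with the convention 0 when the meeting fraction is undefined
# (no partner of that kind exists, i.e. denominator 0).
safe_frac <- function(num, den) ifelse(den > 0, num / den, 0)

#' Expected per-generation payoff of a strategy type
#'
#' Closed-form expected payoff of an agent of the given type residing in
#' group `group`, for the two-group core model. All agents collect both
#' endowments (`2e`) plus the public-good return `n_U * b_PG / N` and their
#' group's club-good return `n_P^i * b_CG / n_i`. Cooperators additionally
#' pay `c_c`. The reciprocal helping stage adds, per expected meeting with a
#' partner the focal type exchanges help with, the net benefit `b_h - c_h`:
#' universalists meet another universalist in-group with probability
#' `p * (n_U^i - 1) / (n_i - 1)` and out-group with probability
#' `(1 - p) * (n_U - n_U^i) / (N - n_i)`; parochialists only count in-group
#' parochialist meetings `p * (n_P^i - 1) / (n_i - 1)`; free-riders gain
#' nothing in stage 2. A meeting fraction whose denominator is zero (no
#' partner of that kind exists) contributes 0.
#'
#' @param params A [model_params()] object.
#' @param state Population state: a `k x 3` count matrix (columns U, P, F).
#' @param group Group index of the focal agent (1-based).
#' @param type Focal type, one of `"U"`, `"P"`, `"F"`.
#' @param as_resident If `TRUE`, evaluate the payoff of a hypothetical
#'   focal resident: the focal agent's own count is treated as at least 1 in
#'   the meeting terms (used for invasion analyses of absent types). The
#'   default `FALSE` uses the printed equations literally, with counts as-is.
#' @return Expected payoff (monetary units).
#' @examples
#' pars <- model_params(p = 1, b_h = 3, mu = 0, check = FALSE)
#' st <- rbind(c(0, 4, 0), c(0, 4, 0))  # both groups all-parochialist
#' expected_payoff(pars, st, group = 1, type = "P")
#' @export
expected_payoff <- function(params, state, group, type, as_resident = FALSE) {
  pars <- as_coop_params(params, check = FALSE)
  st <- as_state_matrix(state)
  if (group < 1 || group > nrow(st)) stop("group index out of range")
  type <- match.arg(type, core_types)
  n_i <- sum(st[group, ])
  N <- sum(st)
  n_U <- sum(st[, "U"])
  n_Ui <- st[group, "U"]
  n_Pi <- st[group, "P"]
  common <- 2 * pars$e + n_U * pars$b_PG / pars$N + n_Pi * pars$b_CG / n_i
  # meeting-term counts; under as_resident an absent focal type is treated
  # as one hypothetical resident in its own focal terms only
  m_Ui <- n_Ui; m_U <- n_U; m_Pi <- n_Pi
  if (as_resident) {
    if (type == "U" && n_Ui == 0) { m_Ui <- 1L; m_U <- n_U - n_Ui + 1L }
    if (type == "P" && n_Pi == 0) m_Pi <- 1L
  }
  net_h <- pars$b_h - pars$c_h
  unname(switch(type,
    U = common - pars$c_c +
      (pars$p * safe_frac(m_Ui - 1, n_i - 1) +
         (1 - pars$p) * safe_frac(m_U - m_Ui, N - n_i)) * net_h,
    P = common - pars$c_c + pars$p * safe_frac(m_Pi - 1, n_i - 1) * net_h,
    F = common))
}

# Expected payoffs for every (state, group, type) combination, vectorized
# over the rows of a state-count matrix `counts` (S x k*3, group-major
# columns U,P,F per group). Returns an S x k*3 matrix in the same layout.
payoff_matrix <- function(params, counts) {
  pars <- params
  k <- pars$k; n <- pars$n; N <- pars$N
  T <- 3L
  ucols <- (seq_len(k) - 1L) * T + 1L
  nU <- rowSums(counts[, ucols, drop = FALSE])
  net_h <- pars$b_h - pars$c_h
  out <- matrix(0, nrow(counts), k * T)
  den_in <- n - 1L
  den_out <- N - n
  for (i in seq_len(k)) {
    nUi <- counts[, (i - 1L) * T + 1L]
    nPi <- counts[, (i - 1L) * T + 2L]
    common <- 2 * pars$e + nU * pars$b_PG / N + nPi * pars$b_CG / n
    meet_U <- pars$p * (if (den_in > 0) (nUi - 1) / den_in else 0) +
      (1 - pars$p) * (if (den_out > 0) (nU - nUi) / den_out else 0)
    meet_P <- pars$p * (if (den_in > 0) (nPi - 1) / den_in else 0)
    out[, (i - 1L) * T + 1L] <- common - pars$c_c + meet_U * net_h
    out[, (i - 1L) * T + 2L] <- common - pars$c_c + meet_P * net_h
    out[, (i - 1L) * T + 3L] <- common
  }
  out
}

#' Exponential fitness
#'
#' Maps a payoff `pi` to the selection weight `exp(pi)` of the
#' frequency-dependent Moran process.
#'
#' @param payoff Numeric vector of payoffs.
#' @return `exp(payoff)`.
#' @seealso [fitness_weights()] for the overflow-safe normalized form used
#'   inside the adoption probability.
#' @export
fitness <- function(payoff) exp(payoff)

#' Normalized fitness weights within a state
#'
#' Computes weights proportional to `exp(payoff)` after subtracting the
#' maximum payoff, so that ratios are preserved without overflow for large
#' payoffs.
#'
#' @param payoff Numeric vector of payoffs.
#' @return Nonnegative weights with `max(weights) == 1`.
#' @export
fitness_weights <- function(payoff) exp(payoff - max(payoff))
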