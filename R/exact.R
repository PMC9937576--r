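#' Probability that a given agent slot is selected to adapt
#'
#' Under the Moran update, one agent is selected to die (adapt its strategy)
#' per event: a group is drawn uniformly (probability `1/k`) and then an
#' agent within it uniformly, so an agent of type `j` in group `i` is
#' selected with probability `(1/k) * (n_ij / n)`. Requires equal group
#' sizes.
#'
#' @param state `k x 3` count matrix (columns U, P, F).
#' @param group Group index (1-based); if `NULL`, the full `k x T` matrix of
#'   selection probabilities is returned.
#' @param type Type label (`"U"`, `"P"`, `"F"`) or column index; if `NULL`
#'   with `group` given, the row for that group is returned.
#' @return Selection probability/ies; all entries sum to 1 over the
#'   population.
#' @export
death_probability <- function(state, group = NULL, type = NULL) {
  st <- as_state_matrix(state)
  sizes <- rowSums(st)
  if (length(unique(sizes)) != 1) {
    stop("death_probability requires equal group sizes (exact engine)")
  }
  k <- nrow(st)
  probs <- st / (k * sizes[1])
  if (is.null(group)) return(probs)
  if (is.null(type)) return(probs[group, ])
  if (is.character(type)) type <- match(type, core_types)
  unname(probs[group, type])
}

#' Probability that the adapting agent switches to a given type
#'
#' Adoption is global: the adapting agent copies a type `y` with probability
#' proportional to the total fitness mass of that type in the whole
#' (pre-death) population, `sum_i n_iy * exp(pi_iy)`, normalized over all
#' types. Payoffs are the expected payoffs of [expected_payoff()];
#' exponentials are computed after subtracting the state's maximum payoff so
#' that ratios are preserved without overflow.
#'
#' @param params A [model_params()] object.
#' @param state `k x 3` count matrix (columns U, P, F).
#' @param target_type Optional type label; if omitted, the probability
#'   vector over all three types is returned.
#' @return Adoption probability/ies summing to 1 over types.
#' @export
adoption_probability <- function(params, state, target_type = NULL) {
  pars <- as_coop_params(params, check = FALSE)
  st <- as_state_matrix(state)
  if (sum(st) == 0) stop("empty population")
  counts <- matrix(as.integer(t(st)), nrow = 1)
  pi_mat <- payoff_matrix(pars, counts)
  w <- as.numeric(counts) * exp(as.numeric(pi_mat) - max(pi_mat))
  w <- matrix(w, nrow = nrow(st), byrow = TRUE)  # k x T
  probs <- colSums(w) / sum(w)
  names(probs) <- core_types
  if (is.null(target_type)) return(probs)
  probs[[match.arg(target_type, core_types)]]
}

# One-agent moves: for each group i and ordered type pair j != y, the column
# being decremented/incremented and the key shift to the destination state.
transition_moves <- function(space) {
  k <- space$k; T <- space$n_types
  ncols <- k * T
  base <- space$n + 1
  pow <- base^((ncols - 1):0)
  moves <- list()
  for (i in seq_len(k)) {
    for (j in seq_len(T)) {
      for (y in seq_len(T)) {
        if (y == j) next
        cj <- (i - 1L) * T + j
        cy <- (i - 1L) * T + y
        delta <- -pow[cj] + pow[cy]
        moves[[length(moves) + 1L]] <- list(i = i, j = j, y = y,
                                            col = cj, delta = delta)
      }
    }
  }
  moves
}

# Adoption-probability matrix over all states: A[s, y] for y in 1..T.
adoption_matrix <- function(params, space) {
  counts <- space$counts
  k <- space$k; T <- space$n_types
  pi_mat <- payoff_matrix(params, counts)
  w <- counts * exp(pi_mat - apply(pi_mat, 1, max))
  A <- matrix(0, nrow(counts), T)
  for (y in seq_len(T)) {
    A[, y] <- rowSums(w[, (seq_len(k) - 1L) * T + y, drop = FALSE])
  }
  A / rowSums(A)
}

# Transition probabilities as triplets (off-diagonal) plus diagonal vector.
transition_triplets <- function(params, space, moves = transition_moves(space)) {
  counts <- space$counts
  S <- nrow(counts)
  k <- space$k; n <- space$n; T <- space$n_types
  A <- adoption_matrix(params, space)
  mu <- params$mu
  from <- integer(0); to <- integer(0); prob <- numeric(0)
  offsum <- numeric(S)
  for (mv in moves) {
    rows <- which(counts[, mv$col] > 0L)
    if (!length(rows)) next
    dest <- match(space$key[rows] + mv$delta, space$key)
    pr <- (counts[rows, mv$col] / (k * n)) *
      (mu / T + (1 - mu) * A[rows, mv$y])
    from <- c(from, rows); to <- c(to, dest); prob <- c(prob, pr)
    offsum[rows] <- offsum[rows] + pr
  }
  list(from = from, to = to, prob = prob, diag = 1 - offsum)
}

#' Build the full Moran transition matrix
#'
#' Constructs the row-stochastic one-event transition matrix `M` over the
#' enumerated state space: the dying agent is selected via
#' [death_probability()]; with probability `mu` its new type is drawn
#' uniformly at random from the `T` types (including its current one), and
#' with probability `1 - mu` via the global fitness-proportional
#' [adoption_probability()]. All type-preserving events accumulate on the
#' diagonal.
#'
#' @param params A [model_params()] object.
#' @param space Optional pre-enumerated [enumerate_states()] space matching
#'   `params` (built on demand otherwise).
#' @param cap State-count guard passed to [enumerate_states()].
#' @return An object of class `"coop_tmatrix"`: list with sparse matrix `M`
#'   (a `Matrix::dgCMatrix`), the `space`, and `params`.
#' @examples
#' tm <- build_transition_matrix(model_params(b_h = 7, p = 0.5))
#' range(Matrix::rowSums(tm$M))  # rows sum to 1
#' @export
build_transition_matrix <- function(params, space = NULL, cap = 1e6) {
  pars <- as_coop_params(params, check = FALSE)
  if (is.null(space)) space <- enumerate_states(pars$n, pars$k, cap = cap)
  stopifnot(space$n == pars$n, space$k == pars$k)
  tr <- transition_triplets(pars, space)
  S <- nrow(space$counts)
  M <- Matrix::sparseMatrix(i = c(tr$from, seq_len(S)),
                            j = c(tr$to, seq_len(S)),
                            x = c(tr$prob, tr$diag),
                            dims = c(S, S))
  structure(list(M = M, space = space, params = pars), class = "coop_tmatrix")
}

#' @export
print.coop_tmatrix <- function(x, ...) {
  cat(sprintf("Moran transition matrix: %d x %d states (n = %d, k = %d, mu = %g)\n",
              nrow(x$M), ncol(x$M), x$space$n, x$space$k, x$params$mu))
  invisible(x)
}

#' Stationary distribution of the Moran chain
#'
#' Computes the long-run (steady-state) probability vector `w` over
#' population states, defined by `w M = w` with `M` row-stochastic — the
#' left eigenvector of `M` for eigenvalue 1, normalized to sum 1. For
#' `mu > 0` the chain is irreducible and this vector is unique and
#' nonnegative (Perron-Frobenius). Three interchangeable backends are
#' provided and must agree to high accuracy:
#' \describe{
#'   \item{`"solve"`}{null-space linear solve of `t(M) - I` with the
#'     normalization row appended (default; deterministic and fast).}
#'   \item{`"eigen"`}{dense eigendecomposition of `t(M)`, leading
#'     eigenvector.}
#'   \item{`"power"`}{power iteration accelerated by repeated matrix
#'     squaring until rows converge.}
#' }
#'
#' @param tm A `"coop_tmatrix"` from [build_transition_matrix()] (or a bare
#'   row-stochastic matrix).
#' @param method Backend, see above.
#' @param tol Convergence tolerance for the power backend.
#' @return Numeric probability vector over states (sums to 1).
#' @export
stationary_distribution <- function(tm, method = c("solve", "eigen", "power"),
                                    tol = 1e-13) {
  method <- match.arg(method)
  if (inherits(tm, "coop_tmatrix")) {
    if (tm$params$mu == 0) {
      stop(paste("mu = 0 makes the chain reducible (homogeneous states are",
                 "absorbing); the stationary distribution is not unique.",
                 "Analyse absorption instead, e.g. with run_simulation()."))
    }
    M <- tm$M
  } else {
    M <- tm
  }
  M <- as.matrix(M)
  S <- nrow(M)
  w <- switch(method,
    solve = {
      A <- t(M) - diag(S)
      A[S, ] <- 1
      b <- c(rep(0, S - 1), 1)
      solve(A, b)
    },
    eigen = {
      ev <- eigen(t(M))
      i <- which.max(Re(ev$values))
      v <- Re(ev$vectors[, i])
      v / sum(v)
    },
    power = {
      P <- M
      for (iter in 1:60) {
        P2 <- P %*% P
        if (max(abs(P2 - P)) < tol) { P <- P2; break }
        P <- P2
      }
      colMeans(P)
    })
  w <- pmax(w, 0)
  w / sum(w)
}

#' Steady-state composition and welfare
#'
#' Solves the stationary distribution for a parameter set and summarizes it:
#' the stationary expectation of each type's population share, and welfare,
#' the stationary expectation of the mean agent payoff per generation
#' (including both stage endowments `2e`).
#'
#' @param params A [model_params()] object.
#' @param space Optional pre-enumerated state space (reused across calls).
#' @param method Stationary backend, see [stationary_distribution()].
#' @return One-row `data.frame` with columns `p`, `b_h`, `prop_U`, `prop_P`,
#'   `prop_F`, `welfare`, `n`, `k`, `mu`, `state_count`.
#' @examples
#' \donttest{
#' steady_state_summary(model_params(b_h = 7, p = 0.5))
#' }
#' @export
steady_state_summary <- function(params, space = NULL,
                                 method = c("solve", "eigen", "power")) {
  pars <- as_coop_params(params, check = FALSE)
  method <- match.arg(method)
  if (is.null(space)) space <- enumerate_states(pars$n, pars$k)
  moves <- transition_moves(space)
  summarize_cell(pars, space, moves, method)
}

# Dense fast path shared by steady_state_summary and sweep_exact.
summarize_cell <- function(pars, space, moves, method = "solve") {
  tr <- transition_triplets(pars, space, moves)
  S <- nrow(space$counts)
  M <- matrix(0, S, S)
  M[cbind(tr$from, tr$to)] <- tr$prob
  diag(M) <- tr$diag
  w <- stationary_distribution_checked(M, pars, method)
  k <- space$k; T <- space$n_types; N <- pars$N
  counts <- space$counts
  pi_mat <- payoff_matrix(pars, counts)
  share <- function(t) rowSums(counts[, (seq_len(k) - 1L) * T + t, drop = FALSE]) / N
  welfare_s <- rowSums(counts * pi_mat) / N
  data.frame(p = pars$p, b_h = pars$b_h,
             prop_U = sum(w * share(1L)),
             prop_P = sum(w * share(2L)),
             prop_F = sum(w * share(3L)),
             welfare = sum(w * welfare_s),
             n = space$n, k = space$k, mu = pars$mu,
             state_count = S)
}

stationary_distribution_checked <- function(M, pars, method) {
  if (pars$mu == 0) {
    stop(paste("mu = 0 makes the chain reducible (homogeneous states are",
               "absorbing); the stationary distribution is not unique."))
  }
  stationary_distribution(M, method = method)
}

#' Exact parameter sweep over fluidity and helping benefit
#'
#' Runs [steady_state_summary()] for every combination of `p_grid` and
#' `bh_grid`, reusing one state-space enumeration. The default grids
#' (`p = 0.5, 0.51, ..., 1.0`; `b_h = 0, 0.1, ..., 9`) span 4641 cells for
#' the two-group baseline.
#'
#' @param params Base [model_params()]; `p` and `b_h` are overridden cell by
#'   cell.
#' @param p_grid Numeric grid of in-group meeting probabilities.
#' @param bh_grid Numeric grid of helping benefits.
#' @param method Stationary backend.
#' @param progress Print a progress line every few hundred cells.
#' @return `data.frame` with one row per `(p, b_h)` cell, columns as in
#'   [steady_state_summary()].
#' @export
sweep_exact <- function(params, p_grid = seq(0.5, 1, by = 0.01),
                        bh_grid = seq(0, 9, by = 0.1),
                        method = c("solve", "eigen", "power"),
                        progress = FALSE) {
  pars <- as_coop_params(params, check = FALSE)
  method <- match.arg(method)
  space <- enumerate_states(pars$n, pars$k)
  moves <- transition_moves(space)
  cells <- expand.grid(b_h = bh_grid, p = p_grid)[, c("p", "b_h")]
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    pars$p <- cells$p[i]
    pars$b_h <- cells$b_h[i]
    out[[i]] <- summarize_cell(pars, space, moves, method)
    if (progress && i %% 500 == 0) {
      message(sprintf("sweep_exact: %d / %d cells", i, nrow(cells)))
    }
  }
  do.call(rbind, out)
}
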