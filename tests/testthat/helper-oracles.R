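# Independent oracles used to cross-check the closed-form and vectorized
# implementations. Deliberately written as plain scalar loops.

# Expected per-agent payoffs by exhaustive enumeration of all stage-2
# donor-receiver pairings, weighted by their probabilities. Agents are laid
# out explicitly from the state counts; helping follows the core rules
# (U helps U anywhere, P helps in-group P, F never).
oracle_expected_payoffs <- function(params, state) {
  st <- state
  k <- nrow(st)
  types <- rep(rep(c("U", "P", "F"), k), times = as.vector(t(st)))
  groups <- rep(seq_len(k), times = rowSums(st))
  N <- length(types)
  actions <- c(U = "public", P = "club", F = "none")[types]
  pay <- stage1_earnings(params, actions, groups) + params$e
  for (d in seq_len(N)) {
    n_g <- sum(groups == groups[d])
    for (r in seq_len(N)) {
      if (r == d) next
      same <- groups[r] == groups[d]
      prob <- if (same) {
        if (n_g > 1) params$p / (n_g - 1) else 0
      } else {
        if (N - n_g > 0) (1 - params$p) / (N - n_g) else 0
      }
      if (prob == 0) next
      helps <- switch(types[d],
                      U = types[r] == "U",
                      P = types[r] == "P" && same,
                      F = FALSE)
      if (helps) {
        pay[d] <- pay[d] - params$c_h * prob
        pay[r] <- pay[r] + params$b_h * prob
      }
    }
  }
  data.frame(group = groups, type = types, payoff = pay)
}

# Scalar brute-force construction of the Moran transition matrix, built
# from first principles (death probability, adoption ratio with plain
# exponentials) on an explicit state list.
oracle_transition_matrix <- function(params, space) {
  counts <- space$counts
  S <- nrow(counts)
  k <- space$k; n <- space$n; T <- 3L
  M <- matrix(0, S, S)
  for (s in seq_len(S)) {
    st <- matrix(counts[s, ], nrow = k, byrow = TRUE,
                 dimnames = list(NULL, c("U", "P", "F")))
    pis <- outer(seq_len(k), seq_len(T), Vectorize(function(i, t) {
      expected_payoff(params, st, i, c("U", "P", "F")[t])
    }))
    wmass <- st * exp(pis)
    adopt <- colSums(wmass) / sum(wmass)
    for (i in seq_len(k)) {
      for (j in seq_len(T)) {
        if (st[i, j] == 0) next
        death <- (1 / k) * (st[i, j] / n)
        for (y in seq_len(T)) {
          pr <- death * (params$mu / T + (1 - params$mu) * adopt[y])
          if (y == j) {
            M[s, s] <- M[s, s] + pr
          } else {
            st2 <- st
            st2[i, j] <- st2[i, j] - 1L
            st2[i, y] <- st2[i, y] + 1L
            s2 <- which(apply(counts, 1, function(r) all(r == as.vector(t(st2)))))
            M[s, s2] <- M[s, s2] + pr
          }
        }
      }
    }
  }
  M
}

# Random valid population state for given group size/count.
random_state <- function(n, k) {
  t(vapply(seq_len(k), function(i) {
    tab <- tabulate(sample.int(3, n, replace = TRUE), nbins = 3)
    as.integer(tab)
  }, integer(3)))
}

regime_cells <- list(c(b_h = 2.5, p = 1), c(b_h = 2.5, p = 0.5),
                   c(b_h = 7, p = 1), c(b_h = 7, p = 0.5))
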