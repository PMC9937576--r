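#' Number of population states
#'
#' For `k` equally sized groups of `n` agents and `T` strategy types, the
#' state space of the Moran chain is the product of per-group compositions:
#' `choose(n + T - 1, T - 1) ^ k` states.
#'
#' @param n Group size.
#' @param k Number of groups.
#' @param n_types Number of strategy types `T`.
#' @return The state count as a double (may exceed integer range).
#' @examples
#' count_states(4, 2)    # 225
#' count_states(50, 2)   # 1758276
#' @export
count_states <- function(n, k, n_types = 3) {
  choose(n + n_types - 1, n_types - 1)^k
}

# All compositions of n into T nonnegative parts, in lexicographic order
# (first part most significant). Rows are compositions.
compositions <- function(n, T) {
  if (T == 1) return(matrix(as.integer(n), 1, 1))
  out <- vector("list", n + 1)
  for (first in 0:n) {
    rest <- compositions(n - first, T - 1)
    out[[first + 1]] <- cbind(as.integer(first), rest)
  }
  do.call(rbind, out)
}

#' Enumerate the full population state space
#'
#' Builds the complete, duplicate-free list of population states for `k`
#' equally sized groups of `n` agents and `n_types` strategy types. States
#' are returned as rows of a count matrix with group-major columns
#' (group 1 type 1, group 1 type 2, ..., group k type T) and are ordered
#' lexicographically on that flattened count vector. The object also carries
#' an integer key per state (base `n + 1` encoding of the counts) used for
#' O(1) neighbour lookup when constructing transitions.
#'
#' @inheritParams count_states
#' @param cap Refuse enumeration when the state count exceeds this guard
#'   (default `1e6`); the count itself is always available via
#'   [count_states()].
#' @return An object of class `"coop_state_space"`: list with `counts`
#'   (S x k*T integer matrix), `n`, `k`, `n_types`, `key` (numeric vector),
#'   and `order` (`"lexicographic"`).
#' @examples
#' ss <- enumerate_states(4, 2)
#' nrow(ss$counts)  # 225
#' @export
enumerate_states <- function(n, k, n_types = 3, cap = 1e6) {
  stopifnot(n >= 1, k >= 1, n_types >= 1)
  S <- count_states(n, k, n_types)
  if (S > cap) {
    stop(sprintf(paste0("state space has %.0f states, above the enumeration ",
                        "cap of %.0f; raise `cap` explicitly if intended"),
                 S, cap))
  }
  comp <- compositions(n, n_types)
  m <- nrow(comp)
  # expand.grid over group compositions with group 1 most significant
  idx <- as.matrix(expand.grid(rev(lapply(seq_len(k), function(i) seq_len(m)))))
  idx <- idx[, rev(seq_len(k)), drop = FALSE]
  counts <- do.call(cbind, lapply(seq_len(k), function(i) comp[idx[, i], , drop = FALSE]))
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, n = as.integer(n), k = as.integer(k),
                 n_types = as.integer(n_types),
                 key = state_key(counts, n),
                 order = "lexicographic"),
            class = "coop_state_space")
}

# Base-(n+1) encoding of count rows; first column most significant so key
# order matches lexicographic state order.
state_key <- function(counts, n) {
  base <- n + 1
  ncols <- ncol(counts)
  pow <- base^((ncols - 1):0)
  as.numeric(counts %*% pow)
}

state_index <- function(space, state) {
  key <- state_key(matrix(as.integer(t(state)), nrow = 1), space$n)
  i <- match(key, space$key)
  if (is.na(i)) stop("state not in enumerated space")
  i
}

#' @export
print.coop_state_space <- function(x, ...) {
  cat(sprintf("Population state space: n = %d, k = %d, %d types, %d states (%s order)\n",
              x$n, x$k, x$n_types, nrow(x$counts), x$order))
  invisible(x)
}
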