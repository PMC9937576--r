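#' Model parameters for the nested social dilemma
#'
#' Bundles every game and evolution constant: the population layout
#' (`k` groups of `n` agents, `N = k * n`), the stage-1 contribution game
#' (endowment `e`, cooperation cost `c_c`, club-good benefit `b_CG`,
#' public-good benefit `b_PG`), the stage-2 helping game (helping cost `c_h`,
#' helping benefit `b_h`), the group-boundary fluidity `p` (probability that
#' a dyadic partner is an in-group member), and the mutation rate `mu` of the
#' Moran process.
#'
#' Both contribution options must be genuine social dilemmas: the marginal
#' per-capita return of a contribution must be below its cost
#' (`b_CG / n < c_c` and `b_PG / N < c_c`) while the total benefit created
#' exceeds the cost (`c_c < b_CG` and `c_c < b_PG`). The defaults are the
#' two-group baseline used throughout: `k = 2`, `n = 4`,
#' `c_c = c_h = e = 1`, `b_CG = 2`, `b_PG = 3`, `mu = 1e-4`.
#'
#' @param k Number of groups (integer, >= 1; the exact engine's closed-form
#'   payoffs assume `k = 2`).
#' @param n Agents per group (integer, >= 1; groups are equally sized).
#' @param e Endowment per stage, in monetary units.
#' @param c_c Cost of contributing in stage 1.
#' @param c_h Cost of helping in stage 2.
#' @param b_CG Club-good benefit, shared over the `n` members of one group.
#' @param b_PG Public-good benefit, shared over all `N` agents.
#' @param b_h Helping benefit conferred on the receiver.
#' @param p Probability that a stage-2 partner is an in-group member
#'   (`p = 1`: solid boundaries; `p = 0.5`: fully fluid).
#' @param mu Mutation probability of the Moran update.
#' @param check If `TRUE` (default) enforce the dilemma inequalities; set to
#'   `FALSE` to build degenerate parameter sets for exploratory use.
#'
#' @return An object of class `"coop_params"`: a named list with the fields
#'   above plus the derived total population size `N`.
#' @examples
#' pars <- model_params(b_h = 3, p = 0.5)
#' pars$N
#' @export
model_params <- function(k = 2, n = 4, e = 1, c_c = 1, c_h = 1,
                         b_CG = 2, b_PG = 3, b_h = 3, p = 0.5,
                         mu = 1e-4, check = TRUE) {
  pars <- list(k = as.integer(k), n = as.integer(n), N = as.integer(k * n),
               e = e, c_c = c_c, c_h = c_h, b_CG = b_CG, b_PG = b_PG,
               b_h = b_h, p = p, mu = mu)
  class(pars) <- "coop_params"
  if (check) validate_params(pars)
  pars
}

#' Validate a parameter set
#'
#' Checks ranges and the two social-dilemma conditions. On failure, the error
#' message names the specific inequality that was violated.
#'
#' @param params A `coop_params` object (or coercible named list).
#' @return `params`, invisibly, if valid.
#' @export
validate_params <- function(params) {
  p <- params
  if (p$k < 1 || p$k != round(p$k)) stop("k must be a positive integer")
  if (p$n < 1 || p$n != round(p$n)) stop("n must be a positive integer")
  for (f in c("e", "c_c", "c_h", "b_CG", "b_PG", "b_h")) {
    if (p[[f]] < 0) stop(sprintf("%s must be >= 0 (got %g)", f, p[[f]]))
  }
  if (p$p < 0 || p$p > 1) stop(sprintf("p must lie in [0, 1] (got %g)", p$p))
  if (p$mu < 0 || p$mu > 1) stop(sprintf("mu must lie in [0, 1] (got %g)", p$mu))
  if (!(p$b_CG / p$n < p$c_c)) {
    stop(sprintf("club-good dilemma violated: b_CG/n < c_c fails (%g/%d = %g >= %g)",
                 p$b_CG, p$n, p$b_CG / p$n, p$c_c))
  }
  if (!(p$c_c < p$b_CG)) {
    stop(sprintf("club-good dilemma violated: c_c < b_CG fails (%g >= %g)",
                 p$c_c, p$b_CG))
  }
  if (!(p$b_PG / p$N < p$c_c)) {
    stop(sprintf("public-good dilemma violated: b_PG/N < c_c fails (%g/%d = %g >= %g)",
                 p$b_PG, p$N, p$b_PG / p$N, p$c_c))
  }
  if (!(p$c_c < p$b_PG)) {
    stop(sprintf("public-good dilemma violated: c_c < b_PG fails (%g >= %g)",
                 p$c_c, p$b_PG))
  }
  invisible(params)
}

#' @export
print.coop_params <- function(x, ...) {
  cat("Nested social dilemma parameters\n")
  cat(sprintf("  population : k = %d groups x n = %d agents (N = %d)\n",
              x$k, x$n, x$N))
  cat(sprintf("  stage 1    : e = %g, c_c = %g, b_CG = %g, b_PG = %g\n",
              x$e, x$c_c, x$b_CG, x$b_PG))
  cat(sprintf("  stage 2    : c_h = %g, b_h = %g, p = %g\n", x$c_h, x$b_h, x$p))
  cat(sprintf("  evolution  : mu = %g\n", x$mu))
  invisible(x)
}

param_fields <- c("k", "n", "e", "c_c", "c_h", "b_CG", "b_PG", "b_h", "p", "mu")

as_coop_params <- function(x, check = TRUE) {
  if (inherits(x, "coop_params")) return(x)
  stopifnot(is.list(x))
  miss <- setdiff(param_fields, names(x))
  if (length(miss)) stop("missing parameter fields: ", paste(miss, collapse = ", "))
  do.call(model_params, c(x[param_fields], list(check = check)))
}
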