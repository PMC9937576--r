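#' Minimal cooperator share for cooperation to proliferate
#'
#' Under solid group boundaries, a cooperative type can spread once its
#' share among potential helping partners exceeds the cost-to-net-benefit
#' ratio of cooperating, `c_c / (b_h - c_h)`: only then does the expected
#' reciprocal helping surplus repay the stage-1 contribution cost.
#'
#' @param c_c Cost of cooperating in stage 1.
#' @param b_h Helping benefit.
#' @param c_h Helping cost.
#' @return The threshold share. When `b_h <= c_h` helping yields no net
#'   reward and the threshold is unattainable: `Inf` is returned with
#'   attribute `unattainable = TRUE`. Values above 1 mean cooperation cannot
#'   proliferate at any composition (attribute `attainable_share = FALSE`).
#' @examples
#' cooperation_share_threshold(1, 3, 1)  # 0.5
#' cooperation_share_threshold(1, 2, 1)  # 1: cooperation needs b_h > 2
#' @export
cooperation_share_threshold <- function(c_c, b_h, c_h) {
  if (b_h <= c_h) {
    return(structure(Inf, unattainable = TRUE))
  }
  thr <- c_c / (b_h - c_h)
  if (thr > 1) attr(thr, "attainable_share") <- FALSE
  thr
}

#' Minimal parochialist share for invading a universalist group
#'
#' With solid boundaries, even against a group composed solely of universal
#' cooperators, parochialists outcompete universal cooperation once their
#' share in the opposing group exceeds
#' `(b_h - c_h) / (b_h - c_h + b_CG)`: above that share their club-good
#' return plus in-group reciprocity beats the universalists' helping
#' surplus, while they still pocket the non-excludable public-good return.
#'
#' @param b_h Helping benefit.
#' @param c_h Helping cost.
#' @param b_CG Club-good benefit.
#' @return The threshold share in (0, 1).
#' @examples
#' parochial_invasion_threshold(3, 1, 2)  # 0.5
#' @export
parochial_invasion_threshold <- function(b_h, c_h, b_CG) {
  if (b_h <= c_h) stop("requires b_h > c_h (helping must carry a net benefit)")
  if (b_CG <= 0) stop("requires b_CG > 0")
  (b_h - c_h) / (b_h - c_h + b_CG)
}

#' Does a universalist majority predict universal dominance?
#'
#' For fully fluid boundaries (`p = 0.5`), universal cooperators outcompete
#' parochialists when the total number of universalists in the population
#' exceeds the number of parochialists within each group; in particular a
#' simple population-wide majority of universalists (`n_U > N/2`) implies
#' universal rather than parochial cooperation emerges. The per-group
#' comparison is the primary operational form; the simple-majority reading
#' is reported alongside.
#'
#' @param state `k x 3` count matrix (columns U, P, F).
#' @param p In-group meeting probability; the condition is stated only for
#'   `p = 0.5`.
#' @return A list of class `"coop_majority_prediction"`: `prediction`
#'   (`"universal"`, `"parochial"`, or `"tie"`), `n_U_total`,
#'   `max_n_P_group`, `simple_majority` (logical, `n_U > N/2`), and
#'   `in_scope`. For `p != 0.5` the prediction is `NA` and `in_scope` is
#'   `FALSE` (the condition is out of scope there, not falsified).
#' @examples
#' st <- rbind(c(3, 3, 0), c(2, 0, 0))
#' universalist_majority_predicts_dominance(st, p = 0.5)
#' @export
universalist_majority_predicts_dominance <- function(state, p = 0.5) {
  st <- as_state_matrix(state)
  n_U <- sum(st[, "U"])
  max_nP <- max(st[, "P"])
  N <- sum(st)
  if (p != 0.5) {
    res <- list(prediction = NA_character_, n_U_total = n_U,
                max_n_P_group = max_nP, simple_majority = NA,
                in_scope = FALSE,
                note = "condition stated only for fully fluid boundaries (p = 0.5)")
  } else {
    pred <- if (n_U > max_nP) "universal" else if (n_U < max_nP) "parochial" else "tie"
    res <- list(prediction = pred, n_U_total = n_U, max_n_P_group = max_nP,
                simple_majority = n_U > N / 2, in_scope = TRUE)
  }
  class(res) <- "coop_majority_prediction"
  res
}

#' @export
print.coop_majority_prediction <- function(x, ...) {
  if (!x$in_scope) {
    cat("Majority condition out of scope:", x$note, "\n")
  } else {
    cat(sprintf("Universalists total: %d; largest parochialist group count: %d\n",
                x$n_U_total, x$max_n_P_group))
    cat("Predicted dominant cooperation:", x$prediction, "\n")
  }
  invisible(x)
}

#' All closed-form threshold conditions at once
#'
#' Convenience wrapper evaluating [cooperation_share_threshold()] and
#' [parochial_invasion_threshold()] for a parameter set.
#'
#' @param params A [model_params()] object.
#' @return `data.frame` with columns `condition`, `threshold`, `attainable`.
#' @export
threshold_table <- function(params) {
  pars <- as_coop_params(params, check = FALSE)
  coop <- cooperation_share_threshold(pars$c_c, pars$b_h, pars$c_h)
  paro <- tryCatch(parochial_invasion_threshold(pars$b_h, pars$c_h, pars$b_CG),
                   error = function(e) NA_real_)
  data.frame(
    condition = c("cooperator share to proliferate",
                  "parochialist share in opposing group to invade"),
    threshold = c(as.numeric(coop), as.numeric(paro)),
    attainable = c(is.finite(coop) && as.numeric(coop) <= 1,
                   !is.na(paro)))
}
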