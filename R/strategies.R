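#' Define a behavioural strategy
#'
#' A strategy is a stage-1 contribution action plus a stage-2 helping rule.
#' The helping rule fires as a pure function of what the donor can observe
#' about the receiver: the receiver's stage-1 action, whether the receiver
#' is in the donor's group, and (for conditional helpers) whether the
#' receiver extended help in the previous round.
#'
#' @param name Short label.
#' @param contribution One of `"public"`, `"club"`, `"none"`.
#' @param help_target Whom the agent helps: `"none"`, `"universal"` (public
#'   contributors, any group), `"parochial_ingroup"` (club contributors of
#'   the donor's own group), or `"any_cooperator"` (any stage-1 contributor,
#'   any group — the nondiscriminating rule).
#' @param conditional If `TRUE`, help is additionally withheld from
#'   receivers in bad standing (second-order discrimination; detects
#'   second-order free-riders). An agent falls into bad standing by
#'   withholding help from a stage-1 contributor in good standing;
#'   justified withholding — from a non-contributor, or from an agent
#'   itself in bad standing — does not spoil standing.
#' @return One-row `data.frame` usable as a strategy-set row.
#' @export
strategy <- function(name, contribution = c("none", "club", "public"),
                     help_target = c("none", "universal", "parochial_ingroup",
                                     "any_cooperator"),
                     conditional = FALSE) {
  data.frame(name = name,
             contribution = match.arg(contribution),
             help_target = match.arg(help_target),
             conditional = conditional,
             stringsAsFactors = FALSE)
}

#' The three core strategies
#'
#' Universal cooperators `U` (contribute to the public good, help other
#' universal cooperators wherever they meet them), parochial cooperators
#' `P` (contribute to the club good, help in-group parochialists), and
#' free-riders `F` (neither contribute nor help). Matches the type space of
#' the exact engine.
#'
#' @param conditional If `TRUE`, the two helper types additionally condition
#'   on the receiver's previous-round helping (used in extended-space
#'   analyses; the exact engine's types are unconditional).
#' @return Strategy-set `data.frame` with rows U, P, F.
#' @export
core_strategies <- function(conditional = FALSE) {
  rbind(strategy("U", "public", "universal", conditional),
        strategy("P", "club", "parochial_ingroup", conditional),
        strategy("F", "none", "none", FALSE))
}

#' Extended strategy space
#'
#' The core space optionally augmented with the named extra strategies:
#' nondiscriminating helpers (`ND`: contribute publicly, help any stage-1
#' cooperator regardless of type or group) and second-order free-riders
#' (`SU`/`SP`: contribute publicly/to the club but never help). When
#' `conditional_helpers = TRUE`, all helping strategies withhold help from
#' receivers who did not help last round, which makes second-order
#' free-riders detectable; with `FALSE` they cannot be told apart from
#' helping cooperators.
#'
#' @param nondiscriminating Include the `ND` strategy.
#' @param second_order Include the `SU` and `SP` strategies.
#' @param conditional_helpers Make all helpers second-order discriminators.
#' @return Strategy-set `data.frame`.
#' @export
extended_strategies <- function(nondiscriminating = FALSE,
                                second_order = FALSE,
                                conditional_helpers = FALSE) {
  s <- core_strategies(conditional = conditional_helpers)
  if (nondiscriminating) {
    s <- rbind(s, strategy("ND", "public", "any_cooperator", conditional_helpers))
  }
  if (second_order) {
    s <- rbind(s, strategy("SU", "public", "none", FALSE),
               strategy("SP", "club", "none", FALSE))
  }
  rownames(s) <- NULL
  s
}

# integer codes shared with the compiled core
contribution_code <- function(x) match(x, c("none", "club", "public")) - 1L
help_target_code <- function(x) {
  match(x, c("none", "universal", "parochial_ingroup", "any_cooperator")) - 1L
}

strategy_codes <- function(strategies) {
  cbind(contribution = contribution_code(strategies$contribution),
        help_target = help_target_code(strategies$help_target),
        conditional = as.integer(strategies$conditional))
}

#' Does a donor's strategy help a given receiver?
#'
#' Pure helping rule: depends only on the donor's strategy and the
#' observable receiver information.
#'
#' @param strat One strategy (a one-row strategy-set `data.frame` or list
#'   with `help_target` and `conditional`).
#' @param receiver_info List with `contribution` (receiver's stage-1 action),
#'   `same_group` (logical), and `helped_last` (logical: the receiver's
#'   standing from its previous-round helping behaviour, `NA` when unknown,
#'   e.g. in round 1).
#' @param benefit_of_doubt How to treat an unknown helping history under a
#'   conditional rule: `TRUE` (default) treats the receiver as having
#'   helped.
#' @return Logical: help or not.
#' @export
helping_decision <- function(strat, receiver_info, benefit_of_doubt = TRUE) {
  target <- strat$help_target
  if (target == "none") return(FALSE)
  fires <- switch(target,
    universal = receiver_info$contribution == "public",
    parochial_ingroup = receiver_info$contribution == "club" &&
      isTRUE(receiver_info$same_group),
    any_cooperator = receiver_info$contribution != "none")
  if (!fires) return(FALSE)
  if (isTRUE(as.logical(strat$conditional))) {
    hl <- receiver_info$helped_last
    if (is.na(hl)) return(benefit_of_doubt)
    return(as.logical(hl))
  }
  TRUE
}
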