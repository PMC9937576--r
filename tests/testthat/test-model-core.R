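test_that("stage-1 earnings reproduce the worked monetary-unit examples", {
  pars <- model_params()

  all_public <- stage1_earnings(pars, rep("public", 8))
  expect_equal(all_public, rep(3, 8))

  one_keeper <- stage1_earnings(pars, c(rep("public", 7), "none"))
  expect_equal(one_keeper[8], 3.625)
  expect_equal(one_keeper[1:7], rep(2.625, 7))

  club <- stage1_earnings(pars, c(rep("club", 3), "none", rep("none", 4)))
  expect_equal(club[1:3], rep(1.5, 3))
  expect_equal(club[4], 2.5)

  cross <- stage1_earnings(pars, c(rep("public", 4), rep("club", 4)))
  expect_equal(cross[1:4], rep(1.5, 4))   # exploited universalist group
  expect_equal(cross[5:8], rep(3.5, 4))   # parochial group pockets both

  expect_equal(stage1_earnings(pars, rep("none", 8)), rep(1, 8))
})

test_that("stage-1 totals conserve endowments, costs and benefits created", {
  pars <- model_params(e = 1, c_c = 0.8, b_CG = 2.5, b_PG = 3.5, check = FALSE)
  set.seed(41)
  for (rep in 1:20) {
    actions <- sample(c("public", "club", "none"), pars$N, replace = TRUE)
    earn <- stage1_earnings(pars, actions)
    expected_total <- pars$N * pars$e -
      sum(actions != "none") * pars$c_c +
      sum(actions == "public") * pars$b_PG +
      sum(actions == "club") * pars$b_CG
    expect_equal(sum(earn), expected_total, tolerance = 1e-12)
  }
})

test_that("stage-1 earnings validate their inputs", {
  pars <- model_params()
  expect_error(stage1_earnings(pars, rep("public", 5)), "expected 8 actions")
  expect_error(stage1_earnings(pars, c(rep("public", 7), "pool")),
               "unknown action")
})

test_that("expected payoffs match hand evaluations of the printed forms", {
  # all free-riders: every game term vanishes, both endowments remain
  pars <- model_params(b_h = 5, p = 0.7)
  st_f <- rbind(c(0, 0, 4), c(0, 0, 4))
  for (g in 1:2) expect_equal(expected_payoff(pars, st_f, g, "F"), 2)

  # solid boundaries, a group entirely parochialist:
  # 2e + PG(0) + CG(4*2/4) - c_c + 1 * (3-1)/(3) * ... = 2 + 2 - 1 + 2 = 5
  pars_p <- model_params(p = 1, b_h = 3, check = FALSE)
  st_p <- rbind(c(0, 4, 0), c(0, 4, 0))
  expect_equal(expected_payoff(pars_p, st_p, 1, "P"), 5)

  # the public-good return is non-excludable: parochialists and
  # free-riders collect n_U * b_PG / N too
  st_mix <- rbind(c(2, 1, 1), c(0, 0, 4))
  pars_m <- model_params(b_h = 3, p = 0.5)
  pg_return <- 2 * 3 / 8
  expect_equal(expected_payoff(pars_m, st_mix, 2, "F"), 2 + pg_return)
})

test_that("expected payoffs equal exhaustive pairing enumeration", {
  set.seed(7)
  pars <- model_params(b_h = 4.5, p = 0.5)
  for (rep in 1:25) {
    st <- random_state(4, 2)
    oracle <- oracle_expected_payoffs(pars, st)
    for (g in 1:2) {
      for (ty in c("U", "P", "F")) {
        rows <- oracle$group == g & oracle$type == ty
        if (!any(rows)) next
        expect_equal(expected_payoff(pars, st, g, ty),
                     unique(round(oracle$payoff[rows], 12)),
                     tolerance = 1e-9)
      }
    }
  }
  # also under solid boundaries and for asymmetric benefits
  pars2 <- model_params(b_h = 2, p = 1, b_CG = 2.6, b_PG = 3.4, check = FALSE)
  st <- rbind(c(1, 2, 1), c(2, 0, 2))
  oracle <- oracle_expected_payoffs(pars2, st)
  for (g in 1:2) {
    for (ty in c("U", "P", "F")) {
      rows <- oracle$group == g & oracle$type == ty
      if (!any(rows)) next
      expect_equal(expected_payoff(pars2, st, g, ty),
                   unique(round(oracle$payoff[rows], 12)), tolerance = 1e-9)
    }
  }
})

test_that("free-riding dominates whenever helping has no net benefit", {
  pars <- model_params(b_h = 1, c_h = 1)  # b_h <= c_h
  space <- enumerate_states(4, 2)
  for (s in seq_len(nrow(space$counts))) {
    st <- matrix(space$counts[s, ], nrow = 2, byrow = TRUE)
    for (g in 1:2) {
      piF <- expected_payoff(pars, st, g, "F")
      expect_gte(piF, expected_payoff(pars, st, g, "U") - 1e-12)
      expect_gte(piF, expected_payoff(pars, st, g, "P") - 1e-12)
    }
  }
})

test_that("degenerate meeting fractions contribute zero", {
  # single-member groups: no in-group partner exists
  pars <- model_params(n = 1, k = 2, b_CG = 0.5, b_PG = 1.5, p = 1,
                       check = FALSE)
  st <- rbind(c(1, 0, 0), c(1, 0, 0))
  expect_equal(expected_payoff(pars, st, 1, "U"),
               2 + 2 * 1.5 / 2 + 0 - 1)
  # one group only: no out-group exists
  pars1 <- model_params(n = 4, k = 1, b_PG = 3, p = 0, check = FALSE)
  st1 <- matrix(c(4, 0, 0), nrow = 1)
  expect_equal(expected_payoff(pars1, st1, 1, "U"), 2 + 3 - 1)
})

test_that("hypothetical-resident payoffs are usable for invasion analysis", {
  pars <- model_params(b_h = 3, p = 1, check = FALSE)
  st <- rbind(c(0, 4, 0), c(0, 4, 0))
  # literally, an absent universalist has a negative meeting term ...
  lit <- expected_payoff(pars, st, 1, "U")
  # ... as a hypothetical resident its own meeting term is zeroed
  res <- expected_payoff(pars, st, 1, "U", as_resident = TRUE)
  expect_equal(res, 2 + 0 + 4 * 2 / 4 - 1)
  expect_lt(lit, res)
})

test_that("fitness is exponential and weight ratios survive normalization", {
  expect_equal(fitness(0), 1)
  expect_equal(fitness(log(2)) / fitness(0), 2)
  pis <- c(700, 700 + log(2))  # would overflow raw exp()
  w <- fitness_weights(pis)
  expect_equal(w[2] / w[1], 2)
  expect_true(all(is.finite(w)))
})
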