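test_that("population initialization is seeded, uniform, and well-formed", {
  pars <- model_params()
  a <- init_population(pars, seed = 42)
  b <- init_population(pars, seed = 42)
  expect_identical(a$strategy, b$strategy)
  expect_equal(tabulate(a$group), c(4, 4))
  # single-strategy space gives a homogeneous start
  solo <- init_population(pars, core_strategies()[3, ], seed = 1)
  expect_true(all(solo$strategy == 1))
  # uniform initial shares within 3-sigma binomial bounds
  set.seed(8)
  big <- model_params(n = 2500, k = 2, b_CG = 2, b_PG = 3, check = FALSE)
  pop <- init_population(big, core_strategies())
  shares <- tabulate(pop$strategy, 3) / big$N
  sigma <- sqrt((1 / 3) * (2 / 3) / big$N)
  expect_true(all(abs(shares - 1 / 3) < 3 * sigma))
})

test_that("pairing respects group membership probabilities", {
  pars <- model_params()
  pop <- init_population(pars, seed = 2)
  set.seed(3)
  r1 <- pair_agents(pop, p = 1)
  expect_true(all(pop$group[r1] == pop$group))
  expect_true(all(r1 != seq_along(r1)))
  r0 <- pair_agents(pop, p = 0)
  expect_true(all(pop$group[r0] != pop$group))
  # p = 0.5 with equal groups: in-group fraction within 3 sigma
  n_draws <- 4000
  ingroup <- 0
  for (i in seq_len(n_draws / 8)) {
    r <- pair_agents(pop, p = 0.5)
    ingroup <- ingroup + sum(pop$group[r] == pop$group)
  }
  frac <- ingroup / n_draws
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n_draws))
  # impossible demands are refused
  solo_group <- init_population(model_params(k = 1, n = 4, b_PG = 3,
                                             check = FALSE),
                                core_strategies(), seed = 1)
  expect_error(pair_agents(solo_group, p = 0.5), "k >= 2")
})

test_that("a mutation-free homogeneous population never changes", {
  pars <- model_params(mu = 0, check = FALSE)
  pop <- init_population(pars, seed = 1)
  pop$strategy[] <- 2L
  for (i in 1:20) {
    res <- abm_iterate(pop, pars)
    pop <- res$population
  }
  expect_true(all(pop$strategy == 2L))
  # same through the compiled path
  run <- run_simulation(pars, seed = 5, max_iter = 50,
                        population = {
                          p0 <- init_population(pars, seed = 5)
                          p0$strategy[] <- 2L
                          p0
                        })
  expect_true(run$converged)
  expect_equal(unname(run$final_composition), c(0, 1, 0))
})

test_that("pure mutation replaces types uniformly regardless of payoffs", {
  pars <- model_params(mu = 1, b_h = 7, p = 0.5, check = FALSE)
  pop <- init_population(pars, seed = 4)
  set.seed(10)
  picks <- integer(0)
  for (i in 1:600) {
    res <- abm_iterate(pop, pars)
    picks <- c(picks, res$new_strategy)
  }
  tab <- table(factor(picks, levels = 1:3))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("the compiled engine and the R iteration agree on update statistics", {
  # from one fixed mixed state, the distribution over next-iteration
  # compositions must be the same for both implementations
  pars <- model_params(b_h = 7, p = 0.5, mu = 0, check = FALSE)
  pop0 <- init_population(pars, seed = 99)
  pop0$strategy <- rep(c(1L, 2L, 3L, 2L), 2)
  set.seed(21)
  n_rep <- 1200
  comp_r <- character(n_rep)
  for (i in seq_len(n_rep)) {
    res <- abm_iterate(pop0, pars)
    comp_r[i] <- paste(tabulate(res$population$strategy, 3), collapse = "-")
  }
  comp_c <- character(n_rep)
  for (i in seq_len(n_rep)) {
    run <- run_simulation(pars, seed = 10000 + i, max_iter = 1,
                          stop_at_homogeneous = FALSE,
                          population = pop0)
    comp_c[i] <- paste(unlist(run$trajectory[2, c("U", "P", "F")]),
                       collapse = "-")
  }
  tab <- table(rep(c("R", "cpp"), each = n_rep), c(comp_r, comp_c))
  suppressWarnings(p <- stats::chisq.test(tab)$p.value)
  expect_gt(p, 1e-3)
})

test_that("payoff-blind imitation reduces to neutral drift", {
  pars <- model_params(b_h = 7, p = 0.5, mu = 0, check = FALSE)
  # a lone universalist among free-riders fixes with probability ~ 1/N
  n_rep <- 400
  fixed <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    pop <- init_population(pars, seed = i)
    pop$strategy <- c(1L, rep(3L, 7))
    run <- run_simulation(pars, seed = 5000 + i, max_iter = 5000,
                          neutral = TRUE, population = pop)
    fixed[i] <- run$final_composition[["U"]] == 1
  }
  phat <- mean(fixed)
  se <- sqrt(phat * (1 - phat) / n_rep)
  expect_lt(abs(phat - 1 / 8), 4 * max(se, 0.01))
})

test_that("runs converge, cap, and average exactly as specified", {
  pars <- model_params(b_h = 3, p = 0.5)
  # single-strategy space converges immediately
  run0 <- run_simulation(pars, core_strategies()[3, ], seed = 1)
  expect_true(run0$converged)
  expect_equal(run0$iterations, 0)
  expect_equal(unname(run0$final_composition), 1)
  # mutation-free runs reach a homogeneous state within the cap (small N)
  for (s in 1:10) {
    run <- run_simulation(model_params(b_h = 3, p = 0.5, mu = 0,
                                       check = FALSE), seed = s)
    expect_true(run$converged)
    expect_equal(sum(run$final_composition == 1), 1)
  }
  # capped runs report the mean composition of the trailing window
  pars_m <- model_params(b_h = 3, p = 0.5, mu = 0.5, check = FALSE)
  run_m <- run_simulation(pars_m, seed = 3, max_iter = 300,
                          average_last = 100, stop_at_homogeneous = FALSE)
  expect_false(run_m$converged)
  tr <- run_m$trajectory
  manual <- colMeans(tr[tr$iteration > 200, c("U", "P", "F")]) / 8
  expect_equal(unname(run_m$final_composition), unname(manual))
  expect_equal(sum(run_m$final_composition), 1, tolerance = 1e-12)
})

test_that("group sizes and population size are conserved through a run", {
  pars <- model_params(n = 8, k = 4, b_h = 3, p = 0.6, mu = 0.01,
                       check = FALSE)
  run <- run_simulation(pars, seed = 17, max_iter = 500,
                        stop_at_homogeneous = FALSE)
  totals <- rowSums(run$trajectory[, -1])
  expect_true(all(totals == pars$N))
})

test_that("sweep designs enumerate the prescribed grids", {
  d <- abm_design()
  expect_equal(attr(d, "total_runs"), 352000)
  expect_equal(nrow(d), 1760)
  expect_setequal(unique(d$n[d$manipulation == "group-size"]),
                  c(4, 8, 16, 32, 64))
  expect_setequal(unique(d$k[d$manipulation == "fragmentation"]),
                  c(2, 4, 8, 16, 32))
  expect_true(all(d$N[d$manipulation == "fragmentation"] == 128))
  # a one-cell design with a few runs produces a one-row summary
  d1 <- abm_design("group-size", p_grid = 0.8, bh_grid = 3,
                   runs_per_cell = 3)[1, ]
  s1 <- sweep_abm(d1, base_seed = 2, keep_runs = TRUE)
  expect_equal(nrow(s1), 1)
  runs <- attr(s1, "runs")
  expect_equal(nrow(runs), 3)
  expect_equal(s1$share_U, mean(runs$share_U))
  # the resource guard refuses unscaled designs
  expect_error(sweep_abm(abm_design()), "guard")
})

test_that("ABM seeds derive deterministically and runs reproduce", {
  expect_identical(coopevo:::derive_seed(1, 5, 7),
                   coopevo:::derive_seed(1, 5, 7))
  a <- run_simulation(model_params(b_h = 4), seed = 123)
  b <- run_simulation(model_params(b_h = 4), seed = 123)
  expect_identical(a$final_composition, b$final_composition)
  expect_identical(a$trajectory, b$trajectory)
})
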