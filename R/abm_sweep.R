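#' Agent-based sweep design
#'
#' Enumerates the cells of an ABM parameter sweep. The full design couples
#' two population manipulations — group size (`k = 8` groups of
#' `n = 4, 8, 16, 32, 64`) and fragmentation (`N = 128` agents split into
#' `k = 2, 4, 8, 16, 32` groups) — with grids over boundary fluidity
#' (`p = 0.5, 0.55, ..., 1.0`) and helping benefit (`b_h = 1, 1.2, ..., 4`)
#' at 200 runs per cell, for 352,000 independent simulation slots in total.
#' `scale` shrinks the runs per cell (rounded up, minimum 1) for desk-scale
#' replication; coarser grids can be passed directly.
#'
#' @param manipulation `"group-size"`, `"fragmentation"`, or `"both"`.
#' @param p_grid,bh_grid Numeric grids.
#' @param runs_per_cell Runs per parameter combination.
#' @param scale Multiplier applied to `runs_per_cell`.
#' @return `data.frame` of cells with columns `manipulation`, `n`, `k`,
#'   `N`, `p`, `b_h`, `runs`; attribute `total_runs` carries the number of
#'   run slots.
#' @examples
#' d <- abm_design()
#' attr(d, "total_runs")  # 352000
#' @export
abm_design <- function(manipulation = c("both", "group-size", "fragmentation"),
                       p_grid = seq(0.5, 1, by = 0.05),
                       bh_grid = seq(1, 4, by = 0.2),
                       runs_per_cell = 200, scale = 1) {
  manipulation <- match.arg(manipulation)
  runs <- max(1L, as.integer(ceiling(runs_per_cell * scale)))
  pops <- list()
  if (manipulation %in% c("both", "group-size")) {
    pops$`group-size` <- data.frame(manipulation = "group-size",
                                    n = c(4L, 8L, 16L, 32L, 64L), k = 8L)
  }
  if (manipulation %in% c("both", "fragmentation")) {
    ks <- c(2L, 4L, 8L, 16L, 32L)
    pops$fragmentation <- data.frame(manipulation = "fragmentation",
                                     n = 128L %/% ks, k = ks)
  }
  pops <- do.call(rbind, pops)
  grid <- expand.grid(cell = seq_len(nrow(pops)), p = p_grid, b_h = bh_grid)
  out <- cbind(pops[grid$cell, ], p = grid$p, b_h = grid$b_h, runs = runs)
  out$N <- out$n * out$k
  rownames(out) <- NULL
  out <- out[, c("manipulation", "n", "k", "N", "p", "b_h", "runs")]
  attr(out, "total_runs") <- sum(out$runs)
  out
}

# deterministic per-run seed below 2^31, derived from base seed, cell, run
derive_seed <- function(base_seed, cell, run) {
  as.integer((as.numeric(base_seed) * 7919 + cell * 104729 + run * 131) %%
               2147483629)
}

#' Run an agent-based parameter sweep
#'
#' Executes [run_simulation()] for every cell of a design (see
#' [abm_design()]) and summarizes each cell: mean final type shares,
#' convergence rate, and mean iterations to convergence/cap. Per-run seeds
#' are derived deterministically from `base_seed`, the cell index, and the
#' run index, so sweeps are reproducible and trivially parallelizable.
#'
#' @param design `data.frame` of cells from [abm_design()] (columns `n`,
#'   `k`, `p`, `b_h`, `runs`; extra columns are carried through).
#' @param params Base [model_params()]; `n`, `k`, `p`, `b_h` are overridden
#'   per cell.
#' @param base_seed Integer base seed.
#' @param max_iter Iteration cap per run.
#' @param strategies Strategy set.
#' @param max_total_runs Resource guard: refuse designs with more run slots
#'   than this unless raised explicitly (the full design has 352,000 slots
#'   and is not desk-scale).
#' @param keep_runs If `TRUE`, attach the per-run table as attribute
#'   `"runs"`.
#' @param progress Print a line per completed cell.
#' @return `data.frame`, one row per cell: design columns plus
#'   `share_<strategy>` means, `convergence_rate`, `mean_iterations`.
#' @export
sweep_abm <- function(design, params = model_params(), base_seed = 1,
                      max_iter = 2000, strategies = core_strategies(),
                      max_total_runs = 10000, keep_runs = FALSE,
                      progress = FALSE) {
  total <- sum(design$runs)
  if (total > max_total_runs) {
    stop(sprintf(paste0("design has %d run slots, above the guard of %d; ",
                        "raise `max_total_runs` to opt in to large sweeps"),
                 total, max_total_runs))
  }
  pars <- as_coop_params(params, check = FALSE)
  share_cols <- paste0("share_", strategies$name)
  cell_rows <- vector("list", nrow(design))
  run_rows <- if (keep_runs) vector("list", nrow(design)) else NULL
  for (i in seq_len(nrow(design))) {
    pars$n <- as.integer(design$n[i]); pars$k <- as.integer(design$k[i])
    pars$N <- pars$n * pars$k
    pars$p <- design$p[i]; pars$b_h <- design$b_h[i]
    nr <- design$runs[i]
    shares <- matrix(NA_real_, nr, nrow(strategies))
    conv <- logical(nr); iters <- integer(nr)
    for (r in seq_len(nr)) {
      res <- run_simulation(pars, strategies,
                            seed = derive_seed(base_seed, i, r),
                            max_iter = max_iter, record_every = 1)
      shares[r, ] <- res$final_composition
      conv[r] <- res$converged
      iters[r] <- res$iterations
    }
    cell <- design[i, , drop = FALSE]
    cell[share_cols] <- as.list(colMeans(shares))
    cell$convergence_rate <- mean(conv)
    cell$mean_iterations <- mean(iters)
    cell_rows[[i]] <- cell
    if (keep_runs) {
      rr <- design[rep(i, nr), c("n", "k", "p", "b_h"), drop = FALSE]
      rr$run <- seq_len(nr)
      rr$seed <- vapply(seq_len(nr), function(r) derive_seed(base_seed, i, r), integer(1))
      rr$converged <- conv
      rr$iterations <- iters
      rr[share_cols] <- shares
      run_rows[[i]] <- rr
    }
    if (progress) message(sprintf("sweep_abm: cell %d / %d", i, nrow(design)))
  }
  out <- do.call(rbind, cell_rows)
  rownames(out) <- NULL
  if (keep_runs) attr(out, "runs") <- do.call(rbind, run_rows)
  out
}
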