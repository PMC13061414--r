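#' Run one simulation replicate
#'
#' Initializes the population and iterates the breeding cycle on the
#' compiled engine, recording a summary every `thin` cycles.  Runs are
#' deterministic given `(params, scenario, seed)`.  With
#' `equilibrium_check = TRUE` the run is advanced in chunks and stopped
#' early once [detect_equilibrium()] fires on the evolving allele means
#' (chunking does not change the random-draw sequence).
#'
#' @param params Parameter list (see [default_parameters()]).
#' @param scenario Scenario list (see [scenario_config()]).
#' @param seed Integer RNG seed; defaults to the scenario seed.
#' @param n_cycles Number of breeding cycles; defaults to
#'   `params$n_cycles`.
#' @param thin Record a summary every `thin` cycles (1 = every cycle).
#' @param equilibrium_check Stop early when all allele means have
#'   flattened (off by default; the fixed run length is the primary
#'   stopping rule).
#' @param eq_window,eq_tol Window (in records) and tolerance for the
#'   equilibrium detector.
#' @return A `dolsim_run`: configuration echo, `records` (one row per
#'   recorded cycle), `equilibrium` (means over the final 10 percent of
#'   records), the final population state, and the seed.
#' @section Extinction: if the population dies out (no breeders,
#'   subordinates or floaters), an error of class `dolsim_extinction` is
#'   signalled carrying the cycle at which it occurred.
#' @export
#' @examples
#' p <- default_parameters(N_b = 50, n_cycles = 200)
#' r <- run_replicate(p, scenario_config("KS_GA", "DOL"), seed = 1,
#'                    thin = 10)
#' r$equilibrium[["mean_dispersal"]]
run_replicate <- function(params, scenario = scenario_config(),
                          seed = scenario$seed,
                          n_cycles = params$n_cycles, thin = 100L,
                          equilibrium_check = FALSE, eq_window = 50L,
                          eq_tol = 1e-4) {
  cfg <- validate_parameters(params, scenario)
  params <- cfg$params
  scenario <- cfg$scenario
  n_cycles <- as.integer(n_cycles)
  thin <- as.integer(thin)
  ep <- engine_params(params, scenario)

  set.seed(seed)
  state <- init_population(params, scenario)

  allele_cols <- c("mean_alpha", "mean_beta", "mean_beta_0", "mean_beta_R",
                   "mean_gamma_0", "mean_gamma_R")
  records <- NULL
  extinct <- NULL
  if (!equilibrium_check) {
    res <- cpp_simulate(state, ep, n_cycles, thin)
    records <- res$records
    state <- res$state
    extinct <- res$extinct_cycle
  } else {
    chunk <- max(thin, as.integer(eq_window) * thin)
    done <- 0L
    recs <- list()
    while (done < n_cycles) {
      step <- min(chunk, n_cycles - done)
      res <- cpp_simulate(state, ep, step, thin)
      recs[[length(recs) + 1L]] <- res$records
      state <- res$state
      done <- done + step
      if (!is.null(res$extinct_cycle)) {
        extinct <- res$extinct_cycle
        break
      }
      series <- do.call(rbind, recs)
      colnames(series) <- record_columns()
      if (detect_equilibrium(series[, allele_cols, drop = FALSE],
                             window = eq_window, tol = eq_tol))
        break
    }
    records <- do.call(rbind, recs)
  }
  records <- as.data.frame(records)
  colnames(records) <- record_columns()

  if (!is.null(extinct)) {
    stop(errorCondition(
      sprintf("population went extinct at cycle %d", extinct),
      cycle = extinct, records = records,
      class = c("dolsim_extinction", "error", "condition")))
  }

  structure(list(params = params, scenario = scenario, seed = seed,
                 n_cycles = n_cycles, thin = thin, records = records,
                 equilibrium = equilibrium_summary(records),
                 final_state = state),
            class = "dolsim_run")
}

#' Detect equilibrium in allele-mean trajectories
#'
#' Declares equilibrium when, for every column of the series, the absolute
#' OLS slope over the last `window` records is below `tol` and the window
#' mean changed by less than `tol` relative to the preceding window.
#' Returns `FALSE` (never `TRUE`) when fewer than two windows of records
#' exist.
#'
#' @param series Matrix or data frame of allele means, one row per
#'   record.
#' @param window Number of records per window.
#' @param tol Flatness tolerance (per-record slope and window-mean
#'   change).
#' @return Logical.
#' @export
detect_equilibrium <- function(series, window, tol) {
  series <- as.matrix(series)
  n <- nrow(series)
  if (n < 2 * window) return(FALSE)
  x <- seq_len(window)
  for (j in seq_len(ncol(series))) {
    y <- series[(n - window + 1):n, j]
    prev <- series[(n - 2 * window + 1):(n - window), j]
    if (anyNA(y) || anyNA(prev)) return(FALSE)
    slope <- stats::cov(x, y) / stats::var(x)
    if (!(abs(slope) < tol && abs(mean(y) - mean(prev)) < tol))
      return(FALSE)
  }
  TRUE
}

#' Deterministic replicate seed derivation
#'
#' Stable integer hash of (master seed, cell index, replicate index), so a
#' grid can be reproduced or dispatched in parallel with identical seed
#' assignment.
#'
#' @param master_seed Integer master seed.
#' @param cell Cell index (1-based).
#' @param rep Replicate index (1-based).
#' @return A positive integer below 2^31.
#' @export
derive_seed <- function(master_seed, cell, rep) {
  p <- 2147483647
  h <- as.numeric(master_seed) %% p
  h <- (h * 69069 + as.numeric(cell)) %% p
  h <- (h * 69069 + as.numeric(rep)) %% p
  as.integer(h) + 1L
}

#' Run a scenario/parameter grid with replicates
#'
#' Cartesian product of the supplied grid values, each cell run for
#' `n_replicates` replicates with seeds derived deterministically from
#' `master_seed`.  Grid names may refer to parameters (e.g. `m`, `x_h`)
#' or scenario switches (e.g. `benefit_mode`, `fecundity_mode`).
#' Per-cell failures (including extinctions) are collected and reported
#' without aborting the grid.
#'
#' @param params Base parameter list.
#' @param scenario Base scenario.
#' @param grid Named list of values to cross, e.g.
#'   `list(m = c(0.1, 0.2, 0.3), x_h = c(3, 5, 7))`.
#' @param n_replicates Replicates per cell; defaults to
#'   `params$n_replicates`.
#' @param master_seed Master seed for replicate seed derivation.
#' @param n_cycles,thin Passed to [run_replicate()].
#' @return A `dolsim_grid`: `cells` (data frame of cell definitions),
#'   `runs` (list over cells of lists over replicates), and `failures`.
#' @export
run_grid <- function(params, scenario = scenario_config(), grid,
                     n_replicates = params$n_replicates, master_seed = 1L,
                     n_cycles = params$n_cycles, thin = 100L) {
  stopifnot(is.list(grid), length(grid) > 0, !is.null(names(grid)))
  cells <- expand.grid(grid, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  scen_keys <- c("benefit_mode", "fecundity_mode", "dispersal_norm")
  runs <- vector("list", nrow(cells))
  failures <- list()
  for (ci in seq_len(nrow(cells))) {
    p <- params
    s <- scenario
    for (key in names(cells)) {
      if (key %in% scen_keys) {
        s[[key]] <- cells[[key]][ci]
      } else if (key %in% names(p)) {
        p[[key]] <- cells[[key]][ci]
      } else {
        config_error(key, "unknown grid key")
      }
    }
    cell_runs <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      sd <- derive_seed(master_seed, ci, r)
      cell_runs[[r]] <- tryCatch(
        run_replicate(p, s, seed = sd, n_cycles = n_cycles, thin = thin),
        error = function(e) {
          failures[[length(failures) + 1L]] <<-
            list(cell = ci, rep = r, seed = sd,
                 message = conditionMessage(e))
          NULL
        })
    }
    runs[[ci]] <- cell_runs
  }
  structure(list(cells = cells, runs = runs, failures = failures,
                 master_seed = master_seed, n_replicates = n_replicates),
            class = "dolsim_grid")
}

#' @export
print.dolsim_grid <- function(x, ...) {
  cat(sprintf("dolsim grid: %d cells x %d replicates (master seed %d), %d failures\n",
              nrow(x$cells), x$n_replicates, x$master_seed,
              length(x$failures)))
  print(x$cells)
  invisible(x)
}

#' Flatten a grid result to a list of runs
#'
#' @param grid A `dolsim_grid`.
#' @return List of successful `dolsim_run` objects.
#' @export
grid_runs <- function(grid) {
  out <- unlist(grid$runs, recursive = FALSE)
  out[!vapply(out, is.null, logical(1))]
}
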