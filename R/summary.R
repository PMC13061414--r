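# Per-cycle summary records and tabular output.

record_columns <- function() {
  c("cycle", "pop_size", "n_breeders", "n_helpers", "n_floaters",
    "mean_alpha", "sd_alpha", "mean_beta", "sd_beta",
    "mean_beta_0", "sd_beta_0", "mean_beta_R", "sd_beta_R",
    "mean_gamma_0", "sd_gamma_0", "mean_gamma_R", "sd_gamma_R",
    "mean_neutral", "sd_neutral",
    "mean_dispersal", "mean_help", "mean_task_defense",
    "group_size_mean", "group_size_sd", "n_occupied",
    "survival_all", "survival_breeder", "survival_helper",
    "survival_floater", "rank_ratio", "relatedness")
}

pop_sd <- function(x) {
  n <- length(x)
  if (n == 0) return(NA_real_)
  mn <- sum(x) / n
  v <- sum(x * x) / n - mn * mn
  sqrt(max(0, v))
}

#' Summarize a population state
#'
#' Computes the per-cycle summary record: allele means and population SDs
#' over all alive individuals, mean phenotypic dispersal over subordinates
#' and floaters, mean help and mean defensive-task probability over
#' subordinates, group size mean and (across-group, population) SD over
#' occupied territories, floater count, realized survival fractions (from
#' the supplied death tallies), the helper/floater dominance-rank ratio,
#' and the neutral-locus breeder-helper relatedness regression slope.
#' Empty classes yield `NA`, never an error; relatedness is `NA` with
#' fewer than two breeder-helper pairs or zero breeder-side variance.
#'
#' @param state A population state (mid-cycle, after breeder replacement,
#'   or at a cycle boundary).
#' @param params,scenario Validated configuration.
#' @param tally Optional survival tallies (as produced by
#'   [survival_step()]); without them the survival fields are `NA`.
#' @param cycle Cycle number stamped on the record.
#' @return Named numeric vector with the columns of the run time series.
#' @export
summarize_state <- function(state, params, scenario = scenario_config(),
                            tally = NULL, cycle = state$cycle) {
  breeders <- state$breeder[!is.na(state$breeder)]
  subs_all <- unlist(state$subs)
  fl <- state$floaters
  alive <- c(breeders, subs_all, fl)
  nb <- length(breeders)
  ns <- length(subs_all)
  nf <- length(fl)
  ntot <- length(alive)
  ind <- state$ind

  rec <- stats::setNames(rep(NA_real_, length(record_columns())),
                         record_columns())
  rec["cycle"] <- cycle
  rec["pop_size"] <- ntot
  rec["n_breeders"] <- nb
  rec["n_helpers"] <- ns
  rec["n_floaters"] <- nf

  for (l in c("alpha", "beta", "beta_0", "beta_R", "gamma_0", "gamma_R",
              "neutral")) {
    if (ntot > 0) {
      x <- ind[[l]][alive]
      rec[paste0("mean_", l)] <- sum(x) / ntot
      rec[paste0("sd_", l)] <- pop_sd(x)
    }
  }

  nonb <- c(subs_all, fl)
  if (length(nonb) > 0) {
    D <- if (scenario$dispersal_norm == "SCALAR") {
      pmin(1, pmax(0, ind$beta[nonb]))
    } else {
      1 / (1 + exp(ind$beta_R[nonb] * ind$age[nonb] - ind$beta_0[nonb]))
    }
    rec["mean_dispersal"] <- mean(D)
  }
  if (ns > 0) {
    rec["mean_help"] <- mean(pmax(0, ind$alpha[subs_all]))
    rec["mean_task_defense"] <-
      mean(1 / (1 + exp(ind$gamma_R[subs_all] * ind$age[subs_all] -
                          ind$gamma_0[subs_all])))
  }

  occ <- which(!is.na(state$breeder))
  rec["n_occupied"] <- length(occ)
  if (length(occ) > 0) {
    N <- 1 + lengths(state$subs)[occ]
    rec["group_size_mean"] <- mean(N)
    rec["group_size_sd"] <- pop_sd(N)
  }

  if (!is.null(tally)) {
    atr <- tally$atrisk_b + tally$atrisk_s + tally$atrisk_f
    srv <- tally$surv_b + tally$surv_s + tally$surv_f
    if (atr > 0) rec["survival_all"] <- srv / atr
    if (tally$atrisk_b > 0)
      rec["survival_breeder"] <- tally$surv_b / tally$atrisk_b
    if (tally$atrisk_s > 0)
      rec["survival_helper"] <- tally$surv_s / tally$atrisk_s
    if (tally$atrisk_f > 0)
      rec["survival_floater"] <- tally$surv_f / tally$atrisk_f
  }

  if (ns > 0 && nf > 0) {
    hw <- ifelse(ind$task[subs_all] == TASK_WORK,
                 pmax(0, ind$alpha[subs_all]), 0)
    rank_help <- dominance_value(ind$age[subs_all], params$y_h, hw)
    rank_float <- dominance_value(ind$age[fl], params$y_h, 0)
    if (sum(rank_float) > 0)
      rec["rank_ratio"] <- mean(rank_help) / mean(rank_float)
  }

  pairs_x <- numeric(0)
  pairs_y <- numeric(0)
  for (g in seq_along(state$breeder)) {
    b <- state$breeder[g]
    sg <- state$subs[[g]]
    if (is.na(b) || length(sg) == 0) next
    pairs_x <- c(pairs_x, rep(ind$neutral[b], length(sg)))
    pairs_y <- c(pairs_y, ind$neutral[sg])
  }
  rec["relatedness"] <- estimate_relatedness(cbind(pairs_x, pairs_y))
  rec
}

#' Equilibrium summary of a run time series
#'
#' Column means over the final fraction of recorded cycles (default the
#' last 10 percent), `NA`s removed per column.  The window is the
#' operational definition of "at equilibrium" for all reported statistics.
#'
#' @param records Data frame of per-cycle summary records.
#' @param frac Fraction of records forming the window.
#' @return Named numeric vector of window means.
#' @export
equilibrium_summary <- function(records, frac = 0.1) {
  n <- nrow(records)
  if (n == 0) return(stats::setNames(rep(NA_real_, ncol(records)),
                                     colnames(records)))
  k <- max(1, ceiling(frac * n))
  w <- records[(n - k + 1):n, , drop = FALSE]
  colMeans(w, na.rm = TRUE)
}

#' Tabulate an evolved task reaction norm
#'
#' Evaluates the task-choice probability at replica-averaged reaction-norm
#' alleles over a dominance grid, for plotting or export.
#'
#' @param gamma_0,gamma_R Averaged allelic values of the task norm.
#' @param R_grid Numeric grid of dominance values.
#' @return Data frame with columns `R` and `T` (defense probability).
#' @export
#' @examples
#' reaction_norm_table(0, 0.5, seq(0, 10, by = 1))
reaction_norm_table <- function(gamma_0, gamma_R, R_grid) {
  data.frame(R = as.numeric(R_grid),
             T = 1 / (1 + exp(gamma_R * as.numeric(R_grid) - gamma_0)))
}

# ---- tabular writers -------------------------------------------------------

write_tsv_with_header <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", dec = ".")
  invisible(path)
}

#' Write a replicate time series to TSV
#'
#' Tab-separated with a header row, `.` decimal separator, `NA` for
#' missing values, and the full configuration plus seed echoed as
#' `#`-prefixed comment lines.
#'
#' @param run A `dolsim_run` from [run_replicate()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_timeseries <- function(run, path) {
  hdr <- c(config_lines(run$params, run$scenario),
           paste0("replicate_seed = ", run$seed))
  write_tsv_with_header(run$records, path, hdr)
}

#' Read back a TSV written by the package
#'
#' @param path File path.
#' @return Data frame of the tabular content (comment headers skipped).
#' @export
read_timeseries <- function(path) {
  utils::read.delim(path, comment.char = "#", sep = "\t",
                    stringsAsFactors = FALSE)
}

# One row per replicate: scenario cell descriptors plus equilibrium means.
replicate_summary_table <- function(runs) {
  rows <- lapply(runs, function(r) {
    data.frame(benefit_mode = r$scenario$benefit_mode,
               fecundity_mode = r$scenario$fecundity_mode,
               m = r$params$m, x_h = r$params$x_h, N_b = r$params$N_b,
               seed = r$seed, n_cycles = r$n_cycles,
               t(r$equilibrium))
  })
  do.call(rbind, rows)
}

#' Write per-replicate equilibrium summaries to TSV
#'
#' @param runs List of `dolsim_run` objects.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_summary <- function(runs, path) {
  df <- replicate_summary_table(runs)
  hdr <- c(config_lines(runs[[1]]$params, runs[[1]]$scenario),
           paste0("n_replicates = ", length(runs)))
  write_tsv_with_header(df, path, hdr)
}

#' Aggregate replicate runs into an equilibrium table
#'
#' Groups replicates by scenario cell (benefit mode, fecundity mode,
#' baseline mortality, defense cost) and reports the across-replicate
#' mean and SD of the main equilibrium statistics: dispersal, survival,
#' group size, floater count, helper/floater rank ratio, relatedness,
#' help and task probability.
#'
#' @param runs List of `dolsim_run` objects (e.g. flattened from
#'   [run_grid()]).
#' @return Data frame with one row per cell.
#' @export
grid_table <- function(runs) {
  df <- replicate_summary_table(runs)
  metrics <- c("mean_dispersal", "survival_all", "group_size_mean",
               "n_floaters", "rank_ratio", "relatedness", "mean_help",
               "mean_task_defense", "mean_gamma_R")
  cell <- interaction(df$benefit_mode, df$fecundity_mode, df$m, df$x_h,
                      drop = TRUE)
  out <- lapply(split(seq_len(nrow(df)), cell), function(idx) {
    sub <- df[idx, , drop = FALSE]
    row <- sub[1, c("benefit_mode", "fecundity_mode", "m", "x_h", "N_b")]
    row$n_replicates <- length(idx)
    for (mtc in metrics) {
      row[[paste0(mtc, "_mean")]] <- mean(sub[[mtc]], na.rm = TRUE)
      row[[paste0(mtc, "_sd")]] <- stats::sd(sub[[mtc]], na.rm = TRUE)
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write the aggregated equilibrium table to TSV
#'
#' @param runs List of `dolsim_run` objects.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_grid_table <- function(runs, path) {
  df <- grid_table(runs)
  write_tsv_with_header(df, path, "dolsim equilibrium grid table")
}

#' @export
print.dolsim_run <- function(x, ...) {
  cat(sprintf("dolsim run: %s / %s, m = %g, x_h = %g, N_b = %d, %d cycles (seed %d)\n",
              x$scenario$benefit_mode, x$scenario$fecundity_mode,
              x$params$m, x$params$x_h, x$params$N_b, x$n_cycles, x$seed))
  eq <- x$equilibrium
  cat(sprintf("  equilibrium: dispersal %.3f, help %.3f, group size %.2f, survival %.3f, relatedness %s\n",
              eq[["mean_dispersal"]], eq[["mean_help"]],
              eq[["group_size_mean"]], eq[["survival_all"]],
              ifelse(is.na(eq[["relatedness"]]), "NA",
                     sprintf("%.3f", eq[["relatedness"]]))))
  invisible(x)
}
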