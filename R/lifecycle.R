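#' Effective cumulative group help under the division-of-labour constraint
#'
#' In the `"DOL"` fecundity mode the breeder's productivity is maximized
#' only when the group's defense and work efforts are roughly balanced:
#' each task's cumulative help is truncated at
#' `H_max = (sum_def + sum_work) / 2 + k_m`, where `k_m` relaxes the
#' requirement of a perfect split.  In `"NO_DOL"` mode the sums pass
#' through unchanged.
#'
#' @param sum_def Cumulative defense help of the group (>= 0).
#' @param sum_work Cumulative work help of the group (>= 0).
#' @param k_m Slack on the balanced split.
#' @param fecundity_mode `"DOL"` or `"NO_DOL"`.
#' @return Numeric vector `c(eff_def, eff_work)`.
#' @export
#' @examples
#' effective_group_help(2, 4, k_m = 0.1, "DOL")  # work capped at 3.1
effective_group_help <- function(sum_def, sum_work, k_m,
                                 fecundity_mode = c("DOL", "NO_DOL")) {
  fecundity_mode <- match.arg(fecundity_mode)
  if (fecundity_mode == "NO_DOL")
    return(c(eff_def = sum_def, eff_work = sum_work))
  h_max <- (sum_def + sum_work) / 2 + k_m
  c(eff_def = min(sum_def, h_max), eff_work = min(sum_work, h_max))
}

#' Mean breeder fecundity
#'
#' Expected number of offspring: baseline fecundity plus a saturating
#' (diminishing-returns) response to the effective cumulative help,
#' `K = k_0 + k_h * S / (1 + S)` with `S = eff_def + eff_work`.  The
#' realized offspring number is Poisson with this mean.
#'
#' @param k_0 Baseline fecundity.
#' @param k_h Help-to-fecundity scale.
#' @param eff_def,eff_work Effective per-task cumulative help.
#' @return Mean fecundity `K`, bounded in `[k_0, k_0 + k_h]`.
#' @export
fecundity_mean <- function(k_0, k_h, eff_def, eff_work) {
  S <- eff_def + eff_work
  k_0 + k_h * S / (1 + S)
}

# ---- per-individual reference engine ---------------------------------------
#
# These step functions execute the breeding cycle one random draw at a time
# in the exact order of the compiled engine (see src/engine.cpp for the
# contract).  They are deliberately unoptimized: their job is to state the
# dynamics in plainly readable form, so the production engine can be tested
# against them bit for bit.

pheno_disp <- function(state, i, scenario) {
  if (scenario$dispersal_norm == "SCALAR") {
    min(1, max(0, state$ind$beta[i]))
  } else {
    1 / (1 + exp(state$ind$beta_R[i] * state$ind$age[i] -
                   state$ind$beta_0[i]))
  }
}

append_individual <- function(state, row) {
  state$ind <- rbind(state$ind, row)
  state
}

#' Reference reproduction step
#'
#' Each breeder produces `Poisson(K)` offspring, where `K` uses the
#' previous cycle's effective help sums; each offspring inherits the
#' breeder's genome through mutation and joins the natal group as an
#' age-1 subordinate (pending its dispersal decision).  Vacant territories
#' produce nothing.
#'
#' @param state Population state.
#' @param params,scenario Validated configuration.
#' @return Updated state.
#' @export
reproduce_step <- function(state, params, scenario) {
  for (g in seq_len(params$N_b)) {
    b <- state$breeder[g]
    if (is.na(b)) next
    eff <- effective_group_help(state$prev_def[g], state$prev_work[g],
                                params$k_m, scenario$fecundity_mode)
    K <- fecundity_mean(params$k_0, params$k_h, eff[[1]], eff[[2]])
    n_off <- stats::rpois(1, K)
    for (j in seq_len(n_off)) {
      gnm <- unlist(state$ind[b, c("alpha", "beta", "beta_0", "beta_R",
                                   "gamma_0", "gamma_R", "neutral")])
      gnm <- mutate_genome(gnm, params$mu, params$sigma_mu)
      row <- new_individuals(1)
      row[1, names(gnm)] <- as.list(gnm)
      row$age <- 1L
      row$role <- ROLE_SUBORDINATE
      row$group <- g
      row$natal <- TRUE
      state <- append_individual(state, row)
      state$subs[[g]] <- c(state$subs[[g]], nrow(state$ind))
    }
  }
  state
}

#' Reference dispersal step
#'
#' Each subordinate (newborns included) becomes a floater with probability
#' equal to its dispersal phenotype D; the floater pool (old floaters
#' first, then fresh dispersers) is then processed in order, each member
#' joining a uniformly random territory as a subordinate with probability
#' 1 - D.  In the group-augmentation-only scenario the newborns that
#' stayed philopatric are finally cross-fostered: their territory labels
#' are shuffled by a random permutation.
#'
#' @inheritParams reproduce_step
#' @return Updated state.
#' @export
dispersal_step <- function(state, params, scenario) {
  newf <- integer(0)
  for (g in seq_len(params$N_b)) {
    keep <- integer(0)
    for (s in state$subs[[g]]) {
      D <- pheno_disp(state, s, scenario)
      if (stats::runif(1) < D) {
        state$ind$natal[s] <- FALSE
        state$ind$role[s] <- ROLE_FLOATER
        state$ind$group[s] <- NA_integer_
        newf <- c(newf, s)
      } else {
        keep <- c(keep, s)
      }
    }
    state$subs[[g]] <- keep
  }
  pool <- c(state$floaters, newf)
  state$floaters <- integer(0)
  for (s in pool) {
    D <- pheno_disp(state, s, scenario)
    if (stats::runif(1) < 1 - D) {
      g2 <- floor(stats::runif(1) * params$N_b) + 1
      if (g2 > params$N_b) g2 <- params$N_b
      state$ind$natal[s] <- FALSE
      state$ind$role[s] <- ROLE_SUBORDINATE
      state$ind$group[s] <- g2
      state$subs[[g2]] <- c(state$subs[[g2]], s)
    } else {
      state$floaters <- c(state$floaters, s)
    }
  }
  if (scenario$benefit_mode == "GA_ONLY") {
    kids <- integer(0)
    labels <- integer(0)
    for (g in seq_len(params$N_b)) {
      for (s in state$subs[[g]]) {
        if (state$ind$age[s] == 1 && state$ind$natal[s]) {
          kids <- c(kids, s)
          labels <- c(labels, g)
        }
      }
    }
    n <- length(kids)
    if (n >= 2) {
      for (i in n:2) {
        j <- floor(stats::runif(1) * i) + 1
        if (j > i) j <- i
        tmp <- labels[i]
        labels[i] <- labels[j]
        labels[j] <- tmp
      }
    }
    if (n >= 1) {
      for (g in seq_len(params$N_b))
        state$subs[[g]] <- setdiff(state$subs[[g]], kids)
      for (k in seq_len(n)) {
        state$subs[[labels[k]]] <- c(state$subs[[labels[k]]], kids[k])
        state$ind$group[kids[k]] <- labels[k]
      }
    }
  }
  state
}

#' Reference task-choice and help step
#'
#' Every subordinate draws the defensive task with probability T (its
#' task reaction norm evaluated at dominance R = age, the work cost not
#' yet being paid) and the work task otherwise; its full help accrues to
#' the group's cumulative sum for that task.  The sums feed the next
#' cycle's reproduction.  Breeders and floaters perform no task.
#'
#' @inheritParams reproduce_step
#' @return Updated state.
#' @export
help_step <- function(state, params) {
  for (g in seq_len(params$N_b)) {
    cd <- 0
    cw <- 0
    for (s in state$subs[[g]]) {
      gnm <- c(gamma_0 = state$ind$gamma_0[s], gamma_R = state$ind$gamma_R[s])
      T_def <- task_probability(gnm, state$ind$age[s])
      H <- max(0, state$ind$alpha[s])
      if (stats::runif(1) < T_def) {
        state$ind$task[s] <- TASK_DEFENSE
        cd <- cd + H
      } else {
        state$ind$task[s] <- TASK_WORK
        cw <- cw + H
      }
    }
    state$prev_def[g] <- cd
    state$prev_work[g] <- cw
  }
  state
}

#' Reference survival step
#'
#' Logistic survival with role-specific arguments: breeders benefit from
#' group size, subordinates additionally pay the defense cost of this
#' cycle's help, floaters get the bare intercept.  Group sizes are frozen
#' at the start of the step and shared by all members of a territory.
#' Death tallies are stored in `state$last_tally`.
#'
#' @inheritParams reproduce_step
#' @return Updated state with the dead removed from all containers.
#' @export
survival_step <- function(state, params) {
  Ng <- vapply(seq_len(params$N_b), function(g)
    (!is.na(state$breeder[g])) + length(state$subs[[g]]), numeric(1))
  one_m <- 1 - params$m
  tally <- list(atrisk_b = 0L, surv_b = 0L, atrisk_s = 0L, surv_s = 0L,
                atrisk_f = 0L, surv_f = 0L)
  for (g in seq_len(params$N_b)) {
    b <- state$breeder[g]
    if (!is.na(b)) {
      S <- one_m / (1 + exp(-params$x_0 - params$x_n * Ng[g]))
      tally$atrisk_b <- tally$atrisk_b + 1L
      if (stats::runif(1) < S) {
        tally$surv_b <- tally$surv_b + 1L
      } else {
        state$breeder[g] <- NA_integer_
      }
    }
    keep <- integer(0)
    for (s in state$subs[[g]]) {
      hd <- if (state$ind$task[s] == TASK_DEFENSE)
        max(0, state$ind$alpha[s]) else 0
      S <- one_m / (1 + exp(-params$x_0 + params$x_h * hd -
                              params$x_n * Ng[g]))
      tally$atrisk_s <- tally$atrisk_s + 1L
      if (stats::runif(1) < S) {
        tally$surv_s <- tally$surv_s + 1L
        keep <- c(keep, s)
      }
    }
    state$subs[[g]] <- keep
  }
  SF <- one_m / (1 + exp(-params$x_0))
  keep <- integer(0)
  for (s in state$floaters) {
    tally$atrisk_f <- tally$atrisk_f + 1L
    if (stats::runif(1) < SF) {
      tally$surv_f <- tally$surv_f + 1L
      keep <- c(keep, s)
    }
  }
  state$floaters <- keep
  state$last_tally <- tally
  state
}

#' Sample floater bidders for breeding vacancies
#'
#' For each vacancy in order, the number of bidders is Poisson with mean
#' `f * N_f / N_b` (the expected number of groups a floater samples times
#' the per-territory floater density), capped by the remaining pool;
#' bidders are drawn without replacement so a floater bids for at most one
#' vacancy per cycle.
#'
#' @param pool Integer identifiers of the available floaters, in pool
#'   order.
#' @param n_vacancies Number of vacancies to sample for.
#' @param N_b Number of breeding territories.
#' @param f Mean number of groups a floater samples.
#' @return List of length `n_vacancies` of identifier vectors.
#' @export
sample_bidders <- function(pool, n_vacancies, N_b, f) {
  lambda <- if (N_b > 0) f * length(pool) / N_b else 0
  out <- vector("list", n_vacancies)
  for (v in seq_len(n_vacancies)) {
    drawn <- sample_one_vacancy(pool, lambda)
    out[[v]] <- drawn$bidders
    pool <- drawn$pool
  }
  out
}

# One vacancy's bidder draw; shared by sample_bidders and fill_vacancies.
sample_one_vacancy <- function(pool, lambda) {
  nb <- stats::rpois(1, lambda)
  nb <- min(nb, length(pool))
  bidders <- integer(0)
  for (j in seq_len(nb)) {
    idx <- floor(stats::runif(1) * length(pool)) + 1
    if (idx > length(pool)) idx <- length(pool)
    bidders <- c(bidders, pool[idx])
    pool <- pool[-idx]
  }
  list(bidders = bidders, pool = pool)
}

#' Reference breeder-replacement step
#'
#' Every territory without a breeder is contested by its surviving
#' subordinates plus a freshly sampled set of floater bidders; the winner
#' is drawn with probability proportional to dominance value (this
#' cycle's work cost included), falling back to a uniform lottery when all
#' dominance values are zero.  Losers stay where they were; a territory
#' with no candidates stays vacant.
#'
#' @inheritParams reproduce_step
#' @return Updated state.
#' @export
fill_vacancies <- function(state, params) {
  lambda <- if (params$N_b > 0)
    params$f * length(state$floaters) / params$N_b else 0
  avail <- state$floaters
  for (g in seq_len(params$N_b)) {
    if (!is.na(state$breeder[g])) next
    drawn <- sample_one_vacancy(avail, lambda)
    bidders <- drawn$bidders
    avail <- drawn$pool
    cand <- c(state$subs[[g]], bidders)
    ncand <- length(cand)
    if (ncand == 0) next
    w <- vapply(cand, function(s) {
      hw <- if (state$ind$task[s] == TASK_WORK)
        max(0, state$ind$alpha[s]) else 0
      dominance_value(state$ind$age[s], params$y_h, hw)
    }, numeric(1))
    tot <- sum(w)
    if (tot <= 0) {
      win <- floor(stats::runif(1) * ncand) + 1
      if (win > ncand) win <- ncand
    } else {
      u <- stats::runif(1) * tot
      acc <- 0
      win <- ncand
      for (k in seq_len(ncand)) {
        acc <- acc + w[k]
        if (u < acc) {
          win <- k
          break
        }
      }
    }
    s <- cand[win]
    state$breeder[g] <- s
    state$ind$role[s] <- ROLE_BREEDER
    state$ind$group[s] <- g
    if (win <= length(state$subs[[g]])) {
      state$subs[[g]] <- state$subs[[g]][-win]
    } else {
      state$floaters <- state$floaters[state$floaters != s]
    }
  }
  state
}

# Survivors ascend one age class; tasks and newborn markers reset.
age_step <- function(state) {
  alive <- c(state$breeder[!is.na(state$breeder)],
             unlist(state$subs), state$floaters)
  state$ind$age[alive] <- state$ind$age[alive] + 1L
  state$ind$task[alive] <- TASK_NONE
  state$ind$natal[alive] <- FALSE
  state
}

#' One full breeding cycle (reference engine)
#'
#' Applies, in order: reproduction, dispersal (with the
#' group-augmentation-only cross-foster), task choice and help
#' accumulation, survival, breeder replacement, and ageing, incrementing
#' the cycle counter.  The per-cycle summary (computed after breeder
#' replacement, before ageing) is stored in `state$last_record`.
#'
#' This per-individual implementation consumes random draws in exactly the
#' same order as the compiled engine used by [run_replicate()]; given the
#' same seed the two produce identical populations.
#'
#' @inheritParams reproduce_step
#' @return Updated state.
#' @export
step_cycle <- function(state, params, scenario) {
  state <- reproduce_step(state, params, scenario)
  state <- dispersal_step(state, params, scenario)
  state <- help_step(state, params)
  state <- survival_step(state, params)
  state <- fill_vacancies(state, params)
  state$cycle <- state$cycle + 1L
  state$last_record <- summarize_state(state, params, scenario,
                                       tally = state$last_tally,
                                       cycle = state$cycle)
  state <- age_step(state)
  state
}
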