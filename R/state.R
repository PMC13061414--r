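# Population state representation shared by the compiled engine and the
# per-individual reference engine.
#
# A state is a list with:
#   ind      data.frame of individuals: the seven allelic values (alpha,
#            beta, beta_0, beta_R, gamma_0, gamma_R, neutral), age, role
#            (0 breeder, 1 subordinate, 2 floater), group (territory index,
#            NA for floaters), task (0 none, 1 defense, 2 work) and the
#            within-cycle philopatric-newborn marker `natal`.
#   breeder  integer vector over territories: row index of the breeder in
#            `ind`, NA when the territory is vacant.
#   subs     list over territories of row-index vectors, in queue order.
#   floaters row-index vector in pool order.
#   prev_def, prev_work  the previous cycle's cumulative help sums per
#            territory (non-cumulative across cycles).
#   cycle    completed-cycle counter.
#
# Row indices in `ind` are private to a representation; two states are the
# same population iff their canonical forms (see canonical_state) agree.

ROLE_BREEDER <- 0L
ROLE_SUBORDINATE <- 1L
ROLE_FLOATER <- 2L

TASK_NONE <- 0L
TASK_DEFENSE <- 1L
TASK_WORK <- 2L

new_individuals <- function(n, alleles = initial_alleles(), neutral = 0,
                            age = 1L, role = ROLE_BREEDER, group = NA_integer_) {
  data.frame(alpha = rep(alleles[["alpha"]], n),
             beta = rep(alleles[["beta"]], n),
             beta_0 = rep(alleles[["beta_0"]], n),
             beta_R = rep(alleles[["beta_R"]], n),
             gamma_0 = rep(alleles[["gamma_0"]], n),
             gamma_R = rep(alleles[["gamma_R"]], n),
             neutral = rep_len(neutral, n),
             age = rep_len(as.integer(age), n),
             role = rep_len(as.integer(role), n),
             group = rep_len(as.integer(group), n),
             task = rep(TASK_NONE, n),
             natal = rep(FALSE, n))
}

#' Initial population state
#'
#' One breeder of age 1 per territory carrying the ancestral allelic values
#' of [initial_alleles()], no subordinates and no floaters.  The neutral
#' (drift-only) locus is drawn i.i.d. standard normal so that the
#' breeder-helper relatedness regression is estimable from the first
#' generations onwards.  Consumes `N_b` normal deviates from the R RNG.
#'
#' @param params Parameter list (uses `N_b`).
#' @param scenario Scenario list (recorded only).
#' @return A population state list (see package internals).
#' @export
init_population <- function(params, scenario = scenario_config()) {
  n <- params$N_b
  ind <- new_individuals(n, neutral = stats::rnorm(n), age = 1L,
                         role = ROLE_BREEDER, group = seq_len(n))
  list(ind = ind,
       breeder = seq_len(n),
       subs = rep(list(integer(0)), n),
       floaters = integer(0),
       prev_def = numeric(n),
       prev_work = numeric(n),
       cycle = 0L)
}

#' Canonical form of a population state
#'
#' Repacks a state so individuals appear in a representation-independent
#' order: territory by territory (breeder first, then subordinates in queue
#' order), then floaters in pool order.  Dead (unreferenced) rows are
#' dropped.  Two states describe the same population exactly when their
#' canonical forms are identical.
#'
#' @param state A population state.
#' @return The state with `ind` reordered and all index structures rebuilt.
#' @export
canonical_state <- function(state) {
  n_t <- length(state$breeder)
  order_idx <- integer(0)
  breeder <- rep(NA_integer_, n_t)
  subs <- vector("list", n_t)
  role <- integer(0)
  group <- integer(0)
  pos <- 0L
  for (g in seq_len(n_t)) {
    b <- state$breeder[g]
    if (!is.na(b)) {
      order_idx <- c(order_idx, b)
      pos <- pos + 1L
      breeder[g] <- pos
      role <- c(role, ROLE_BREEDER)
      group <- c(group, g)
    }
    sg <- state$subs[[g]]
    if (length(sg) > 0) {
      order_idx <- c(order_idx, sg)
      subs[[g]] <- pos + seq_along(sg)
      pos <- pos + length(sg)
      role <- c(role, rep(ROLE_SUBORDINATE, length(sg)))
      group <- c(group, rep(g, length(sg)))
    } else {
      subs[[g]] <- integer(0)
    }
  }
  fl <- state$floaters
  if (length(fl) > 0) {
    order_idx <- c(order_idx, fl)
    floaters <- pos + seq_along(fl)
    role <- c(role, rep(ROLE_FLOATER, length(fl)))
    group <- c(group, rep(NA_integer_, length(fl)))
  } else {
    floaters <- integer(0)
  }
  ind <- state$ind[order_idx,
                   c("alpha", "beta", "beta_0", "beta_R", "gamma_0",
                     "gamma_R", "neutral", "age", "task"),
                   drop = FALSE]
  ind$role <- role
  ind$group <- group
  ind <- ind[, c("alpha", "beta", "beta_0", "beta_R", "gamma_0", "gamma_R",
                 "neutral", "age", "role", "group", "task")]
  rownames(ind) <- NULL
  list(ind = ind, breeder = breeder, subs = subs, floaters = floaters,
       prev_def = as.numeric(state$prev_def),
       prev_work = as.numeric(state$prev_work),
       cycle = as.integer(state$cycle))
}

# Conservation check: every referenced individual sits in exactly one
# container and indices are in range.  Returns TRUE or stops.
check_state <- function(state) {
  refs <- c(state$breeder[!is.na(state$breeder)],
            unlist(state$subs), state$floaters)
  if (anyDuplicated(refs) > 0)
    stop("state corrupt: an individual appears in more than one container")
  if (length(refs) > 0 && (min(refs) < 1 || max(refs) > nrow(state$ind)))
    stop("state corrupt: index out of range")
  if (length(state$subs) != length(state$breeder))
    stop("state corrupt: territory containers disagree in length")
  TRUE
}

state_pop_size <- function(state) {
  sum(!is.na(state$breeder)) + length(unlist(state$subs)) +
    length(state$floaters)
}
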