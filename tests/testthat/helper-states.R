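# Builders for small hand-made population states used across the tests.

# A state with explicit group composition.  `groups` is a list, one element
# per territory: list(breeder = genome-or-NULL, subs = list of genomes),
# each genome a named vector as from genome().  Ages can be attached to a
# genome via attr(g, "age").
make_state <- function(groups, floaters = list(), prev_def = NULL,
                       prev_work = NULL) {
  n_t <- length(groups)
  ind <- new_individuals(0)
  breeder <- rep(NA_integer_, n_t)
  subs <- rep(list(integer(0)), n_t)
  fl <- integer(0)
  add <- function(g, role, grp) {
    row <- new_individuals(1, role = role, group = grp)
    row[1, names(g)] <- as.list(unname(g))
    row$age <- as.integer(attr(g, "age") %||% 1L)
    ind <<- rbind(ind, row)
    nrow(ind)
  }
  for (t in seq_len(n_t)) {
    b <- groups[[t]]$breeder
    if (!is.null(b)) breeder[t] <- add(b, 0L, t)
    for (s in groups[[t]]$subs %||% list())
      subs[[t]] <- c(subs[[t]], add(s, 1L, t))
  }
  for (g in floaters) fl <- c(fl, add(g, 2L, NA_integer_))
  list(ind = ind, breeder = breeder, subs = subs, floaters = fl,
       prev_def = prev_def %||% numeric(n_t),
       prev_work = prev_work %||% numeric(n_t),
       cycle = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

aged <- function(g, age) {
  attr(g, "age") <- age
  g
}

toy_params <- function(...) {
  p <- default_parameters(N_b = 3, n_cycles = 10)
  over <- list(...)
  p[names(over)] <- over
  p
}

# Run the compiled engine directly on a state.
run_engine <- function(state, params, scenario, n_cycles, thin = 1L) {
  cfg <- validate_parameters(params, scenario)
  dolsim:::cpp_simulate(state,
                        dolsim:::engine_params(cfg$params, cfg$scenario),
                        as.integer(n_cycles), as.integer(thin))
}
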