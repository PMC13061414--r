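test_that("division-of-labour cap truncates the task sums at the balanced split", {
  expect_equal(effective_group_help(3, 3, 0.1, "DOL"),
               c(eff_def = 3, eff_work = 3))
  expect_equal(effective_group_help(2, 4, 0.1, "DOL"),
               c(eff_def = 2, eff_work = 3.1))
  expect_equal(effective_group_help(0, 7, 0.1, "NO_DOL"),
               c(eff_def = 0, eff_work = 7))
  expect_equal(effective_group_help(7, 0, 0, "DOL"),
               c(eff_def = 3.5, eff_work = 0))
})

test_that("fecundity saturates between baseline and baseline plus help scale", {
  expect_identical(fecundity_mean(1, 1, 0, 0), 1)
  expect_equal(fecundity_mean(1, 1, 0.5, 0.5), 1.5)
  expect_equal(fecundity_mean(1, 1, 1e9, 1e9), 2, tolerance = 1e-8)
  set.seed(2)
  for (i in 1:50) {
    ed <- stats::rexp(1)
    ew <- stats::rexp(1)
    K <- fecundity_mean(1, 1, ed, ew)
    expect_true(K >= 1 && K <= 2)
  }
})

test_that("with no slack an imbalanced task split never increases fecundity", {
  set.seed(3)
  for (i in 1:100) {
    a <- stats::rexp(1, 1 / 3)
    b <- stats::rexp(1, 1 / 3)
    eff <- effective_group_help(a, b, 0, "DOL")
    bal <- effective_group_help((a + b) / 2, (a + b) / 2, 0, "DOL")
    K_imb <- fecundity_mean(1, 1, eff[[1]], eff[[2]])
    K_bal <- fecundity_mean(1, 1, bal[[1]], bal[[2]])
    expect_lte(K_imb, K_bal + 1e-12)
  }
})

test_that("reproduction is Poisson with the help-dependent mean, vacancies produce nothing", {
  p <- toy_params(N_b = 1, mu = 0)
  s <- scenario_config("KS_GA", "DOL")
  # no previous help: Poisson(k_0 = 1)
  st <- make_state(list(list(breeder = genome())))
  set.seed(5)
  counts <- replicate(4000, {
    out <- reproduce_step(st, p, s)
    length(out$subs[[1]])
  })
  expect_equal(mean(counts), 1, tolerance = 0.05)
  expect_equal(stats::var(counts), 1, tolerance = 0.1)
  # balanced previous help (5, 5) with DoL slack 0.1: mean 1 + 10/11
  st2 <- make_state(list(list(breeder = genome())),
                    prev_def = 5, prev_work = 5)
  set.seed(6)
  counts2 <- replicate(4000, length(reproduce_step(st2, p, s)$subs[[1]]))
  expect_equal(mean(counts2), 1 + 10 / 11, tolerance = 0.05)
  # vacant territory: nothing
  st3 <- make_state(list(list(breeder = NULL)))
  set.seed(7)
  expect_identical(length(reproduce_step(st3, p, s)$subs[[1]]), 0L)
  # offspring are age-1 natal subordinates carrying the breeder genome (mu = 0)
  set.seed(8)
  out <- reproduce_step(make_state(list(list(breeder = genome(alpha = 2,
                                                              neutral = 3)))),
                        p, s)
  if (length(out$subs[[1]]) > 0) {
    kids <- out$ind[out$subs[[1]], ]
    expect_true(all(kids$age == 1L))
    expect_true(all(kids$alpha == 2))
    expect_true(all(kids$neutral == 3))
    expect_true(all(kids$natal))
  }
})

test_that("dispersal empties groups at full dispersal and is identity at philopatry", {
  p <- toy_params(N_b = 2)
  s <- scenario_config()
  st <- make_state(list(
    list(breeder = genome(), subs = list(genome(), genome())),
    list(breeder = genome(), subs = list(genome()))))
  set.seed(1)
  out <- dispersal_step(st, p, s)  # all beta = 1
  expect_identical(lengths(out$subs), c(0L, 0L))
  expect_identical(length(out$floaters), 3L)

  g0 <- genome(beta = 0)
  st2 <- make_state(list(list(breeder = g0, subs = list(g0, g0)),
                         list(breeder = g0)))
  set.seed(2)
  out2 <- dispersal_step(st2, p, s)
  expect_identical(out2$subs, st2$subs)
  expect_identical(out2$floaters, integer(0))
})

test_that("cross-fostering permutes philopatric newborns across groups", {
  p <- toy_params(N_b = 2)
  s <- scenario_config("GA_ONLY")
  g0 <- genome(beta = 0)
  st <- make_state(list(list(breeder = g0, subs = list(g0)),
                        list(breeder = g0, subs = list(g0))))
  st$ind$natal[st$subs[[1]]] <- TRUE
  st$ind$natal[st$subs[[2]]] <- TRUE
  kid1 <- st$subs[[1]]
  stays <- 0L
  n_try <- 400
  set.seed(77)
  for (i in seq_len(n_try)) {
    out <- dispersal_step(st, p, s)
    expect_identical(lengths(out$subs), c(1L, 1L))  # permutation, not loss
    if (kid1 %in% out$subs[[1]]) stays <- stays + 1L
  }
  # 2-element Fisher-Yates: identity permutation with probability 1/2
  expect_gt(stays / n_try, 0.5 - 4 * sqrt(0.25 / n_try))
  expect_lt(stays / n_try, 0.5 + 4 * sqrt(0.25 / n_try))
})

test_that("task draws split help binomially between defense and work sums", {
  # T = 0.25 via gamma_0 = -log(3), gamma_R = 0; 4000 helpers with H = 1
  p <- toy_params(N_b = 1)
  gh <- genome(alpha = 1, gamma_0 = -log(3))
  st <- make_state(list(list(breeder = genome(),
                             subs = rep(list(gh), 4000))))
  set.seed(4)
  out <- help_step(st, p)
  expect_equal(out$prev_def[1] + out$prev_work[1], 4000)
  expect_equal(out$prev_def[1], 1000, tolerance = 0.1)
  # deterministic defense at T = 1 (gamma_0 very large)
  st2 <- make_state(list(list(breeder = genome(),
                              subs = list(genome(alpha = 2,
                                                 gamma_0 = 50)))))
  set.seed(5)
  out2 <- help_step(st2, p)
  expect_equal(unname(out2$prev_def[1]), 2)
  expect_equal(unname(out2$prev_work[1]), 0)
  # no helpers, or helpers with no help: both sums zero
  st3 <- make_state(list(list(breeder = genome(),
                              subs = list(genome(alpha = -1)))))
  set.seed(6)
  out3 <- help_step(st3, p)
  expect_identical(unname(out3$prev_def[1]), 0)
  expect_identical(unname(out3$prev_work[1]), 0)
})

test_that("survival probabilities follow the role-specific logistic forms", {
  # floater closed form: m = 0.1, x_0 = 1.5
  SF <- 0.9 / (1 + exp(-1.5))
  expect_equal(SF, 0.735817, tolerance = 1e-6)
  p <- toy_params(N_b = 1, m = 0.1)
  st <- make_state(list(list(breeder = NULL)),
                   floaters = rep(list(genome()), 4000))
  set.seed(9)
  out <- survival_step(st, p)
  t <- out$last_tally
  expect_identical(t$atrisk_f, 4000L)
  expect_equal(t$surv_f / t$atrisk_f, SF, tolerance = 0.03)
  # m = 1: nobody survives
  p1 <- toy_params(N_b = 1, m = 1)
  set.seed(10)
  out1 <- survival_step(st, p1)
  expect_identical(out1$last_tally$surv_f, 0L)
  expect_identical(length(out1$floaters), 0L)
})

test_that("survival is bounded by 1 - m, decreasing in defense cost, increasing in group size", {
  m <- 0.2; x0 <- 1.5; xh <- 5; xn <- 3
  S_H <- function(H, N) (1 - m) / (1 + exp(-x0 + xh * H - xn * N))
  S_B <- function(N) (1 - m) / (1 + exp(-x0 - xn * N))
  grid_H <- seq(0, 3, by = 0.25)
  # below the double-precision saturation of the logistic the bound and
  # the monotonicities are strict
  grid_N <- 1:9
  for (N in grid_N) {
    vals <- S_H(grid_H, N)
    expect_true(all(vals < 1 - m))
    expect_true(all(diff(vals) < 0))
  }
  for (H in grid_H) {
    vals <- S_H(H, grid_N)
    expect_true(all(diff(vals) > 0))
  }
  expect_true(all(S_H(grid_H, 100) <= 1 - m))
  # Eq-limit: breeder survival approaches 1 - m as N grows
  expect_equal(S_B(500), 1 - m, tolerance = 1e-8)
  # subordinate with no defense cost and x_n = 0 equals the floater form
  expect_equal((1 - m) / (1 + exp(-x0 + xh * 0 - 0 * 4)),
               (1 - m) / (1 + exp(-x0)))
})

test_that("floater bidders are Poisson-sampled without replacement at rate f*N_f/N_b", {
  set.seed(12)
  sets <- sample_bidders(pool = 1:10000, n_vacancies = 300, N_b = 5000,
                         f = 2)
  counts <- lengths(sets)
  expect_equal(mean(counts), 4, tolerance = 0.05)  # 2 * 10000 / 5000
  all_ids <- unlist(sets)
  expect_false(anyDuplicated(all_ids) > 0)  # one bid per floater
  expect_identical(lengths(sample_bidders(integer(0), 5, 100, 2)),
                   rep(0L, 5))
  expect_identical(lengths(sample_bidders(1:50, 5, 100, 0)), rep(0L, 5))
})

test_that("vacancy lottery is dominance-weighted with a uniform fallback", {
  p <- toy_params(N_b = 1, f = 0)
  # two subordinate candidates with dominance 3 and 1: win odds 3:1
  g3 <- aged(genome(), 3)
  g1 <- aged(genome(), 1)
  st <- make_state(list(list(breeder = NULL, subs = list(g3, g1))))
  set.seed(13)
  n <- 20000
  wins_old <- 0L
  for (i in seq_len(n)) {
    out <- fill_vacancies(st, p)
    if (out$breeder[1] == st$subs[[1]][1]) wins_old <- wins_old + 1L
  }
  expect_equal(wins_old / n, 0.75, tolerance = 4 * sqrt(0.1875 / n) / 0.75)
  # single candidate wins with certainty
  st1 <- make_state(list(list(breeder = NULL, subs = list(g1))))
  set.seed(14)
  out <- fill_vacancies(st1, p)
  expect_identical(out$breeder[1], st1$subs[[1]][1])
  # all-zero dominance (age 1, heavy work cost): uniform lottery
  ph <- toy_params(N_b = 1, f = 0, y_h = 10)
  gz <- genome(alpha = 1)
  stz <- make_state(list(list(breeder = NULL, subs = list(gz, gz))))
  stz$ind$task[stz$subs[[1]]] <- dolsim:::TASK_WORK
  set.seed(15)
  wins1 <- 0L
  for (i in 1:4000) {
    out <- fill_vacancies(stz, ph)
    if (out$breeder[1] == stz$subs[[1]][1]) wins1 <- wins1 + 1L
  }
  expect_equal(wins1 / 4000, 0.5, tolerance = 0.1)
})

test_that("a full cycle conserves individuals: survivors plus newborns", {
  p <- toy_params(N_b = 5, m = 0.3)
  for (bm in c("KS_GA", "GA_ONLY")) {
    cfg <- validate_parameters(p, scenario_config(bm))
    set.seed(21)
    st <- init_population(cfg$params, cfg$scenario)
    for (i in 1:6) {
      before <- dolsim:::state_pop_size(st)
      rows_before <- nrow(st$ind)
      st <- step_cycle(st, cfg$params, cfg$scenario)
      births <- nrow(st$ind) - rows_before
      t <- st$last_tally
      deaths <- (t$atrisk_b - t$surv_b) + (t$atrisk_s - t$surv_s) +
        (t$atrisk_f - t$surv_f)
      expect_identical(dolsim:::state_pop_size(st),
                       before + births - deaths)
    }
  }
})

test_that("certain mortality extinguishes the population in one cycle", {
  p <- toy_params(N_b = 4, m = 1)
  cfg <- validate_parameters(p, scenario_config())
  set.seed(30)
  st <- init_population(cfg$params, cfg$scenario)
  st <- step_cycle(st, cfg$params, cfg$scenario)
  expect_identical(dolsim:::state_pop_size(st), 0L)
})
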