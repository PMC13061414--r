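test_that("state summaries compute the documented population statistics", {
  p <- toy_params(N_b = 2)
  s <- scenario_config()
  # 2 occupied groups of sizes 2 and 4: mean 3, population SD 1
  st <- make_state(list(
    list(breeder = genome(), subs = list(genome())),
    list(breeder = genome(), subs = list(genome(), genome(), genome()))))
  rec <- summarize_state(st, p, s)
  expect_equal(rec[["group_size_mean"]], 3)
  expect_equal(rec[["group_size_sd"]], 1)
  expect_identical(rec[["n_floaters"]], 0)
  expect_identical(rec[["pop_size"]], 6)

  # all-breeder state: size 1, SD 0, rank ratio missing
  st2 <- make_state(list(list(breeder = genome()),
                         list(breeder = genome())))
  rec2 <- summarize_state(st2, p, s)
  expect_equal(rec2[["group_size_mean"]], 1)
  expect_equal(rec2[["group_size_sd"]], 0)
  expect_true(is.na(rec2[["rank_ratio"]]))
  expect_true(is.na(rec2[["relatedness"]]))

  # helpers and floaters all at dominance 2: rank ratio exactly 1
  h <- aged(genome(), 2)
  st3 <- make_state(list(list(breeder = genome(), subs = list(h, h))),
                    floaters = list(h, h))
  p1 <- toy_params(N_b = 1)
  rec3 <- summarize_state(st3, p1, s)
  expect_equal(rec3[["rank_ratio"]], 1)
  # dispersal phenotype averaged over subordinates and floaters
  expect_equal(rec3[["mean_dispersal"]], 1)
})

test_that("summary relatedness uses current breeder-helper pairs only", {
  p <- toy_params(N_b = 3)
  s <- scenario_config()
  gb <- function(nv) genome(neutral = nv)
  st <- make_state(list(
    list(breeder = gb(1), subs = list(gb(1), gb(1))),
    list(breeder = gb(-2), subs = list(gb(-2))),
    list(breeder = NULL, subs = list(gb(5)))))  # vacant: no pair
  rec <- summarize_state(st, p, s)
  expect_equal(rec[["relatedness"]], 1)  # clones of their breeders
})

test_that("reaction norm tables evaluate the task norm over a dominance grid", {
  flat <- reaction_norm_table(0, 0, 0:10)
  expect_equal(flat$T, rep(0.5, 11))
  dec <- reaction_norm_table(0.5, 0.8, seq(0, 12, by = 0.5))
  expect_true(all(diff(dec$T) < 0))
  expect_true(all(dec$T > 0 & dec$T < 1))
  empty <- reaction_norm_table(1, 1, numeric(0))
  expect_identical(nrow(empty), 0L)
})

test_that("time series round-trip through the TSV format", {
  p <- default_parameters(N_b = 30, n_cycles = 80)
  r <- run_replicate(p, scenario_config("GA_ONLY"), seed = 4, thin = 10)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_timeseries(r, path)
  back <- read_timeseries(path)
  expect_identical(colnames(back), colnames(r$records))
  # an all-missing column reads back as logical NA; same values either way
  back[] <- lapply(back, as.numeric)
  expect_equal(back, r$records, tolerance = 1e-12,
               ignore_attr = TRUE)
  # configuration echoed in '#' headers
  hdr <- readLines(path, n = 20)
  expect_true(any(grepl("^# m = 0.1$", hdr)))
  expect_true(any(grepl("^# benefit_mode = GA_ONLY$", hdr)))
  expect_true(any(grepl("^# replicate_seed = 4$", hdr)))
})

test_that("replicate summaries and grid aggregation match brute-force recomputation", {
  p <- default_parameters(N_b = 25, n_cycles = 60)
  runs <- lapply(1:3, function(i)
    run_replicate(p, scenario_config("KS_GA"), seed = i, thin = 10))
  df <- dolsim:::replicate_summary_table(runs)
  expect_identical(nrow(df), 3L)
  expect_equal(df$mean_dispersal,
               vapply(runs, function(r)
                 r$equilibrium[["mean_dispersal"]], numeric(1)))

  agg <- grid_table(runs)
  expect_identical(nrow(agg), 1L)
  expect_identical(agg$n_replicates, 3L)
  disp <- vapply(runs, function(r) r$equilibrium[["mean_dispersal"]],
                 numeric(1))
  expect_equal(agg$mean_dispersal_mean, mean(disp))
  expect_equal(agg$mean_dispersal_sd, stats::sd(disp))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary(runs, path)
  expect_equal(read_timeseries(path)$mean_dispersal, disp,
               tolerance = 1e-12)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_grid_table(runs, path2)
  expect_equal(read_timeseries(path2)$mean_dispersal_mean, mean(disp),
               tolerance = 1e-12)
})

test_that("an empty run set still writes a header-only table", {
  p <- default_parameters(N_b = 20, n_cycles = 40)
  r <- run_replicate(p, seed = 1, thin = 10)
  r$records <- r$records[0, ]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_timeseries(r, path)
  back <- read_timeseries(path)
  expect_identical(nrow(back), 0L)
  expect_identical(colnames(back), dolsim:::record_columns())
})

test_that("realized survival fractions converge to the logistic forms when evolution is frozen", {
  # mu = 0, ancestral genes: everyone disperses, no helping, x_n irrelevant
  # at equilibrium every individual survives at the floater closed form
  p <- default_parameters(N_b = 150, mu = 0, m = 0.1)
  r <- run_replicate(p, scenario_config("KS_ONLY"), seed = 6,
                     n_cycles = 400, thin = 1)
  SF <- 0.9 / (1 + exp(-1.5))
  surv <- r$records$survival_all[100:400]
  expect_equal(mean(surv), SF, tolerance = 0.01)
  fl <- r$records$survival_floater[100:400]
  expect_equal(mean(fl, na.rm = TRUE), SF, tolerance = 0.01)
})
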