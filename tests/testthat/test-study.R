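test_that("without clustering all five methods calibrate alike", {
  set.seed(81)
  cfg <- small_config(sigma_u2 = 0)
  pop <- generate_source_population(cfg)
  r <- run_replicate(pop, cfg)
  expect_false(any(r$failed))
  expect_lt(max(r$slope) - min(r$slope), 0.05)
  expect_lt(max(r$citl) - min(r$citl), 0.05)
})

test_that("oracle predictions from the true probabilities calibrate", {
  set.seed(82)
  pop <- generate_source_population(sim_config(icc = 0.30))
  cal <- calibration(pop$data$y, pop$eta)
  expect_lt(abs(cal$slope - 1), 3 * cal$slope_se)
  expect_lt(abs(cal$citl), 3 * cal$citl_se)
})

test_that("RE-zero is more mis-calibrated than RE-integ at high ICC", {
  set.seed(83)
  cfg <- sim_config(icc = 0.30, n_replicates = 10)
  pop <- generate_source_population(cfg)
  out <- do.call(rbind, replicate(10, run_replicate(
    pop, cfg, methods = c("re_zero", "re_integ")), simplify = FALSE))
  rz <- out$slope[out$method == "re_zero"]
  ri <- out$slope[out$method == "re_integ"]
  expect_gt(mean(rz <= ri), 0.5)
})

test_that("run_study is deterministic in its seed and aggregates correctly", {
  cfg <- small_config(icc = 0.10)
  a <- run_study(cfg, iccs = 0.10, seed = 99,
                 methods = c("no_clustering", "re_zero"))
  b <- run_study(cfg, iccs = 0.10, seed = 99,
                 methods = c("no_clustering", "re_zero"))
  expect_identical(a$table, b$table)
  expect_identical(a$replicates, b$replicates)
  expect_equal(nrow(a$replicates), 2 * cfg$n_replicates)
  ## medians recomputable from the replicate rows
  rz <- a$replicates[a$replicates$method == "re_zero", ]
  expect_equal(a$table$slope[a$table$method == "re_zero"],
               median(rz$slope))
  expect_error(run_study(sim_config(icc = 0.1, n_replicates = 0)),
               "n_replicates")
})

test_that("study outputs are written as CSV and JSON", {
  cfg <- small_config(icc = 0.10)
  s <- run_study(cfg, iccs = 0.10, seed = 5, methods = "no_clustering")
  dir <- tempfile()
  write_study_csv(s, dir)
  t1 <- read.csv(file.path(dir, "table1.csv"))
  expect_equal(t1$slope, s$table$slope, tolerance = 1e-12)
  meta <- jsonlite::read_json(file.path(dir, "run.json"))
  expect_equal(meta$seed, 5)
})

test_that("prediction curves show the naive method as the most extreme", {
  set.seed(85)
  cfg <- sim_config(icc = 0.30)
  pop <- generate_source_population(cfg)
  sp <- draw_training_validation(pop, cfg)
  ri <- ri_logistic(sp$training)
  mle <- logistic_mle(sp$training)
  cur <- prediction_curves(list(ri, mle), x1 = seq(-4, 4, by = 0.25))
  expect_setequal(unique(cur$method),
                  c("re_zero", "re_integ", "re_approx", "no_clustering"))
  rz <- cur[cur$method == "re_zero", ]
  rint <- cur[cur$method == "re_integ", ]
  ## monotone in x1, and the naive curve crosses from below to above
  expect_true(all(diff(rz$risk) > 0))
  expect_true(all(diff(rint$risk) > 0))
  hi <- rz$x1 > 2
  expect_true(all(rz$risk[hi] > rint$risk[hi]))
  lo <- rz$x1 < -2
  expect_true(all(rz$risk[lo] < rint$risk[lo]))
})

test_that("fitted models serialise to JSON", {
  d <- make_clustered(K = 6, n_per = 25, seed = 86)
  ri <- ri_logistic(d, order = 21)
  js <- jsonlite::fromJSON(fit_to_json(ri))
  expect_equal(js$sigma_u2, ri$sigma_u2, tolerance = 1e-12)
  expect_equal(unlist(js$coefficients), coef(ri), tolerance = 1e-12)
  path <- tempfile(fileext = ".json")
  fit_to_json(logistic_mle(d), path)
  expect_equal(unlist(jsonlite::read_json(path)$coefficients),
               coef(logistic_mle(d)), tolerance = 1e-10)
})
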