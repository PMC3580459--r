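test_that("span metric implements the bin-count rule on constructed rasters", {
  stim <- 1:40
  # all 40 stimulated neurons spike every 50 ms on [2 s, 8 s] -> span 6 s
  tt <- seq(2000, 7999, by = 50)
  r <- toy_raster(rep(tt, each = 40), rep(stim, length(tt)))
  expect_equal(working_memory_span(r, stimulated_ids = stim, M = 40), 6)
  # exactly M/2 active never qualifies (strict inequality)
  r2 <- toy_raster(rep(tt, each = 20), rep(1:20, length(tt)))
  expect_equal(working_memory_span(r2, stimulated_ids = stim, M = 40), 0)
  # empty raster
  expect_equal(working_memory_span(toy_raster(numeric(0), integer(0)),
                                   stimulated_ids = stim, M = 40), 0)
  # invariance to row order and to non-stimulated spikes
  r3 <- rbind(r, toy_raster(runif(500, 0, 9000), sample(60:100, 500, TRUE)))
  r3 <- r3[sample(nrow(r3)), ]
  expect_equal(working_memory_span(r3, stimulated_ids = stim, M = 40), 6)
  # the 80% alternative rule is stricter
  r4 <- toy_raster(rep(tt, each = 25), rep(1:25, length(tt)))
  expect_equal(working_memory_span(r4, stimulated_ids = stim, M = 40), 6)
  expect_equal(working_memory_span(r4, stimulated_ids = stim, M = 40,
                                   threshold_frac = 0.8), 0)
})

test_that("clinical table ships the 28 calibration records", {
  cl <- clinical_table()
  expect_equal(nrow(cl), 28)
  expect_identical(names(cl), c("drug", "dose_mg", "weeks", "adascog_effect"))
  expect_setequal(unique(cl$weeks), c(12, 26, 52, 78))
  expect_equal(sum(cl$drug == "placebo"), 4)
  expect_equal(cl$adascog_effect[cl$drug == "placebo" & cl$weeks == 12], 0.27)
  expect_equal(cl$adascog_effect[cl$drug == "donepezil" & cl$dose_mg == 5 &
                                 cl$weeks == 12], -1.77)
})

test_that("clinical correlation reproduces closed-form least squares", {
  cl3 <- data.frame(drug = "x", dose_mg = 0, weeks = c(12, 12, 12),
                    adascog_effect = c(-1, -2, -3))
  fit <- correlate_clinical(c(1, 2, 3), cl3)
  expect_equal(fit$r2, 1)
  expect_equal(fit$slope, -1)
  # hand-computed 4-point set against the normal equations
  x <- c(1, 2, 4, 7); y <- c(0.5, -0.2, -1.1, -2.4)
  cl4 <- data.frame(drug = "x", dose_mg = 0, weeks = 12, adascog_effect = y)
  f4 <- correlate_clinical(x, cl4)
  sxx <- sum((x - mean(x))^2); sxy <- sum((x - mean(x)) * (y - mean(y)))
  b <- sxy / sxx; a <- mean(y) - b * mean(x)
  r2 <- 1 - sum((y - a - b * x)^2) / sum((y - mean(y))^2)
  expect_equal(f4$slope, b)
  expect_equal(f4$intercept, a)
  expect_equal(f4$r2, r2)
  # degenerate inputs
  expect_error(correlate_clinical(c(2, 2, 2), cl3), "zero span variance")
  expect_error(correlate_clinical(c(1, 2), cl3[1:2, ]), "insufficient data")
  # nested models: quadratic never fits worse
  set.seed(1)
  x8 <- 1:8; y8 <- -x8 + 0.1 * x8^2 + rnorm(8, 0, 0.2)
  cl8 <- data.frame(drug = "x", dose_mg = 0, weeks = 12, adascog_effect = y8)
  expect_gte(correlate_clinical(x8, cl8, degree = 2)$r2,
             correlate_clinical(x8, cl8, degree = 1)$r2)
})

test_that("DOE screen sizes as 2n runs and finds a planted driver", {
  ranges <- lapply(stats::setNames(1:7, paste0("p", 1:7)),
                   function(i) c(0, 1))
  scr <- doe_screen(ranges, function(p) 3 * p[["p4"]] + 0.01 * p[["p1"]])
  expect_equal(scr$n_runs, 14)
  expect_equal(nrow(scr$design), 14)
  expect_identical(scr$pareto$param[1], "p4")
  # fold-over designs are not orthogonal: the weak p1 term bleeds
  # into the estimate by 0.01 * 3/7
  expect_equal(unname(scr$effects["p4"]), 3, tolerance = 0.005)
  # constant response has zero effects everywhere
  flat <- doe_screen(ranges, function(p) 42)
  expect_true(all(abs(flat$effects) < 1e-12))
  expect_error(doe_screen(list(a = c(1, 1)), identity), "distinct")
})

test_that("DOE screen flags non-finite design points but still ranks", {
  ranges <- list(a = c(0, 1), b = c(0, 1), c = c(0, 1))
  f <- function(p) if (p[["b"]] > 0.5 && p[["c"]] > 0.5) NaN else 2 * p[["a"]]
  expect_warning(scr <- doe_screen(ranges, f), "non-finite")
  expect_identical(scr$pareto$param[1], "a")
})

test_that("response-surface refinement solves a quadratic bowl within budget", {
  target <- c(x = 1.5, y = -2, z = 0.5)
  bowl <- function(p) -sum((p - target)^2)
  out <- optimize_response_surface(c(x = 0.5, y = -1, z = 1), bowl, budget = 50)
  expect_lte(out$n_evals, 50)
  expect_equal(nrow(out$trace), out$n_evals)
  expect_true(all(abs(out$best - target) < 0.01 * pmax(abs(target), 1)))
  # budget 1 returns the evaluated start
  one <- optimize_response_surface(c(x = 0, y = 0, z = 0), bowl, budget = 1)
  expect_equal(one$n_evals, 1)
  expect_equal(unname(one$best), c(0, 0, 0))
})

test_that("sensitivity scan is a faithful one-at-a-time slice", {
  base <- c(a = 1, b = 2)
  f <- function(p) p[["a"]]^2 + p[["b"]]
  sc <- sensitivity_scan("a", c(1), base, f)
  expect_equal(sc$response, f(base))
  sc2 <- sensitivity_scan("a", seq(0, 2, 0.5), base, f)
  expect_equal(sc2$response, seq(0, 2, 0.5)^2 + 2)
  expect_error(sensitivity_scan("zz", 1, base, f), "unknown parameter")
})

test_that("run_condition is reproducible and reports trial statistics", {
  a <- run_condition(NULL, n_trials = 2, base_seed = 3, duration_s = 3)
  b <- run_condition(NULL, n_trials = 2, base_seed = 3, duration_s = 3)
  expect_identical(a$spans, b$spans)
  expect_equal(a$n_trials, 2)
  expect_false(is.na(a$sd_span))
  one <- run_condition(NULL, n_trials = 1, base_seed = 3, duration_s = 3)
  expect_true(is.na(one$sd_span))   # single trial: dispersion undefined
})
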