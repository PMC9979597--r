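test_that("the cost function is a weighted squared scaled relative deviation", {
  sp <- metric_specs(c("rho", "a"), c(0.9, 4.2), weight = c(1, 2))
  expect_equal(cost_function(c(rho = 0.9, a = 4.2), sp), 0)
  one <- metric_specs("rho", 0.9)
  expect_equal(cost_function(c(rho = 0.9 * 1.05), one), 0.25)
  # doubling a weight doubles that metric's contribution
  base <- cost_function(c(rho = 0.95, a = 4.2), sp)
  sp2 <- metric_specs(c("rho", "a"), c(0.9, 4.2), weight = c(2, 2))
  expect_equal(cost_function(c(rho = 0.95, a = 4.2), sp2), 2 * base)
  # invariance under joint rescaling of metric and reference
  spc <- metric_specs("rho", 0.9 * 7)
  expect_equal(cost_function(c(rho = 0.9 * 1.05 * 7), spc), 0.25)
  expect_error(cost_function(c(rho = 1), sp), "missing metric.*a")
  expect_error(metric_specs("x", 0), "nonzero")
})

test_that("training samples are uniform within bounds and seed-deterministic", {
  bounds <- lj_bounds()
  X <- sample_training(bounds, 500, seed = 4)
  expect_equal(dim(X), c(500, 18))
  for (k in seq_len(18)) {
    expect_gte(min(X[, k]), bounds$low[k])
    expect_lte(max(X[, k]), bounds$high[k])
  }
  expect_identical(sample_training(bounds, 500, seed = 4), X)
  deg <- bounds; deg$low[3] <- deg$high[3] <- 0.4
  Xd <- sample_training(deg, 20, seed = 1)
  expect_true(all(Xd[, 3] == 0.4))
  expect_error(sample_training(bounds, 0), "positive")
})

test_that("the optimization loop records crashes, stays in bounds and reproduces exactly", {
  ff <- cogito_ff()
  specs <- metric_specs("d", 1)
  bounds <- lj_bounds(ff)
  crash <- function(params) stop("boom")
  opt <- optimize_lj(crash, specs, bounds, n_train = 5, n_iter = 3,
                     crash_penalty = 1e6, seed = 2)
  expect_length(opt$records, 8)
  expect_true(all(!vapply(opt$records, `[[`, TRUE, "completed")))
  expect_true(all(vapply(opt$records, `[[`, 0, "cost") == 1e6))
  expect_null(opt$best)

  backend <- quadratic_backend(specs, canonical_lj_optimum(ff), bounds)
  o1 <- optimize_lj(backend, specs, bounds, n_train = 8, n_iter = 6, seed = 5)
  o2 <- optimize_lj(backend, specs, bounds, n_train = 8, n_iter = 6, seed = 5)
  expect_identical(as.data.frame(o1), as.data.frame(o2))
  P <- do.call(rbind, lapply(o1$records, `[[`, "params"))
  for (k in seq_len(18)) {
    expect_gte(min(P[, k]), bounds$low[k])
    expect_lte(max(P[, k]), bounds$high[k])
  }
  # n_iter = 0 degenerates to pure random search of length n_train
  o0 <- optimize_lj(backend, specs, bounds, n_train = 6, n_iter = 0, seed = 3)
  expect_length(o0$records, 6)
  P0 <- do.call(rbind, lapply(o0$records, `[[`, "params"))
  X0 <- sample_training(bounds, 6, cogito:::derive_seed(3, "train"))
  expect_equal(unname(P0), unname(X0))
})

test_that("filter-and-average extraction uses only completed low-cost records", {
  p <- seq(0.1, 1.8, by = 0.1)
  names(p) <- paste0("p", 1:18)
  delta <- rep(0.01, 18)
  mkrec <- function(params, completed, cost)
    list(params = params, completed = completed, metrics = NULL, cost = cost)
  opt <- structure(list(records = list(
    mkrec(p, TRUE, 0.5),
    mkrec(p + delta, TRUE, 1.0),
    mkrec(p - delta, TRUE, 0.8),
    mkrec(p + 5, TRUE, 50),          # above threshold
    mkrec(p + 9, FALSE, 1e6)         # crashed
  )), class = "cogito_opt")
  out <- extract_parameters(opt, cost_threshold = 2)
  expect_equal(unname(out), unname(p))        # symmetric deltas cancel
  one <- extract_parameters(opt, cost_threshold = 0.6)
  expect_equal(unname(one), unname(p))        # single survivor verbatim
  # hand-computed mean over the completed below-threshold subset
  hand <- (p + (p + delta) + (p - delta) + (p + 5)) / 4
  expect_equal(unname(extract_parameters(opt, cost_threshold = 100)),
               unname(hand))
  expect_error(extract_parameters(opt, cost_threshold = 0.1), "threshold")
})

test_that("optimization histories persist to tabular text and reload", {
  ff <- cogito_ff()
  specs <- metric_specs("d", 1)
  bounds <- lj_bounds(ff)
  backend <- quadratic_backend(specs, canonical_lj_optimum(ff), bounds)
  opt <- optimize_lj(backend, specs, bounds, n_train = 5, n_iter = 2, seed = 8)
  tf <- tempfile(fileext = ".tsv")
  write_history(opt, tf)
  back <- read_history(tf)
  expect_equal(nrow(back), 7)
  expect_equal(back$cost, vapply(opt$records, `[[`, 0, "cost"),
               tolerance = 1e-12)
  expect_equal(extract_parameters(back, cost_threshold = Inf),
               extract_parameters(opt, cost_threshold = Inf),
               tolerance = 1e-12)
})

test_that("with all weight on one metric, optimization drives that metric to its reference", {
  ff <- cogito_ff()
  specs <- metric_specs(c("primary", "ignored"), c(1.0, 3.0),
                        weight = c(1, 0))
  bounds <- lj_bounds(ff)
  optimum <- canonical_lj_optimum(ff)
  # 'primary' deviates with distance from the optimum; 'ignored' is constantly off
  backend <- function(params) {
    z <- (params[bounds$param] - optimum[bounds$param]) /
      (bounds$high - bounds$low)
    list(completed = TRUE,
         metrics = c(primary = 1.0 * (1 + mean(z^2)), ignored = 99))
  }
  opt <- optimize_lj(backend, specs, bounds, n_train = 20, n_iter = 20,
                     seed = 6)
  expect_lt(abs(opt$best$metrics[["primary"]] - 1.0), 0.01)
  expect_equal(opt$best$cost,
               cost_function(opt$best$metrics, specs))
})

test_that("applying an LJ vector to the force field feeds the evaluator", {
  ff <- cogito_ff()
  pars <- canonical_lj_optimum(ff)
  pars["C3H6.sigma"] <- 0.5
  ff2 <- set_lj_params(ff, pars)
  expect_equal(ff2$lj$sigma[ff2$lj_index["C3H6"]], 0.5)
  expect_equal(mix_lj(ff2, "C3H6", "C3H6")[["sigma"]], 0.5)
  expect_error(set_lj_params(ff, pars[-1]), "every")
})
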