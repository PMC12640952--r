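# Kinetic model fitting: closed-form flow step, grid + refinement search,
# model-object methods.

test_that("closed-form flow scale equals the projection and respects bounds", {
  times <- default_times()
  aif <- default_aif()
  basis <- forward_tissue_curve(aif, 1, 2, 0.1, times)
  tac <- tac_curve(times, 2 * basis$values)
  expect_equal(closed_form_mbf(tac, basis, bounds = c(0, 10)), 2)
  # orthogonal tac clips to zero
  expect_equal(closed_form_mbf(tac_curve(times, rep(0, length(times))), basis), 0)
  neg <- tac_curve(times, -basis$values)
  expect_equal(closed_form_mbf(neg, basis, bounds = c(0, 600)), 0)
  # random case equals an independent least-squares solve
  set.seed(3)
  y <- rnorm(length(times))
  b <- basis$values
  expect_equal(closed_form_mbf(tac_curve(times, y), basis, bounds = c(-1e6, 1e6)),
               unname(coef(lm(y ~ b - 1))), tolerance = 1e-10)
  expect_error(closed_form_mbf(tac, tac_curve(times, rep(0, length(times)))),
               "zero")
})

test_that("noiseless parameter recovery is exact to within 1%", {
  times <- default_times()
  aif <- default_aif()
  tac <- forward_tissue_curve(aif, 300, 2, 0.15, times)
  fit <- fit_rpm1(tac, aif)
  expect_lt(abs(coef(fit)[["mbf"]] - 300) / 300, 0.01)
  expect_lt(abs(coef(fit)[["delay_s"]] - 2), 0.05)
  expect_lt(abs(coef(fit)[["k_decay"]] - 0.15), 0.01)
  expect_true(fit$converged)
})

test_that("refined fit dominates an exhaustive fine-grid oracle", {
  times <- default_times()
  aif <- default_aif()
  grid <- rpm1_grid(aif, times)
  # independent brute-force lattice over (mbf, delay, k)
  oracle_rss <- function(tac) {
    best <- Inf
    for (m in seq(25, 575, by = 25)) for (dl in seq(0, 8, by = 0.5))
      for (k in c(0.02, 0.05, 0.08, 0.12, 0.18, 0.25, 0.4, 0.6)) {
        r <- sum((tac$values -
                    forward_tissue_curve(aif, m, dl, k, times)$values)^2)
        if (r < best) best <- r
      }
    best
  }
  set.seed(11)
  for (i in 1:12) {
    truth <- c(runif(1, 50, 500), runif(1, 0, 6), runif(1, 0.05, 0.35))
    tac <- forward_tissue_curve(aif, truth[1], truth[2], truth[3], times)
    fit <- fit_rpm1(tac, aif, grid = grid)
    expect_lte(fit$rss, oracle_rss(tac) + 1e-9)
    expect_lte(fit$rss, fit$grid_rss + 1e-12)
  }
})

test_that("zero-flow truth stays near zero under noise and rss is bounded", {
  times <- default_times()
  aif <- default_aif()
  set.seed(21)
  for (i in 1:5) {
    noise <- rnorm(length(times), 0, 10)
    fit <- fit_rpm1(tac_curve(times, noise), aif)
    expect_gte(coef(fit)[["mbf"]], 0)
    expect_lt(coef(fit)[["mbf"]], 100)
    expect_lte(fit$rss, sum(noise^2) + 1e-9)
  }
})

test_that("fitted MBF is invariant to common scaling of AIF and TAC", {
  times <- default_times()
  aif <- default_aif()
  tac <- forward_tissue_curve(aif, 250, 1, 0.2, times)
  f1 <- fit_rpm1(tac, aif)
  s <- 3.7
  f2 <- fit_rpm1(tac_curve(times, s * tac$values),
                 tac_curve(times, s * aif$values))
  expect_equal(coef(f1)[["mbf"]], coef(f2)[["mbf"]], tolerance = 1e-6)
})

test_that("MBF error degrades monotonically with noise", {
  times <- default_times()
  aif <- default_aif()
  grid <- rpm1_grid(aif, times)
  clean <- forward_tissue_curve(aif, 300, 2, 0.15, times)$values
  rmse_at <- function(sd) {
    errs <- vapply(1:8, function(s) {
      set.seed(100 + s)
      fit <- fit_rpm1(tac_curve(times, clean + rnorm(length(times), 0, sd)),
                      aif, grid = grid)
      (coef(fit)[["mbf"]] - 300)^2
    }, numeric(1))
    sqrt(mean(errs))
  }
  expect_lt(rmse_at(10), rmse_at(40))
})

test_that("degenerate inputs are rejected", {
  times <- default_times()
  aif <- default_aif()
  zero <- tac_curve(times, rep(0, length(times)))
  tac <- forward_tissue_curve(aif, 100, 1, 0.1, times)
  expect_error(fit_rpm1(tac, zero), "degenerate")
  bad <- tac; bad$values[3] <- NaN
  expect_error(fit_rpm1(bad, aif), "finite")
})

test_that("the model object supports the standard fitted-model methods", {
  times <- default_times()
  aif <- default_aif()
  set.seed(5)
  tac <- tac_curve(times, forward_tissue_curve(aif, 280, 2, 0.12, times)$values +
                     rnorm(length(times), 0, 4))
  fit <- fit_rpm1(tac, aif)
  expect_s3_class(fit, "rpm1")
  expect_named(coef(fit), c("mbf", "delay_s", "k_decay"))
  expect_equal(fitted(fit) + residuals(fit), tac$values)
  expect_equal(deviance(fit), sum(residuals(fit)^2), tolerance = 1e-8)
  expect_equal(predict(fit), fitted(fit))
  expect_length(predict(fit, times_s = seq(0, 30, 0.5)), 61L)
  sm <- summary(fit)
  expect_equal(sm$sigma, sqrt(fit$rss / (length(times) - 3)))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(length(times), 3L))
  expect_output(print(fit), "MBF")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
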