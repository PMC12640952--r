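# CAD-RADS grading, threshold derivation, statistics, patient classification.

test_that("stenosis-to-grade bins match the reporting standard", {
  expect_equal(cadrads_from_stenosis(0), 0L)
  expect_equal(cadrads_from_stenosis(50), 3L)
  expect_equal(cadrads_from_stenosis(100), 5L)
  expect_equal(cadrads_from_stenosis(24), 1L)
  expect_equal(cadrads_from_stenosis(25), 2L)
  expect_equal(cadrads_from_stenosis(49), 2L)
  expect_equal(cadrads_from_stenosis(69), 3L)
  expect_equal(cadrads_from_stenosis(70), 4L)
  expect_equal(cadrads_from_stenosis(99), 4L)
  # fractional reads truncate toward zero before binning
  expect_equal(cadrads_from_stenosis(69.5), 3L)
  expect_equal(cadrads_from_stenosis(24.9), 1L)
  expect_equal(cadrads_from_stenosis(c(0, 10, 30, 60, 80, 100)),
               c(0L, 1L, 2L, 3L, 4L, 5L))
  expect_error(cadrads_from_stenosis(101), "0, 100")
  expect_error(cadrads_from_stenosis(-1), "0, 100")
})

test_that("obstructive stenosis is grade 3 and above", {
  expect_false(is_obstructive(2L))
  expect_true(is_obstructive(3L))
  expect_true(is_obstructive(5L))
  expect_equal(is_obstructive(0:5), c(F, F, F, T, T, T))
  expect_error(is_obstructive(6L), "0..5")
})

test_that("perfectly separated classes put every replicate threshold in the gap", {
  tb <- data.frame(patient_id = sprintf("P%02d", 1:20),
                   cadrads = rep(c(4L, 0L), each = 10),
                   territory_mbf = c(seq(100, 145, 5), seq(250, 295, 5)))
  res <- bootstrap_youden_threshold(tb, n_boot = 200, seed = 2)
  expect_true(all(res$replicates > 145 & res$replicates < 250))
  expect_gte(res$ci_low, 145)
  expect_lte(res$ci_high, 250)
  expect_lte(res$ci_low, res$threshold)
  expect_lte(res$threshold, res$ci_high)
})

test_that("per-replicate thresholds equal the brute-force ROC oracle", {
  tb <- data.frame(patient_id = sprintf("P%d", 1:8),
                   cadrads = c(4L, 4L, 4L, 4L, 0L, 0L, 0L, 0L),
                   territory_mbf = c(120, 180, 210, 140, 260, 230, 190, 310))
  # replicate 0: the un-resampled table
  expect_equal(ccperf:::youden_threshold(tb$territory_mbf, tb$cadrads == 4L),
               youden_oracle(tb$territory_mbf, tb$cadrads == 4L))
  # oracle equality across random resamples
  set.seed(13)
  for (i in 1:50) {
    take <- sample(8, replace = TRUE)
    v <- tb$territory_mbf[take]; p <- tb$cadrads[take] == 4L
    if (all(p) || all(!p) || length(unique(v)) < 2) next
    expect_equal(ccperf:::youden_threshold(v, p), youden_oracle(v, p))
  }
  expect_error(bootstrap_youden_threshold(
    data.frame(patient_id = "a", cadrads = 0L, territory_mbf = 1)), "both")
})

test_that("bootstrap threshold is deterministic given the seed", {
  tb <- two_normal_table(n_per = 100, seed = 4)
  r1 <- bootstrap_youden_threshold(tb, n_boot = 100, seed = 9)
  r2 <- bootstrap_youden_threshold(tb, n_boot = 100, seed = 9)
  expect_identical(r1$replicates, r2$replicates)
})

test_that("Spearman correlation handles ties and matches a rank-then-Pearson oracle", {
  x <- c(1, 2, 2, 3, 5, 5, 5, 8)
  y <- c(10, 9, 9, 7, 6, 6, 4, 1)
  got <- spearman_rho(x, y)
  rx <- rank(x); ry <- rank(y)
  rho_oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(got$rho, rho_oracle, tolerance = 1e-12)
  t_o <- rho_oracle * sqrt((8 - 2) / (1 - rho_oracle^2))
  expect_equal(got$p, 2 * pt(-abs(t_o), 6), tolerance = 1e-12)
  # strictly decreasing: rho = -1, shuffling rows changes nothing
  expect_equal(spearman_rho(1:10, 10:1)$rho, -1)
  set.seed(2)
  ord <- sample(8)
  expect_equal(spearman_rho(x[ord], y[ord])$rho, got$rho)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:2, 2:1), "at least 3")
})

test_that("pooled t-test matches the hand formula and its symmetries", {
  a <- c(10, 12, 9, 11, 13); b <- c(14, 15, 13, 17)
  got <- unpaired_ttest(a, b)
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_equal(got$t, t_hand, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(t_hand), 7), tolerance = 1e-12)
  swapped <- unpaired_ttest(b, a)
  expect_equal(swapped$t, -got$t)
  expect_equal(swapped$p, got$p)
  same <- unpaired_ttest(c(1, 1), c(1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  ident <- unpaired_ttest(a, a)
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
})

test_that("patient classification follows the rule order", {
  terr <- function(mbf, grades) data.frame(
    vessel = c("LAD", "LCX", "RCA"), representative_mbf = mbf,
    cadrads = grades)
  # obstructive LAD with territory MBF 178: flow-limiting
  c1 <- classify_patient(terr(c(178, 280, 300), c(4L, 0L, 0L)))
  expect_equal(c1$label, "flow_limiting")
  # all clear
  expect_equal(classify_patient(terr(c(280, 260, 300), c(0L, 0L, 0L)))$label,
               "normal")
  # obstructive but preserved flow everywhere
  expect_equal(classify_patient(terr(c(250, 280, 300), c(4L, 0L, 0L)))$label,
               "discordant_preserved")
  # non-obstructive with one low territory, no segment report: focal MVD
  expect_equal(classify_patient(terr(c(150, 280, 300), c(0L, 1L, 0L)))$label,
               "mvd_focal")
  # grades 0, 10 of 16 segments at 120 (global mean 130): diffuse MVD
  seg <- rep(120, 16); seg[11:16] <- c(160, 150, 140, 120, 110, 100)
  geo <- aha_segment_angles()
  rep16 <- data.frame(segment = geo$segment, ring = geo$ring, mean_mbf = seg,
                      pixel_count = 100L, area_pixels = 100L, excluded = FALSE)
  attr(rep16, "global_mean_mbf") <- 130
  class(rep16) <- c("aha_report", "data.frame")
  c5 <- classify_patient(terr(c(120, 130, 125), c(0L, 0L, 0L)),
                         aha_report = rep16)
  expect_equal(c5$label, "mvd_diffuse")
  expect_error(classify_patient(terr(rep(NA_real_, 3), c(0L, 0L, 0L))),
               "evaluable")
})

test_that("raising the threshold never reduces the ischemic count", {
  set.seed(8)
  vals <- runif(200, 50, 400)
  counts <- vapply(c(100, 150, 200, 250, 300),
                   function(th) sum(classify_ischemic(vals, th)), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("cohort summary conserves counts and recovers MVD truth", {
  tab <- cached("big_cohort", function()
    simulate_cohort(cohort_config(n_patients = 700L, seed = 3L)))
  cs <- cohort_summary(tab, threshold = 200)
  expect_equal(sum(cs$counts), length(unique(tab$patient_id)))
  expect_equal(nrow(cs$patients), length(unique(tab$patient_id)))
  # each patient gets exactly one label
  expect_true(all(cs$patients$label %in%
                    c("normal", "flow_limiting", "mvd_focal", "mvd_diffuse",
                      "discordant_preserved")))
  # obstructed territories run lower than non-obstructed (3 SE)
  ts <- cs$territory_stats
  se <- sqrt(sum(ts$sd_mbf^2 / ts$n))
  expect_lt(ts$mean_mbf[ts$group == "obstructed"] + 3 * se,
            ts$mean_mbf[ts$group == "non_obstructed"])
  expect_lt(cs$spearman$rho, 0)
  # truth-label recovery at the default separations
  expect_gte(cs$mvd_confusion$sensitivity, 0.9)
  expect_gte(cs$mvd_confusion$specificity, 0.9)
})
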