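# Polar-map conversion, AHA-16 reporting, territory statistics.

# assemble an aha_report directly (for oracle tests that need arbitrary
# segment values)
make_report <- function(mean_mbf, excluded = rep(FALSE, 16)) {
  geo <- aha_segment_angles()
  df <- data.frame(segment = geo$segment, ring = geo$ring,
                   mean_mbf = mean_mbf, pixel_count = 100L,
                   area_pixels = 100L, excluded = excluded)
  attr(df, "global_mean_mbf") <- mean(mean_mbf[!excluded])
  class(df) <- c("aha_report", "data.frame")
  df
}

truth_polar <- function(study, n_radius = 24L, n_angle = 72L) {
  masks <- heart_masks(study$truth$masks, study$spacing_mm)
  lm <- detect_landmarks(study, masks,
                         septal_angle_deg = study$truth$septal_angle_deg)
  build_polar_map(study$truth$mbf_map, masks, lm, n_radius = n_radius,
                  n_angle = n_angle)
}

test_that("segment geometry tiles each ring over 360 degrees", {
  geo <- aha_segment_angles()
  for (rg in c("basal", "mid", "apical")) {
    g <- geo[geo$ring == rg, ]
    span <- sum(ifelse(g$hi > g$lo, g$hi - g$lo, 360 - g$lo + g$hi))
    expect_equal(span, 360)
  }
  expect_equal(nrow(geo), 16L)
  terr <- aha_territories()
  expect_setequal(unlist(terr), 1:16)
  expect_equal(sum(lengths(terr)), 16L)
})

test_that("the generated LAD adjacency reproduces the canonical ten pairs", {
  pairs <- aha_adjacent_pairs("LAD")
  printed <- rbind(c(1, 2), c(1, 7), c(1, 8), c(2, 7), c(2, 8), c(7, 8),
                   c(13, 14), c(7, 13), c(8, 13), c(8, 14))
  printed <- printed[order(printed[, 1], printed[, 2]), ]
  expect_equal(unname(pairs), unname(printed))
})

test_that("uniform phantom maps to a flat polar raster preserving the mean", {
  st <- default_noiseless_study()
  pol <- truth_polar(st)
  vals <- pol$raster[is.finite(pol$raster)]
  expect_gt(length(vals), 0)
  expect_lt(max(abs(vals - 300)) / 300, 0.01)
  myo_mean <- mean(st$truth$mbf_map[st$truth$masks == 1L])
  expect_lt(abs(mean(vals) - myo_mean) / myo_mean, 0.05)
})

test_that("polar mean tracks the voxel mean within 5% on a smooth gradient", {
  cfg <- phantom_config(noise_sd_hu = 0, sector_truth = list(
    list(angle_deg = c(0, 120), slices = c(1L, 8L), mbf = 150, delay_s = 2, k_decay = 0.15),
    list(angle_deg = c(120, 240), slices = c(1L, 8L), mbf = 250, delay_s = 2, k_decay = 0.15),
    list(angle_deg = c(240, 360), slices = c(1L, 8L), mbf = 350, delay_s = 2, k_decay = 0.15)))
  st <- build_phantom(cfg, seed = 3)
  pol <- truth_polar(st)
  vals <- pol$raster[is.finite(pol$raster)]
  myo_mean <- mean(st$truth$mbf_map[st$truth$masks == 1L])
  expect_lt(abs(mean(vals) - myo_mean) / myo_mean, 0.05)
})

test_that("a deficit at a known angle appears at the matching polar angles", {
  # deficit image angles [60, 180]; origin 120 -> polar [300, 360) u [0, 60)
  cfg <- deficit_phantom_config(angle_deg = c(60, 180), noise_sd_hu = 0)
  st <- build_phantom(cfg, seed = 2)
  pol <- truth_polar(st)
  col_mean <- colMeans(pol$raster, na.rm = TRUE)
  low_bins <- which(col_mean < 225)
  expected <- which(pol$angle_deg >= 300 | pol$angle_deg < 60)
  bin_deg <- 360 / length(col_mean)
  for (b in low_bins) {
    expect_true(min(abs(c(pol$angle_deg[b] - pol$angle_deg[expected],
                          360 - abs(pol$angle_deg[b] - pol$angle_deg[expected])))) <=
                  bin_deg)
  }
  expect_setequal(setdiff(expected, low_bins), integer(0))
})

test_that("fully sampled uniform map gives 16 included equal segments", {
  st <- default_noiseless_study()
  rep16 <- aha16_report(truth_polar(st))
  expect_equal(nrow(rep16), 16L)
  expect_false(any(rep16$excluded))
  expect_false(17 %in% rep16$segment)
  expect_lt(diff(range(rep16$mean_mbf)) / 300, 0.01)
  expect_equal(attr(rep16, "global_mean_mbf"), mean(rep16$mean_mbf))
})

test_that("the 30% sampling rule excludes exactly the starved segment", {
  st <- default_noiseless_study()
  pol <- truth_polar(st)
  # blank 75% of segment 13's pixels (apical ring, angles [315, 45))
  rings <- ccperf:::polar_rings(nrow(pol$raster))
  rsel <- which(rings == "apical")
  asel <- which(pol$angle_deg >= 315 | pol$angle_deg < 45)
  cells <- expand.grid(r = rsel, a = asel)
  kill <- cells[seq_len(ceiling(0.75 * nrow(cells))), ]
  pol$raster[as.matrix(kill)] <- NA_real_
  rep16 <- aha16_report(pol)
  expect_true(rep16$excluded[rep16$segment == 13])
  expect_false(any(rep16$excluded[rep16$segment != 13]))
})

test_that("rotating the polar map by 60 degrees permutes ring segments cyclically", {
  cfg <- phantom_config(noise_sd_hu = 0, sector_truth = list(
    list(angle_deg = c(0, 120), slices = c(1L, 8L), mbf = 150, delay_s = 2, k_decay = 0.15),
    list(angle_deg = c(120, 240), slices = c(1L, 8L), mbf = 250, delay_s = 2, k_decay = 0.15),
    list(angle_deg = c(240, 360), slices = c(1L, 8L), mbf = 350, delay_s = 2, k_decay = 0.15)))
  st <- build_phantom(cfg, seed = 3)
  pol <- truth_polar(st)
  n_angle <- ncol(pol$raster)
  shift <- n_angle / 6  # 60 degrees
  rot <- pol
  rot$raster <- pol$raster[, c((shift + 1):n_angle, 1:shift)]
  r0 <- aha16_report(pol)
  r1 <- aha16_report(rot)
  expect_equal(r1$mean_mbf[1:6], r0$mean_mbf[c(2:6, 1)])
  expect_equal(r1$mean_mbf[7:12], r0$mean_mbf[c(8:12, 7)])
})

test_that("territory representative MBF equals brute-force pair enumeration", {
  set.seed(31)
  for (i in 1:1000) {
    mbf <- runif(16, 50, 400)
    excl <- runif(16) < 0.25
    if (all(excl)) excl[sample(16, 1)] <- FALSE
    rep16 <- make_report(mbf, excl)
    for (tr in c("LAD", "RCA", "LCX")) {
      pairs <- aha_adjacent_pairs(tr)
      vals <- apply(pairs, 1, function(p) {
        if (excl[p[1]] || excl[p[2]]) return(NA_real_)
        mean(mbf[p])
      })
      got <- territory_mbf(rep16, tr)
      if (all(is.na(vals))) {
        expect_false(got$evaluable)
      } else {
        expect_equal(got$value, min(vals, na.rm = TRUE))
        expect_equal(mean(mbf[got$pair]), got$value)
      }
    }
  }
})

test_that("uniform territory values give the flat representative", {
  rep16 <- make_report(rep(300, 16))
  t <- territory_mbf(rep16, "LAD")
  expect_equal(t$value, 300)
  expect_true(t$evaluable)
})

test_that("relative MBF normalises to the best territory and is scale-free", {
  mbf <- rep(300, 16)
  lad <- aha_territories()$LAD
  mbf[lad] <- 150  # LAD representative 150, others 300
  rep16 <- make_report(mbf)
  rel <- relative_mbf(rep16)
  expect_equal(attr(rel, "reference_mbf"), 300)
  expect_equal(rel$relative_mbf[rel$segment %in% lad], rep(0.5, 6))
  # uniform report: everything relative 1
  relu <- relative_mbf(make_report(rep(250, 16)))
  expect_true(all(abs(relu$relative_mbf - 1) < 1e-12))
  # doubling all MBF leaves relative values unchanged
  rel2 <- relative_mbf(make_report(2 * mbf))
  expect_equal(rel2$relative_mbf, rel$relative_mbf)
  expect_error(relative_mbf(make_report(rep(0, 16))), "> 0")
})

test_that("ischemia flagging is strict at the threshold and vectorised", {
  expect_true(classify_ischemic(199.9, 200))
  expect_false(classify_ischemic(200, 200))
  v <- c(150, 200, 250, NA)
  expect_equal(classify_ischemic(v, 200), c(TRUE, FALSE, FALSE, NA))
  expect_error(classify_ischemic(100, 0), "threshold")
})
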