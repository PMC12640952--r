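# Synthetic phantom: AIF synthesis, forward kinetic model, study rendering,
# beam-hardening artifact simulation.

test_that("gamma-variate AIF peaks at onset + alpha*beta, is zero pre-onset and linear in amplitude", {
  times <- seq(0, 30, by = 0.25)
  p <- aif_params(amplitude = 200, onset_s = 4, alpha = 3, beta = 2)
  aif <- make_aif(p, times)
  expect_equal(times[which.max(aif$values)], 4 + 3 * 2)
  expect_equal(max(aif$values), 200)
  expect_true(all(aif$values[times <= 4] == 0))
  # doubling amplitude doubles every sample and the AUC
  aif2 <- make_aif(aif_params(amplitude = 400, onset_s = 4, alpha = 3, beta = 2),
                   times)
  expect_equal(aif2$values, 2 * aif$values)
  expect_equal(curve_auc(aif2), 2 * curve_auc(aif))
  expect_error(make_aif(p, c(0, 1, 1, 2)), "strictly increasing")
  expect_error(aif_params(amplitude = -1), "amplitude")
  expect_error(aif_params(recirc_fraction = 1), "recirc_fraction")
})

test_that("recirculation adds a delayed bump without moving the first-pass peak", {
  times <- seq(0, 40, by = 0.5)
  base <- make_aif(aif_params(), times)
  rec <- make_aif(aif_params(recirc_fraction = 0.3, recirc_delay_s = 12), times)
  expect_equal(times[which.max(rec$values)], times[which.max(base$values)])
  expect_true(all(rec$values >= base$values))
  expect_gt(sum(rec$values - base$values), 0)
})

test_that("forward tissue curve matches independent quadrature oracles", {
  times <- default_times()
  aif <- default_aif()
  # mbf = 0 gives the zero curve; negative parameters are rejected
  expect_equal(forward_tissue_curve(aif, 0, 2, 0.1, times)$values,
               rep(0, length(times)))
  expect_error(forward_tissue_curve(aif, -1, 0, 0.1, times), "mbf")
  expect_error(forward_tissue_curve(aif, 100, 0, -0.1, times), "k_decay")
  expect_equal(forward_tissue_curve(aif, 100, 0, 0.1, times)$values[1], 0)

  # k = 0: reduces to the cumulative integral of the delayed AIF; check
  # against direct trapezoidal integration
  delay <- 2.5
  ct <- forward_tissue_curve(aif, 120, delay, 0, times)
  g <- approx(aif$times_s + delay, aif$values, xout = times, yleft = 0,
              yright = aif$values[length(times)])$y
  oracle <- (120 / 6000) *
    vapply(seq_along(times), function(i) {
      if (i == 1) return(0)
      sum(diff(times[1:i]) * (g[1:(i - 1)] + g[2:i]) / 2)
    }, numeric(1))
  expect_equal(ct$values, oracle, tolerance = 1e-12)

  # boxcar AIF, zero delay: closed form f*H*(1 - exp(-k t))/k
  tt <- seq(0, 20, by = 0.1)
  H <- 100; k <- 0.2
  box <- tac_curve(tt, rep(H, length(tt)))
  ct2 <- forward_tissue_curve(box, 300, 0, k, tt)
  closed <- (300 / 6000) * H * (1 - exp(-k * tt)) / k
  expect_lt(max(abs(ct2$values[-1] - closed[-1]) / closed[-1]), 0.01)
})

test_that("forward model is linear in MBF", {
  times <- default_times()
  aif <- default_aif()
  for (k in c(0, 0.1, 0.3)) {
    c1 <- forward_tissue_curve(aif, 150, 1.5, k, times)$values
    c2 <- forward_tissue_curve(aif, 300, 1.5, k, times)$values
    expect_equal(c2, 2 * c1, tolerance = 1e-12)
  }
})

test_that("phantom voxels reproduce the forward model exactly when clean", {
  st <- default_noiseless_study()
  tr <- st$truth
  times <- st$frame_times_s
  fwd <- forward_tissue_curve(tr$aif, 300, 2, 0.15, times)$values
  idx <- which(tr$masks == 1L)
  for (i in idx[c(1, 250, length(idx))]) {
    ci <- arrayInd(i, dim(tr$masks))
    tac <- st$frames[ci[1], ci[2], ci[3], ]
    expect_equal(tac, 75 + fwd, tolerance = 1e-12, ignore_attr = TRUE)
  }
  # aorta mean HU at the AIF peak frame = baseline + AIF peak
  pk <- which.max(tr$aif$values)
  ao <- tr$masks == 3L
  expect_equal(mean(st$frames[, , , pk][ao]),
               tr$aif_params$baseline_hu + max(tr$aif$values))
})

test_that("phantom truth payload is complete and consistent with sectors", {
  cfg <- deficit_phantom_config(noise_sd_hu = 0)
  st <- build_phantom(cfg, seed = 2)
  tr <- st$truth
  myo <- tr$masks == 1L
  expect_false(anyNA(tr$mbf_map[myo]))
  expect_true(all(is.na(tr$mbf_map[!myo])))
  # per-voxel truth equals the sector specification everywhere
  expect_true(all(tr$mbf_map[myo][tr$sector_id[myo] == 1] == 150))
  expect_true(all(tr$mbf_map[myo][tr$sector_id[myo] == 2] == 300))
  expect_setequal(unique(as.vector(tr$masks)), 0:3)
})

test_that("identical seeds give bit-identical studies", {
  cfg <- phantom_config(noise_sd_hu = 12, motion_amplitude_vox = 2)
  s1 <- build_phantom(cfg, seed = 7)
  s2 <- build_phantom(cfg, seed = 7)
  expect_identical(s1$frames, s2$frames)
  expect_identical(s1$truth$shifts, s2$truth$shifts)
  s3 <- build_phantom(cfg, seed = 8)
  expect_false(identical(s1$frames, s3$frames))
})

test_that("overlapping sectors and invalid geometry are rejected", {
  expect_error(phantom_config(sector_truth = list(
    list(angle_deg = c(0, 200), slices = c(1, 8), mbf = 300, delay_s = 2, k_decay = 0.1),
    list(angle_deg = c(180, 360), slices = c(1, 8), mbf = 100, delay_s = 2, k_decay = 0.1))),
    "overlap")
  expect_error(phantom_config(myo_inner_mm = 25, myo_outer_mm = 20), "myo_inner")
  expect_error(phantom_config(n_frames = 5), "n_frames")
})

test_that("beam-hardening artifact is identity for zero coeffs or zero enhancement", {
  st <- default_noiseless_study()
  fr <- st$frames[, , , 15]
  expect_identical(apply_beam_hardening(fr, c(0, 0, 0), st$truth$masks,
                                        enhancement = 300), fr)
  expect_identical(apply_beam_hardening(fr, c(0, 0.2, 0), st$truth$masks,
                                        enhancement = 0), fr)
})

test_that("cupping increases myocardial HU variance at peak enhancement", {
  st <- default_noiseless_study()
  pk <- which.max(st$truth$aif$values)
  fr <- st$frames[, , , pk]
  myo <- st$truth$masks == 1L
  cupped <- apply_beam_hardening(fr, c(0, 0.15, 0), st$truth$masks,
                                 enhancement = max(st$truth$aif$values))
  expect_gt(var(cupped[myo]), var(fr[myo]))
})
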