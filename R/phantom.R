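#' Gamma-variate arterial input function parameters
#'
#' The aortic input is modelled as a gamma-variate enhancement curve
#' \eqn{A \cdot ((t-t_0)/(\alpha\beta))^\alpha e^{\alpha - (t-t_0)/\beta}} for
#' \eqn{t > t_0}, normalised so the peak enhancement equals `amplitude` at
#' \eqn{t_0 + \alpha\beta}. An optional recirculation bump adds a delayed,
#' scaled copy of the first pass.
#'
#' @param baseline_hu pre-contrast blood HU (carried as metadata; curve values
#'   are enhancement above this baseline).
#' @param amplitude peak enhancement above baseline, HU. Must be > 0.
#' @param onset_s bolus arrival time, seconds, >= 0.
#' @param alpha dimensionless gamma-variate shape, > 0.
#' @param beta gamma-variate time scale, seconds, > 0.
#' @param recirc_fraction amplitude fraction of the recirculation bump, in
#'   \[0, 1).
#' @param recirc_delay_s delay of the recirculation bump, seconds.
#' @return object of class `aif_params`.
#' @export
aif_params <- function(baseline_hu = 50, amplitude = 350, onset_s = 4,
                       alpha = 3, beta = 2, recirc_fraction = 0,
                       recirc_delay_s = 10) {
  if (amplitude <= 0) stopf("amplitude must be > 0")
  if (alpha <= 0 || beta <= 0) stopf("alpha and beta must be > 0")
  if (onset_s < 0) stopf("onset_s must be >= 0")
  if (recirc_fraction < 0 || recirc_fraction >= 1)
    stopf("recirc_fraction must be in [0, 1)")
  structure(list(baseline_hu = baseline_hu, amplitude = amplitude,
                 onset_s = onset_s, alpha = alpha, beta = beta,
                 recirc_fraction = recirc_fraction,
                 recirc_delay_s = recirc_delay_s),
            class = "aif_params")
}

gamma_variate <- function(t, amplitude, onset_s, alpha, beta) {
  tt <- t - onset_s
  v <- numeric(length(t))
  pos <- tt > 0
  # peak-normalised gamma variate: value = A at tt = alpha*beta
  v[pos] <- amplitude * (tt[pos] / (alpha * beta))^alpha *
    exp(alpha - tt[pos] / beta)
  v
}

#' Synthesise an arterial input function
#'
#' @param params an [aif_params()] object.
#' @param times_s strictly increasing sample times, seconds.
#' @return a [tac_curve()] of enhancement above baseline; identically zero for
#'   `t <= onset_s`.
#' @examples
#' aif <- make_aif(aif_params(amplitude = 300, onset_s = 4), seq(0, 30, 1))
#' aif$times_s[which.max(aif$values)]  # peak at onset + alpha*beta = 10 s
#' @export
make_aif <- function(params, times_s) {
  stopifnot(inherits(params, "aif_params"))
  if (any(diff(times_s) <= 0)) stopf("times_s must be strictly increasing")
  v <- gamma_variate(times_s, params$amplitude, params$onset_s,
                     params$alpha, params$beta)
  if (params$recirc_fraction > 0) {
    v <- v + params$recirc_fraction *
      gamma_variate(times_s, params$amplitude,
                    params$onset_s + params$recirc_delay_s,
                    params$alpha, params$beta)
  }
  tac_curve(times_s, v)
}

#' Forward tissue curve from the one-compartment kinetic model
#'
#' Realises the simplified Johnson-Wilson tissue model with three free
#' parameters (MBF, time delay, decay constant) as a one-compartment
#' convolution with an exponential impulse response:
#' \deqn{C_t(t) = f \int_0^t C_a(\tau - \Delta)\, e^{-k (t-\tau)}\, d\tau}
#' with \eqn{f = \mathrm{MBF}/6000} per second (MBF in mL·min^-1·(100 g)^-1,
#' tissue density 1 g/mL). The integral is evaluated by an exact trapezoidal
#' recursion on the supplied time grid, so `forward_tissue_curve` agrees with
#' direct trapezoidal quadrature to machine precision.
#'
#' @param aif arterial input [tac_curve()] (enhancement above baseline).
#' @param mbf myocardial blood flow, mL·min^-1·(100 g)^-1, >= 0.
#' @param delay_s arterial delay, seconds, >= 0.
#' @param k_decay washout decay constant, 1/s, >= 0.
#' @param times_s output sample times, strictly increasing.
#' @return a [tac_curve()]; `C_t(0) = 0` and `mbf = 0` gives the zero curve.
#' @export
forward_tissue_curve <- function(aif, mbf, delay_s, k_decay, times_s) {
  if (mbf < 0) stopf("mbf must be >= 0")
  if (k_decay < 0) stopf("k_decay must be >= 0")
  if (delay_s < 0) stopf("delay_s must be >= 0")
  g <- stats::approx(aif$times_s + delay_s, aif$values, xout = times_s,
                     yleft = 0, yright = aif$values[length(aif$values)])$y
  tac_curve(times_s, (mbf / 6000) * exp_conv(g, times_s, k_decay))
}

# Causal trapezoidal convolution of g(t) with exp(-k t) on grid `times`.
# I_i = e^{-k dt} I_{i-1} + dt/2 (g_{i-1} e^{-k dt} + g_i); algebraically
# identical to trapezoidal quadrature of the full integral at every node.
exp_conv <- function(g, times, k) {
  n <- length(times)
  out <- numeric(n)
  if (n < 2L) return(out)
  dt <- diff(times)
  ek <- exp(-k * dt)
  for (i in 2:n) {
    out[i] <- ek[i - 1L] * out[i - 1L] +
      dt[i - 1L] / 2 * (g[i - 1L] * ek[i - 1L] + g[i])
  }
  out
}

#' Digital dynamic perfusion phantom configuration
#'
#' Defines a short-axis left-ventricular phantom: an LV blood-pool cylinder
#' wrapped by a myocardial annulus, plus a separate aortic cylinder, imaged
#' over a dynamic contrast-enhanced acquisition. Myocardial sectors carry
#' configurable true kinetic parameters so every downstream estimate can be
#' checked against ground truth.
#'
#' @param grid_shape integer triple, voxels (x, y, z).
#' @param voxel_mm numeric triple, voxel spacing in mm.
#' @param n_frames number of time frames (>= 10).
#' @param frame_dt_s frame spacing, seconds.
#' @param heart_center_mm in-plane (x, y) centre of the LV axis, mm from the
#'   volume corner.
#' @param lv_radius_mm LV blood-pool radius.
#' @param myo_inner_mm,myo_outer_mm myocardial annulus radii;
#'   `lv_radius_mm <= myo_inner_mm < myo_outer_mm`.
#' @param aorta_center_mm in-plane (x, y) centre of the aortic cylinder.
#' @param aorta_radius_mm aortic radius.
#' @param sector_truth list of sectors, each
#'   `list(angle_deg = c(lo, hi), slices = c(lo, hi), mbf =, delay_s =, k_decay =)`;
#'   angles in image degrees (counterclockwise from +x), wrap allowed
#'   (`lo > hi`). Sectors must tile the myocardium without overlap.
#' @param aif an [aif_params()] object.
#' @param lv_delay_s delay of the LV blood-pool curve relative to the aorta.
#' @param myo_baseline_hu,background_hu pre-contrast HU of myocardium and
#'   non-heart background.
#' @param noise_sd_hu i.i.d. Gaussian HU noise per voxel per frame.
#' @param bh_coeffs beam-hardening polynomial coefficients for radial powers
#'   1..3 (see [apply_beam_hardening()]); `c(0,0,0)` disables the artifact.
#' @param motion_amplitude_vox max absolute per-frame integer translation
#'   (voxels); 0 disables motion.
#' @param rv_angle_deg optional angular position of a right-ventricular stub
#'   abutting the myocardium (used for insertion-landmark detection); NULL
#'   omits the RV.
#' @param rv_radius_mm radius of the RV stub.
#' @param septal_angle_deg true angular position (image degrees) of the
#'   anterior septal insertion, used as the polar-map angular origin when no
#'   RV structure is present.
#' @param apex_taper fractional reduction of the LV/myocardial radii at the
#'   apical slice (slice 1), tapering linearly to the full radii at the base;
#'   gives the phantom the conical apex-to-base geometry of a real ventricle
#'   (and through-plane structure for registration).
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(48L, 48L, 8L),
                           voxel_mm = c(2, 2, 2),
                           n_frames = 30L,
                           frame_dt_s = 1.0,
                           heart_center_mm = c(36, 48),
                           lv_radius_mm = 12,
                           myo_inner_mm = 12,
                           myo_outer_mm = 20,
                           aorta_center_mm = c(76, 48),
                           aorta_radius_mm = 6,
                           sector_truth = list(list(
                             angle_deg = c(0, 360), slices = c(1L, grid_shape[3]),
                             mbf = 300, delay_s = 2, k_decay = 0.15)),
                           aif = aif_params(),
                           lv_delay_s = 0,
                           myo_baseline_hu = 75,
                           background_hu = 0,
                           noise_sd_hu = 0,
                           bh_coeffs = c(0, 0, 0),
                           motion_amplitude_vox = 0L,
                           rv_angle_deg = NULL,
                           rv_radius_mm = 8,
                           septal_angle_deg = 120,
                           apex_taper = 0.15) {
  if (n_frames < 10L) stopf("n_frames must be >= 10")
  if (!(myo_inner_mm < myo_outer_mm)) stopf("myo_inner_mm must be < myo_outer_mm")
  ext <- grid_shape * voxel_mm
  if (myo_outer_mm >= min(ext[1:2]) / 2)
    stopf("myo_outer_mm must fit inside the in-plane grid extent")
  if (apex_taper < 0 || apex_taper >= 1) stopf("apex_taper must be in [0, 1)")
  for (s in sector_truth) {
    if (s$mbf < 0 || s$k_decay < 0 || s$delay_s < 0)
      stopf("sector truth parameters must be >= 0")
  }
  check_sector_overlap(sector_truth)
  structure(list(grid_shape = as.integer(grid_shape), voxel_mm = voxel_mm,
                 n_frames = as.integer(n_frames), frame_dt_s = frame_dt_s,
                 heart_center_mm = heart_center_mm, lv_radius_mm = lv_radius_mm,
                 myo_inner_mm = myo_inner_mm, myo_outer_mm = myo_outer_mm,
                 aorta_center_mm = aorta_center_mm,
                 aorta_radius_mm = aorta_radius_mm,
                 sector_truth = sector_truth, aif = aif,
                 lv_delay_s = lv_delay_s,
                 myo_baseline_hu = myo_baseline_hu,
                 background_hu = background_hu, noise_sd_hu = noise_sd_hu,
                 bh_coeffs = bh_coeffs,
                 motion_amplitude_vox = as.integer(motion_amplitude_vox),
                 rv_angle_deg = rv_angle_deg, rv_radius_mm = rv_radius_mm,
                 septal_angle_deg = septal_angle_deg,
                 apex_taper = apex_taper),
            class = "phantom_config")
}

# angular interval membership with wrap: lo > hi means the range crosses 0.
angle_in_range <- function(a, lo, hi) {
  a <- wrap_deg(a); lo <- wrap_deg(lo); hi <- ifelse(hi == 360, 360, wrap_deg(hi))
  if (lo < hi) a >= lo & a < hi else a >= lo | a < hi
}

check_sector_overlap <- function(sectors) {
  if (length(sectors) < 2L) return(invisible(TRUE))
  probe <- seq(0, 359.5, by = 0.5)
  for (i in seq_along(sectors)) {
    for (j in seq_along(sectors)) {
      if (j <= i) next
      si <- sectors[[i]]; sj <- sectors[[j]]
      zi <- seq(si$slices[1], si$slices[2]); zj <- seq(sj$slices[1], sj$slices[2])
      if (length(intersect(zi, zj)) == 0L) next
      ai <- angle_in_range(probe, si$angle_deg[1], si$angle_deg[2])
      aj <- angle_in_range(probe, sj$angle_deg[1], sj$angle_deg[2])
      if (any(ai & aj)) stopf("sector_truth sectors %d and %d overlap", i, j)
    }
  }
  invisible(TRUE)
}

#' Construct a dynamic study object
#'
#' Container for a 4D dynamic contrast-enhanced CT series. Arrays are stored
#' in (x, y, z, t) order with 1-based indices (the native R / NIfTI layout).
#'
#' @param frames 4D numeric HU array (x, y, z, t).
#' @param frame_times_s acquisition time of each frame, strictly increasing.
#' @param spacing_mm voxel spacing triple.
#' @param truth optional ground-truth payload (phantom only).
#' @return object of class `dynamic_study`.
#' @export
dynamic_study <- function(frames, frame_times_s, spacing_mm, truth = NULL) {
  if (length(dim(frames)) != 4L) stopf("frames must be a 4D array (x,y,z,t)")
  if (dim(frames)[4] != length(frame_times_s))
    stopf("frame_times_s length must match the 4th array dimension")
  if (any(diff(frame_times_s) <= 0)) stopf("frame_times_s must be strictly increasing")
  if (!all(is.finite(frames))) stopf("frames must be finite")
  structure(list(frames = frames, frame_times_s = as.numeric(frame_times_s),
                 spacing_mm = spacing_mm, truth = truth),
            class = "dynamic_study")
}

#' @export
print.dynamic_study <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Dynamic CT study: %dx%dx%d voxels x %d frames, t = [%.1f, %.1f] s, spacing %s mm%s\n",
              d[1], d[2], d[3], d[4], min(x$frame_times_s), max(x$frame_times_s),
              paste(x$spacing_mm, collapse = "x"),
              if (!is.null(x$truth)) " (with ground truth)" else ""))
  invisible(x)
}

#' Build a synthetic dynamic perfusion study
#'
#' Renders the configured phantom: myocardial voxels follow the forward
#' kinetic model with their sector's true parameters, blood voxels (LV pool,
#' aorta, optional RV stub) carry the arterial input curve, and the frames are
#' optionally degraded by Gaussian HU noise, a cupping beam-hardening artifact
#' and per-frame integer translations (applied circularly and recorded in the
#' truth payload). Identical seeds give bit-identical studies.
#'
#' @param config a [phantom_config()].
#' @param seed integer RNG seed.
#' @return a [dynamic_study()] whose `truth` holds the label masks
#'   (0 background, 1 myocardium, 2 LV blood, 3 aorta), the per-voxel true MBF
#'   map, the AIF parameters and curve, applied shifts, beam-hardening
#'   coefficients and phantom geometry.
#' @export
build_phantom <- function(config, seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  cf <- config
  d <- cf$grid_shape
  times <- (seq_len(cf$n_frames) - 1L) * cf$frame_dt_s
  aif <- make_aif(cf$aif, times)

  # in-plane voxel-centre coordinates (mm)
  xs <- (seq_len(d[1]) - 0.5) * cf$voxel_mm[1]
  ys <- (seq_len(d[2]) - 0.5) * cf$voxel_mm[2]
  gx <- matrix(xs, d[1], d[2])
  gy <- matrix(ys, d[1], d[2], byrow = TRUE)
  r_heart <- sqrt((gx - cf$heart_center_mm[1])^2 + (gy - cf$heart_center_mm[2])^2)
  r_aorta <- sqrt((gx - cf$aorta_center_mm[1])^2 + (gy - cf$aorta_center_mm[2])^2)
  ang <- wrap_deg(atan2(gy - cf$heart_center_mm[2], gx - cf$heart_center_mm[1]) * 180 / pi)

  ao2d <- r_aorta <= cf$aorta_radius_mm
  rv2d <- matrix(FALSE, d[1], d[2])
  if (!is.null(cf$rv_angle_deg)) {
    th <- cf$rv_angle_deg * pi / 180
    rv_c <- cf$heart_center_mm + (cf$myo_outer_mm + cf$rv_radius_mm - 2) *
      c(cos(th), sin(th))
    rv2d <- sqrt((gx - rv_c[1])^2 + (gy - rv_c[2])^2) <= cf$rv_radius_mm
  }
  # conical taper: radii shrink linearly toward the apex (slice 1)
  zscale <- if (d[3] > 1L)
    1 - cf$apex_taper * (d[3] - seq_len(d[3])) / (d[3] - 1L) else 1

  # sector truth curves
  sector_curves <- lapply(cf$sector_truth, function(s)
    forward_tissue_curve(aif, s$mbf, s$delay_s, s$k_decay, times)$values)
  lv_curve <- stats::approx(times + cf$lv_delay_s, aif$values, xout = times,
                            yleft = 0, yright = aif$values[length(times)])$y

  masks <- array(0L, d)
  mbf_map <- array(NA_real_, d)
  sector_id <- array(NA_integer_, d)
  frames <- array(cf$background_hu, c(d, cf$n_frames))
  rv_mask <- array(FALSE, d)
  for (z in seq_len(d[3])) {
    lv2d <- r_heart <= cf$lv_radius_mm * zscale[z]
    myo2d <- r_heart > cf$myo_inner_mm * zscale[z] &
      r_heart <= cf$myo_outer_mm * zscale[z]
    rv2d_z <- rv2d & !myo2d & !lv2d & !ao2d
    m <- masks[, , z]
    m[myo2d] <- 1L; m[lv2d] <- 2L; m[ao2d] <- 3L
    masks[, , z] <- m
    idx_lv <- which(lv2d); idx_ao <- which(ao2d); idx_rv <- which(rv2d_z)
    for (t in seq_len(cf$n_frames)) {
      fr <- frames[, , z, t]
      fr[myo2d] <- cf$myo_baseline_hu
      fr[idx_lv] <- cf$aif$baseline_hu + lv_curve[t]
      fr[idx_ao] <- cf$aif$baseline_hu + aif$values[t]
      fr[idx_rv] <- cf$aif$baseline_hu + lv_curve[t]
      frames[, , z, t] <- fr
    }
    rv_m <- rv_mask[, , z]; rv_m[idx_rv] <- TRUE; rv_mask[, , z] <- rv_m
    # myocardial sectors
    for (si in seq_along(cf$sector_truth)) {
      s <- cf$sector_truth[[si]]
      if (z < s$slices[1] || z > s$slices[2]) next
      inplane <- myo2d & angle_in_range(ang, s$angle_deg[1], s$angle_deg[2])
      if (!any(inplane)) next
      idx <- which(inplane)
      for (t in seq_len(cf$n_frames)) {
        fr <- frames[, , z, t]
        fr[idx] <- cf$myo_baseline_hu + sector_curves[[si]][t]
        frames[, , z, t] <- fr
      }
      mm <- mbf_map[, , z]; mm[idx] <- s$mbf; mbf_map[, , z] <- mm
      sm <- sector_id[, , z]; sm[idx] <- si; sector_id[, , z] <- sm
    }
  }
  if (anyNA(mbf_map[masks == 1L]))
    stopf("sector_truth does not cover the full myocardium")

  set.seed(as.integer(seed))
  # beam hardening (before noise; artifact is deterministic image bias)
  if (any(cf$bh_coeffs != 0)) {
    geom <- heart_geometry(masks, cf$voxel_mm)
    lv_enh <- lv_curve
    for (t in seq_len(cf$n_frames)) {
      frames[, , , t] <- apply_beam_hardening(frames[, , , t], cf$bh_coeffs,
                                              masks, enhancement = lv_enh[t],
                                              geometry = geom)
    }
  }
  shifts <- matrix(0L, cf$n_frames, 3L)
  if (cf$motion_amplitude_vox > 0L) {
    shifts[] <- sample(seq(-cf$motion_amplitude_vox, cf$motion_amplitude_vox),
                       cf$n_frames * 3L, replace = TRUE)
    shifts[, 3] <- 0L  # keep through-plane anatomy intact on thin slabs
    # the registration reference (peak mean-enhancement frame) stays unmoved
    fmeans <- vapply(seq_len(cf$n_frames),
                     function(t) mean(frames[, , , t]), numeric(1))
    shifts[which.max(fmeans), ] <- 0L
    for (t in seq_len(cf$n_frames)) {
      if (any(shifts[t, ] != 0L))
        frames[, , , t] <- circ_shift3(frames[, , , t], shifts[t, ])
    }
  }
  if (cf$noise_sd_hu > 0) {
    frames <- frames + array(stats::rnorm(length(frames), 0, cf$noise_sd_hu),
                             dim(frames))
  }

  dynamic_study(frames, times, cf$voxel_mm,
                truth = list(masks = masks, mbf_map = mbf_map,
                             sector_id = sector_id, rv_mask = rv_mask,
                             aif_params = cf$aif, aif = aif,
                             shifts = shifts, bh_coeffs = cf$bh_coeffs,
                             config = cf,
                             septal_angle_deg = cf$septal_angle_deg,
                             heart_center_vox = cf$heart_center_mm / cf$voxel_mm[1:2] + 0.5,
                             aorta_center_vox = cf$aorta_center_mm / cf$voxel_mm[1:2] + 0.5))
}

# centre (in-plane, voxel units), max myocardial radius and radius map used by
# both the artifact simulator and the corrector.
heart_geometry <- function(masks, voxel_mm) {
  d <- dim(masks)
  heart <- masks == 1L | masks == 2L
  idx <- which(heart, arr.ind = TRUE)
  cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
  gx <- matrix(seq_len(d[1]), d[1], d[2])
  gy <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  r2d <- sqrt(((gx - cx) * voxel_mm[1])^2 + ((gy - cy) * voxel_mm[2])^2)
  myo_idx <- which(masks == 1L, arr.ind = TRUE)
  rmax <- max(sqrt(((myo_idx[, 1] - cx) * voxel_mm[1])^2 +
                   ((myo_idx[, 2] - cy) * voxel_mm[2])^2))
  list(center = c(cx, cy), r2d = r2d, rmax = rmax,
       region2d = r2d <= rmax * 1.05)
}

#' Apply a simulated beam-hardening (cupping) artifact
#'
#' Adds a radially varying HU bias inside the heart region, scaled by the
#' instantaneous iodine enhancement:
#' \deqn{bias(r, t) = E(t) \sum_{i=1}^{3} c_i (r/R)^i}
#' where \eqn{E(t)} is the blood-pool enhancement at the frame, \eqn{r} the
#' in-plane distance from the heart centre and \eqn{R} the outer myocardial
#' radius. Zero coefficients (or zero enhancement) return the input unchanged.
#' The same polynomial family is used, with negated sign, by the corrector in
#' [correct_beam_hardening()].
#'
#' @param frame 3D HU volume (one time frame).
#' @param coeffs numeric length-3 polynomial coefficients for powers 1..3 of
#'   (r/R).
#' @param masks label volume (1 myocardium, 2 LV blood, 3 aorta) defining the
#'   heart geometry.
#' @param enhancement scalar blood-pool enhancement E(t) of this frame, HU.
#' @param geometry optional precomputed [heart geometry][apply_beam_hardening]
#'   (internal use).
#' @return 3D HU volume with the artifact added.
#' @export
apply_beam_hardening <- function(frame, coeffs, masks, enhancement,
                                 geometry = NULL) {
  coeffs <- as.numeric(coeffs)
  if (length(coeffs) > 3L) stopf("at most 3 coefficients (powers 1..3)")
  coeffs <- c(coeffs, numeric(3L - length(coeffs)))
  if (any(!is.finite(coeffs))) stopf("coeffs must be finite")
  if (all(coeffs == 0) || enhancement == 0) return(frame)
  if (is.null(geometry)) geometry <- heart_geometry(masks, c(1, 1, 1))
  rn <- geometry$r2d / geometry$rmax
  bias2d <- enhancement * (coeffs[1] * rn + coeffs[2] * rn^2 + coeffs[3] * rn^3)
  bias2d[!geometry$region2d] <- 0
  out <- frame
  for (z in seq_len(dim(frame)[3])) out[, , z] <- out[, , z] + bias2d
  out
}
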