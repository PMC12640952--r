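#' Heart label masks
#'
#' @param labels integer 3D array: 0 background, 1 myocardium, 2 LV blood
#'   pool, 3 aorta.
#' @param spacing_mm voxel spacing triple.
#' @return object of class `heart_masks`.
#' @export
heart_masks <- function(labels, spacing_mm) {
  if (!all(labels %in% 0:3)) stopf("labels must be in {0,1,2,3}")
  if (!any(labels == 1L)) stopf("myocardium label is empty")
  structure(list(labels = labels, spacing_mm = spacing_mm),
            class = "heart_masks")
}

#' @export
print.heart_masks <- function(x, ...) {
  cat(sprintf("Heart masks: %d myocardium, %d LV blood, %d aorta voxels\n",
              sum(x$labels == 1L), sum(x$labels == 2L), sum(x$labels == 3L)))
  invisible(x)
}

# per-component circularity score and mean cross-sectional area
component_stats <- function(comp_mask) {
  d <- dim(comp_mask)
  areas <- circs <- numeric(0)
  for (z in seq_len(d[3])) {
    sl <- comp_mask[, , z]
    a <- sum(sl)
    if (a == 0L) next
    ci <- which(sl, arr.ind = TRUE)
    cx <- mean(ci[, 1]); cy <- mean(ci[, 2])
    rmax <- max(sqrt((ci[, 1] - cx)^2 + (ci[, 2] - cy)^2)) + 0.5
    areas <- c(areas, a)
    circs <- c(circs, a / (pi * rmax^2))
  }
  list(circularity = stats::weighted.mean(circs, areas),
       mean_area = mean(areas))
}

#' Detect the aortic ROI and extract the arterial input function
#'
#' Finds the most circular, strongly enhancing connected region on the
#' unregistered data: voxels are ranked by temporal enhancement range
#' (after light spatial smoothing), thresholded at half the maximum range,
#' grouped into connected components, and each component is scored by its
#' per-slice circularity; among near-equally circular candidates the one with
#' the smallest cross-section is taken (the aorta is more compact than the LV
#' blood pool). The ROI's mean time-attenuation curve, referenced to its
#' pre-contrast baseline, is returned as the AIF.
#'
#' @param study a [dynamic_study()].
#' @param min_range_hu absolute floor on the temporal enhancement range; if no
#'   voxel exceeds it an error is raised.
#' @return list with `center` (voxel coords), `radius_vox`, `mask` (logical 3D)
#'   and `aif` (a [tac_curve()]).
#' @export
detect_aorta_roi <- function(study, min_range_hu = 50) {
  d <- dim(study$frames)
  if (d[4] < 10L) stopf("need at least 10 frames")
  rng <- array(0, d[1:3])
  lo <- array(Inf, d[1:3])
  hi <- array(-Inf, d[1:3])
  for (t in seq_len(d[4])) {
    fr <- box_smooth3(study$frames[, , , t])
    lo <- pmin(lo, fr); hi <- pmax(hi, fr)
  }
  rng <- hi - lo
  if (max(rng) < min_range_hu)
    stopf("no enhancing region found (max temporal range %.1f HU)", max(rng))
  cand <- rng >= 0.5 * max(rng)
  comp <- connected_components3(cand)
  ncomp <- max(comp, na.rm = TRUE)
  best <- NULL
  stats_list <- list()
  for (c in seq_len(ncomp)) {
    m <- !is.na(comp) & comp == c
    if (sum(m) < 4L) next
    stats_list[[length(stats_list) + 1L]] <- c(id = c, unlist(component_stats(m)))
  }
  if (length(stats_list) == 0L) stopf("no enhancing region found")
  st <- do.call(rbind, stats_list)
  top <- max(st[, "circularity"])
  cands <- st[st[, "circularity"] >= top - 0.1, , drop = FALSE]
  pick <- cands[which.min(cands[, "mean_area"]), "id"]
  mask <- !is.na(comp) & comp == pick
  ci <- which(mask, arr.ind = TRUE)
  center <- colMeans(ci)
  radius <- sqrt(mean((ci[, 1] - center[1])^2 + (ci[, 2] - center[2])^2) * 2)
  tac <- colMeans(tac_matrix(study, which(mask)))
  cv0 <- tac_curve(study$frame_times_s, tac - min(tac))
  onset <- onset_frame(cv0)
  aif <- tac_curve(study$frame_times_s,
                   tac - mean(tac[seq_len(onset - 1L)]))
  list(center = center, radius_vox = radius, mask = mask, aif = aif)
}

# Integer-voxel phase correlation: returns s such that `mov` equals `ref`
# circularly shifted by s. The cross-power normalisation is regularised so
# noise-only frequencies do not dominate the whitened spectrum.
phase_corr_shift <- function(ref, mov, eps_frac = 0.01) {
  d <- dim(ref)
  Fr <- stats::fft(ref)
  Fm <- stats::fft(mov)
  C <- Fm * Conj(Fr)
  mag <- Mod(C)
  if (max(mag) < .Machine$double.eps) return(c(0L, 0L, 0L))
  C <- C / (mag + eps_frac * max(mag))
  r <- Re(stats::fft(C, inverse = TRUE))
  p <- arrayInd(which.max(r), d) - 1L
  s <- ifelse(p > d / 2, p - d, p)
  as.integer(s)
}

#' Temporal registration of a dynamic study
#'
#' Estimates a per-frame 3D translation against a reference frame by phase
#' correlation and applies the inverse shift to align every frame. Integer
#' translations are recovered exactly; flat (information-free) frames fall
#' back to zero shift. Re-running on the output yields zero additional shift.
#'
#' @param study a [dynamic_study()].
#' @param reference frame index, or `"peak"` for the frame of maximal mean
#'   enhancement.
#' @return list with `study` (registered), `shifts` (n_frames x 3 integer
#'   matrix of the estimated per-frame displacements) and `reference`.
#' @export
register_temporal <- function(study, reference = "peak") {
  d <- dim(study$frames)
  nt <- d[4]
  frame_mean <- vapply(seq_len(nt), function(t) mean(study$frames[, , , t]),
                       numeric(1))
  ref <- if (identical(reference, "peak")) which.max(frame_mean)
         else as.integer(reference)
  if (ref < 1L || ref > nt) stopf("reference frame out of range")
  refvol <- study$frames[, , , ref]
  shifts <- matrix(0L, nt, 3L)
  frames <- study$frames
  for (t in seq_len(nt)) {
    if (t == ref) next
    s <- phase_corr_shift(refvol, study$frames[, , , t])
    shifts[t, ] <- s
    if (any(s != 0L)) frames[, , , t] <- circ_shift3(study$frames[, , , t], -s)
  }
  out <- dynamic_study(frames, study$frame_times_s, study$spacing_mm,
                       truth = study$truth)
  list(study = out, shifts = shifts, reference = ref)
}

# n-layer 26-neighbourhood binary dilation (edge-clipped, no wrap)
dilate3 <- function(mask, layers = 1L) {
  d <- dim(mask)
  shift_pad <- function(m, s) {
    out <- array(FALSE, d)
    src <- lapply(1:3, function(k) {
      i <- seq_len(d[k]) - s[k]
      i[i >= 1L & i <= d[k]]
    })
    dst <- lapply(1:3, function(k) {
      i <- seq_len(d[k])
      i[(i - s[k]) >= 1L & (i - s[k]) <= d[k]]
    })
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (i in seq_len(layers)) {
    out <- mask
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      out <- out | shift_pad(mask, c(dx, dy, dz))
    }
    mask <- out
  }
  mask
}

#' Myocardium and aorta segmentation
#'
#' Pluggable segmentation: `"external"` validates and passes through a label
#' volume produced elsewhere (e.g. a trained network); `"fallback"` is a
#' classical intensity-based segmenter for phantom-like data. The fallback
#' finds blood structures (LV pool, aorta) on the peak-enhancement frame by
#' thresholding at half the maximal smoothed enhancement and splitting by
#' connected components (the compact circular component is the aorta, the
#' largest is the LV pool); the myocardium is the mid-enhancement shell
#' around the LV pool, gated on the time-averaged post-onset enhancement
#' (which averages down frame noise) relative to the LV blood pool.
#'
#' @param study a [dynamic_study()].
#' @param method `"external"` or `"fallback"`.
#' @param external_masks for `"external"`: a `heart_masks` object or label
#'   array matching the study geometry.
#' @param myo_enh_frac length-2 fractions of the LV-pool time-averaged
#'   enhancement bounding myocardial intensity in the fallback.
#' @param max_shell_mm maximal myocardial shell thickness searched by the
#'   fallback.
#' @return a [heart_masks()] object.
#' @export
segment_heart <- function(study, method = c("external", "fallback"),
                          external_masks = NULL,
                          myo_enh_frac = c(0.06, 0.70),
                          max_shell_mm = 12) {
  method <- match.arg(method)
  d <- dim(study$frames)[1:3]
  if (method == "external") {
    if (is.null(external_masks)) stopf("external_masks required")
    labels <- if (inherits(external_masks, "heart_masks"))
      external_masks$labels else external_masks
    if (!all(dim(labels) == d)) stopf("external mask geometry mismatch")
    return(heart_masks(labels, study$spacing_mm))
  }

  nt <- dim(study$frames)[4]
  frame_mean <- vapply(seq_len(nt), function(t) mean(study$frames[, , , t]),
                       numeric(1))
  mcv <- tac_curve(study$frame_times_s, frame_mean - min(frame_mean))
  onset <- onset_frame(mcv)
  pre <- seq_len(max(onset - 1L, 1L))
  base <- array(0, d)
  for (t in pre) base <- base + study$frames[, , , t] / length(pre)
  peak_t <- which.max(frame_mean)
  enh <- box_smooth3(study$frames[, , , peak_t] - base)

  blood_thr <- 0.5 * max(enh)
  blood <- enh >= blood_thr
  comp <- connected_components3(blood)
  ncomp <- max(comp, na.rm = TRUE)
  if (ncomp < 2L) stopf("could not separate LV pool and aorta")
  sizes <- tabulate(comp[!is.na(comp)], ncomp)
  lv_id <- which.max(sizes)
  # aorta: most circular remaining component of nontrivial size
  best <- NULL
  for (c in setdiff(seq_len(ncomp), lv_id)) {
    m <- !is.na(comp) & comp == c
    if (sum(m) < 4L) next
    cs <- component_stats(m)
    if (is.null(best) || cs$circularity > best$circ) {
      best <- list(id = c, circ = cs$circularity)
    }
  }
  if (is.null(best)) stopf("could not identify an aortic component")
  lv <- !is.na(comp) & comp == lv_id
  ao <- !is.na(comp) & comp == best$id

  # time-averaged post-onset enhancement: noise shrinks by sqrt(n_frames)
  post <- seq(onset, nt)
  enh_mean <- array(0, d)
  for (t in post) enh_mean <- enh_mean + (study$frames[, , , t] - base) / length(post)
  lv_level <- mean(enh_mean[lv])

  layers <- max(1L, ceiling(max_shell_mm / mean(study$spacing_mm[1:2])))
  ring <- dilate3(lv, layers) & !lv & !ao
  myo <- ring & enh_mean >= myo_enh_frac[1] * lv_level &
    enh_mean <= myo_enh_frac[2] * lv_level
  comp_m <- connected_components3(myo)
  if (all(is.na(comp_m))) stopf("fallback segmentation found no myocardium")
  sizes_m <- tabulate(comp_m[!is.na(comp_m)], max(comp_m, na.rm = TRUE))
  myo <- !is.na(comp_m) & comp_m == which.max(sizes_m)

  labels <- array(0L, d)
  labels[myo] <- 1L
  labels[lv] <- 2L
  labels[ao] <- 3L
  heart_masks(labels, study$spacing_mm)
}

# minimal rotation matrix taking unit vector u onto unit vector v
rot_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # 180 degrees: rotate about any axis orthogonal to u
    a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- a - sum(a * u) * u; w <- w / sqrt(sum(w^2))
    return(2 * outer(w, w) - diag(3))
  }
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  wx <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + wx + wx %*% wx / (1 + c_)
}

# Resample a 3D volume under coordinate rotation R (mm space, about the
# volume centre): out(p) = in(R p). Trilinear, or nearest for label volumes.
rotate_volume3 <- function(vol, R, spacing_mm, nearest = FALSE, fill = NA) {
  d <- dim(vol)
  ctr <- (d + 1) / 2
  g <- arrayInd(seq_len(prod(d)), d)
  p <- sweep(g, 2, ctr) * matrix(spacing_mm, nrow(g), 3, byrow = TRUE)
  q <- p %*% t(R)
  q <- sweep(q / matrix(spacing_mm, nrow(q), 3, byrow = TRUE), 2, ctr, "+")
  if (nearest) {
    qi <- round(q)
    ok <- qi[, 1] >= 1 & qi[, 1] <= d[1] & qi[, 2] >= 1 & qi[, 2] <= d[2] &
      qi[, 3] >= 1 & qi[, 3] <= d[3]
    out <- rep(fill, prod(d))
    lin <- qi[ok, 1] + (qi[ok, 2] - 1) * d[1] + (qi[ok, 3] - 1) * d[1] * d[2]
    out[ok] <- vol[lin]
    return(array(out, d))
  }
  f <- floor(q)
  w <- q - f
  out <- rep(if (is.na(fill)) 0 else fill, prod(d))
  acc <- numeric(prod(d))
  inside <- rep(TRUE, prod(d))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    xi <- f[, 1] + cx; yi <- f[, 2] + cy; zi <- f[, 3] + cz
    wt <- (if (cx == 1) w[, 1] else 1 - w[, 1]) *
      (if (cy == 1) w[, 2] else 1 - w[, 2]) *
      (if (cz == 1) w[, 3] else 1 - w[, 3])
    ok <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3]
    inside <- inside & (ok | wt < 1e-12)
    lin <- xi[ok] + (yi[ok] - 1) * d[1] + (zi[ok] - 1) * d[1] * d[2]
    acc[ok] <- acc[ok] + wt[ok] * vol[lin]
  }
  out[inside] <- acc[inside]
  if (!is.na(fill)) out[!inside] <- fill
  array(out, d)
}

#' Reorient a study into short-axis geometry
#'
#' Resamples every frame so the volume z-axis aligns with the supplied LV
#' long axis (trilinear interpolation about the volume centre). The identity
#' axis (0, 0, 1) returns the input unchanged.
#'
#' @param study a [dynamic_study()].
#' @param long_axis unit 3-vector of the LV long axis in image coordinates.
#' @param fill HU value for voxels sampled from outside the volume.
#' @return a reoriented [dynamic_study()] (truth payload dropped: voxelwise
#'   truth no longer applies after resampling).
#' @export
reorient_short_axis <- function(study, long_axis, fill = 0) {
  n <- sqrt(sum(long_axis^2))
  if (n < 1e-12) stopf("long_axis must be a nonzero vector")
  if (abs(n - 1) > 1e-6) stopf("long_axis must be a unit vector")
  if (max(abs(long_axis - c(0, 0, 1))) < 1e-12) return(study)
  R <- rot_between(c(0, 0, 1), long_axis)
  frames <- study$frames
  for (t in seq_along(study$frame_times_s)) {
    frames[, , , t] <- rotate_volume3(study$frames[, , , t], R,
                                      study$spacing_mm, fill = fill)
  }
  dynamic_study(frames, study$frame_times_s, study$spacing_mm, truth = NULL)
}

#' Detect polar-map landmarks
#'
#' The LV centre is the centroid of the LV blood pool over the
#' mid-ventricular slices. The septal insertion points (anterior and inferior
#' RV insertions) are located where an enhancing right-ventricular structure
#' abuts the myocardium: the angular extremes of the RV-myocardium contact
#' region. Without an RV structure the insertion angle must be supplied
#' explicitly.
#'
#' @param study a [dynamic_study()].
#' @param masks a [heart_masks()] object.
#' @param septal_angle_deg explicit anterior-insertion angle (image degrees)
#'   used when no RV structure is detectable.
#' @return object of class `heart_landmarks`: `lv_center`, `septum_upper`
#'   (anterior insertion), `septum_lower` (inferior insertion) voxel
#'   coordinates, and `origin_angle_deg` (the polar-map angular origin).
#' @export
detect_landmarks <- function(study, masks, septal_angle_deg = NULL) {
  labels <- masks$labels
  d <- dim(labels)
  zmid <- seq(max(1L, floor(d[3] / 3)), min(d[3], ceiling(2 * d[3] / 3)))
  lv_idx <- which(labels[, , zmid, drop = FALSE] == 2L, arr.ind = TRUE)
  if (nrow(lv_idx) == 0L) stopf("LV blood pool empty on mid slices")
  lv_center <- c(mean(lv_idx[, 1]), mean(lv_idx[, 2]),
                 mean(zmid[lv_idx[, 3]]))

  nt <- dim(study$frames)[4]
  frame_mean <- vapply(seq_len(nt), function(t) mean(study$frames[, , , t]),
                       numeric(1))
  peak_t <- which.max(frame_mean)
  mcv <- tac_curve(study$frame_times_s, frame_mean - min(frame_mean))
  onset <- onset_frame(mcv)
  pre <- seq_len(max(onset - 1L, 1L))
  base <- array(0, d)
  for (t in pre) base <- base + study$frames[, , , t] / length(pre)
  enh <- study$frames[, , , peak_t] - base

  # enhancing blood-pool-like voxels that are neither LV nor aorta (nor the
  # partial-volume crumbs on their rims) and abut the myocardium
  blood_like <- enh >= 0.5 * max(enh) & !dilate3(labels == 2L | labels == 3L, 1L)
  near_myo <- dilate3(labels == 1L, 1L)
  rv <- array(FALSE, d)
  if (any(blood_like)) {
    comp <- connected_components3(blood_like)
    for (c in seq_len(max(comp, na.rm = TRUE))) {
      m <- !is.na(comp) & comp == c
      if (sum(m) >= 20L && any(m & near_myo)) rv <- rv | m
    }
  }
  if (sum(rv) >= 20L) {
    # model RV cross-section and outer myocardial boundary as circles; the
    # insertion points are their (sub-voxel) intersections
    ci <- which(rv, arr.ind = TRUE)
    rv_c <- c(mean(ci[, 1]), mean(ci[, 2]))
    rv_r <- sqrt(nrow(ci) / length(unique(ci[, 3])) / pi)
    mi <- which(labels == 1L, arr.ind = TRUE)
    R_out <- max(sqrt((mi[, 1] - lv_center[1])^2 + (mi[, 2] - lv_center[2])^2)) + 0.5
    dvec <- rv_c - lv_center[1:2]
    dist <- sqrt(sum(dvec^2))
    rv_ang <- atan2(dvec[2], dvec[1]) * 180 / pi
    carg <- (dist^2 + R_out^2 - rv_r^2) / (2 * dist * R_out)
    if (abs(carg) >= 1) {
      if (!is.null(septal_angle_deg))
        return(landmarks_from_angle(lv_center, labels, septal_angle_deg))
      stopf("RV structure does not abut the myocardium")
    }
    gam <- acos(carg) * 180 / pi
    mk_pt <- function(a_deg) c(lv_center[1] + R_out * cos(a_deg * pi / 180),
                               lv_center[2] + R_out * sin(a_deg * pi / 180),
                               lv_center[3])
    septum_upper <- mk_pt(rv_ang + gam)
    septum_lower <- mk_pt(rv_ang - gam)
    origin <- wrap_deg(rv_ang + gam)
  } else if (!is.null(septal_angle_deg)) {
    return(landmarks_from_angle(lv_center, labels, septal_angle_deg))
  } else {
    stopf(paste("no RV structure found and no septal_angle_deg supplied;",
                "set the insertion angle explicitly"))
  }
  structure(list(lv_center = lv_center, septum_upper = septum_upper,
                 septum_lower = septum_lower, origin_angle_deg = origin),
            class = "heart_landmarks")
}

# landmarks synthesised from an explicitly configured insertion angle; the
# inferior insertion defaults to 120 degrees clockwise of the anterior one
landmarks_from_angle <- function(lv_center, labels, septal_angle_deg) {
  mi <- which(labels == 1L, arr.ind = TRUE)
  r <- max(sqrt((mi[, 1] - lv_center[1])^2 + (mi[, 2] - lv_center[2])^2))
  mk <- function(a_deg) c(lv_center[1] + r * cos(a_deg * pi / 180),
                          lv_center[2] + r * sin(a_deg * pi / 180),
                          lv_center[3])
  structure(list(lv_center = lv_center, septum_upper = mk(septal_angle_deg),
                 septum_lower = mk(septal_angle_deg - 120),
                 origin_angle_deg = wrap_deg(septal_angle_deg)),
            class = "heart_landmarks")
}
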