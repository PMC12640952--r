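# Bullseye polar maps and the modified AHA-16 segment model (apical cap
# excluded from MBF analysis).

#' AHA-16 segment geometry
#'
#' Angular extent of each segment in polar-map degrees, where 0 is the
#' anterior septal (RV) insertion and angles increase counterclockwise viewed
#' from the apex. Basal segments 1-6 and mid segments 7-12 span 60 degrees
#' each; apical segments 13-16 span 90 degrees, rotated 45 degrees so the
#' apical-anterior segment straddles the anterior direction. The apical cap
#' (segment 17) is excluded from this model.
#'
#' @return data.frame with columns `segment`, `ring` ("basal", "mid",
#'   "apical"), `lo`, `hi` (degrees; `lo > hi` marks a range wrapping 0).
#' @export
aha_segment_angles <- function() {
  six <- function(seg0, ring) data.frame(
    segment = seg0 + 0:5, ring = ring,
    lo = c(300, 0, 60, 120, 180, 240),
    hi = c(360, 60, 120, 180, 240, 300))
  rbind(
    six(1L, "basal"),
    six(7L, "mid"),
    data.frame(segment = 13:16, ring = "apical",
               lo = c(315, 45, 135, 225), hi = c(45, 135, 225, 315)))
}

#' Coronary territory membership (right-dominant)
#'
#' Standard right-dominant assignment of AHA-16 segments to the three
#' coronary territories.
#'
#' @return named list of segment vectors for LAD, RCA and LCX.
#' @export
aha_territories <- function() {
  list(LAD = c(1L, 2L, 7L, 8L, 13L, 14L),
       RCA = c(3L, 4L, 9L, 10L, 15L),
       LCX = c(5L, 6L, 11L, 12L, 16L))
}

# closed circular arcs [lo, hi] (wrap allowed); do they share at least a point?
arcs_touch <- function(lo1, hi1, lo2, hi2) {
  split_arc <- function(lo, hi) {
    if (lo <= hi) list(c(lo, hi)) else list(c(lo, 360), c(0, hi))
  }
  for (a in split_arc(lo1, hi1)) for (b in split_arc(lo2, hi2)) {
    if (max(a[1], b[1]) <= min(a[2], b[2])) return(TRUE)
    # modular identification of 0 and 360
    if ((a[2] %% 360) == (b[1] %% 360) || (b[2] %% 360) == (a[1] %% 360))
      return(TRUE)
  }
  FALSE
}

#' Spatially adjacent segment pairs within a territory
#'
#' Generates the unordered pairs of segments that share a boundary (an arc or
#' a corner point) on the bullseye, restricted to one coronary territory.
#' Two segments are adjacent when their rings are the same or neighbouring
#' (basal-mid or mid-apical, never basal-apical) and their closed angular
#' extents intersect. Applied to the LAD territory this rule reproduces the
#' ten canonical pairs \[1,2\], \[1,7\], \[1,8\], \[2,7\], \[2,8\], \[7,8\],
#' \[13,14\], \[7,13\], \[8,13\], \[8,14\].
#'
#' @param territory "LAD", "RCA" or "LCX".
#' @return integer matrix, one row per pair, columns `a`, `b` (a < b).
#' @export
aha_adjacent_pairs <- function(territory = c("LAD", "RCA", "LCX")) {
  territory <- match.arg(territory)
  segs <- aha_territories()[[territory]]
  geo <- aha_segment_angles()
  ring_idx <- c(basal = 3L, mid = 2L, apical = 1L)
  out <- NULL
  for (i in seq_along(segs)) for (j in seq_along(segs)) {
    if (j <= i) next
    a <- geo[geo$segment == segs[i], ]
    b <- geo[geo$segment == segs[j], ]
    if (abs(ring_idx[[a$ring]] - ring_idx[[b$ring]]) > 1L) next
    if (arcs_touch(a$lo, a$hi, b$lo, b$hi))
      out <- rbind(out, c(min(segs[i], segs[j]), max(segs[i], segs[j])))
  }
  colnames(out) <- c("a", "b")
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' Convert a 3D MBF map to a bullseye polar map
#'
#' Myocardial voxels are binned by polar angle about the LV centre (origin at
#' the anterior septal insertion, counterclockwise viewed from the apex) and
#' by radius, with the slice position mapping linearly from apex (map centre)
#' to base (rim): each slice spreads over its share of the radius bins.
#' Multiple samples per bin are averaged; bins receiving no sample are NaN.
#'
#' @param mbf_map a `perfusion_map` or 3D MBF array (NA outside myocardium).
#' @param masks a [heart_masks()] object or label array.
#' @param landmarks a `heart_landmarks` object (from [detect_landmarks()]).
#' @param n_radius,n_angle raster dimensions; `n_radius` should be divisible
#'   by 3 (one third per ring) and `n_angle` by 24 (60- and 90-degree segment
#'   boundaries, 45-degree apical offset).
#' @param apex `"low"` if slice 1 is the apex, `"high"` if the last slice is.
#' @param clockwise flip the angular direction (for volumes whose in-plane
#'   handedness is mirrored).
#' @return object of class `polar_map`: `raster` (n_radius x n_angle,
#'   apex-centre rows first), bin centre coordinates, and the angular origin.
#' @export
build_polar_map <- function(mbf_map, masks, landmarks, n_radius = 24L,
                            n_angle = 72L, apex = c("low", "high"),
                            clockwise = FALSE) {
  apex <- match.arg(apex)
  mbf <- if (inherits(mbf_map, "perfusion_map")) mbf_map$mbf else mbf_map
  labels <- if (inherits(masks, "heart_masks")) masks$labels else masks
  d <- dim(labels)
  myo_idx <- which(labels == 1L & !is.na(mbf))
  if (length(myo_idx) == 0L) stopf("no myocardial MBF samples")
  ci <- arrayInd(myo_idx, d)
  zs <- sort(unique(ci[, 3]))
  nz <- length(zs)
  zord <- match(ci[, 3], zs)
  if (apex == "high") zord <- nz + 1L - zord

  ang_img <- atan2(ci[, 2] - landmarks$lv_center[2],
                   ci[, 1] - landmarks$lv_center[1]) * 180 / pi
  theta <- wrap_deg(if (clockwise) landmarks$origin_angle_deg - ang_img
                    else ang_img - landmarks$origin_angle_deg)
  abin <- pmin(floor(theta / 360 * n_angle) + 1L, n_angle)

  raster_sum <- matrix(0, n_radius, n_angle)
  raster_n <- matrix(0L, n_radius, n_angle)
  vals <- mbf[myo_idx]
  for (i in seq_along(myo_idx)) {
    r_lo <- floor((zord[i] - 1L) / nz * n_radius) + 1L
    r_hi <- max(r_lo, ceiling(zord[i] / nz * n_radius))
    rows <- r_lo:min(r_hi, n_radius)
    raster_sum[rows, abin[i]] <- raster_sum[rows, abin[i]] + vals[i]
    raster_n[rows, abin[i]] <- raster_n[rows, abin[i]] + 1L
  }
  raster <- raster_sum / ifelse(raster_n > 0L, raster_n, NA_integer_)
  structure(list(raster = raster,
                 angle_deg = (seq_len(n_angle) - 0.5) * 360 / n_angle,
                 radius_frac = (seq_len(n_radius) - 0.5) / n_radius,
                 origin_angle_deg = landmarks$origin_angle_deg),
            class = "polar_map")
}

#' @export
print.polar_map <- function(x, ...) {
  cat(sprintf("Polar MBF map: %d radius x %d angle bins, %.0f%% sampled\n",
              nrow(x$raster), ncol(x$raster),
              100 * mean(is.finite(x$raster))))
  invisible(x)
}

# ring of each radius bin: apical = inner third, mid, basal = outer third
polar_rings <- function(n_radius) {
  cut(seq_len(n_radius), breaks = c(0, n_radius / 3, 2 * n_radius / 3, n_radius),
      labels = c("apical", "mid", "basal"))
}

#' AHA-16 segment report from a polar map
#'
#' Computes per-segment mean MBF over the sampled (non-NaN) polar-map pixels,
#' applying the sampling-exclusion rule: a segment is excluded when fewer
#' than 30% of its geometric pixels are sampled. The apical cap is not part
#' of the model. The global mean is the mean over included segment means.
#'
#' @param polar a [build_polar_map()] result.
#' @param min_sampled_frac exclusion threshold (default 0.30).
#' @return object of class `aha_report`: data.frame with `segment`, `ring`,
#'   `mean_mbf`, `pixel_count`, `area_pixels`, `excluded`, plus attribute
#'   `global_mean_mbf`.
#' @export
aha16_report <- function(polar, min_sampled_frac = 0.30) {
  stopifnot(inherits(polar, "polar_map"))
  geo <- aha_segment_angles()
  rings <- polar_rings(nrow(polar$raster))
  rep_df <- data.frame(segment = geo$segment, ring = geo$ring,
                       mean_mbf = NA_real_, pixel_count = 0L,
                       area_pixels = 0L, excluded = TRUE)
  for (i in seq_len(nrow(geo))) {
    rsel <- rings == geo$ring[i]
    asel <- angle_in_range(polar$angle_deg, geo$lo[i], geo$hi[i])
    px <- polar$raster[rsel, asel]
    rep_df$area_pixels[i] <- length(px)
    rep_df$pixel_count[i] <- sum(is.finite(px))
    if (rep_df$pixel_count[i] > 0L)
      rep_df$mean_mbf[i] <- mean(px[is.finite(px)])
    rep_df$excluded[i] <-
      rep_df$pixel_count[i] < min_sampled_frac * rep_df$area_pixels[i]
  }
  if (all(rep_df$excluded)) stopf("all AHA segments are excluded")
  attr(rep_df, "global_mean_mbf") <-
    mean(rep_df$mean_mbf[!rep_df$excluded])
  class(rep_df) <- c("aha_report", "data.frame")
  rep_df
}

#' @export
print.aha_report <- function(x, ...) {
  cat("AHA-16 segment report (apical cap excluded)\n")
  print.data.frame(cbind(x[, c("segment", "ring")],
                         mean_mbf = round(x$mean_mbf, 1),
                         sampled = sprintf("%d/%d", x$pixel_count, x$area_pixels),
                         excluded = x$excluded), row.names = FALSE)
  cat(sprintf("global mean MBF (included segments): %.1f mL/min/100g\n",
              attr(x, "global_mean_mbf")))
  invisible(x)
}

#' Territory representative MBF by the adjacent-pair minimum
#'
#' Over all spatially adjacent segment pairs within the territory whose two
#' segments are both included, returns the smallest pair-mean MBF and the
#' minimising pair. Using a pair instead of the single worst segment damps
#' local noise.
#'
#' @param report an [aha16_report()] result.
#' @param territory "LAD", "RCA" or "LCX".
#' @return list with `value` (representative MBF; NA if unevaluable), `pair`
#'   (integer 2-vector or NULL) and `evaluable`.
#' @export
territory_mbf <- function(report, territory = c("LAD", "RCA", "LCX")) {
  territory <- match.arg(territory)
  pairs <- aha_adjacent_pairs(territory)
  best <- list(value = NA_real_, pair = NULL, evaluable = FALSE)
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    ia <- report$segment == a; ib <- report$segment == b
    if (report$excluded[ia] || report$excluded[ib]) next
    m <- mean(c(report$mean_mbf[ia], report$mean_mbf[ib]))
    if (!is.finite(m)) next
    if (!best$evaluable || m < best$value) {
      best <- list(value = m, pair = c(a, b), evaluable = TRUE)
    }
  }
  best
}

#' Relative MBF normalisation
#'
#' Adds a `relative_mbf` column: each segment's MBF divided by the largest
#' territory representative MBF, so the reference (best-perfused) territory
#' has representative relative MBF 1.
#'
#' @param report an [aha16_report()] result.
#' @return the report with a `relative_mbf` column and attribute
#'   `reference_mbf`.
#' @export
relative_mbf <- function(report) {
  reps <- vapply(names(aha_territories()),
                 function(tr) territory_mbf(report, tr)$value, numeric(1))
  if (all(is.na(reps))) stopf("no evaluable territory")
  ref <- max(reps, na.rm = TRUE)
  if (!is.finite(ref) || ref <= 0) stopf("maximum representative MBF must be > 0")
  report$relative_mbf <- report$mean_mbf / ref
  attr(report, "reference_mbf") <- ref
  report
}

#' Flag ischemic values against an MBF threshold
#'
#' Strict inequality: a value exactly at the threshold is not ischemic.
#'
#' @param values numeric MBF values (vectorised; NA propagates).
#' @param threshold abnormal-flow MBF threshold, mL·min^-1·(100 g)^-1; the
#'   operating value derived in this framework is 200.
#' @return logical vector.
#' @export
classify_ischemic <- function(values, threshold = 200) {
  if (threshold <= 0) stopf("threshold must be > 0")
  values < threshold
}
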