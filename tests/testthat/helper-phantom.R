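# Shared fixtures: small phantom configurations and a per-session cache so
# expensive studies are built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# compact phantom (~160 myocardial voxels) for fit-heavy simulations
small_phantom_config <- function(noise_sd_hu = 0, ...) {
  phantom_config(
    grid_shape = c(24L, 24L, 4L), voxel_mm = c(2, 2, 2),
    heart_center_mm = c(22, 24), lv_radius_mm = 6,
    myo_inner_mm = 6, myo_outer_mm = 10,
    aorta_center_mm = c(40, 24), aorta_radius_mm = 5,
    sector_truth = list(list(angle_deg = c(0, 360), slices = c(1L, 4L),
                             mbf = 300, delay_s = 2, k_decay = 0.15)),
    noise_sd_hu = noise_sd_hu, ...)
}

# default-geometry phantom with a low-flow sector spanning the given image
# angles (degrees)
deficit_phantom_config <- function(angle_deg = c(60, 180), mbf_low = 150,
                                   mbf_high = 300, noise_sd_hu = 10, ...) {
  phantom_config(
    sector_truth = list(
      list(angle_deg = angle_deg, slices = c(1L, 8L), mbf = mbf_low,
           delay_s = 2, k_decay = 0.15),
      list(angle_deg = rev(angle_deg), slices = c(1L, 8L), mbf = mbf_high,
           delay_s = 2, k_decay = 0.15)),
    noise_sd_hu = noise_sd_hu, ...)
}

default_noiseless_study <- function() {
  cached("default_noiseless", function()
    build_phantom(phantom_config(noise_sd_hu = 0), seed = 1L))
}

default_times <- function() seq(0, 30, by = 1)

default_aif <- function() {
  cached("default_aif", function() make_aif(aif_params(), default_times()))
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# synthetic cohort table of two normal strata, in the cohort_table schema
two_normal_table <- function(n_per = 500L, mean_neg = 274, sd_neg = 62,
                             mean_pos = 165, sd_pos = 61, seed = 1L) {
  set.seed(seed)
  data.frame(
    patient_id = sprintf("P%04d", seq_len(2L * n_per)),
    cadrads = rep(c(0L, 4L), each = n_per),
    territory_mbf = c(stats::rnorm(n_per, mean_neg, sd_neg),
                      stats::rnorm(n_per, mean_pos, sd_pos)))
}

# independent closed-form oracle: Youden-optimal threshold for two normal
# densities is their crossing point between the means
analytic_youden_optimum <- function(mean_pos = 165, sd_pos = 61,
                                    mean_neg = 274, sd_neg = 62) {
  stats::uniroot(function(x) stats::dnorm(x, mean_pos, sd_pos) -
                   stats::dnorm(x, mean_neg, sd_neg),
                 c(mean_pos, mean_neg))$root
}

# brute-force ROC oracle: scan every midpoint candidate directly
youden_oracle <- function(values, positive) {
  u <- sort(unique(values))
  cand <- (u[-length(u)] + u[-1]) / 2
  best_j <- -Inf; best_c <- NA_real_
  for (cth in cand) {
    sens <- mean(values[positive] < cth)
    spec <- mean(values[!positive] >= cth)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) { best_j <- j; best_c <- cth }
  }
  best_c
}
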