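#' Synthetic cohort configuration
#'
#' Parameters of the synthetic per-territory cohort generator. The default
#' group separations are the per-vessel territory MBF means reported for
#' obstructed vs non-obstructed territories after excluding diabetics
#' (165 +/- 61 vs 274 +/- 62 mL·min^-1·(100 g)^-1); microvascular-disease
#' (MVD) patients draw all territories from a globally reduced distribution.
#'
#' @param n_patients number of patients; each contributes one row per vessel
#'   (LAD, LCX, RCA).
#' @param p_diabetes probability a patient is diabetic.
#' @param p_female probability a patient is female.
#' @param p_mvd_diabetes probability a diabetic patient has diffuse MVD.
#' @param nonobstructed_mean,nonobstructed_sd territory MBF distribution for
#'   CAD-RADS < 3 territories, mL·min^-1·(100 g)^-1.
#' @param obstructed_mean,obstructed_sd territory MBF distribution for
#'   CAD-RADS >= 3 territories.
#' @param mvd_global_mean,mvd_global_sd territory MBF distribution for MVD
#'   patients (all territories, regardless of CAD-RADS).
#' @param cadrads_probabilities length-6 probability vector over per-vessel
#'   CAD-RADS grades 0..5.
#' @param seed integer RNG seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 200L,
                          p_diabetes = 0.17,
                          p_female = 0.39,
                          p_mvd_diabetes = 0.6,
                          nonobstructed_mean = 274, nonobstructed_sd = 62,
                          obstructed_mean = 165, obstructed_sd = 61,
                          mvd_global_mean = 130, mvd_global_sd = 35,
                          cadrads_probabilities = c(0.40, 0.20, 0.23, 0.09, 0.07, 0.01),
                          seed = 1L) {
  pr <- c(p_diabetes, p_female, p_mvd_diabetes)
  if (any(pr < 0 | pr > 1)) stopf("probabilities must be in [0, 1]")
  if (any(c(nonobstructed_sd, obstructed_sd, mvd_global_sd) <= 0))
    stopf("sds must be > 0")
  if (length(cadrads_probabilities) != 6L || any(cadrads_probabilities < 0))
    stopf("cadrads_probabilities must be 6 nonnegative values")
  cadrads_probabilities <- cadrads_probabilities / sum(cadrads_probabilities)
  structure(list(n_patients = as.integer(n_patients), p_diabetes = p_diabetes,
                 p_female = p_female, p_mvd_diabetes = p_mvd_diabetes,
                 nonobstructed_mean = nonobstructed_mean,
                 nonobstructed_sd = nonobstructed_sd,
                 obstructed_mean = obstructed_mean,
                 obstructed_sd = obstructed_sd,
                 mvd_global_mean = mvd_global_mean,
                 mvd_global_sd = mvd_global_sd,
                 cadrads_probabilities = cadrads_probabilities,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a synthetic per-territory cohort
#'
#' One row per (patient, vessel). Per-vessel CAD-RADS grades are drawn from
#' the configured distribution; territory MBF is drawn from the obstructed
#' distribution iff CAD-RADS >= 3, otherwise from the non-obstructed
#' distribution. Diabetic patients are MVD with probability
#' `p_mvd_diabetes`; MVD patients draw every territory from the globally
#' reduced MVD distribution regardless of CAD-RADS. MBF values are truncated
#' at zero. Ground-truth labels (`is_mvd`, `is_obstructed`) are retained.
#'
#' @param config a [cohort_config()].
#' @return data.frame of class `cohort_table` with columns `patient_id`,
#'   `sex` ("F"/"M"), `diabetes` (logical), `vessel` ("LAD"/"LCX"/"RCA"),
#'   `cadrads` (integer 0..5), `territory_mbf`, `is_mvd`, `is_obstructed`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cf <- config
  set.seed(cf$seed)
  vessels <- c("LAD", "LCX", "RCA")
  n <- cf$n_patients
  sex <- ifelse(stats::runif(n) < cf$p_female, "F", "M")
  diabetes <- stats::runif(n) < cf$p_diabetes
  is_mvd <- diabetes & stats::runif(n) < cf$p_mvd_diabetes
  rows <- data.frame(
    patient_id = rep(sprintf("P%04d", seq_len(n)), each = 3L),
    sex = rep(sex, each = 3L),
    diabetes = rep(diabetes, each = 3L),
    vessel = rep(vessels, times = n),
    stringsAsFactors = FALSE)
  rows$cadrads <- sample(0:5, nrow(rows), replace = TRUE,
                         prob = cf$cadrads_probabilities)
  rows$is_obstructed <- is_obstructive(rows$cadrads)
  rows$is_mvd <- rep(is_mvd, each = 3L)
  mu <- ifelse(rows$is_mvd, cf$mvd_global_mean,
               ifelse(rows$is_obstructed, cf$obstructed_mean,
                      cf$nonobstructed_mean))
  sdv <- ifelse(rows$is_mvd, cf$mvd_global_sd,
                ifelse(rows$is_obstructed, cf$obstructed_sd,
                       cf$nonobstructed_sd))
  rows$territory_mbf <- pmax(0, stats::rnorm(nrow(rows), mu, sdv))
  rows <- rows[, c("patient_id", "sex", "diabetes", "vessel", "cadrads",
                   "territory_mbf", "is_mvd", "is_obstructed")]
  class(rows) <- c("cohort_table", "data.frame")
  rows
}
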