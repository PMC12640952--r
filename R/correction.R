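# Image-based automated beam-hardening correction (ABHC).
#
# The artifact model is an enhancement-scaled radial polynomial (cupping)
# matching the family simulated by apply_beam_hardening(); the corrector
# searches the polynomial coefficients that minimise an image-domain artifact
# cost, with no access to projection data.

# Blood-pool enhancement E(t) per frame, from the LV pool TAC referenced to
# its pre-contrast mean.
blood_enhancement <- function(study, labels) {
  lv <- which(labels == 2L)
  if (length(lv) == 0L) stopf("LV blood-pool mask is empty")
  m <- colMeans(tac_matrix(study, lv))
  cv <- tac_curve(study$frame_times_s, m - min(m))
  onset <- onset_frame(cv)
  pmax(0, m - mean(m[seq_len(onset - 1L)]))
}

# Subtract the polynomial bias with the given coefficients from every frame.
apply_bh_correction <- function(study, labels, coeffs, enh = NULL, geom = NULL) {
  if (is.null(geom)) geom <- heart_geometry(labels, study$spacing_mm)
  if (is.null(enh)) enh <- blood_enhancement(study, labels)
  frames <- study$frames
  for (t in seq_along(study$frame_times_s)) {
    frames[, , , t] <- apply_beam_hardening(frames[, , , t], -coeffs, labels,
                                            enhancement = enh[t],
                                            geometry = geom)
  }
  dynamic_study(frames, study$frame_times_s, study$spacing_mm,
                truth = study$truth)
}

#' Beam-hardening artifact cost
#'
#' Image-domain cost functional driving the automated correction. For a
#' candidate coefficient vector the correction is applied, then
#' \deqn{cost = \mathrm{mean}_t\, \mathrm{Var}(HU_{myo}(t)) +
#'   \lambda\, \mathrm{mean}\, (\Delta_t \bar{HU}_{myo})^2}
#' where the first (spatial) term is the within-myocardium HU variance per
#' frame (mean-removed, so a global HU offset does not change the cost) and
#' the second (temporal) term is the mean squared frame-to-frame change of
#' the mean myocardial HU over the pre-contrast frames — the window where
#' true enhancement is flat, so fluctuation there is artifact or
#' correction-injected error. Deterministic; lower is better.
#'
#' @param study a [dynamic_study()].
#' @param masks heart label array or `heart_masks` (1 = myocardium, 2 = LV).
#' @param coeffs candidate correction coefficients (powers 1..3 of r/R).
#' @param lambda weight of the temporal term.
#' @return scalar cost (HU^2).
#' @export
bh_cost <- function(study, masks, coeffs = c(0, 0, 0), lambda = 1.0) {
  labels <- if (inherits(masks, "heart_masks")) masks$labels else masks
  if (!any(labels == 1L)) stopf("myocardium mask is empty")
  prep <- bh_prepare(study, labels)
  bh_cost_prepared(prep, coeffs, lambda)
}

# Precompute everything the cost needs so the optimiser evaluates cheaply:
# myocardial TAC matrix and the radial-power bias bases restricted to the
# myocardium.
bh_prepare <- function(study, labels) {
  geom <- heart_geometry(labels, study$spacing_mm)
  enh <- blood_enhancement(study, labels)
  myo_idx <- which(labels == 1L)
  tacs <- tac_matrix(study, myo_idx)          # n_myo x n_frames, raw HU
  ci <- arrayInd(myo_idx, dim(labels))
  rn <- geom$r2d[cbind(ci[, 1], ci[, 2])] / geom$rmax
  pows <- lapply(1:3, function(p) outer(rn^p, enh))  # n_myo x n_frames each
  aif_like <- tac_curve(study$frame_times_s, enh + 1e-9)
  onset <- onset_frame(aif_like)
  # pre-contrast frames: the only window where true myocardial enhancement is
  # flat, so any frame-to-frame change there is artifact or injected error
  flat_frames <- seq_len(max(onset - 1L, 1L))
  list(tacs = tacs, pows = pows, enh = enh, geom = geom,
       flat_frames = flat_frames, labels = labels)
}

bh_cost_prepared <- function(prep, coeffs, lambda = 1.0) {
  coeffs <- c(as.numeric(coeffs), numeric(3L))[1:3]
  m <- prep$tacs - coeffs[1] * prep$pows[[1]] - coeffs[2] * prep$pows[[2]] -
    coeffs[3] * prep$pows[[3]]
  spatial <- mean(apply(m, 2, stats::var))
  mt <- colMeans(m)
  dmt <- diff(mt[prep$flat_frames])
  temporal <- if (length(dmt) > 0) mean(dmt^2) else 0
  spatial + lambda * temporal
}

#' Automated beam-hardening correction
#'
#' Minimises [bh_cost()] over the polynomial correction coefficients by
#' derivative-free Nelder-Mead simplex search started from the zero vector
#' (identity correction), then applies the best correction to every frame.
#' The result never has a larger cost than the identity: if the search fails
#' to improve, the study is returned unchanged with `converged = FALSE`.
#'
#' @param study a [dynamic_study()].
#' @param masks heart label array or `heart_masks`.
#' @param lambda temporal-term weight in the cost.
#' @param maxit maximum simplex iterations.
#' @return list with `study` (corrected [dynamic_study()]), `coeffs` (fitted
#'   coefficients, powers 1..3), `cost` and `cost_identity`, and `converged`.
#' @export
correct_beam_hardening <- function(study, masks, lambda = 1.0, maxit = 300L) {
  labels <- if (inherits(masks, "heart_masks")) masks$labels else masks
  if (!any(labels == 1L)) stopf("myocardium mask is empty")
  prep <- bh_prepare(study, labels)
  cost0 <- bh_cost_prepared(prep, c(0, 0, 0), lambda)
  opt <- tryCatch(
    stats::optim(c(0, 0, 0), function(cc) bh_cost_prepared(prep, cc, lambda),
                 method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value) || opt$value > cost0) {
    warning("beam-hardening search did not improve on identity; returning input")
    return(list(study = study, coeffs = c(0, 0, 0), cost = cost0,
                cost_identity = cost0, converged = FALSE))
  }
  corrected <- apply_bh_correction(study, labels, opt$par, enh = prep$enh,
                                   geom = prep$geom)
  list(study = corrected, coeffs = opt$par, cost = opt$value,
       cost_identity = cost0, converged = opt$convergence == 0)
}
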