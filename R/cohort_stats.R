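# Cohort-level statistics: CAD-RADS grading, bootstrap ROC / Youden
# threshold derivation, rank correlation, group tests, and the
# obstructive-vs-microvascular discordance classifier.

#' CAD-RADS grade from percent stenosis
#'
#' Bins luminal diameter stenosis into CAD-RADS 0-5: 0 (0%), 1 (1-24%),
#' 2 (25-49%), 3 (50-69%), 4 (70-99%), 5 (100%). Fractional percentages are
#' truncated toward zero before binning (clinical reads are integers).
#'
#' @param stenosis_percent numeric in \[0, 100\] (vectorised).
#' @return integer grades 0..5.
#' @export
cadrads_from_stenosis <- function(stenosis_percent) {
  if (any(!is.finite(stenosis_percent)) ||
      any(stenosis_percent < 0 | stenosis_percent > 100))
    stopf("stenosis_percent must be in [0, 100]")
  p <- trunc(stenosis_percent)
  ifelse(p == 0, 0L,
  ifelse(p <= 24, 1L,
  ifelse(p <= 49, 2L,
  ifelse(p <= 69, 3L,
  ifelse(p <= 99, 4L, 5L)))))
}

#' Is a CAD-RADS grade obstructive?
#'
#' CAD-RADS >= 3 (>= 50% stenosis) is deemed obstructive.
#'
#' @param grade integer 0..5 (vectorised).
#' @return logical.
#' @export
is_obstructive <- function(grade) {
  if (any(!grade %in% 0:5)) stopf("grade must be in 0..5")
  grade >= 3
}

# Empirical Youden-optimal threshold for one sample. Positive = low-flow
# class; the positive call is value < threshold. Candidates are midpoints of
# sorted unique values; ties in J resolve to the lowest threshold.
youden_threshold <- function(values, positive) {
  u <- sort(unique(values))
  if (length(u) < 2L) return(u[1])
  cand <- (u[-length(u)] + u[-1L]) / 2
  npos <- sum(positive); nneg <- sum(!positive)
  # counts of observations <= u_i, cumulated over the sorted unique grid
  ord <- order(values)
  vs <- values[ord]; ps <- positive[ord]
  cum_pos <- cumsum(ps)[findInterval(u, vs)]
  cum_neg <- cumsum(!ps)[findInterval(u, vs)]
  # integer-scaled Youden score (J * npos * nneg): exact tie comparisons, so
  # equal-J candidates resolve to the lowest threshold
  j <- cum_pos[-length(u)] * nneg - cum_neg[-length(u)] * npos
  cand[which.max(j)]  # which.max returns the first (lowest) maximiser
}

#' Bootstrap ROC / Youden optimal MBF threshold
#'
#' Restricts the table to the unequivocal CAD-RADS grades 0 and 4 (grade 4 is
#' the positive, low-flow-expected class), then for each bootstrap replicate
#' resamples rows (or patients with all their territories, when stratified),
#' computes the empirical ROC over candidate thresholds (midpoints of the
#' sorted unique MBF values, with "MBF < threshold" the positive call) and
#' takes the threshold maximising the Youden index J = sensitivity +
#' specificity - 1 (ties resolve to the lowest threshold). Returns the mean
#' replicate threshold and the percentile 95% confidence interval.
#'
#' @param table a `cohort_table` data.frame (columns `territory_mbf`,
#'   `cadrads`, `patient_id`).
#' @param n_boot number of bootstrap replicates.
#' @param stratify_by_patient resample patients (keeping all their
#'   territories) instead of rows.
#' @param seed integer RNG seed; results are deterministic given the seed.
#' @return object of class `threshold_result`: `threshold` (mean over
#'   replicates), `ci_low`, `ci_high`, `n_boot`, `stratified`, `seed`,
#'   `replicates`.
#' @export
bootstrap_youden_threshold <- function(table, n_boot = 1000L,
                                       stratify_by_patient = FALSE,
                                       seed = 1L) {
  tb <- table[table$cadrads %in% c(0L, 4L), , drop = FALSE]
  pos <- tb$cadrads == 4L
  if (nrow(tb) == 0L || all(pos) || all(!pos))
    stopf("need both CAD-RADS 0 and CAD-RADS 4 rows")
  set.seed(as.integer(seed))
  reps <- numeric(n_boot)
  if (stratify_by_patient) {
    pats <- unique(tb$patient_id)
    rows_by_pat <- split(seq_len(nrow(tb)), tb$patient_id)[pats]
    for (b in seq_len(n_boot)) {
      take <- unlist(rows_by_pat[sample(length(pats), replace = TRUE)],
                     use.names = FALSE)
      reps[b] <- youden_threshold(tb$territory_mbf[take], pos[take])
    }
  } else {
    for (b in seq_len(n_boot)) {
      take <- sample(nrow(tb), replace = TRUE)
      reps[b] <- youden_threshold(tb$territory_mbf[take], pos[take])
    }
  }
  ci <- stats::quantile(reps, c(0.025, 0.975), names = FALSE)
  structure(list(threshold = mean(reps), ci_low = ci[1], ci_high = ci[2],
                 n_boot = as.integer(n_boot),
                 stratified = isTRUE(stratify_by_patient),
                 seed = as.integer(seed), replicates = reps),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("Optimal MBF threshold: %.1f mL/min/100g (95%% CI %.1f-%.1f), %d %sbootstraps\n",
              x$threshold, x$ci_low, x$ci_high, x$n_boot,
              if (x$stratified) "patient-stratified " else ""))
  invisible(x)
}

#' Spearman rank correlation with tie correction
#'
#' Mid-rank (average-rank) Spearman's rho, i.e. the Pearson correlation of
#' the tied ranks, with a two-sided p-value from the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}}.
#'
#' @param x,y paired numeric vectors, n >= 3, neither constant.
#' @return list with `rho` and `p`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must be paired")
  n <- length(x)
  if (n < 3L) stopf("need at least 3 pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stopf("inputs must not be constant")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Unpaired two-sample t-test (pooled variance)
#'
#' Two-sided Student's t-test with pooled variance. Degenerate inputs with
#' zero pooled variance return t = 0, p = 1 when the means are equal.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @export
unpaired_ttest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stopf("each group needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b))
    return(list(t = 0, p = 1, df = length(a) + length(b) - 2L,
                mean_a = mean(a), mean_b = mean(b)))
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_a = mean(a), mean_b = mean(b))
}

#' Classify a patient: flow-limiting stenosis vs microvascular disease
#'
#' Combines per-territory CCTA stenosis grades with per-territory MBF and
#' (optionally) the AHA segment report. Rules, evaluated in order:
#' \enumerate{
#'   \item any obstructive territory (CAD-RADS >= 3) with territory
#'     MBF < threshold: `flow_limiting`;
#'   \item all territories non-obstructive and the diffuse criterion holds
#'     (> 50% of included AHA segments ischemic and global mean MBF below
#'     the threshold): `mvd_diffuse`;
#'   \item all territories non-obstructive and >= 1 territory MBF below the
#'     threshold: `mvd_focal`;
#'   \item >= 1 obstructive territory and every territory MBF at or above
#'     the threshold: `discordant_preserved` (possible collateral supply or
#'     anatomically overestimated stenosis);
#'   \item otherwise: `normal`.
#' }
#'
#' @param territories data.frame with columns `vessel`, `representative_mbf`,
#'   `cadrads`; territories with NA representative MBF are unevaluable and
#'   dropped.
#' @param aha_report optional [aha16_report()] result enabling the diffuse
#'   criterion; without it, rule 2 cannot fire and diffuse low flow is
#'   labelled `mvd_focal`.
#' @param threshold ischemia MBF threshold (strict `<`).
#' @return object of class `patient_classification`: `label`, per-territory
#'   `flags` (ischemic, obstructive), `global_mean_mbf` (NA without a
#'   report).
#' @export
classify_patient <- function(territories, aha_report = NULL, threshold = 200) {
  tr <- territories[is.finite(territories$representative_mbf), , drop = FALSE]
  if (nrow(tr) == 0L) stopf("no evaluable territory")
  obstr <- is_obstructive(tr$cadrads)
  isch <- classify_ischemic(tr$representative_mbf, threshold)
  global_mean <- NA_real_
  diffuse <- FALSE
  if (!is.null(aha_report)) {
    inc <- !aha_report$excluded
    seg_isch <- classify_ischemic(aha_report$mean_mbf[inc], threshold)
    global_mean <- attr(aha_report, "global_mean_mbf")
    diffuse <- mean(seg_isch) > 0.5 && global_mean < threshold
  }
  label <-
    if (any(obstr & isch)) "flow_limiting"
    else if (!any(obstr) && diffuse) "mvd_diffuse"
    else if (!any(obstr) && any(isch)) "mvd_focal"
    else if (any(obstr) && !any(isch)) "discordant_preserved"
    else "normal"
  structure(list(label = label,
                 flags = data.frame(vessel = tr$vessel, ischemic = isch,
                                    obstructive = obstr),
                 global_mean_mbf = global_mean, threshold = threshold),
            class = "patient_classification")
}

#' @export
print.patient_classification <- function(x, ...) {
  cat(sprintf("Patient classification: %s (threshold %.0f mL/min/100g)\n",
              x$label, x$threshold))
  print.data.frame(x$flags, row.names = FALSE)
  invisible(x)
}

#' Cohort summary statistics
#'
#' Per-patient classification of a cohort table plus group descriptive
#' statistics: subgroup counts by diabetes and obstructive-vessel count,
#' obstructed vs non-obstructed territory means and their t-test, and the
#' Spearman correlation of territory MBF with CAD-RADS. A patient is
#' predicted to have microvascular disease when the mean MBF of their
#' non-obstructed territories (all territories, if every vessel is
#' obstructed) is below the threshold — focal flow-limiting disease lowers
#' MBF only downstream of the stenosis, so preserved territories are where
#' diffuse MVD is visible.
#'
#' @param table a `cohort_table` data.frame.
#' @param threshold ischemia MBF threshold.
#' @return object of class `cohort_summary`: `patients` (per-patient labels
#'   and MVD prediction), `counts` (label x subgroup), `territory_stats`,
#'   `spearman`, and `mvd_confusion` when truth labels are present.
#' @export
cohort_summary <- function(table, threshold = 200) {
  stopifnot(all(c("patient_id", "vessel", "cadrads", "territory_mbf") %in%
                  names(table)))
  by_pat <- split(table, table$patient_id)
  labels <- character(length(by_pat))
  mvd_pred <- logical(length(by_pat))
  n_obstr <- integer(length(by_pat))
  diab <- logical(length(by_pat))
  for (i in seq_along(by_pat)) {
    p <- by_pat[[i]]
    terr <- data.frame(vessel = p$vessel, representative_mbf = p$territory_mbf,
                       cadrads = p$cadrads)
    labels[i] <- classify_patient(terr, threshold = threshold)$label
    nonob <- !is_obstructive(p$cadrads)
    ref <- if (any(nonob)) p$territory_mbf[nonob] else p$territory_mbf
    mvd_pred[i] <- mean(ref) < threshold
    n_obstr[i] <- sum(!nonob)
    diab[i] <- isTRUE(p$diabetes[1])
  }
  patients <- data.frame(patient_id = names(by_pat), label = labels,
                         mvd_pred = mvd_pred, n_obstructive = n_obstr,
                         diabetes = diab)
  subgroup <- interaction(ifelse(diab, "DM", "noDM"),
                          cut(n_obstr, c(-1, 0, 1, 3),
                              labels = c("0v", "1v", "multi")), drop = FALSE)
  counts <- table(factor(labels, levels = c("normal", "flow_limiting",
                                            "mvd_focal", "mvd_diffuse",
                                            "discordant_preserved")),
                  subgroup)
  ob <- is_obstructive(table$cadrads)
  tstat <- if (sum(ob) >= 2 && sum(!ob) >= 2)
    unpaired_ttest(table$territory_mbf[ob], table$territory_mbf[!ob]) else NULL
  terr_stats <- data.frame(
    group = c("obstructed", "non_obstructed"),
    n = c(sum(ob), sum(!ob)),
    mean_mbf = c(mean(table$territory_mbf[ob]), mean(table$territory_mbf[!ob])),
    sd_mbf = c(stats::sd(table$territory_mbf[ob]),
               stats::sd(table$territory_mbf[!ob])))
  sp <- spearman_rho(table$territory_mbf, table$cadrads)
  out <- list(patients = patients, counts = counts,
              territory_stats = terr_stats, ttest = tstat, spearman = sp,
              threshold = threshold)
  if ("is_mvd" %in% names(table)) {
    truth <- vapply(by_pat, function(p) isTRUE(p$is_mvd[1]), logical(1))
    out$mvd_confusion <- list(
      sensitivity = if (any(truth)) mean(mvd_pred[truth]) else NA_real_,
      specificity = if (any(!truth)) mean(!mvd_pred[!truth]) else NA_real_,
      n_mvd = sum(truth), n_non_mvd = sum(!truth))
  }
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary (%d patients, threshold %.0f mL/min/100g)\n",
              nrow(x$patients), x$threshold))
  print(x$counts)
  print(x$territory_stats, row.names = FALSE)
  cat(sprintf("Spearman rho(MBF, CAD-RADS) = %.3f (p = %.2g)\n",
              x$spearman$rho, x$spearman$p))
  if (!is.null(x$ttest))
    cat(sprintf("obstructed vs non-obstructed t = %.2f (p = %.2g)\n",
                x$ttest$t, x$ttest$p))
  if (!is.null(x$mvd_confusion))
    cat(sprintf("MVD truth recovery: sensitivity %.2f, specificity %.2f\n",
                x$mvd_confusion$sensitivity, x$mvd_confusion$specificity))
  invisible(x)
}
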