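#' Analytical-validation statistics
#'
#' Diagnostic-accuracy summaries used in panel validation against an
#' orthogonal reference method: positive and negative percent agreement
#' (PPA = TP/(TP+FN), NPA = TN/(TN+FP)) with exact Clopper-Pearson
#' confidence intervals, zygosity concordance, replicate precision
#' (repeatability and reproducibility) and condition-vs-control variant
#' detection rates.
#'
#' @name validation_stats
NULL

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Two-sided equal-tailed exact interval obtained by inverting the binomial
#' tail probabilities (beta-quantile closed form). At the boundaries,
#' `x = 0` gives `low = 0`, `high = 1 - (alpha/2)^(1/n)`; `x = n` gives
#' `low = (alpha/2)^(1/n)`, `high = 1`.
#'
#' @param x number of successes (0..n).
#' @param n number of trials (>= 1).
#' @param level confidence level (default 0.95).
#' @return numeric vector `c(low, high)` on the proportion scale.
#' @export
clopper_pearson <- function(x, n, level = 0.95) {
  if (n < 1) stop("n must be >= 1")
  if (x < 0 || x > n) stop("x must be in 0..n")
  alpha <- 1 - level
  low <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  high <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(low = low, high = high)
}

#' PPA/NPA concordance against a reference method
#'
#' @param tp,fp,fn,tn non-negative counts. TP: variant detected by both
#'   methods; FN: reference-only; FP: panel-only; TN: concordantly negative
#'   positions.
#' @param level confidence level for the exact intervals (default 0.95).
#' @return a `concordance_result` list: the counts, `ppa`/`npa` (proportion
#'   scale, `NA` when the denominator is zero) and `ppa_ci`/`npa_ci`.
#' @export
concordance <- function(tp, fp, fn, tn, level = 0.95) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("all counts are zero")
  ppa <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  npa <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn, level = level,
    ppa = ppa,
    npa = npa,
    ppa_ci = if (!is.na(ppa)) clopper_pearson(tp, tp + fn, level) else c(low = NA_real_, high = NA_real_),
    npa_ci = if (!is.na(npa)) clopper_pearson(tn, tn + fp, level) else c(low = NA_real_, high = NA_real_)),
    class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  pct <- function(p) if (is.na(p)) "n/a" else sprintf("%.1f%%", 100 * p)
  cat(sprintf("PPA %s (%.0f%% CI: %s-%s)  [TP %d, FN %d]\n",
              pct(x$ppa), 100 * x$level, pct(x$ppa_ci[["low"]]),
              pct(x$ppa_ci[["high"]]), x$tp, x$fn))
  cat(sprintf("NPA %s (%.0f%% CI: %s-%s)  [TN %d, FP %d]\n",
              pct(x$npa), 100 * x$level, pct(x$npa_ci[["low"]]),
              pct(x$npa_ci[["high"]]), x$tn, x$fp))
  invisible(x)
}

#' Zygosity concordance between panel calls and a reference method
#'
#' Labels are collapsed to the two clinically relevant groups:
#' homozygous/hemizygous vs heterozygous.
#'
#' @param truth,called character vectors of equal, positive length with
#'   values in `heterozygous`, `homozygous`, `hemizygous` (or the collapsed
#'   `hom_hemi`/`het`).
#' @return list with the 2x2 `table` (truth rows, call columns), `n` and
#'   `concordance_rate`.
#' @export
zygosity_concordance <- function(truth, called) {
  if (!length(truth) || length(truth) != length(called))
    stop("truth and called must be non-empty and paired")
  collapse <- function(z) {
    z <- ifelse(z %in% c("homozygous", "hemizygous", "hom_hemi"), "hom_hemi",
         ifelse(z %in% c("heterozygous", "het"), "het", NA))
    if (anyNA(z)) stop("zygosity labels must be heterozygous/homozygous/hemizygous")
    factor(z, levels = c("hom_hemi", "het"))
  }
  t2 <- table(truth = collapse(truth), called = collapse(called))
  list(table = t2, n = length(truth),
       concordance_rate = sum(diag(t2)) / length(truth))
}

#' Full-factorial replicate design for precision studies
#'
#' @param n_operators,n_lots,n_days,n_replicates design dimensions
#'   (defaults 2 operators x 3 reagent lots x 3 days x 8 replicates = 144).
#' @return a data.frame with one row per replicate: `replicate_id`,
#'   `operator`, `lot`, `day`, `rep`.
#' @export
replicate_design <- function(n_operators = 2L, n_lots = 3L, n_days = 3L,
                             n_replicates = 8L) {
  g <- expand.grid(rep = seq_len(n_replicates), day = seq_len(n_days),
                   lot = seq_len(n_lots), operator = seq_len(n_operators))
  g <- g[, c("operator", "lot", "day", "rep")]
  g$replicate_id <- sprintf("op%d_lot%d_day%d_rep%d",
                            g$operator, g$lot, g$day, g$rep)
  g[, c("replicate_id", "operator", "lot", "day", "rep")]
}

#' Repeatability and reproducibility of replicate variant detection
#'
#' Repeatability compares the replicates of one design cell (same operator,
#' lot and day); reproducibility pools all replicates. Agreement is the
#' fraction of expected variant observations (expected variants x
#' replicates) that were detected, reported per variant class.
#'
#' @param design data.frame from [replicate_design()].
#' @param expected data.frame of truth variants with columns `id` and
#'   `class` (`"SNV"` or `"indel"`).
#' @param detected named list: for each `replicate_id`, a character vector
#'   of detected variant `id`s. Optionally each element may instead be a
#'   data.frame with columns `id` and `vaf`.
#' @return list with `reproducibility` (per-class detected/expected and
#'   agreement), `repeatability` (per design cell and class), and
#'   `vaf_summary` (per-variant mean and sd of VAF across replicates, when
#'   VAFs were supplied).
#' @export
precision_agreement <- function(design, expected, detected) {
  missing_cells <- setdiff(design$replicate_id, names(detected))
  if (length(missing_cells))
    stop("missing detection results for design cells: ",
         paste(missing_cells, collapse = ", "))
  ids_of <- function(x) if (is.data.frame(x)) x$id else x
  classes <- sort(unique(expected$class))
  per_class_counts <- function(rep_ids) {
    sapply(classes, function(cl) {
      ids <- expected$id[expected$class == cl]
      exp_n <- length(ids) * length(rep_ids)
      det_n <- sum(vapply(rep_ids, function(r)
        sum(ids %in% ids_of(detected[[r]])), 0L))
      c(detected = det_n, expected = exp_n)
    })
  }
  repro_counts <- per_class_counts(design$replicate_id)
  reproducibility <- data.frame(
    class = classes,
    detected = repro_counts["detected", ],
    expected = repro_counts["expected", ],
    agreement = repro_counts["detected", ] / repro_counts["expected", ],
    row.names = NULL)
  cells <- split(design$replicate_id,
                 interaction(design$operator, design$lot, design$day, drop = TRUE))
  repeatability <- do.call(rbind, lapply(names(cells), function(cell) {
    ct <- per_class_counts(cells[[cell]])
    data.frame(cell = cell, class = classes,
               detected = ct["detected", ], expected = ct["expected", ],
               agreement = ct["detected", ] / ct["expected", ],
               row.names = NULL)
  }))
  vaf_summary <- NULL
  if (all(vapply(detected, is.data.frame, TRUE))) {
    long <- do.call(rbind, lapply(names(detected), function(r)
      cbind(detected[[r]], replicate_id = r)))
    agg <- split(long$vaf, long$id)
    vaf_summary <- data.frame(
      id = names(agg),
      n = lengths(agg),
      mean_vaf = vapply(agg, mean, 0.0),
      sd_vaf = vapply(agg, stats::sd, 0.0),
      row.names = NULL)
  }
  list(reproducibility = reproducibility, repeatability = repeatability,
       vaf_summary = vaf_summary)
}

#' Condition-vs-control variant detection rate
#'
#' The denominator is the set of variants detected in the control condition
#' (not a truth set); variants seen only under the test condition are
#' reported as `gained`, not folded into the rate.
#'
#' @param control data.frame of control-detected variants with columns `id`
#'   and `class`.
#' @param condition character vector (or data.frame with `id`) of variant
#'   ids detected under the test condition.
#' @param label condition label carried into the result.
#' @return a data.frame with one row per class: `condition`, `class`,
#'   `n_control`, `n_condition`, `rate`, `gained`.
#' @export
detection_rate <- function(control, condition, label = "condition") {
  if (!nrow(control)) stop("empty control set")
  cond_ids <- if (is.data.frame(condition)) condition$id else condition
  out <- do.call(rbind, lapply(sort(unique(control$class)), function(cl) {
    ids <- control$id[control$class == cl]
    data.frame(condition = label, class = cl,
               n_control = length(ids),
               n_condition = sum(ids %in% cond_ids),
               rate = mean(ids %in% cond_ids))
  }))
  out$gained <- length(setdiff(cond_ids, control$id))
  out
}
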