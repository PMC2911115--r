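#' Confusion counts at a cutoff rank
#'
#' Genes ranked at or above the cutoff are predicted positive; counts are
#' computed over benchmark genes only.
#'
#' @param scores An `lls_scores` table.
#' @param cutoff Rank cutoff in `1..N`.
#' @param positives,negatives Benchmark gene sets; both must be subsets of
#'   the scored universe and disjoint.
#' @return Named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusion_at_cutoff <- function(scores, cutoff, positives, negatives) {
  n <- nrow(scores)
  if (length(cutoff) != 1 || is.na(cutoff) || cutoff < 1 || cutoff > n) {
    abort(sprintf("cutoff must lie in 1..%d", n))
  }
  outside <- setdiff(c(positives, negatives), scores$gene)
  if (length(outside) > 0) {
    abort(sprintf("benchmark gene(s) outside the scored universe: %s",
                  paste(head(outside, 5), collapse = ", ")))
  }
  predicted <- scores$gene[scores$rank <= cutoff]
  tp <- length(intersect(positives, predicted))
  fp <- length(intersect(negatives, predicted))
  c(tp = tp, fp = fp, tn = length(negatives) - fp, fn = length(positives) - tp)
}

#' Quality metrics of a binary classification
#'
#' Standard confusion-based measures: sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)`, accuracy
#' `(TP+TN)/(TP+TN+FP+FN)` and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. Any metric with
#' a zero denominator is reported as missing, never silently zero; the MCC
#' is missing if any of its four factors is zero.
#'
#' @param counts Named vector or list with `tp`, `fp`, `tn`, `fn` (as from
#'   [confusion_at_cutoff()]); alternatively pass the four counts via the
#'   named arguments.
#' @param tp,fp,tn,fn Individual counts (ignored when `counts` is given).
#' @return One-row tibble with columns `sensitivity`, `specificity`,
#'   `precision`, `accuracy`, `mcc`.
#' @export
quality_metrics <- function(counts = NULL, tp = NULL, fp = NULL, tn = NULL, fn = NULL) {
  if (!is.null(counts)) {
    counts <- as.list(counts)
    tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  }
  if (any(c(tp, fp, tn, fn) < 0)) abort("counts must be non-negative")
  if (tp + fp + tn + fn == 0) abort("all-zero confusion counts")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
  tibble::tibble(
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    precision = safe_div(tp, tp + fp),
    accuracy = safe_div(tp + tn, tp + tn + fp + fn),
    mcc = if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / sqrt(mcc_den))
}

# Vectorized metric curves for one positive benchmark against the shared
# negative benchmark, over every cutoff rank. Returns a tibble of N rows.
metric_curve <- function(scores, positives, negatives) {
  ord <- scores |> dplyr::arrange(.data$rank)
  is_pos <- ord$gene %in% positives
  is_neg <- ord$gene %in% negatives
  tp <- cumsum(is_pos)
  fp <- cumsum(is_neg)
  fn <- length(intersect(positives, ord$gene)) - tp
  tn <- length(intersect(negatives, ord$gene)) - fp
  safe <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  mcc_den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  tibble::tibble(
    rank = ord$rank, gene = ord$gene,
    sensitivity = safe(tp, tp + fn),
    specificity = safe(tn, tn + fp),
    precision = safe(tp, tp + fp),
    accuracy = safe(tp + tn, tp + tn + fp + fn),
    mcc = ifelse(mcc_den == 0, NA_real_, (tp * tn - fp * fn) / sqrt(mcc_den)))
}

#' Per-rank quality-metric profile combined over two positive benchmarks
#'
#' Each metric is computed at every cutoff rank separately against the two
#' positive benchmarks (sharing one negative benchmark) and the two values
#' are combined by geometric mean. The MCC, being signed, is combined on
#' the shifted scale `(MCC + 1) / 2` and back-transformed, which keeps the
#' combination well-defined for negative values and reduces to the plain
#' geometric mean on identical inputs. Sensitivity is checked to be
#' non-decreasing and specificity non-increasing in the cutoff rank for
#' each benchmark (a structural property of threshold classifiers),
#' guarding against bookkeeping errors on every run.
#'
#' @param scores An `lls_scores` table.
#' @param bench_pos1,bench_pos2 The two positive benchmark gene sets.
#' @param bench_neg The negative benchmark gene set.
#' @return A tibble of class `metric_profile`: `rank`, `gene`, combined
#'   `sensitivity`, `specificity`, `precision`, `accuracy`, `mcc`, plus the
#'   per-benchmark curves in suffixed columns.
#' @export
metric_profile <- function(scores, bench_pos1, bench_pos2, bench_neg) {
  if (length(bench_pos1) == 0 || length(bench_pos2) == 0 || length(bench_neg) == 0) {
    abort("benchmarks must be non-empty")
  }
  c1 <- metric_curve(scores, bench_pos1, bench_neg)
  c2 <- metric_curve(scores, bench_pos2, bench_neg)
  for (curve in list(c1, c2)) {
    sens <- curve$sensitivity[!is.na(curve$sensitivity)]
    spec <- curve$specificity[!is.na(curve$specificity)]
    if (is.unsorted(sens) || is.unsorted(rev(spec))) {
      abort("metric curve violated threshold monotonicity; scoring is inconsistent")
    }
  }
  out <- tibble::tibble(
    rank = c1$rank, gene = c1$gene,
    sensitivity = geo_mean2(c1$sensitivity, c2$sensitivity),
    specificity = geo_mean2(c1$specificity, c2$specificity),
    precision = geo_mean2(c1$precision, c2$precision),
    accuracy = geo_mean2(c1$accuracy, c2$accuracy),
    mcc = geo_mean_mcc(c1$mcc, c2$mcc))
  for (m in c("sensitivity", "specificity", "precision", "accuracy", "mcc")) {
    out[[paste0(m, "_1")]] <- c1[[m]]
    out[[paste0(m, "_2")]] <- c2[[m]]
  }
  class(out) <- c("metric_profile", class(out))
  out
}

#' Select the target cutoff under quality constraints
#'
#' Among cutoff ranks whose combined metrics satisfy every constraint
#' (default: accuracy >= 0.80, precision >= 0.80, specificity >= 0.90), the
#' rank maximizing the combined MCC is chosen; ties go to the largest rank
#' (the more sensitive classification). If no rank satisfies the
#' constraints, the unconstrained MCC argmax is returned and the result is
#' flagged infeasible with a warning. The historical "Materials" variant of
#' the constraint set (specificity and precision >= 0.80, no accuracy
#' constraint) is available via `constraints = materials_constraints()`.
#'
#' @param profile A [metric_profile()] tibble.
#' @param scores The `lls_scores` table the profile was computed from.
#' @param constraints Named numeric vector of lower bounds on combined
#'   metrics.
#' @return A list of class `start_classification`: `tf`, `scores`,
#'   `cutoff`, `targets`, `metrics` (combined metrics at the cutoff),
#'   `feasible`, `constraints`, `profile`.
#' @export
select_cutoff <- function(profile, scores,
                          constraints = c(accuracy = 0.80, precision = 0.80,
                                          specificity = 0.90)) {
  if (any(constraints <= 0 | constraints > 1)) {
    abort("constraint values must lie in (0, 1]")
  }
  ok <- rep(TRUE, nrow(profile))
  for (m in names(constraints)) {
    ok <- ok & !is.na(profile[[m]]) & profile[[m]] >= constraints[[m]]
  }
  feasible <- any(ok)
  cand <- if (feasible) profile[ok, ] else profile
  best_mcc <- max(cand$mcc, na.rm = TRUE)
  cutoff <- max(cand$rank[!is.na(cand$mcc) & cand$mcc == best_mcc])
  if (!feasible) {
    warn("no cutoff satisfies the quality constraints; returning the unconstrained MCC argmax")
  }
  structure(list(
    tf = attr(scores, "tf"),
    scores = scores,
    cutoff = cutoff,
    targets = scores$gene[scores$rank <= cutoff],
    metrics = profile[profile$rank == cutoff,
                      c("sensitivity", "specificity", "precision", "accuracy", "mcc")],
    feasible = feasible,
    constraints = constraints,
    profile = profile), class = "start_classification")
}

#' @rdname select_cutoff
#' @export
materials_constraints <- function() c(precision = 0.80, specificity = 0.80)

#' @export
print.start_classification <- function(x, ...) {
  cat(sprintf("G1/S target classification (%s)\n", x$tf %||% "unknown TF"))
  cat(sprintf("  cutoff rank: %d  (%d targets)\n", x$cutoff, length(x$targets)))
  cat(sprintf("  feasible under constraints [%s]: %s\n",
              paste(sprintf("%s>=%.2f", names(x$constraints), x$constraints),
                    collapse = ", "),
              ifelse(x$feasible, "yes", "NO (unconstrained MCC argmax)")))
  m <- x$metrics
  cat(sprintf("  benchmark metrics at cutoff: sens %.3f, spec %.3f, prec %.3f, acc %.3f, MCC %.3f\n",
              m$sensitivity, m$specificity, m$precision, m$accuracy, m$mcc))
  invisible(x)
}
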