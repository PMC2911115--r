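#' Consensus list of cell-cycle-regulated genes
#'
#' A gene is consensus-CCR iff it appears within the first `top_n` entries
#' of at least `min_lists` of the supplied periodicity rankings (the study
#' rule: top 800 in at least three of five studies).
#'
#' @param ranked_lists List of character vectors, each a ranking without
#'   duplicates.
#' @param top_n Depth considered per list (default 800).
#' @param min_lists Minimum number of supporting lists (default 3).
#' @return Sorted character vector of consensus genes.
#' @export
consensus_ccr <- function(ranked_lists, top_n = 800L, min_lists = 3L) {
  for (i in seq_along(ranked_lists)) {
    if (anyDuplicated(ranked_lists[[i]])) {
      abort(sprintf("ranking %d contains duplicate genes", i))
    }
  }
  tops <- lapply(ranked_lists, head, top_n)
  counts <- table(unlist(tops))
  sort(names(counts)[counts >= min_lists])
}

#' Overlap (Venn) report for two or three gene sets
#'
#' Cardinalities of every exclusive Venn region plus, for each set, the
#' percentage of the set falling in each region it participates in.
#'
#' @param sets Named list of 2 or 3 character vectors.
#' @return Tibble with columns `region` (e.g. `"A&B"`), `count`, and one
#'   percentage column per set (`NA` where the set is not involved).
#' @export
overlap_report <- function(sets) {
  k <- length(sets)
  if (!k %in% 2:3 || is.null(names(sets))) {
    abort("sets must be a named list of 2 or 3 gene sets")
  }
  sets <- lapply(sets, unique)
  membership <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(membership) <- names(sets)
  universe <- unique(unlist(sets))
  inset <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) inset <- matrix(inset, nrow = 1, dimnames = list(NULL, names(sets)))
  rows <- purrr::map_dfr(seq_len(nrow(membership)), function(i) {
    want <- unlist(membership[i, ])
    in_region <- apply(inset, 1, function(r) all(r == want))
    region <- paste(names(sets)[want], collapse = "&")
    row <- tibble::tibble(region = region, count = sum(in_region))
    for (nm in names(sets)) {
      row[[paste0("pct_", nm)]] <- if (want[[nm]] && length(sets[[nm]]) > 0) {
        100 * sum(in_region) / length(sets[[nm]])
      } else NA_real_
    }
    row
  })
  rows
}

#' Cell-cycle peak-phase distribution of a target set
#'
#' Bins the targets' peak times (percent of the cycle, `[0, 100)`) into a
#' histogram; genes with no peak data (ND) are counted separately. If a
#' consensus CCR set is supplied, the fraction of targets that are CCR is
#' reported alongside.
#'
#' @param targets Character vector of target genes.
#' @param cc_peaks Tibble `gene`, `cc_peak` (`NA` = ND).
#' @param bin_width Histogram bin width in percent (default 5).
#' @param ccr_set Optional consensus CCR gene set.
#' @return A list of class `peak_phase_distribution`: `histogram` (tibble
#'   `bin_start`, `bin_end`, `count`), `n_nd`, `n_targets`, `ccr_fraction`
#'   (`NA` without `ccr_set`).
#' @export
peak_phase_distribution <- function(targets, cc_peaks, bin_width = 5,
                                    ccr_set = NULL) {
  peaks <- cc_peaks$cc_peak[match(targets, cc_peaks$gene)]
  known <- peaks[!is.na(peaks)]
  if (any(known < 0 | known >= 100)) abort("peak times must lie in [0, 100)")
  breaks <- seq(0, 100, by = bin_width)
  idx <- findInterval(known, breaks, rightmost.closed = FALSE)
  hist <- tibble::tibble(
    bin_start = breaks[-length(breaks)],
    bin_end = breaks[-1],
    count = vapply(seq_len(length(breaks) - 1L), function(i) sum(idx == i), integer(1)))
  structure(list(
    histogram = hist,
    n_nd = sum(is.na(peaks)),
    n_targets = length(targets),
    ccr_fraction = if (is.null(ccr_set)) NA_real_ else
      length(intersect(targets, ccr_set)) / length(targets)),
    class = "peak_phase_distribution")
}

#' Positional summary of promoter motif occurrences
#'
#' Splits all motif occurrences in the targets' promoters into upstream
#' zones (by default 1-200 bp, 201-500 bp and beyond 500 bp from the TSS;
#' a boundary position belongs to the proximal zone, matching the
#' [scan_motif()] inclusive-window convention) and reports both
#' per-occurrence zone fractions and per-gene status: at least one
#' proximal site, sites only beyond the proximal zone, or none.
#'
#' @param targets Character vector of target genes.
#' @param promoters Promoter tibble.
#' @param motif IUPAC consensus (default `ACGCG`, the reporting motif).
#' @param boundaries Two increasing zone boundaries in bp (default 200,
#'   500).
#' @return A list of class `motif_position_summary`: `occurrences` (tibble
#'   `zone`, `count`, `fraction`), `genes` (tibble `status`, `count`,
#'   `fraction`), `per_gene` (tibble `gene`, `n_proximal`, `n_total`,
#'   `status`).
#' @export
motif_position_summary <- function(targets, promoters, motif = "ACGCG",
                                   boundaries = c(200L, 500L)) {
  if (length(boundaries) != 2 || diff(boundaries) <= 0) {
    abort("boundaries must be two increasing positions")
  }
  prom <- promoters |> dplyr::filter(.data$gene %in% targets)
  hits <- motif_hits(prom, motif, window = Inf)
  zone_of <- function(pos) {
    dplyr::case_when(pos <= boundaries[1] ~ "proximal",
                     pos <= boundaries[2] ~ "mid",
                     TRUE ~ "distal")
  }
  zones <- c("proximal", "mid", "distal")
  occ_counts <- if (nrow(hits) == 0) {
    stats::setNames(rep(0L, 3), zones)
  } else {
    z <- factor(zone_of(hits$position), levels = zones)
    stats::setNames(as.integer(table(z)), zones)
  }
  n_occ <- sum(occ_counts)
  occurrences <- tibble::tibble(
    zone = zones, count = unname(occ_counts),
    fraction = if (n_occ == 0) rep(NA_real_, 3) else unname(occ_counts) / n_occ)
  per_gene <- tibble::tibble(gene = prom$gene) |>
    dplyr::left_join(
      hits |> dplyr::summarise(n_proximal = sum(.data$position <= boundaries[1]),
                               n_total = dplyr::n(), .by = "gene"),
      by = "gene") |>
    dplyr::mutate(n_proximal = dplyr::coalesce(.data$n_proximal, 0L),
                  n_total = dplyr::coalesce(.data$n_total, 0L),
                  status = dplyr::case_when(.data$n_proximal > 0 ~ "proximal",
                                            .data$n_total > 0 ~ "distal_only",
                                            TRUE ~ "none"))
  gene_counts <- per_gene |>
    dplyr::count(status = factor(.data$status, levels = c("proximal", "distal_only", "none")),
                 .drop = FALSE, name = "count") |>
    dplyr::mutate(status = as.character(.data$status),
                  fraction = .data$count / nrow(per_gene))
  structure(list(occurrences = occurrences, genes = gene_counts,
                 per_gene = per_gene, motif = motif, boundaries = boundaries),
            class = "motif_position_summary")
}

#' Rescore after removing one classifier
#'
#' Recomputes total scores with the named classifier's contribution
#' excluded; by the additivity of the model this equals subtracting that
#' classifier's contribution column from every gene's total (the
#' score-decomposition identity), but the ranking is rebuilt from scratch.
#' Used for the motif-free internal-consistency analysis and for
#' benchmarking location datasets without circular binding evidence.
#'
#' @param binned Binned classifier matrix.
#' @param weights `lls_weights` table.
#' @param classifier_id Classifier to remove.
#' @return An `lls_scores` table over the remaining classifiers.
#' @export
rescore_without <- function(binned, weights, classifier_id) {
  specs <- attr(binned, "specs")
  ids <- if (!is.null(specs)) specs$id else setdiff(names(binned), "gene")
  if (!classifier_id %in% ids) {
    abort(sprintf("classifier '%s' is not active in this matrix", classifier_id))
  }
  keep <- setdiff(ids, classifier_id)
  reduced <- binned[, c("gene", keep)]
  if (!is.null(specs)) attr(reduced, "specs") <- specs[specs$id %in% keep, ]
  attr(reduced, "tf") <- attr(binned, "tf")
  total_scores(reduced, weights |> dplyr::filter(.data$classifier != classifier_id))
}

#' Benchmark a location dataset against a binding-free classification
#'
#' Uses a classification built without the binding classifier as the
#' reference: at each cutoff rank, reference targets are the positives and
#' the remaining candidates the negatives, and the location study's
#' bound/unbound calls are scored as predictions; the MCC is emitted per
#' cutoff (missing where any MCC factor is zero, e.g. for an empty call
#' set).
#'
#' @param bound_genes Character vector of genes the location study calls
#'   bound.
#' @param reference_scores `lls_scores` from a binding-free model (see
#'   [rescore_without()]).
#' @param cutoffs Integer vector of reference cutoff ranks to sweep
#'   (default every rank).
#' @return A tibble of class `location_benchmark`: `cutoff`, `tp`, `fp`,
#'   `tn`, `fn`, `mcc`.
#' @export
benchmark_location_dataset <- function(bound_genes, reference_scores,
                                       cutoffs = seq_len(nrow(reference_scores))) {
  ord <- reference_scores |> dplyr::arrange(.data$rank)
  bound <- ord$gene %in% bound_genes
  n_bound_cum <- cumsum(bound)
  n_bound <- sum(bound)
  n <- nrow(ord)
  if (any(cutoffs < 1 | cutoffs > n)) abort(sprintf("cutoffs must lie in 1..%d", n))
  tp <- n_bound_cum[cutoffs]
  fn <- cutoffs - tp
  fp <- n_bound - tp
  tn <- (n - cutoffs) - fp
  mcc_den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  out <- tibble::tibble(cutoff = as.integer(cutoffs), tp = tp, fp = fp,
                        tn = tn, fn = fn,
                        mcc = ifelse(mcc_den == 0, NA_real_,
                                     (tp * tn - fp * fn) / sqrt(mcc_den)))
  class(out) <- c("location_benchmark", class(out))
  out
}

#' Predictive power on divergently transcribed gene pairs
#'
#' Divergent pairs share one promoter, so binding data alone cannot tell
#' which member is regulated; externally derived regulation labels per gene
#' provide an independent benchmark. Every labelled gene contributes one
#' prediction (membership in the target set); genes labelled `unknown` are
#' skipped.
#'
#' @param pairs Tibble with columns `gene_a`, `gene_b`, `label_a`,
#'   `label_b`; labels in `regulated`, `not_regulated`, `unknown`.
#' @param targets Character vector of predicted target genes.
#' @return One-row [quality_metrics()] tibble with the confusion counts
#'   attached as attribute `counts`.
#' @export
divergent_pair_mcc <- function(pairs, targets) {
  if (any(pairs$gene_a == pairs$gene_b)) abort("a divergent pair must hold two distinct genes")
  long <- dplyr::bind_rows(
    tibble::tibble(gene = pairs$gene_a, label = pairs$label_a),
    tibble::tibble(gene = pairs$gene_b, label = pairs$label_b))
  bad <- setdiff(unique(long$label), c("regulated", "not_regulated", "unknown"))
  if (length(bad) > 0) abort(sprintf("unknown regulation label(s): %s", paste(bad, collapse = ", ")))
  long <- long |> dplyr::filter(.data$label != "unknown") |> dplyr::distinct()
  if (nrow(long) == 0) abort("no labelled genes among the pairs")
  predicted <- long$gene %in% targets
  actual <- long$label == "regulated"
  counts <- c(tp = sum(predicted & actual), fp = sum(predicted & !actual),
              tn = sum(!predicted & !actual), fn = sum(!predicted & actual))
  out <- quality_metrics(counts)
  attr(out, "counts") <- counts
  out
}

#' Functional-class enrichment of a target set
#'
#' Two-tailed Fisher exact test per functional class on the 2x2 table
#' (target / non-target) x (in class / out of class) over the candidate
#' universe. Genes of unknown class are excluded from the class
#' percentages. Raw p-values are reported (a Bonferroni column is added
#' for transparency); empty classes are skipped with a notice.
#'
#' @param targets Character vector of target genes.
#' @param classes Tibble `gene`, `class` covering the universe (`unknown`
#'   allowed).
#' @param universe Character vector of candidate genes.
#' @return Tibble: `class`, `n_class`, `n_target_in_class`, `pct_targets`,
#'   `pct_universe`, `fold_enrichment`, `p_value`, `p_bonferroni`.
#' @export
functional_enrichment <- function(targets, classes, universe) {
  outside <- setdiff(targets, universe)
  if (length(outside) > 0) abort("targets must be a subset of the universe")
  cls <- classes |> dplyr::filter(.data$gene %in% universe)
  unclassed <- setdiff(universe, cls$gene)
  if (length(unclassed) > 0) {
    cls <- dplyr::bind_rows(cls, tibble::tibble(gene = unclassed, class = "unknown"))
  }
  known <- cls |> dplyr::filter(.data$class != "unknown")
  class_names <- sort(unique(known$class))
  n_known_universe <- nrow(known)
  n_known_targets <- sum(known$gene %in% targets)
  rows <- purrr::map(class_names, function(cl) {
    in_class <- known$gene[known$class == cl]
    if (length(in_class) == 0) {
      message(sprintf("functional class '%s' is empty; skipped", cl))
      return(NULL)
    }
    a <- length(intersect(in_class, targets))              # target, in class
    b <- sum(known$gene %in% targets) - a                  # target, other class
    c_ <- length(in_class) - a                             # non-target, in class
    d <- n_known_universe - a - b - c_
    p <- fisher.test(matrix(c(a, b, c_, d), nrow = 2), alternative = "two.sided")$p.value
    pct_t <- if (n_known_targets == 0) NA_real_ else 100 * a / n_known_targets
    pct_u <- 100 * length(in_class) / n_known_universe
    tibble::tibble(class = cl, n_class = length(in_class), n_target_in_class = a,
                   pct_targets = pct_t, pct_universe = pct_u,
                   fold_enrichment = if (is.na(pct_t) || pct_u == 0) NA_real_ else pct_t / pct_u,
                   p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  out
}
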