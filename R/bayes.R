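#' Bin thresholds from averaged order statistics of random candidate subsets
#'
#' Continuous classifiers are divided into four bins delimited by three cut
#' values. Each cut is the mean, over `n_sets` random draws of `set_size`
#' candidate genes, of the draw's rank-`k` order statistic (ascending,
#' 1-based) for `k` in `ranks`. Genes with missing values are excluded from
#' the draws. The same seed yields the same thresholds.
#'
#' @param x Numeric vector of one classifier's values over the candidate
#'   universe (`NA` allowed).
#' @param n_sets Number of random subsets (default 3).
#' @param set_size Subset size (default 40).
#' @param ranks Order-statistic ranks to average (default 10, 20, 30).
#' @param seed Optional integer seed; if `NULL` the current RNG state is
#'   used (callers binning several classifiers seed once and draw in a
#'   documented order).
#' @return Numeric vector `c(t1, t2, t3)` with `t1 <= t2 <= t3`.
#' @export
derive_bin_thresholds <- function(x, n_sets = 3L, set_size = 40L,
                                  ranks = c(10L, 20L, 30L), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pool <- x[!is.na(x)]
  if (length(pool) < set_size) {
    abort(sprintf("only %d genes carry values; need at least set_size = %d",
                  length(pool), set_size))
  }
  draws <- vapply(seq_len(n_sets), function(i) {
    sort(sample(pool, set_size))[ranks]
  }, numeric(length(ranks)))
  t <- if (length(ranks) == 1L) mean(draws) else rowMeans(draws)
  stats::setNames(t, paste0("t", seq_along(ranks)))
}

#' Assign continuous values to bins by the half-open rule
#'
#' Bin 1 is `(-Inf, t1]`, bin 2 `(t1, t2]`, bin 3 `(t2, t3]`, bin 4
#' `(t3, Inf)`; the bins partition the line. Missing values map to the
#' designated `"missing"` pseudo-bin (whose weight is fixed at zero).
#'
#' @param value Numeric vector.
#' @param thresholds Ordered numeric vector `c(t1, t2, t3)`.
#' @return Character vector of bin ids (`"b1"`..`"b4"` or `"missing"`).
#' @export
assign_bin <- function(value, thresholds) {
  if (is.unsorted(thresholds)) abort("thresholds must be ordered t1 <= t2 <= t3")
  b <- 4L - (value <= thresholds[3]) - (value <= thresholds[2]) - (value <= thresholds[1])
  ifelse(is.na(value), "missing", paste0("b", b))
}

#' Bin every classifier column of a matrix
#'
#' Continuous classifiers are binned with [assign_bin()] using thresholds
#' derived by the random-subset procedure; categorical classifiers bypass
#' it -- their declared categories are the bins. Missing cells map to the
#' `"missing"` pseudo-bin in either case.
#'
#' @param matrix A `classifier_matrix` from [assemble_classifier_matrix()].
#' @param n_sets,set_size,ranks Binning parameters, see
#'   [derive_bin_thresholds()].
#' @param seed Integer seed; thresholds for the continuous classifiers are
#'   drawn sequentially from this seed in column order.
#' @return A list with `binned` (tibble of gene + character bin columns)
#'   and `thresholds` (tibble `classifier`, `t1`, `t2`, `t3`).
#' @export
bin_classifier_matrix <- function(matrix, n_sets = 3L, set_size = 40L,
                                  ranks = c(10L, 20L, 30L), seed = 1L) {
  specs <- attr(matrix, "specs")
  if (is.null(specs)) abort("matrix lacks classifier specs; build it with assemble_classifier_matrix()")
  set.seed(seed)
  binned <- tibble::tibble(gene = matrix$gene)
  thr <- list()
  for (i in seq_len(nrow(specs))) {
    id <- specs$id[i]
    if (specs$kind[i] == "continuous") {
      t3 <- derive_bin_thresholds(matrix[[id]], n_sets, set_size, ranks, seed = NULL)
      thr[[id]] <- t3
      binned[[id]] <- assign_bin(matrix[[id]], t3)
    } else {
      v <- as.character(matrix[[id]])
      lev <- specs$levels[[i]]
      bad <- setdiff(stats::na.omit(unique(v)), lev)
      if (length(bad) > 0) {
        abort(sprintf("classifier '%s' takes undeclared label(s): %s", id,
                      paste(bad, collapse = ", ")))
      }
      binned[[id]] <- ifelse(is.na(v), "missing", v)
    }
  }
  thresholds <- purrr::imap_dfr(thr, function(t, id) {
    tibble::tibble(classifier = id, t1 = t[1], t2 = t[2], t3 = t[3])
  })
  attr(binned, "specs") <- specs
  attr(binned, "tf") <- attr(matrix, "tf")
  list(binned = binned, thresholds = thresholds)
}

#' Log-likelihood weights per classifier bin from control sets
#'
#' For every (classifier, bin) the weight is
#' `LLS = ln(P(bin | positive) / P(bin | negative))`, where the
#' conditional frequencies are estimated from the training control sets
#' with additive smoothing:
#' `P(bin | class) = (count + pseudocount) / (class_size + pseudocount * n_bins)`.
#' With a positive pseudocount all weights are finite for any control
#' configuration. The `"missing"` pseudo-bin carries weight 0 (absent
#' evidence is neutral).
#'
#' @param binned Binned matrix (the `binned` element of
#'   [bin_classifier_matrix()]).
#' @param controls List with character vectors `positives` and `negatives`.
#' @param pseudocount Additive smoothing constant (default 0.5).
#' @return A tibble of class `lls_weights` with columns `classifier`,
#'   `bin`, `n_pos`, `n_neg`, `p_pos`, `p_neg`, `lls`; control sizes and
#'   the pseudocount attached as attributes.
#' @export
estimate_lls_weights <- function(binned, controls, pseudocount = 0.5) {
  specs <- attr(binned, "specs")
  if (is.null(specs)) abort("binned matrix lacks classifier specs")
  pos <- normalize_gene_ids(controls$positives, "positive control")
  neg <- normalize_gene_ids(controls$negatives, "negative control")
  if (length(pos) == 0 || length(neg) == 0) abort("control classes must be non-empty")
  if (length(intersect(pos, neg)) > 0) abort("positive and negative controls overlap")
  absent <- setdiff(c(pos, neg), binned$gene)
  if (length(absent) > 0) {
    abort(sprintf("control gene(s) not in the binned matrix: %s",
                  paste(head(absent, 5), collapse = ", ")))
  }
  n_pos_total <- length(pos)
  n_neg_total <- length(neg)
  rows <- purrr::map_dfr(seq_len(nrow(specs)), function(i) {
    id <- specs$id[i]
    bins <- if (specs$kind[i] == "continuous") paste0("b", 1:4) else specs$levels[[i]]
    v <- binned[[id]]
    vp <- v[binned$gene %in% pos]
    vn <- v[binned$gene %in% neg]
    n_bins <- length(bins)
    purrr::map_dfr(bins, function(b) {
      cp <- sum(vp == b)
      cn <- sum(vn == b)
      p_pos <- (cp + pseudocount) / (n_pos_total + pseudocount * n_bins)
      p_neg <- (cn + pseudocount) / (n_neg_total + pseudocount * n_bins)
      tibble::tibble(classifier = id, bin = b, n_pos = cp, n_neg = cn,
                     p_pos = p_pos, p_neg = p_neg, lls = log(p_pos / p_neg))
    }) |>
      dplyr::bind_rows(tibble::tibble(classifier = id, bin = "missing",
                                      n_pos = sum(vp == "missing"),
                                      n_neg = sum(vn == "missing"),
                                      p_pos = NA_real_, p_neg = NA_real_,
                                      lls = 0))
  })
  if (any(!is.finite(rows$lls))) {
    abort("non-finite LLS weight; use a positive pseudocount")
  }
  structure(rows,
            class = c("lls_weights", class(rows)),
            pseudocount = pseudocount,
            n_pos = n_pos_total, n_neg = n_neg_total)
}

#' Total log-likelihood scores and ranking
#'
#' The total score of a gene is the sum over all active classifiers of the
#' weight of the bin the gene falls in; missing evidence contributes 0.
#' Genes are ranked 1..N by descending total with ties broken
#' lexicographically by systematic name, so output is deterministic.
#'
#' @param binned Binned matrix (gene + bin-id columns).
#' @param weights An `lls_weights` table covering every (classifier, bin)
#'   pair occurring in `binned`.
#' @return A tibble of class `lls_scores`: `gene`, one contribution column
#'   per classifier, `sum` and `rank`, sorted by rank.
#' @export
total_scores <- function(binned, weights) {
  specs <- attr(binned, "specs")
  ids <- if (!is.null(specs)) specs$id else setdiff(names(binned), "gene")
  missing_cls <- setdiff(ids, unique(weights$classifier))
  if (length(missing_cls) > 0) {
    abort(sprintf("classifier(s) absent from the weight table: %s",
                  paste(missing_cls, collapse = ", ")))
  }
  out <- tibble::tibble(gene = binned$gene)
  for (id in ids) {
    w <- weights |> dplyr::filter(.data$classifier == id)
    lut <- stats::setNames(w$lls, w$bin)
    bins <- binned[[id]]
    unknown <- setdiff(unique(bins), names(lut))
    if (length(unknown) > 0) {
      abort(sprintf("bin(s) of classifier '%s' absent from the weight table: %s",
                    id, paste(unknown, collapse = ", ")))
    }
    out[[id]] <- unname(lut[bins])
  }
  out$sum <- rowSums(out[ids])
  out <- out |> dplyr::arrange(dplyr::desc(.data$sum), .data$gene) |>
    dplyr::mutate(rank = dplyr::row_number())
  attr(out, "tf") <- attr(binned, "tf")
  class(out) <- c("lls_scores", class(out))
  out
}

#' Build training control sets from prior target annotations
#'
#' Positives for each factor are drawn first from the intersection of the
#' two prior classifications, excluding genes annotated for both factors
#' (dual-regulated) and genes regulated by other cell-cycle transcription
#' factors; if the intersection falls short of `n_pos` it is topped up with
#' the best-ranked single-study targets under the same exclusions (40
#' positives for Mbp1, 32 for Swi4 by default). Negatives are
#' `n_neg_groups` seeded random draws of `n_pos` genes from the candidates
#' unannotated for that factor, merged with duplicates removed.
#'
#' @param annotations Tibble with columns `study` (two study labels), `tf`,
#'   `gene`, `rank`.
#' @param universe Character vector of candidate genes.
#' @param n_pos Named integer vector of positive-set sizes per factor.
#' @param other_tf Genes annotated as regulated by other cell-cycle
#'   factors, excluded from positives.
#' @param n_neg_groups Number of negative draws to merge (default 5).
#' @param seed Optional integer seed for the negative draws and top-up
#'   ties.
#' @return A list of class `control_sets`, per factor a list with
#'   `positives` and `negatives`.
#' @export
build_control_sets <- function(annotations, universe,
                               n_pos = c(mbp1 = 40L, swi4 = 32L),
                               other_tf = character(0),
                               n_neg_groups = 5L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  studies <- unique(annotations$study)
  if (length(studies) != 2) abort("annotations must come from exactly two prior studies")
  tfs <- names(n_pos)
  ann_genes <- function(tf, study = NULL) {
    a <- annotations[annotations$tf == tf, ]
    if (!is.null(study)) a <- a[a$study == study, ]
    a
  }
  out <- purrr::map(stats::setNames(tfs, tfs), function(tf) {
    other <- setdiff(tfs, tf)
    dual <- intersect(unique(ann_genes(tf)$gene),
                      unique(unlist(lapply(other, function(o) ann_genes(o)$gene))))
    excluded <- union(dual, other_tf)
    in_both <- intersect(ann_genes(tf, studies[1])$gene, ann_genes(tf, studies[2])$gene)
    core <- setdiff(intersect(in_both, universe), excluded)
    need <- n_pos[[tf]]
    if (length(core) >= need) {
      positives <- sort(core)[seq_len(need)]
    } else {
      singles <- ann_genes(tf) |>
        dplyr::filter(!.data$gene %in% in_both, !.data$gene %in% excluded,
                      .data$gene %in% universe) |>
        dplyr::summarise(best_rank = min(.data$rank), .by = "gene") |>
        dplyr::arrange(.data$best_rank, .data$gene)
      topup <- head(singles$gene, need - length(core))
      if (length(core) + length(topup) < need) {
        abort(sprintf("cannot reach %d positives for %s: shortfall of %d genes",
                      need, tf, need - length(core) - length(topup)))
      }
      positives <- c(sort(core), topup)
    }
    neg_pool <- setdiff(universe, unique(ann_genes(tf)$gene))
    if (length(neg_pool) < need) {
      abort(sprintf("not enough unannotated genes to draw negatives for %s", tf))
    }
    negatives <- unique(unlist(replicate(n_neg_groups, sample(neg_pool, need),
                                         simplify = FALSE)))
    list(positives = positives, negatives = negatives)
  })
  structure(out, class = "control_sets")
}
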