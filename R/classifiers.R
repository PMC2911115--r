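#' Classifier specifications per transcription factor
#'
#' Returns the set of nine evidence classifiers active for a factor. Both
#' factors share the peak-time, motif, binding, overexpression and
#' cell-cycle-peak classifiers; the mutant-derived expression classifiers
#' differ: the wild-type/`mbp1` ratio and correlation are used only for
#' Mbp1, while the 40-60 min average and the wild-type(20-40)/`swi4` ratio
#' are used only for Swi4. Two presets ship for Swi4: `"methods-text"`
#' keeps the 20 min wild-type value (nine classifiers), `"file2-layout"`
#' replaces it with the 40-60 min average alone (eight classifiers,
#' mirroring the supplementary score-matrix column layout).
#'
#' @param tf `"mbp1"` or `"swi4"`.
#' @param preset `"methods-text"` (default) or `"file2-layout"`.
#' @return A tibble with columns `id`, `kind` (`continuous`/`categorical`)
#'   and `levels` (list column of declared categories, `NULL` for
#'   continuous classifiers).
#' @export
classifier_specs <- function(tf = c("mbp1", "swi4"),
                             preset = c("methods-text", "file2-layout")) {
  tf <- match.arg(tf)
  preset <- match.arg(preset)
  peak_levels <- c("20", "40", "60", "80")
  motif_levels <- c("absent", "present")
  binding_levels <- if (tf == "mbp1") c("none", "one", "multiple") else
    c("none", "one_other", "one_weighted_study", "multiple")
  spec <- function(id, kind, levels = NULL) {
    tibble::tibble(id = id, kind = kind, levels = list(levels))
  }
  common_head <- spec("peak_time_wt", "categorical", peak_levels)
  common_tail <- dplyr::bind_rows(
    spec("motif", "categorical", motif_levels),
    spec("binding", "categorical", binding_levels),
    spec("cln3_oe", "continuous"),
    spec("clb2_oe", "continuous"),
    spec("cc_peak", "continuous"))
  mid <- if (tf == "mbp1") {
    dplyr::bind_rows(spec("value20_wt", "continuous"),
                     spec("corr_wt_mbp1", "continuous"),
                     spec("ratio_wt_mbp1", "continuous"))
  } else if (preset == "methods-text") {
    dplyr::bind_rows(spec("value20_wt", "continuous"),
                     spec("av40_60_wt", "continuous"),
                     spec("ratio_wt2040_swi4", "continuous"))
  } else {
    dplyr::bind_rows(spec("av40_60_wt", "continuous"),
                     spec("ratio_wt2040_swi4", "continuous"))
  }
  dplyr::bind_rows(common_head, mid, common_tail)
}

#' Time of peak expression in the wild type
#'
#' For each gene with a complete four-point wild-type profile, returns the
#' timepoint (20, 40, 60 or 80 min) of the maximum value; ties are broken
#' toward the earliest timepoint. Genes with any missing timepoint get a
#' missing result.
#'
#' @param panel Long-format expression tibble.
#' @param strain Genotype label to evaluate (default `"wt"`).
#' @return Tibble with columns `gene` and `peak_time_wt` (character,
#'   `"20"`..`"80"`, or `NA`).
#' @export
peak_time_wt <- function(panel, strain = "wt") {
  panel |>
    dplyr::filter(.data$strain == !!strain) |>
    dplyr::summarise(
      peak_time_wt = if (dplyr::n() == 4L && !anyNA(.data$value)) {
        as.character(.data$time[which.max(.data$value)])
      } else NA_character_,
      .by = "gene")
}

#' Continuous expression features for a factor
#'
#' Computes the mutant-informed expression classifiers from the panel. For
#' Mbp1: the 20 min wild-type value, the Pearson correlation between the
#' wild-type and `mbp1` profiles over the four shared timepoints, and the
#' ratio of the wild-type series maximum to the `mbp1` series maximum. For
#' Swi4: the 20 min value, the mean of the 40 and 60 min wild-type values,
#' and the ratio of the wild-type maximum at 20 or 40 min to the `swi4`
#' series maximum. Ratio denominators are floored at `eps` (log2 units)
#' before division, making the ratios finite and monotone in the numerator
#' even for uninduced mutant profiles. Genes whose relevant mutant profile
#' is absent get missing features.
#'
#' @param panel Long-format expression tibble.
#' @param tf `"mbp1"` or `"swi4"`.
#' @param eps Denominator floor (default 0.1).
#' @return Tibble keyed by `gene` with the factor's continuous expression
#'   feature columns.
#' @export
expression_features <- function(panel, tf = c("mbp1", "swi4"), eps = 0.1) {
  tf <- match.arg(tf)
  wide <- panel |>
    tidyr::pivot_wider(id_cols = "gene", names_from = c("strain", "time"),
                       values_from = "value", names_sep = "_")
  need <- function(cols) all(cols %in% names(wide))
  wt_cols <- paste0("wt_", c(20, 40, 60, 80))
  if (!need(wt_cols)) abort("expression panel lacks a complete wild-type series")
  wt <- as.matrix(wide[wt_cols])
  out <- tibble::tibble(gene = wide$gene, value20_wt = unname(wt[, 1]))
  floor_max <- function(m) pmax(apply(m, 1, function(r) if (anyNA(r)) NA_real_ else max(r)), eps)
  if (tf == "mbp1") {
    mut_cols <- paste0("mbp1_", c(20, 40, 60, 80))
    if (!need(mut_cols)) abort("expression panel lacks the mbp1 mutant series")
    mut <- as.matrix(wide[mut_cols])
    wt_max <- apply(wt, 1, function(r) if (anyNA(r)) NA_real_ else max(r))
    out$corr_wt_mbp1 <- vapply(seq_len(nrow(wt)), function(i) {
      a <- wt[i, ]; b <- mut[i, ]
      if (anyNA(a) || anyNA(b) || stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
      else cor(a, b)
    }, numeric(1))
    out$ratio_wt_mbp1 <- wt_max / floor_max(mut)
  } else {
    mut_cols <- paste0("swi4_", c(20, 40, 60, 80))
    if (!need(mut_cols)) abort("expression panel lacks the swi4 mutant series")
    mut <- as.matrix(wide[mut_cols])
    out$av40_60_wt <- rowMeans(wt[, 2:3, drop = FALSE])
    wt2040_max <- apply(wt[, 1:2, drop = FALSE], 1,
                        function(r) if (anyNA(r)) NA_real_ else max(r))
    out$ratio_wt2040_swi4 <- wt2040_max / floor_max(mut)
  }
  out
}

#' Scan a promoter for an IUPAC consensus motif within an upstream window
#'
#' Counts all (possibly overlapping) occurrences of the consensus whose
#' entire span lies within upstream positions 1..`window`, where position 1
#' is the base immediately upstream of the TSS (the last base of the
#' sequence). Degenerate IUPAC letters in the motif (e.g. R = A/G) are
#' honoured; ambiguity codes in the subject sequence are treated literally,
#' so an N in the promoter matches nothing. Only the given strand is
#' scanned.
#'
#' @param seq A single promoter sequence (character scalar, 5' to 3', last
#'   base adjacent to the TSS).
#' @param motif IUPAC consensus string.
#' @param window Upstream window in bp (`window >= nchar(motif)`).
#' @return A list with `count` and `positions`, the 1-based upstream start
#'   coordinates (position of each match's 5' end), sorted increasing.
#' @export
scan_motif <- function(seq, motif, window) {
  motif <- toupper(motif)
  chars <- strsplit(motif, "")[[1]]
  bad <- setdiff(chars, names(IUPAC_MAP))
  if (length(bad) > 0) abort(sprintf("non-IUPAC character(s) in motif: %s", paste(bad, collapse = ", ")))
  if (window < nchar(motif)) abort("window must be at least the motif length")
  subject <- Biostrings::DNAString(toupper(seq))
  hits <- Biostrings::matchPattern(motif, subject, fixed = "subject")
  starts <- Biostrings::start(hits)
  upstream <- nchar(seq) - starts + 1L
  upstream <- sort(upstream[upstream <= window])
  list(count = length(upstream), positions = upstream)
}

#' All motif occurrences across a promoter set
#'
#' Applies [scan_motif()] to every promoter and returns one row per
#' occurrence within the window.
#'
#' @param promoters Promoter tibble (`gene`, `sequence`).
#' @param motif IUPAC consensus string.
#' @param window Upstream window in bp; `Inf` scans full promoters.
#' @return Tibble with columns `gene` and `position` (upstream start
#'   coordinate); genes without occurrences contribute no rows.
#' @export
motif_hits <- function(promoters, motif, window = Inf) {
  w <- if (is.infinite(window)) max(nchar(promoters$sequence)) else window
  purrr::map2_dfr(promoters$gene, promoters$sequence, function(g, s) {
    hit <- scan_motif(s, motif, min(w, nchar(s)))
    if (hit$count == 0) return(NULL)
    tibble::tibble(gene = g, position = hit$positions)
  })
}

#' Binding-evidence category per gene
#'
#' Collapses the four genome-wide location studies into mutually exclusive,
#' exhaustive categories. For Mbp1: `none`, `one` or `multiple` studies
#' detected the interaction. For Swi4 the single-study case distinguishes
#' the Swi4-rich weighted study (whose calls are considered more reliable
#' and learn their own weight) from the other three: `none`, `one_other`,
#' `one_weighted_study`, `multiple`.
#'
#' @param binding Tibble of bound calls (`tf`, `study`, `gene`).
#' @param tf `"mbp1"` or `"swi4"`.
#' @param universe Character vector of all candidate genes.
#' @param studies Character vector of the four expected study labels.
#' @param weighted_study The Swi4-rich study label.
#' @return Tibble with columns `gene` and `binding` (character category).
#' @export
binding_category <- function(binding, tf = c("mbp1", "swi4"), universe,
                             studies = c("iyer", "simon", "lee", "harbison"),
                             weighted_study = "iyer") {
  tf <- match.arg(tf)
  unknown <- setdiff(unique(binding$study), studies)
  if (length(unknown) > 0) {
    abort(sprintf("unknown location study id(s): %s", paste(unknown, collapse = ", ")))
  }
  calls <- binding |> dplyr::filter(.data$tf == !!tf, .data$gene %in% universe)
  per_gene <- calls |>
    dplyr::summarise(n_studies = dplyr::n_distinct(.data$study),
                     weighted_only = dplyr::n_distinct(.data$study) == 1L &&
                       all(.data$study == weighted_study),
                     .by = "gene")
  tibble::tibble(gene = universe) |>
    dplyr::left_join(per_gene, by = "gene") |>
    dplyr::mutate(
      n_studies = dplyr::coalesce(.data$n_studies, 0L),
      binding = if (tf == "mbp1") {
        dplyr::case_when(.data$n_studies == 0L ~ "none",
                         .data$n_studies == 1L ~ "one",
                         TRUE ~ "multiple")
      } else {
        dplyr::case_when(.data$n_studies == 0L ~ "none",
                         .data$n_studies == 1L & .data$weighted_only ~ "one_weighted_study",
                         .data$n_studies == 1L ~ "one_other",
                         TRUE ~ "multiple")
      }) |>
    dplyr::select("gene", "binding")
}

#' Assemble the per-gene classifier matrix for one factor
#'
#' Joins all evidence sources into one row per candidate gene with one
#' column per active classifier: wild-type peak time, the factor's
#' continuous expression features, motif presence/absence within the
#' factor's window (MCB ACGCGT / 200 bp for Mbp1, SCB CRCGAA / 400 bp for
#' Swi4 by default), the binding category, the two overexpression responses
#' and the cell-cycle peak percentage. Genes missing an input (e.g. no
#' cell-cycle peak) keep an `NA` cell; missing never becomes zero.
#'
#' @param dataset A `start_dataset` (or any list with elements
#'   `expression`, `binding`, `promoters`, `cc_peaks`, `overexpression`).
#' @param tf `"mbp1"` or `"swi4"`.
#' @param preset Classifier preset, see [classifier_specs()].
#' @param motif Consensus used by the motif classifier; defaults to the
#'   factor's consensus (`ACGCGT` or `CRCGAA`).
#' @param window Upstream window for the motif classifier; defaults to 200
#'   (Mbp1) or 400 (Swi4) bp.
#' @param weighted_study Swi4-rich study label for [binding_category()].
#' @param eps Ratio denominator floor, see [expression_features()].
#' @return A tibble (`classifier_matrix`) with column `gene` plus one
#'   column per active classifier; classifier specs attached as attribute
#'   `specs`.
#' @export
assemble_classifier_matrix <- function(dataset, tf = c("mbp1", "swi4"),
                                       preset = c("methods-text", "file2-layout"),
                                       motif = NULL, window = NULL,
                                       weighted_study = "iyer", eps = 0.1) {
  tf <- match.arg(tf)
  preset <- match.arg(preset)
  specs <- classifier_specs(tf, preset)
  motif <- motif %||% if (tf == "mbp1") "ACGCGT" else "CRCGAA"
  window <- window %||% if (tf == "mbp1") 200L else 400L
  universe <- sort(unique(dataset$expression$gene))

  feats <- expression_features(dataset$expression, tf, eps = eps)
  with_hit <- motif_hits(dataset$promoters, motif, window) |>
    dplyr::distinct(.data$gene) |>
    dplyr::pull("gene")
  motif_col <- tibble::tibble(gene = dataset$promoters$gene,
                              motif = ifelse(dataset$promoters$gene %in% with_hit,
                                             "present", "absent"))
  studies <- unique(dataset$binding$study)
  mat <- tibble::tibble(gene = universe) |>
    dplyr::left_join(peak_time_wt(dataset$expression), by = "gene") |>
    dplyr::left_join(feats, by = "gene") |>
    dplyr::left_join(motif_col, by = "gene") |>
    dplyr::left_join(binding_category(dataset$binding, tf, universe,
                                      studies = studies,
                                      weighted_study = weighted_study),
                     by = "gene") |>
    dplyr::left_join(dataset$overexpression, by = "gene") |>
    dplyr::left_join(dataset$cc_peaks, by = "gene")
  mat <- mat[, c("gene", specs$id)]
  attr(mat, "specs") <- specs
  attr(mat, "tf") <- tf
  class(mat) <- c("classifier_matrix", class(mat))
  mat
}
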