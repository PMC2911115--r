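# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Naive sliding-window IUPAC consensus scan. Returns upstream start
# coordinates (position of the match 5' end, position 1 = last base) of all
# matches whose entire span lies within 1..window.
oracle_scan <- function(seq, motif, window) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  s <- strsplit(toupper(seq), "")[[1]]
  m <- strsplit(toupper(motif), "")[[1]]
  L <- length(s)
  k <- length(m)
  hits <- integer(0)
  for (i in seq_len(L - k + 1)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!s[i + j - 1] %in% iupac[[m[j]]]) { ok <- FALSE; break }
    }
    if (ok) {
      u <- L - i + 1L  # upstream coordinate of the 5' end
      if (u <= window) hits <- c(hits, u)
    }
  }
  sort(hits)
}

# Brute-force confusion counts from raw sets.
oracle_confusion <- function(ranked_genes, cutoff, positives, negatives) {
  pred <- ranked_genes[seq_len(cutoff)]
  tp <- sum(positives %in% pred)
  fp <- sum(negatives %in% pred)
  c(tp = tp, fp = fp, tn = length(negatives) - fp, fn = length(positives) - tp)
}

# Textbook metric formulas, written independently (NA on zero denominators).
oracle_metrics <- function(cts) {
  tp <- cts[["tp"]]; fp <- cts[["fp"]]; tn <- cts[["tn"]]; fn <- cts[["fn"]]
  dv <- function(a, b) if (b == 0) NA_real_ else a / b
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  list(sensitivity = dv(tp, tp + fn), specificity = dv(tn, tn + fp),
       precision = dv(tp, tp + fp), accuracy = dv(tp + tn, tp + fp + tn + fn),
       mcc = if (den == 0) NA_real_ else (tp * tn - fp * fn) / sqrt(den))
}

# Smoothed LLS weight by direct application of the formula.
oracle_lls <- function(count_pos, size_pos, count_neg, size_neg, pc, n_bins) {
  log(((count_pos + pc) / (size_pos + pc * n_bins)) /
        ((count_neg + pc) / (size_neg + pc * n_bins)))
}

# A minimal hand-assembled dataset wrapper for classifier-matrix tests.
tiny_dataset <- function(expression, binding = NULL, promoters = NULL,
                         cc_peaks = NULL, overexpression = NULL) {
  genes <- unique(expression$gene)
  if (is.null(binding)) {
    binding <- tibble::tibble(tf = character(0), study = character(0),
                              gene = character(0))
  }
  if (is.null(promoters)) {
    promoters <- tibble::tibble(gene = genes, anchor = "tss", length = 20L,
                                sequence = strrep("AT", 10))
  }
  if (is.null(cc_peaks)) cc_peaks <- tibble::tibble(gene = genes, cc_peak = 50)
  if (is.null(overexpression)) {
    overexpression <- tibble::tibble(gene = genes, cln3_oe = 0, clb2_oe = 0)
  }
  list(expression = expression, binding = binding, promoters = promoters,
       cc_peaks = cc_peaks, overexpression = overexpression)
}

# Long-format expression rows for one gene from per-strain 4-vectors.
expr_rows <- function(gene, ...) {
  strains <- list(...)
  purrr::imap_dfr(strains, function(v, s) {
    tibble::tibble(gene = gene, strain = s, time = c(20L, 40L, 60L, 80L),
                   value = v)
  })
}
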