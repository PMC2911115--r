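#' Simulation parameters for the synthetic G1/S dataset
#'
#' Bundles every tunable of the synthetic-data generator with defaults
#' matching the study conditions the analysis assumes: 445 candidate genes
#' of which 111 are MBF targets and 94 SBF targets with 36 shared; MCB
#' (ACGCGT) planting in the proximal 200 bp at probability 0.65 for MBF
#' targets versus 0.045 background, SCB (CRCGAA) within 400 bp at 0.78
#' versus 0.33; cell-cycle peak times unimodal early (normal, mean 20% of
#' the cycle) for MBF targets and bimodal (25% / 40%) for SBF targets; four
#' ChIP-chip location studies with study-specific sensitivity (the
#' Swi4-rich study the most sensitive for Swi4) and a common false-positive
#' rate.
#'
#' @param n_genes Number of candidate genes.
#' @param n_mbf,n_sbf,n_shared Planted MBF / SBF target counts and their
#'   overlap (`n_shared <= min(n_mbf, n_sbf)`).
#' @param amplitude_meanlog,amplitude_sdlog Log-normal parameters of the
#'   wild-type induction amplitude (log2 units).
#' @param noise_sd Gaussian noise standard deviation on every log2 value.
#' @param attenuation Named list of multiplicative factors applied to a
#'   target's induction amplitude per genotype: `cognate` (the deletion of
#'   the gene's own regulator), `shared_single` (a dual target in a single
#'   deletion), `swi6`/`swi4mbp1` (residual response when both regulons are
#'   disabled), `control` (strain without the inducible cyclin).
#' @param peak_times,peak_probs Candidate induction peak times (min) and
#'   their sampling probabilities for planted targets.
#' @param binding Tibble with columns `study`, `sens_mbp1`, `sens_swi4`,
#'   `fpr`; `weighted_study` names the Swi4-rich study given its own
#'   binding category.
#' @param weighted_study See `binding`.
#' @param promoter_length,gc Promoter length (bp) and background GC
#'   fraction.
#' @param mbf_motif,mbf_window,p_mbf_proximal,p_mbf_background MCB planting:
#'   motif, proximal window (bp upstream of the TSS), planting probability
#'   in MBF targets and in all other genes.
#' @param sbf_motif,sbf_window,p_sbf_proximal,p_sbf_background SCB planting,
#'   analogous.
#' @param cc_mbf_mean,cc_mbf_sd,cc_sbf_means,cc_sbf_sd Cell-cycle peak-time
#'   distributions (percent of cycle) for MBF targets (normal) and SBF
#'   targets (equal-weight two-component mixture).
#' @param non_ccr_frac Fraction of non-targets with no cell-cycle peak (ND).
#' @param target_nd_frac Fraction of targets with missing peak data.
#' @param oe_cln3_target,oe_cln3_bg,oe_clb2_target,oe_clb2_bg Mean/sd pairs
#'   for the Cln3- and Clb2-overexpression responses of targets and
#'   non-targets (log2 units).
#' @param oe_missing_frac Fraction of genes with missing overexpression
#'   values.
#' @param label_noise Label-noise rate used when emulating the two prior
#'   published classifications that real control sets derive from.
#' @param other_tf_frac Fraction of genes annotated as regulated by other
#'   cell-cycle transcription factors (excluded from control positives).
#' @param n_pos Named integer vector of training-positive sizes per factor.
#' @param n_neg_groups Number of random negative groups merged per factor.
#' @param bench_size,bench_dual Positive-benchmark size and its
#'   dual-regulated quota.
#' @param bench_neg_draws,bench_neg_size Negative-benchmark draw count and
#'   per-draw size.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_genes = 445L,
                       n_mbf = 111L, n_sbf = 94L, n_shared = 36L,
                       amplitude_meanlog = log(2), amplitude_sdlog = 0.4,
                       noise_sd = 0.25,
                       attenuation = list(cognate = 0.2, shared_single = 0.6,
                                          swi6 = 0.05, swi4mbp1 = 0.05, control = 0),
                       peak_times = c(20, 40, 60), peak_probs = c(0.35, 0.5, 0.15),
                       binding = tibble::tibble(
                         study = c("iyer", "simon", "lee", "harbison"),
                         sens_mbp1 = c(0.30, 0.40, 0.50, 0.75),
                         sens_swi4 = c(0.70, 0.35, 0.35, 0.35),
                         fpr = c(0.03, 0.03, 0.03, 0.03)),
                       weighted_study = "iyer",
                       promoter_length = 1000L, gc = 0.38,
                       mbf_motif = "ACGCGT", mbf_window = 200L,
                       p_mbf_proximal = 0.65, p_mbf_background = 0.045,
                       sbf_motif = "CRCGAA", sbf_window = 400L,
                       p_sbf_proximal = 0.78, p_sbf_background = 0.33,
                       cc_mbf_mean = 20, cc_mbf_sd = 5,
                       cc_sbf_means = c(25, 40), cc_sbf_sd = 5,
                       non_ccr_frac = 0.3, target_nd_frac = 0.05,
                       oe_cln3_target = c(1.5, 0.5), oe_cln3_bg = c(0, 0.5),
                       oe_clb2_target = c(-0.3, 0.4), oe_clb2_bg = c(0, 0.4),
                       oe_missing_frac = 0.05,
                       label_noise = 0.10, other_tf_frac = 0.05,
                       n_pos = c(mbp1 = 40L, swi4 = 32L), n_neg_groups = 5L,
                       bench_size = 40L, bench_dual = 10L,
                       bench_neg_draws = 2L, bench_neg_size = 40L) {
  p <- as.list(environment())
  if (p$n_shared > min(p$n_mbf, p$n_sbf)) {
    abort("n_shared must not exceed min(n_mbf, n_sbf)")
  }
  probs <- c(p$p_mbf_proximal, p$p_mbf_background, p$p_sbf_proximal,
             p$p_sbf_background, p$gc, p$label_noise, p$other_tf_frac,
             p$non_ccr_frac, p$target_nd_frac, p$oe_missing_frac,
             p$binding$sens_mbp1, p$binding$sens_swi4, p$binding$fpr)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (p$amplitude_sdlog < 0) abort("amplitude dispersion must be non-negative")
  if (p$mbf_window > p$promoter_length || p$sbf_window > p$promoter_length) {
    abort("motif planting windows must fit within the promoter length")
  }
  if (!p$weighted_study %in% p$binding$study) abort("weighted_study must be one of the binding studies")
  structure(p, class = "sim_params")
}

# Triangular induction profile: 0 at time 0, apex `amplitude` at `peak`,
# linear decay with slope amplitude/60 on both sides. The simplest
# rise-peak-fall shape consistent with a single induction wave.
induction_profile <- function(amplitude, peak, timepoints = c(20, 40, 60, 80)) {
  amplitude * pmax(0, 1 - abs(timepoints - peak) / 60)
}

#' Generate a random promoter sequence with planted motifs
#'
#' Background bases are i.i.d. with the requested GC fraction; planted
#' motifs are written verbatim at the requested positions, with degenerate
#' IUPAC letters in a planted motif resolved uniformly among their allowed
#' bases. Positions follow the package's upstream coordinate convention:
#' position 1 is the base immediately upstream of the TSS (the last base of
#' the returned string) and a motif planted at position `u` has its 5' end
#' at upstream position `u`, spanning positions `u` down to
#' `u - nchar(motif) + 1`.
#'
#' @param length Promoter length in bp.
#' @param gc Background GC fraction in `[0, 1]`.
#' @param planted Tibble (or data frame) with columns `motif` and
#'   `position` (upstream start coordinate). May be empty.
#' @return A single uppercase A/C/G/T string of the requested length.
#' @export
generate_promoter <- function(length, gc, planted = NULL) {
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq_chars <- sample(names(base_probs), length, replace = TRUE, prob = base_probs)
  if (!is.null(planted) && nrow(planted) > 0) {
    spans <- purrr::pmap(planted, function(motif, position, ...) {
      m <- nchar(motif)
      if (position > length || position < m) {
        abort(sprintf("planted motif '%s' at position %d does not fit in a %d bp promoter",
                      motif, position, length))
      }
      i <- length - position + 1  # string index of the motif 5' end
      i:(i + m - 1)
    })
    all_idx <- unlist(spans)
    if (anyDuplicated(all_idx)) abort("planted motifs overlap")
    for (k in seq_len(nrow(planted))) {
      letters_k <- resolve_iupac(planted$motif[k])
      seq_chars[spans[[k]]] <- letters_k
    }
  }
  paste(seq_chars, collapse = "")
}

# IUPAC nucleotide codes used for consensus motifs.
IUPAC_MAP <- list(A = "A", C = "C", G = "G", T = "T",
                  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T"))

# Draw one concrete instantiation of an IUPAC consensus, uniformly per
# degenerate position.
resolve_iupac <- function(motif) {
  chars <- strsplit(toupper(motif), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_MAP))
  if (length(bad) > 0) abort(sprintf("non-IUPAC character(s) in motif: %s", paste(bad, collapse = ", ")))
  vapply(chars, function(ch) {
    opts <- IUPAC_MAP[[ch]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1), USE.NAMES = FALSE)
}

#' Generate a complete synthetic dataset with planted MBF/SBF targets
#'
#' Produces every input the scoring pipeline consumes -- expression panel,
#' four binding call sets per factor, promoters, cell-cycle peak map,
#' overexpression responses -- together with the planted truth. Planted
#' targets are induced in the wild type with genotype-dependent
#' attenuation: near-zero response in `swi6` and `swi4mbp1` for all
#' targets, MBF targets attenuated in `mbp1`, SBF targets in `swi4`, and a
#' flat `cln3control` genotype. The same seed yields a bit-identical
#' dataset.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `start_dataset` with elements `expression`
#'   (long tibble), `binding` (tibble `tf`, `study`, `gene`), `promoters`,
#'   `cc_peaks`, `overexpression`, `truth` (tibble `gene`, `mbf`, `sbf`,
#'   `planted_mcb`, `planted_scb`), `params` and `seed`.
#' @export
simulate_dataset <- function(params = sim_params(), seed) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  p <- params
  genes <- sprintf("YSN%04dW", seq_len(p$n_genes))

  # --- truth assignment ------------------------------------------------
  mbf <- sample(genes, p$n_mbf)
  shared <- sample(mbf, p$n_shared)
  sbf <- c(shared, sample(setdiff(genes, mbf), p$n_sbf - p$n_shared))
  truth <- tibble::tibble(
    gene = genes,
    mbf = genes %in% mbf,
    sbf = genes %in% sbf)
  klass <- dplyr::case_when(
    truth$mbf & truth$sbf ~ "shared",
    truth$mbf ~ "mbf_only",
    truth$sbf ~ "sbf_only",
    TRUE ~ "none")

  # --- expression panel ------------------------------------------------
  timepoints <- c(20L, 40L, 60L, 80L)
  genotypes <- c("wt", "mbp1", "swi4", "swi6", "swi4mbp1", "cln3control")
  amplitude <- ifelse(klass == "none", 0, rlnorm(p$n_genes, p$amplitude_meanlog, p$amplitude_sdlog))
  peak <- sample(p$peak_times, p$n_genes, replace = TRUE, prob = p$peak_probs)
  att <- p$attenuation
  genotype_factor <- function(kl, g) {
    dplyr::case_when(
      g == "wt" ~ 1,
      g == "cln3control" ~ att$control,
      g == "swi6" ~ att$swi6,
      g == "swi4mbp1" ~ att$swi4mbp1,
      g == "mbp1" & kl == "mbf_only" ~ att$cognate,
      g == "swi4" & kl == "sbf_only" ~ att$cognate,
      g == "mbp1" & kl == "shared" ~ att$shared_single,
      g == "swi4" & kl == "shared" ~ att$shared_single,
      TRUE ~ 1)
  }
  grid <- tidyr::expand_grid(gene_idx = seq_len(p$n_genes), strain = genotypes,
                             time = timepoints)
  fac <- genotype_factor(klass[grid$gene_idx], grid$strain)
  clean <- amplitude[grid$gene_idx] * fac *
    pmax(0, 1 - abs(grid$time - peak[grid$gene_idx]) / 60)
  expression <- tibble::tibble(
    gene = genes[grid$gene_idx], strain = grid$strain, time = grid$time,
    value = clean + rnorm(nrow(grid), 0, p$noise_sd))

  # --- binding calls ---------------------------------------------------
  binding <- purrr::map_dfr(seq_len(nrow(p$binding)), function(i) {
    st <- p$binding$study[i]
    dplyr::bind_rows(
      tibble::tibble(tf = "mbp1", study = st,
                     gene = genes[runif(p$n_genes) < ifelse(truth$mbf, p$binding$sens_mbp1[i], p$binding$fpr[i])]),
      tibble::tibble(tf = "swi4", study = st,
                     gene = genes[runif(p$n_genes) < ifelse(truth$sbf, p$binding$sens_swi4[i], p$binding$fpr[i])]))
  })

  # --- promoters with planted motifs -----------------------------------
  m_mcb <- nchar(p$mbf_motif)
  m_scb <- nchar(p$sbf_motif)
  plant_mcb <- runif(p$n_genes) < ifelse(truth$mbf, p$p_mbf_proximal, p$p_mbf_background)
  plant_scb <- runif(p$n_genes) < ifelse(truth$sbf, p$p_sbf_proximal, p$p_sbf_background)
  sequences <- vapply(seq_len(p$n_genes), function(i) {
    planted <- NULL
    if (plant_mcb[i]) {
      planted <- tibble::tibble(motif = p$mbf_motif,
                                position = sample(m_mcb:p$mbf_window, 1))
    }
    if (plant_scb[i]) {
      repeat {
        pos <- sample(m_scb:p$sbf_window, 1)
        if (is.null(planted) ||
            min(abs(pos - planted$position)) >= max(m_mcb, m_scb)) break
      }
      planted <- dplyr::bind_rows(planted,
                                  tibble::tibble(motif = p$sbf_motif, position = pos))
    }
    generate_promoter(p$promoter_length, p$gc, planted)
  }, character(1))
  promoters <- tibble::tibble(gene = genes, anchor = "tss",
                              length = p$promoter_length, sequence = sequences)

  # --- cell-cycle peak map ---------------------------------------------
  raw_peak <- numeric(p$n_genes)
  for (i in seq_len(p$n_genes)) {
    raw_peak[i] <- switch(klass[i],
      mbf_only = rnorm(1, p$cc_mbf_mean, p$cc_mbf_sd),
      shared   = rnorm(1, p$cc_mbf_mean, p$cc_mbf_sd),
      sbf_only = rnorm(1, sample(p$cc_sbf_means, 1), p$cc_sbf_sd),
      none     = runif(1, 0, 100))
  }
  raw_peak <- raw_peak %% 100
  nd <- ifelse(klass == "none",
               runif(p$n_genes) < p$non_ccr_frac,
               runif(p$n_genes) < p$target_nd_frac)
  cc_peaks <- tibble::tibble(gene = genes, cc_peak = ifelse(nd, NA_real_, raw_peak))

  # --- overexpression responses ----------------------------------------
  is_target <- klass != "none"
  cln3 <- ifelse(is_target,
                 rnorm(p$n_genes, p$oe_cln3_target[1], p$oe_cln3_target[2]),
                 rnorm(p$n_genes, p$oe_cln3_bg[1], p$oe_cln3_bg[2]))
  clb2 <- ifelse(is_target,
                 rnorm(p$n_genes, p$oe_clb2_target[1], p$oe_clb2_target[2]),
                 rnorm(p$n_genes, p$oe_clb2_bg[1], p$oe_clb2_bg[2]))
  cln3[runif(p$n_genes) < p$oe_missing_frac] <- NA_real_
  clb2[runif(p$n_genes) < p$oe_missing_frac] <- NA_real_
  overexpression <- tibble::tibble(gene = genes, cln3_oe = cln3, clb2_oe = clb2)

  truth$planted_mcb <- plant_mcb
  truth$planted_scb <- plant_scb
  structure(list(expression = expression, binding = binding,
                 promoters = promoters, cc_peaks = cc_peaks,
                 overexpression = overexpression, truth = truth,
                 params = p, seed = seed),
            class = "start_dataset")
}

#' Emulate prior published target classifications from planted truth
#'
#' The real control sets derive from two previously published
#' classifications; synthetically this is emulated by corrupting the truth
#' labels with a configurable noise rate: each study keeps a true target
#' with probability `1 - label_noise` and adds `round(label_noise * n_true)`
#' spurious non-targets, then ranks its list by a noisy relevance score so
#' "top-ranked" selection rules are meaningful. A random fraction of genes
#' is additionally annotated as regulated by other cell-cycle factors.
#'
#' @param truth Truth tibble from [simulate_dataset()].
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @return A list with `annotations` (tibble `study`, `tf`, `gene`, `rank`)
#'   and `other_tf` (character vector of gene ids).
#' @export
simulate_prior_annotations <- function(truth, params = sim_params(), seed) {
  set.seed(seed)
  p <- params
  make_list <- function(study, tf, targets) {
    keep <- targets[runif(length(targets)) >= p$label_noise]
    n_spurious <- round(p$label_noise * length(targets))
    pool <- setdiff(truth$gene, targets)
    spurious <- sample(pool, min(n_spurious, length(pool)))
    g <- c(keep, spurious)
    score <- c(rep(2, length(keep)), rep(0, length(spurious))) + rnorm(length(g), 0, 0.5)
    tibble::tibble(study = study, tf = tf, gene = g, rank = rank(-score, ties.method = "first"))
  }
  ann <- dplyr::bind_rows(
    make_list("beyer", "mbp1", truth$gene[truth$mbf]),
    make_list("beyer", "swi4", truth$gene[truth$sbf]),
    make_list("holloway", "mbp1", truth$gene[truth$mbf]),
    make_list("holloway", "swi4", truth$gene[truth$sbf]))
  other_tf <- sample(truth$gene, round(p$other_tf_frac * nrow(truth)))
  list(annotations = ann, other_tf = other_tf)
}

#' Derive training control sets and evaluation benchmarks from planted truth
#'
#' Reproduces, on synthetic data, the study's training/evaluation split:
#' noisy prior classifications are generated from the truth
#' ([simulate_prior_annotations()]), training control sets are built from
#' them with [build_control_sets()] (40 positives for Mbp1, 32 for Swi4;
#' negatives are five merged random groups of unannotated genes), and
#' held-out benchmarks are drawn disjoint from the training positives: two
#' positive benchmarks per factor of 40 genes each (10 dual-regulated + 30
#' single-factor) and a negative benchmark merging two draws of 40
#' unannotated genes (hence somewhat fewer than 80 after de-duplication).
#'
#' @param truth Truth tibble from [simulate_dataset()].
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @return A list with `controls` (per-factor positives/negatives),
#'   `benchmarks` (per-factor `pos1`, `pos2`, `neg`), `annotations` and
#'   `other_tf`.
#' @export
split_truth_controls <- function(truth, params = sim_params(), seed) {
  priors <- simulate_prior_annotations(truth, params, seed)
  ann <- priors$annotations
  controls <- build_control_sets(ann, universe = truth$gene,
                                 n_pos = params$n_pos,
                                 other_tf = priors$other_tf,
                                 n_neg_groups = params$n_neg_groups,
                                 seed = seed + 1L)
  set.seed(seed + 2L)
  annotated <- function(tf) unique(ann$gene[ann$tf == tf])
  dual <- intersect(annotated("mbp1"), annotated("swi4"))
  benchmarks <- purrr::map(c(mbp1 = "mbp1", swi4 = "swi4"), function(tf) {
    train_pos <- controls[[tf]]$positives
    dual_pool <- setdiff(dual, train_pos)
    single_pool <- setdiff(setdiff(annotated(tf), dual), train_pos)
    n_single <- params$bench_size - params$bench_dual
    if (length(dual_pool) < params$bench_dual || length(single_pool) < n_single) {
      abort(sprintf("not enough annotated %s genes outside the training set for benchmarks", tf))
    }
    draw_pos <- function() c(sample(dual_pool, params$bench_dual),
                             sample(single_pool, n_single))
    neg_pool <- setdiff(truth$gene, annotated(tf))
    if (length(neg_pool) < params$bench_neg_size) {
      abort(sprintf("not enough unannotated genes for the %s negative benchmark", tf))
    }
    neg <- unique(unlist(replicate(params$bench_neg_draws,
                                   sample(neg_pool, params$bench_neg_size),
                                   simplify = FALSE)))
    list(pos1 = draw_pos(), pos2 = draw_pos(), neg = neg)
  })
  list(controls = controls, benchmarks = benchmarks,
       annotations = ann, other_tf = priors$other_tf)
}
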