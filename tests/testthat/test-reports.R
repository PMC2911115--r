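test_that("consensus CCR membership needs top-n support in enough lists", {
  lists <- list(c("A", "B", "C", "D"), c("B", "A", "E"), c("A", "B"),
                c("C", "E"), c("E", "C"))
  got <- consensus_ccr(lists, top_n = 2, min_lists = 3)
  # A: lists 1,2(top2? B,A yes),3 -> 3 lists; B: 1,2? top2 of list2 = B,A -> yes, 3 -> 3; C: 1(no, rank3),4,5 -> 2; E: 2(no, rank3),4,5 -> 2
  expect_equal(got, c("A", "B"))
  expect_error(consensus_ccr(list(c("A", "A", "B"))), "duplicate")

  # brute-force membership counting on random toy rankings
  set.seed(55)
  genes <- sprintf("G%02d", 1:50)
  for (i in 1:10) {
    lists <- replicate(5, sample(genes, sample(20:50, 1)), simplify = FALSE)
    got <- consensus_ccr(lists, top_n = 15, min_lists = 3)
    counts <- sapply(genes, function(g) {
      sum(vapply(lists, function(l) g %in% head(l, 15), logical(1)))
    })
    expect_equal(got, sort(names(counts)[counts >= 3]))
  }
})

test_that("overlap reports reproduce the headline target-set structure", {
  # 111 MBF and 94 SBF targets sharing 36: union 169
  genes <- sprintf("G%03d", 1:300)
  mbf <- genes[1:111]
  sbf <- genes[c(1:36, 112:169)]
  rep2 <- overlap_report(list(MBF = mbf, SBF = sbf))
  expect_equal(sum(rep2$count), 169)
  expect_equal(rep2$count[rep2$region == "MBF&SBF"], 36)
  expect_equal(rep2$count[rep2$region == "MBF"], 75)
  expect_equal(rep2$count[rep2$region == "SBF"], 58)

  disjoint <- overlap_report(list(a = c("X", "Y"), b = c("Z")))
  expect_equal(disjoint$count[disjoint$region == "a&b"], 0)

  # random sets against brute-force set algebra, including three-way
  set.seed(77)
  for (i in 1:10) {
    s <- list(a = sample(genes, 40), b = sample(genes, 60), c = sample(genes, 25))
    got <- overlap_report(s)
    abc <- length(Reduce(intersect, s))
    expect_equal(got$count[got$region == "a&b&c"], abc)
    only_a <- length(setdiff(setdiff(s$a, s$b), s$c))
    expect_equal(got$count[got$region == "a"], only_a)
    ab <- length(setdiff(intersect(s$a, s$b), s$c))
    expect_equal(got$count[got$region == "a&b"], ab)
    expect_equal(sum(got$count), length(unique(unlist(s))))
  }
})

test_that("peak-phase histograms bin targets and count ND separately", {
  peaks <- tibble::tibble(gene = c("A", "B", "C", "D"),
                          cc_peak = c(20, 22, NA, 97))
  ph <- peak_phase_distribution(c("A", "B", "C", "D"), peaks, bin_width = 5)
  expect_equal(sum(ph$histogram$count), 3)
  expect_equal(ph$histogram$count[ph$histogram$bin_start == 20], 2L)
  expect_equal(ph$n_nd, 1)
  # all targets in one bin
  one <- peak_phase_distribution(c("A", "B"),
                                 tibble::tibble(gene = c("A", "B"), cc_peak = c(20, 20)))
  expect_equal(sum(one$histogram$count > 0), 1)
  # all ND
  nd <- peak_phase_distribution("C", peaks)
  expect_equal(nd$n_nd, 1)
  expect_equal(sum(nd$histogram$count), 0)
  # CCR fraction against an explicit consensus set
  ph2 <- peak_phase_distribution(c("A", "B", "C"), peaks, ccr_set = c("A", "X"))
  expect_equal(ph2$ccr_fraction, 1 / 3)
})

test_that("synthetic MBF targets peak near the configured early-G1 mode", {
  p <- sim_params()
  ds <- simulate_dataset(p, seed = 23)
  mbf <- ds$truth$gene[ds$truth$mbf]
  ph <- peak_phase_distribution(mbf, ds$cc_peaks, bin_width = 5)
  mode_bin <- ph$histogram$bin_start[which.max(ph$histogram$count)]
  expect_lte(abs(mode_bin - 20), 5)
})

test_that("motif position summaries assign zones with inclusive boundaries", {
  prom <- tibble::tibble(
    gene = "G1", anchor = "tss", length = 600,
    # one ACGCG with its 5' end at upstream position 150
    sequence = paste0(strrep("T", 600 - 150), "ACGCG", strrep("T", 145)))
  ms <- motif_position_summary("G1", prom, motif = "ACGCG")
  expect_equal(ms$occurrences$fraction, c(1, 0, 0))
  expect_equal(ms$genes$count[ms$genes$status == "proximal"], 1L)

  # occurrence at exactly 200 falls in the proximal zone
  prom200 <- tibble::tibble(
    gene = "G1", anchor = "tss", length = 600,
    sequence = paste0(strrep("T", 400), "ACGCG", strrep("T", 195)))
  ms200 <- motif_position_summary("G1", prom200, motif = "ACGCG")
  expect_equal(ms200$occurrences$fraction, c(1, 0, 0))

  # and at 201 it does not
  prom201 <- tibble::tibble(
    gene = "G1", anchor = "tss", length = 600,
    sequence = paste0(strrep("T", 399), "ACGCG", strrep("T", 196)))
  ms201 <- motif_position_summary("G1", prom201, motif = "ACGCG")
  expect_equal(ms201$occurrences$fraction, c(0, 1, 0))
  expect_equal(ms201$genes$count[ms201$genes$status == "distal_only"], 1L)

  # planted proximal fraction of synthetic MBF targets within binomial 99% CI
  p <- sim_params()
  ds <- simulate_dataset(p, seed = 29)
  mbf <- ds$truth$gene[ds$truth$mbf]
  ms <- motif_position_summary(mbf, ds$promoters, motif = p$mbf_motif,
                               boundaries = c(p$mbf_window, 500L))
  n_prox <- ms$genes$count[ms$genes$status == "proximal"]
  ci <- qbinom(c(0.005, 0.995), length(mbf), p$p_mbf_proximal)
  expect_gte(n_prox, ci[1])  # chance hits can only add
  expect_lte(n_prox, ci[2] + qbinom(0.999, length(mbf), 0.05))
})

test_that("location benchmarking matches its confusion construction", {
  genes <- sprintf("G%03d", 1:100)
  sc <- tibble::tibble(gene = genes, sum = seq(10, 0.1, length.out = 100)) |>
    dplyr::mutate(rank = dplyr::row_number())
  class(sc) <- c("lls_scores", class(sc))
  # calls identical to the reference targets at cutoff 30: MCC 1 there
  bench <- benchmark_location_dataset(genes[1:30], sc, cutoffs = c(10, 30, 60))
  expect_equal(bench$mcc[bench$cutoff == 30], 1)
  expect_lt(bench$mcc[bench$cutoff == 10], 1)
  # empty call set: every MCC factor with TP+FP = 0 is undefined
  empty <- benchmark_location_dataset(character(0), sc, cutoffs = c(10, 50))
  expect_true(all(is.na(empty$mcc)))
  # synthetic calls of known sensitivity/FPR: empirical MCC close to the
  # analytic expectation from the confusion construction
  set.seed(91)
  n <- 10000
  big <- tibble::tibble(gene = sprintf("B%05d", 1:n), sum = seq(n, 1)) |>
    dplyr::mutate(rank = dplyr::row_number())
  class(big) <- c("lls_scores", class(big))
  k <- 2000
  sens <- 0.7; fpr <- 0.05
  bound <- c(big$gene[1:k][runif(k) < sens], big$gene[(k + 1):n][runif(n - k) < fpr])
  got <- benchmark_location_dataset(bound, big, cutoffs = k)$mcc
  tp <- sens * k; fp <- fpr * (n - k); fn <- (1 - sens) * k; tn <- (1 - fpr) * (n - k)
  expected <- (tp * tn - fp * fn) / sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  expect_lt(abs(got - expected), 0.03)
})

test_that("divergent-pair evaluation scores labelled genes only", {
  pairs <- tibble::tibble(
    gene_a = c("A1", "B1", "C1"), gene_b = c("A2", "B2", "C2"),
    label_a = c("regulated", "not_regulated", "unknown"),
    label_b = c("unknown", "regulated", "unknown"))
  # perfect prediction: regulated genes in targets, others out
  m <- divergent_pair_mcc(pairs, targets = c("A1", "B2"))
  expect_equal(m$mcc, 1)
  expect_equal(unname(attr(m, "counts")["tp"]), 2L)
  # fully unknown pair contributes nothing
  expect_equal(sum(attr(m, "counts")), 3L)  # C1/C2 skipped
  expect_error(divergent_pair_mcc(pairs[0, ], "A1"), "no labelled")
  expect_error(divergent_pair_mcc(tibble::tibble(gene_a = "X", gene_b = "X",
                                                 label_a = "regulated",
                                                 label_b = "unknown"), "X"),
               "distinct")

  # label-independent predictions give MCC near zero over permutations
  set.seed(13)
  genes_a <- sprintf("A%03d", 1:150)
  genes_b <- sprintf("B%03d", 1:150)
  labels <- sample(c("regulated", "not_regulated"), 300, replace = TRUE)
  base_pairs <- tibble::tibble(gene_a = genes_a, gene_b = genes_b,
                               label_a = labels[1:150], label_b = labels[151:300])
  mccs <- replicate(300, {
    targets <- sample(c(genes_a, genes_b), 100)
    divergent_pair_mcc(base_pairs, targets)$mcc
  })
  expect_lt(abs(mean(mccs, na.rm = TRUE)), 0.05)
})

test_that("functional enrichment agrees with hypergeometric enumeration", {
  universe <- sprintf("G%03d", 1:100)
  classes <- tibble::tibble(gene = universe,
                            class = c(rep("dna_rrr", 10), rep("others", 90)))
  targets <- universe[c(1:10, 11:20)]  # all 10 class genes + 10 others
  res <- functional_enrichment(targets, classes, universe)
  row <- res[res$class == "dna_rrr", ]
  # two-tailed Fisher p by direct enumeration of the hypergeometric tail:
  # P(X = k) for K = 10 class genes, n = 20 targets drawn from N = 100
  dens <- dhyper(0:10, 10, 90, 20)
  p_oracle <- sum(dens[dens <= dens[11] * (1 + 1e-7)])
  expect_equal(row$p_value, p_oracle, tolerance = 1e-9)
  expect_equal(row$n_target_in_class, 10)
  expect_gt(row$fold_enrichment, 4)

  # targets = universe: p = 1 for every class
  res_all <- functional_enrichment(universe, classes, universe)
  expect_true(all(res_all$p_value == 1))

  # Fisher p symmetric under transposing the 2x2 table
  p1 <- fisher.test(matrix(c(8, 12, 2, 78), 2))$p.value
  p2 <- fisher.test(t(matrix(c(8, 12, 2, 78), 2)))$p.value
  expect_equal(p1, p2)

  # unknown-class genes are excluded from percentages
  classes2 <- dplyr::mutate(classes,
                            class = ifelse(gene %in% universe[91:100], "unknown", class))
  res2 <- functional_enrichment(targets, classes2, universe)
  expect_equal(res2$pct_universe[res2$class == "dna_rrr"], 100 * 10 / 90)
  expect_error(functional_enrichment(c(universe[1], "ZZZ"), classes, universe),
               "subset")
})

test_that("rescoring without a classifier shifts ranks as a fresh rerun would", {
  ds <- simulate_dataset(sim_params(n_genes = 120L, n_mbf = 30L, n_sbf = 24L,
                                    n_shared = 9L), seed = 3)
  tc <- split_truth_controls(ds$truth, sim_params(
    n_genes = 120L, n_mbf = 30L, n_sbf = 24L, n_shared = 9L,
    n_pos = c(mbp1 = 10L, swi4 = 8L), bench_size = 8L, bench_dual = 3L,
    bench_neg_size = 20L), seed = 4)
  m <- assemble_classifier_matrix(ds, "mbp1")
  bb <- bin_classifier_matrix(m, set_size = 30L, ranks = c(8L, 15L, 23L), seed = 5)
  w <- estimate_lls_weights(bb$binned, tc$controls$mbp1)
  full <- total_scores(bb$binned, w)
  # removing a zero-weight classifier leaves totals unchanged
  w0 <- w
  w0$lls[w0$classifier == "motif"] <- 0
  full0 <- total_scores(bb$binned, w0)
  red0 <- rescore_without(bb$binned, w0, "motif")
  expect_equal(dplyr::arrange(tibble::as_tibble(red0), gene)$sum,
               dplyr::arrange(tibble::as_tibble(full0), gene)$sum)
  # and a from-scratch 8-classifier pipeline gives identical scores/ranks
  specs8 <- attr(bb$binned, "specs")
  keep <- specs8$id[specs8$id != "motif"]
  binned8 <- bb$binned[, c("gene", keep)]
  attr(binned8, "specs") <- specs8[specs8$id != "motif", ]
  w8 <- estimate_lls_weights(binned8, tc$controls$mbp1)
  sc8 <- total_scores(binned8, w8)
  red <- rescore_without(bb$binned, w, "motif")
  expect_equal(red$gene, sc8$gene)
  expect_equal(red$sum, sc8$sum, tolerance = 1e-12)
  expect_error(rescore_without(bb$binned, w, "not_a_classifier"), "not active")
})
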