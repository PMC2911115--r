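test_that("bin thresholds are averaged order statistics of random subsets", {
  # one forced draw of all 40 values 1..40: thresholds are the 10/20/30th
  t <- derive_bin_thresholds(1:40, n_sets = 1, set_size = 40, seed = 1)
  expect_equal(unname(t), c(10, 20, 30))

  # constant column: all thresholds equal the constant, everything in bin 1
  tc <- derive_bin_thresholds(rep(2.5, 60), seed = 3)
  expect_equal(unname(tc), c(2.5, 2.5, 2.5))
  expect_true(all(assign_bin(rep(2.5, 10), tc) == "b1"))

  expect_error(derive_bin_thresholds(1:10), "set_size")

  # re-implementation oracle with the same seed and draw order
  set.seed(11)
  x <- rnorm(200)
  got <- derive_bin_thresholds(x, seed = 99)
  set.seed(99)
  draws <- sapply(1:3, function(i) sort(sample(x, 40))[c(10, 20, 30)])
  expect_equal(unname(got), unname(rowMeans(draws)))
})

test_that("bin assignment follows the half-open rule and partitions the line", {
  t <- c(t1 = -1, t2 = 0.5, t3 = 2)
  expect_equal(assign_bin(-1, t), "b1")       # boundary belongs left
  expect_equal(assign_bin(-0.999, t), "b2")
  expect_equal(assign_bin(0.5, t), "b2")
  expect_equal(assign_bin(2, t), "b3")
  expect_equal(assign_bin(2.001, t), "b4")
  expect_equal(assign_bin(NA_real_, t), "missing")
  expect_error(assign_bin(1, c(2, 1, 3)), "ordered")

  set.seed(5)
  v <- runif(10000, -10, 10)
  bins <- assign_bin(v, t)
  expect_true(all(bins %in% paste0("b", 1:4)))
  # each value lands in exactly the interval its bin claims
  expect_true(all((bins == "b1") == (v <= t[1])))
  expect_true(all((bins == "b2") == (v > t[1] & v <= t[2])))
  expect_true(all((bins == "b3") == (v > t[2] & v <= t[3])))
  expect_true(all((bins == "b4") == (v > t[3])))
})

make_binned <- function(n = 260, seed = 1) {
  set.seed(seed)
  genes <- sprintf("G%03d", seq_len(n))
  binned <- tibble::tibble(
    gene = genes,
    c1 = sample(c(paste0("b", 1:4), "missing"), n, replace = TRUE,
                prob = c(0.3, 0.3, 0.2, 0.15, 0.05)),
    c2 = sample(c("none", "one", "multiple"), n, replace = TRUE))
  attr(binned, "specs") <- tibble::tibble(
    id = c("c1", "c2"), kind = c("continuous", "categorical"),
    levels = list(NULL, c("none", "one", "multiple")))
  binned
}

test_that("LLS weights follow the smoothed log-ratio formula", {
  # 20/40 positives vs 50/200 negatives in one bin, no smoothing: ln 2
  binned <- tibble::tibble(gene = sprintf("G%03d", 1:240),
                           c1 = c(rep("b1", 20), rep("b2", 20),
                                  rep("b1", 50), rep("b2", 150)))
  attr(binned, "specs") <- tibble::tibble(id = "c1", kind = "categorical",
                                          levels = list(c("b1", "b2")))
  ctrl <- list(positives = sprintf("G%03d", 1:40),
               negatives = sprintf("G%03d", 41:240))
  w0 <- estimate_lls_weights(binned, ctrl, pseudocount = 0)
  expect_equal(w0$lls[w0$bin == "b1"], log(2), tolerance = 1e-12)

  # equal frequencies give weight zero at any pseudocount
  expect_equal(w0$lls[w0$bin == "b2"], log((20 / 40) / (150 / 200)), tolerance = 1e-12)
  binned2 <- binned
  binned2$c1 <- rep(c("b1", "b2"), 120)
  w_eq <- estimate_lls_weights(binned2, ctrl, pseudocount = 0.5)
  expect_equal(w_eq$lls[w_eq$bin == "b1"], 0, tolerance = 1e-12)

  # empty-bin smoothing: 0/200 negatives, 10/40 positives, pc = 1, 4 bins
  binned3 <- tibble::tibble(gene = sprintf("G%03d", 1:240),
                            c1 = c(rep("b1", 10), rep("b2", 30),
                                   rep("b2", 200)))
  attr(binned3, "specs") <- tibble::tibble(id = "c1", kind = "continuous",
                                           levels = list(NULL))
  w1 <- estimate_lls_weights(binned3, ctrl, pseudocount = 1)
  expect_equal(w1$lls[w1$bin == "b1"], log((11 / 44) / (1 / 204)), tolerance = 1e-12)
  # and without smoothing the same configuration is rejected as non-finite
  expect_error(estimate_lls_weights(binned3, ctrl, pseudocount = 0), "pseudocount")

  # the missing pseudo-bin always carries weight zero
  wmiss <- estimate_lls_weights(make_binned(), list(
    positives = sprintf("G%03d", 1:40), negatives = sprintf("G%03d", 41:240)),
    pseudocount = 0.5)
  expect_true(all(wmiss$lls[wmiss$bin == "missing"] == 0))
})

test_that("LLS weights match the formula oracle on random control splits", {
  for (seed in 1:5) {
    binned <- make_binned(seed = seed)
    ctrl <- list(positives = binned$gene[1:40], negatives = binned$gene[41:240])
    w <- estimate_lls_weights(binned, ctrl, pseudocount = 0.5)
    for (i in seq_len(nrow(w))) {
      if (w$bin[i] == "missing") next
      col <- binned[[w$classifier[i]]]
      n_bins <- if (w$classifier[i] == "c1") 4 else 3
      cp <- sum(col[1:40] == w$bin[i])
      cn <- sum(col[41:240] == w$bin[i])
      expect_equal(w$lls[i], oracle_lls(cp, 40, cn, 200, 0.5, n_bins),
                   tolerance = 1e-12)
    }
  }
})

test_that("enlarging a bin's positive count never decreases its weight", {
  for (c0 in 0:39) {
    w_lo <- oracle_lls(c0, 40, 5, 200, 0.5, 4)
    w_hi <- oracle_lls(c0 + 1, 41, 5, 200, 0.5, 4)
    expect_gte(w_hi, w_lo)
  }
})

test_that("total scores sum bin weights, rank deterministically, and decompose", {
  binned <- make_binned(seed = 7)
  ctrl <- list(positives = binned$gene[1:40], negatives = binned$gene[41:240])
  w <- estimate_lls_weights(binned, ctrl, pseudocount = 0.5)
  scores <- total_scores(binned, w)
  expect_equal(scores$sum, scores$c1 + scores$c2, tolerance = 1e-12)
  expect_equal(scores$rank, seq_len(nrow(scores)))
  expect_true(all(diff(scores$sum) <= 1e-12))

  # independent bin-lookup-and-sum oracle on 50 random genes
  set.seed(8)
  for (g in sample(binned$gene, 50)) {
    expected <- 0
    for (cl in c("c1", "c2")) {
      b <- binned[[cl]][binned$gene == g]
      expected <- expected + if (b == "missing") 0 else
        w$lls[w$classifier == cl & w$bin == b]
    }
    expect_equal(scores$sum[scores$gene == g], expected, tolerance = 1e-12)
  }

  # all-zero weights give total zero
  w0 <- w; w0$lls <- 0
  expect_true(all(total_scores(binned, w0)$sum == 0))

  # removing a classifier equals subtracting its contribution column
  reduced <- rescore_without(binned, w, "c2")
  merged <- dplyr::left_join(tibble::as_tibble(scores),
                             tibble::as_tibble(reduced),
                             by = "gene", suffix = c("", ".red"))
  expect_true(all(abs(merged$sum - merged$c2 - merged$sum.red) < 1e-9))

  expect_error(total_scores(binned, w[w$classifier != "c2", ]), "absent")
})

test_that("control-set construction follows the priority and exclusion rules", {
  # annotations where the two-study intersection alone covers n_pos
  genes <- sprintf("G%02d", 1:60)
  ann <- dplyr::bind_rows(
    tibble::tibble(study = "beyer", tf = "mbp1", gene = genes[1:12], rank = 1:12),
    tibble::tibble(study = "holloway", tf = "mbp1", gene = genes[1:12], rank = 1:12),
    tibble::tibble(study = "beyer", tf = "swi4", gene = genes[11:20], rank = 1:10),
    tibble::tibble(study = "holloway", tf = "swi4", gene = genes[13:22], rank = 1:10))
  cs <- build_control_sets(ann, genes, n_pos = c(mbp1 = 8L, swi4 = 4L), seed = 2)
  # all positives from the intersection, dual-annotated genes excluded
  expect_length(cs$mbp1$positives, 8)
  expect_true(all(cs$mbp1$positives %in% genes[1:10]))  # G11, G12 are dual
  swi4_ann <- genes[11:22]
  expect_false(any(cs$mbp1$positives %in% swi4_ann))
  # swi4 intersection is genes 13..20 minus dual (G13..G20 are not mbp1-annotated
  # except none), so positives come from there
  expect_true(all(cs$swi4$positives %in% genes[13:20]))
  # negatives avoid annotation for the factor and are merged without duplicates
  expect_false(any(cs$mbp1$negatives %in% genes[1:12]))
  expect_false(anyDuplicated(cs$mbp1$negatives) > 0)
  expect_lte(length(cs$mbp1$negatives), 40)

  # top-up path: intersection too small, singles ranked by best prior rank
  ann2 <- dplyr::bind_rows(
    tibble::tibble(study = "beyer", tf = "mbp1", gene = genes[1:2], rank = 1:2),
    tibble::tibble(study = "holloway", tf = "mbp1", gene = genes[1:2], rank = 1:2),
    tibble::tibble(study = "beyer", tf = "mbp1", gene = genes[3:8], rank = 3:8),
    tibble::tibble(study = "beyer", tf = "swi4", gene = genes[30:35], rank = 1:6),
    tibble::tibble(study = "holloway", tf = "swi4", gene = genes[30:35], rank = 1:6))
  cs2 <- build_control_sets(ann2, genes, n_pos = c(mbp1 = 5L, swi4 = 4L), seed = 3)
  expect_equal(sort(cs2$mbp1$positives), c(genes[1:2], genes[3:5]))
  # shortfall is an error naming the gap
  expect_error(build_control_sets(ann2, genes, n_pos = c(mbp1 = 20L, swi4 = 4L)),
               "shortfall")

  # same seed reproduces the same negatives
  cs3 <- build_control_sets(ann, genes, n_pos = c(mbp1 = 8L, swi4 = 4L), seed = 2)
  expect_identical(cs$mbp1$negatives, cs3$mbp1$negatives)
})

test_that("planted targets outscore non-targets on synthetic data", {
  ds <- simulate_dataset(sim_params(), seed = 17)
  tc <- split_truth_controls(ds$truth, sim_params(), seed = 18)
  m <- assemble_classifier_matrix(ds, "mbp1")
  bb <- bin_classifier_matrix(m, seed = 19)
  w <- estimate_lls_weights(bb$binned, tc$controls$mbp1)
  sc <- total_scores(bb$binned, w)
  is_t <- sc$gene %in% ds$truth$gene[ds$truth$mbf]
  obs <- mean(sc$sum[is_t]) - mean(sc$sum[!is_t])
  set.seed(20)
  perm <- replicate(1000, {
    sh <- sample(is_t)
    mean(sc$sum[sh]) - mean(sc$sum[!sh])
  })
  expect_lt(mean(perm >= obs), 0.001)
})
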