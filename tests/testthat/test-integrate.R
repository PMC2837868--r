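test_that("gene medians follow the stated conventions", {
  map <- data.frame(probe = sprintf("P%04d", 1:8),
                    gene = c(rep("g3", 3), rep("g1", 1), rep("g4", 4)),
                    stringsAsFactors = FALSE)
  p <- make_profile(c(0.1, 0.3, 0.5, 0.9, 0.1, 0.3, 0.5, 0.7),
                    platform = "expression", scale = "log10")
  m <- gene_median_expression(p, map)
  expect_equal(m["g3", 1], 0.3)       # odd count
  expect_equal(m["g1", 1], 0.9)       # single probe
  expect_equal(m["g4", 1], 0.4)       # even count: midpoint
  # a gene with no surviving probes is absent, not zero
  map2 <- rbind(map, data.frame(probe = "P9999", gene = "ghost"))
  m2 <- gene_median_expression(p, map2)
  expect_false("ghost" %in% rownames(m2))
})

test_that("g1/g0 stratification excludes opposite-direction carriers from both", {
  gene <- data.frame(chrom = "chr1", start = 10e6, end = 11e6)
  calls <- data.frame(
    sample = c("A", "B", "C"), chrom = "chr1",
    start = c(9e6, 9e6, 50e6), end = c(12e6, 12e6, 60e6),
    direction = c("gain", "loss", "gain"), stringsAsFactors = FALSE)
  st <- stratify_by_copy_number(gene, calls, "gain", c("A", "B", "C", "D"))
  expect_equal(st$g1, "A")
  expect_setequal(st$g0, c("C", "D"))   # B carries the loss: neither set
  # gene outside every call: empty g1
  far <- data.frame(chrom = "chr2", start = 1e6, end = 2e6)
  st2 <- stratify_by_copy_number(far, calls, "gain", c("A", "B", "C", "D"))
  expect_equal(length(st2$g1), 0)
  expect_setequal(st2$g0, c("A", "B", "C", "D"))
})

test_that("signed fold change obeys sign convention, antisymmetry and errors", {
  expect_equal(signed_fold_change(2, 1), 2)
  expect_equal(signed_fold_change(1, 2), -2)
  expect_equal(signed_fold_change(3, 3), 1)
  # log-scale route: FC = base^(summary difference)
  expect_equal(signed_fold_change(log10(c(2, 2)), log10(c(1, 1)),
                                  log_base = 10), 2)
  set.seed(71)
  for (k in 1:20) {
    a <- rnorm(5); b <- rnorm(7)
    if (abs(median(a) - median(b)) < 1e-12) next
    expect_equal(signed_fold_change(a, b, log_base = 10),
                 -signed_fold_change(b, a, log_base = 10))
  }
  expect_error(signed_fold_change(numeric(0), 1), "empty")
  expect_error(signed_fold_change(-1, 2), "positive")
})

test_that("candidate selection is inclusive at the cut and direction-partitioned", {
  cmp <- data.frame(gene = c("a", "b", "c", "d"),
                    chrom = "chr1", start = 1, end = 2,
                    direction = c("gain", "gain", "loss", "loss"),
                    n_g1 = 5, n_g0 = 5,
                    fc_g1_g0 = c(2.0, 1.9, -34.6, -1.9),
                    fc_cancer_normal = NA, significant = NA,
                    stringsAsFactors = FALSE)
  sel <- select_candidates(cmp, min_fc = 2)
  expect_setequal(sel$gene, c("a", "c"))
  s <- attr(sel, "summary")
  expect_equal(s$n_gain, 1); expect_equal(s$n_loss, 1)
  # raising the cut never adds candidates
  sel3 <- select_candidates(cmp, min_fc = 3)
  expect_true(all(sel3$gene %in% sel$gene))
  # strong negatives live in the loss list only
  expect_equal(sel$direction[sel$gene == "c"], "loss")
})

test_that("planted 3-fold dosage effects are estimated within [2.5, 3.6]", {
  # per-sample gene value = median of 3 probes (sd 0.1 log10 each);
  # |g1| = 8, |g0| = 12
  inside <- 0; below_cut_null <- 0; n_rep <- 100
  set.seed(72)
  for (r in seq_len(n_rep)) {
    med3 <- function(n, shift = 0)
      vapply(seq_len(n), function(i) median(shift + rnorm(3, 0, 0.1)),
             numeric(1))
    fc <- signed_fold_change(med3(8, log10(3)), med3(12), log_base = 10)
    if (fc >= 2.5 && fc <= 3.6) inside <- inside + 1
    fc0 <- signed_fold_change(med3(8), med3(12), log_base = 10)
    if (abs(fc0) < 2) below_cut_null <- below_cut_null + 1
  }
  expect_gte(inside / n_rep, 0.9)
  expect_gte(below_cut_null / n_rep, 0.95)
})

test_that("overexpressed candidates only arise from gains, underexpressed from losses", {
  w <- tiny_world(seed = 73)
  g <- w$genome; cfg <- w$config
  co <- simulate_cohort(g, cfg)
  calls <- do.call(rbind, lapply(co, function(s) {
    p <- preprocess_acgh(simulate_acgh(s, g, cfg))
    as.data.frame(apply_filters(call_aberrations(p, estimate_noise(p))))
  }))
  classes <- stats::setNames(vapply(co, `[[`, character(1), "class"), names(co))
  regions <- do.call(rbind, lapply(c("gain", "loss"), function(d)
    as.data.frame(recurrent_regions(
      build_frequency_track(calls, d, classes), 0.25))))
  ex <- lapply(co[1:10], simulate_expression, genome = g, config = cfg)
  mat <- gene_median_expression(loess_normalize(ex), g$expr_probes)
  cmp <- copy_number_comparisons(mat, g$genes, calls, names(co),
                                 regions = regions)
  sel <- select_candidates(cmp)
  expect_gt(nrow(sel), 0)
  expect_true(all(sel$fc_g1_g0[sel$direction == "gain"] >= 2))
  expect_true(all(sel$fc_g1_g0[sel$direction == "loss"] <= -2))
})
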