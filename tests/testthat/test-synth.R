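test_that("genome simulation honors its construction contract and is deterministic", {
  g <- simulate_genome(1, 1e7, 100, 200, 20, seed = 1)
  expect_equal(nrow(g$acgh_probes), 100)
  expect_true(all(diff(g$acgh_probes$start) > 0))
  expect_true(all(g$acgh_probes$start >= 0 & g$acgh_probes$start < 1e7))
  expect_equal(nrow(g$genes), 20)
  # genes tiled without overlap
  expect_true(all(g$genes$start[-1] >= g$genes$end[-20]))
  # every gene has >= 1 expression probe; probes map to at most one gene
  expect_true(all(g$genes$gene %in% g$expr_probes$gene))
  expect_true(all(diff(g$expr_probes$start) > 0))
  g2 <- simulate_genome(1, 1e7, 100, 200, 20, seed = 1)
  expect_identical(g, g2)
  g3 <- simulate_genome(1, 1e7, 100, 200, 20, seed = 2)
  expect_false(identical(g$acgh_probes$start, g3$acgh_probes$start))
})

test_that("impossible gene tiling is rejected", {
  expect_error(simulate_genome(1, 1e6, 100, 1e6, 1e6, seed = 1), "tile")
})

test_that("cohort carrier counts equal the rounded recurrence target", {
  g <- simulate_genome(2, 2e7, 600, 300, 40, seed = 3)
  reg <- data.frame(chrom = "chr1", start = 5e6, end = 8e6,
                    copy_number = 4L, direction = "gain",
                    recurrence = 0.4, dosage_fold = 3)
  cfg <- sim_config(regions = reg, seed = 5)  # 13 + 7 = 20 cancer samples
  co <- simulate_cohort(g, cfg)
  carriers <- sum(vapply(co, function(x) nrow(x$segments) > 0, logical(1)))
  expect_equal(carriers, round(0.4 * 20))  # exactly 8
  # zero recurrence: nobody carries
  reg0 <- transform(reg, recurrence = 0)
  co0 <- simulate_cohort(g, sim_config(regions = reg0, seed = 5))
  expect_true(all(vapply(co0, function(x) nrow(x$segments) == 0, logical(1))))
  # determinism of carrier assignment
  co2 <- simulate_cohort(g, cfg)
  expect_identical(lapply(co, `[[`, "segments"), lapply(co2, `[[`, "segments"))
})

test_that("overlapping opposite-direction planted regions are rejected", {
  g <- simulate_genome(1, 2e7, 300, 150, 20, seed = 3)
  reg <- data.frame(chrom = "chr1", start = c(5e6, 6e6), end = c(8e6, 9e6),
                    copy_number = c(4L, 1L), direction = c("gain", "loss"),
                    recurrence = 1, dosage_fold = c(3, 1 / 3))
  expect_error(simulate_cohort(g, sim_config(regions = reg, seed = 5)),
               "opposite direction")
})

test_that("zero-noise aCGH probes sit exactly at log2(copy number / 2)", {
  g <- simulate_genome(1, 1e7, 300, 150, 20, seed = 4)
  mkreg <- function(cn, dir) data.frame(chrom = "chr1", start = 2e6, end = 5e6,
                                        copy_number = cn, direction = dir,
                                        recurrence = 1, dosage_fold = 1)
  for (case in list(list(4L, "gain", 1), list(1L, "loss", -1))) {
    cfg <- sim_config(regions = mkreg(case[[1]], case[[2]]), seed = 6,
                      acgh_sd = 0, outlier_rate = 0)
    co <- simulate_cohort(g, cfg)
    p <- simulate_acgh(co[[1]], g, cfg, scale = "log2")
    inside <- p$start >= 2e6 & p$start < 5e6
    expect_true(all(p$value[inside] == case[[3]]))
    expect_true(all(p$value[!inside] == 0))
  }
  # neutral genome: all zero
  cfg0 <- sim_config(regions = NULL, seed = 6, acgh_sd = 0, outlier_rate = 0)
  co0 <- simulate_cohort(g, cfg0)
  p0 <- simulate_acgh(co0[[1]], g, cfg0, scale = "log2")
  expect_true(all(p0$value == 0))
  # raw scale carries the same information
  praw <- simulate_acgh(co0[[1]], g, cfg0)
  expect_equal(log2(praw$value), p0$value)
})

test_that("zero-noise expression probes sit at log10 of the dosage multiplier", {
  g <- simulate_genome(1, 1e7, 300, 150, 20, seed = 4)
  for (case in list(list(3L, "gain", 2, log10(2)),
                    list(1L, "loss", 0.5, log10(0.5)))) {
    reg <- data.frame(chrom = "chr1", start = 2e6, end = 5e6,
                      copy_number = case[[1]], direction = case[[2]],
                      recurrence = 1, dosage_fold = case[[3]])
    cfg <- sim_config(regions = reg, seed = 6, expr_sd = 0, outlier_rate = 0)
    co <- simulate_cohort(g, cfg)
    p <- simulate_expression(co[[1]], g, cfg)
    dosage_genes <- names(co[[1]]$dosage)[co[[1]]$dosage != 1]
    hit <- !is.na(g$expr_probes$gene) & g$expr_probes$gene %in% dosage_genes
    expect_equal(p$value[hit], rep(case[[4]], sum(hit)), tolerance = 1e-12)
    expect_true(all(p$value[!hit] == 0))
  }
})

test_that("assay simulation round-trips at zero noise and is seed-deterministic", {
  panel <- default_assay_panel(cancer_fold = 1, dosage_fold = 1)
  cfg <- sim_config(regions = NULL, seed = 9, ct_sd = 0, bio_sd_log2 = 0,
                    bio_sd_log10 = 0, trac_cv = 0)
  a <- simulate_assays(cfg, panel)
  rel <- qpcr_relative_expression(a$ct, a$qpcr_samples)
  expect_equal(rel$rel_expr, rep(1, nrow(rel)), tolerance = 1e-12)
  # replicate wells with zero noise carry identical control-normalized signal
  tn <- trac_normalize(a$trac)
  per_well <- a$trac$target_signal / a$trac$control_signal
  expect_equal(tapply(per_well, interaction(a$trac$sample, a$trac$gene,
                                            drop = TRUE), sd)[
    tapply(per_well, interaction(a$trac$sample, a$trac$gene, drop = TRUE),
           length) > 1],
    tapply(per_well, interaction(a$trac$sample, a$trac$gene, drop = TRUE), sd)[
      tapply(per_well, interaction(a$trac$sample, a$trac$gene, drop = TRUE),
             length) > 1] * 0, tolerance = 1e-12)
  b <- simulate_assays(cfg, panel)
  expect_identical(a$ct, b$ct)
  expect_identical(a$trac, b$trac)
})

test_that("zero-noise round trip: calling recovers planted probe spans exactly and integration recovers dosage", {
  g <- simulate_genome(2, 2e7, 1000, 600, 60, seed = 12)
  reg <- data.frame(chrom = c("chr1", "chr2"), start = 5e6, end = 9e6,
                    copy_number = c(3L, 1L), direction = c("gain", "loss"),
                    recurrence = 1, dosage_fold = c(3, 1 / 3))
  cfg <- sim_config(regions = reg, seed = 13, acgh_sd = 0, expr_sd = 0,
                    outlier_rate = 0, n_expression = 20)
  co <- simulate_cohort(g, cfg)
  s <- co[[1]]
  p <- preprocess_acgh(simulate_acgh(s, g, cfg), z = FALSE)
  calls <- call_aberrations(p, noise_est(0.01), threshold = 12)
  expect_equal(nrow(calls), 2)
  for (k in 1:2) {
    probes <- g$acgh_probes[g$acgh_probes$chrom == reg$chrom[k] &
                              g$acgh_probes$start >= reg$start[k] &
                              g$acgh_probes$start < reg$end[k], ]
    row <- calls[calls$chrom == reg$chrom[k], ]
    expect_equal(row$start, min(probes$start))
    expect_equal(row$end, max(probes$end))
    expect_equal(row$n_probes, nrow(probes))
  }
  # dosage recovery to 1e-9 of the planted effect
  ex <- lapply(co[1:6], simulate_expression, genome = g, config = cfg)
  mat <- gene_median_expression(ex, g$expr_probes)
  dosage_genes <- names(s$dosage)[s$dosage != 1]
  fcalls <- apply_filters(calls)
  gm <- g$genes[g$genes$gene %in% dosage_genes, ]
  for (k in seq_len(nrow(gm))) {
    dir <- reg$direction[match(gm$chrom[k], reg$chrom)]
    st <- stratify_by_copy_number(gm[k, ], fcalls, dir, profile_sample(p))
    expect_equal(st$g1, profile_sample(p))
    fc <- 10^(mat[gm$gene[k], 1])   # vs baseline 0 (all samples are carriers)
    planted <- if (dir == "gain") 3 else 1 / 3
    expect_equal(unname(fc), planted, tolerance = 1e-9)
  }
})
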