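mk_calls <- function(samples, starts, ends, direction = "gain",
                     chrom = "chr1") {
  data.frame(sample = samples, chrom = chrom, start = starts, end = ends,
             direction = direction, n_probes = 10L,
             mean_log2 = ifelse(direction == "gain", 1, -1), score = 20,
             stringsAsFactors = FALSE)
}

cls <- function(samples, class = "tissue") stats::setNames(rep(class, length(samples)), samples)

test_that("frequency track counts carriers per breakpoint span", {
  classes <- cls(c("S1", "S2", "S3"))
  # single call
  tr1 <- build_frequency_track(mk_calls("S1", 10e6, 50e6), "gain", classes)
  expect_equal(nrow(tr1), 1)
  expect_equal(tr1$n_tissue, 1)
  # staggered intervals: counts 1,2,3,2,1
  tr <- build_frequency_track(
    mk_calls(c("S1", "S2", "S3"), c(10e6, 20e6, 30e6), c(50e6, 60e6, 70e6)),
    "gain", classes)
  expect_equal(tr$start, c(10, 20, 30, 50, 60) * 1e6)
  expect_equal(tr$n_tissue, c(1, 2, 3, 2, 1))
  # no calls: identically zero (empty) track
  tr0 <- build_frequency_track(mk_calls("S1", 1, 2)[0, ], "gain", classes)
  expect_equal(nrow(tr0), 0)
  # conservation: integral of track equals summed call lengths
  expect_equal(sum((tr$end - tr$start) * (tr$n_tissue + tr$n_cell)),
               3 * 40e6)
  # same-sample overlap is an upstream invariant violation
  expect_error(build_frequency_track(
    mk_calls(c("S1", "S1"), c(10e6, 30e6), c(50e6, 60e6)), "gain", classes),
    "overlapping")
})

test_that("recurrent regions reproduce the published frequency arithmetic", {
  # 13 tissues + 7 cell lines
  classes <- c(cls(sprintf("T%02d", 1:13)),
               cls(sprintf("CL%02d", 1:7), "cell_line"))
  region_for <- function(n_t, n_c) {
    carriers <- c(sprintf("T%02d", seq_len(n_t)),
                  sprintf("CL%02d", seq_len(n_c)))
    tr <- build_frequency_track(
      mk_calls(carriers, 143.59e6, 145.82e6), "gain", classes)
    recurrent_regions(tr, 0.25)
  }
  # 6 tissues + 3 cell lines of 20 -> 45%
  r <- region_for(6, 3)
  expect_equal(r$frequency, 45)
  expect_equal(r$n_tissue, 6); expect_equal(r$n_cell, 3)
  expect_equal(r$size_mb, 2.23)
  # 0 tissues + 5 cell lines -> 25%, still emitted
  r2 <- region_for(0, 5)
  expect_equal(r2$frequency, 25)
  # 4 of 20 (20%) -> below threshold, not emitted
  expect_equal(nrow(region_for(3, 1)), 0)
})

test_that("region sizes match the printed two-decimal Mb convention", {
  expect_equal(region_size_mb(35.02e6, 35.30e6), 0.28)
  expect_equal(region_size_mb(0.04e6, 57.98e6), 57.94)
  expect_error(region_size_mb(5e6, 5e6), "start")
})

test_that("gene annotation uses half-open >= 1 bp overlap", {
  classes <- cls(c("S1", "S2"))
  tr <- build_frequency_track(mk_calls(c("S1", "S2"), 10e6, 20e6),
                              "gain", classes)
  rr <- recurrent_regions(tr, 0.25)
  gm <- data.frame(gene = c("inside", "abut_end", "straddle_start", "outside"),
                   chrom = "chr1",
                   start = c(12e6, 20e6, 9e6, 30e6),
                   end = c(13e6, 21e6, 11e6, 31e6), stringsAsFactors = FALSE)
  out <- annotate_genes(rr, gm)
  expect_setequal(out$genes[[1]], c("inside", "straddle_start"))
})

test_that("recurrence mapping matches a per-basepair brute force", {
  set.seed(51)
  for (rep in 1:5) {
    n_samp <- sample(4:10, 1)
    samples <- sprintf("S%02d", seq_len(n_samp))
    classes <- cls(samples)
    rows <- do.call(rbind, lapply(samples, function(s) {
      k <- sample(1:4, 1)
      starts <- sort(sample(0:190, k)) * 1e6
      lens <- sample(5:40, k, replace = TRUE) * 1e6
      ends <- pmin(starts + lens, 200e6)
      # enforce per-sample disjointness
      keep <- c(TRUE, starts[-1] >= cummax(ends[-k]))
      mk_calls(s, starts[keep], ends[keep])
    }))
    tr <- build_frequency_track(rows, "gain", classes)
    rr <- recurrent_regions(tr, 0.25)
    want <- oracle_recurrent_bp(rows, "gain", n_samp, 0.25, "chr1",
                                0, 200e6, step = 1e6)
    expect_equal(nrow(rr), nrow(want))
    if (nrow(rr)) {
      expect_equal(sort(rr$start), sort(want$start))
      expect_equal(sort(rr$end), sort(want$end))
    }
    # monotonicity: a higher threshold never adds or enlarges regions
    rr2 <- recurrent_regions(tr, 0.5)
    expect_lte(nrow(rr2), nrow(rr))
    for (k in seq_len(nrow(rr2))) {
      parent <- rr[rr$start <= rr2$start[k] & rr$end >= rr2$end[k], ]
      expect_gte(nrow(parent), 1)
    }
  }
})

test_that("planted regions are recovered as single regions with tight boundaries", {
  w <- tiny_world(seed = 61, acgh_sd = 0, outlier_rate = 0)
  g <- w$genome; cfg <- w$config
  co <- simulate_cohort(g, cfg)
  calls <- do.call(rbind, lapply(co, function(s) {
    p <- preprocess_acgh(simulate_acgh(s, g, cfg), z = FALSE)
    as.data.frame(apply_filters(call_aberrations(p, noise_est(0.01))))
  }))
  classes <- stats::setNames(vapply(co, `[[`, character(1), "class"),
                             names(co))
  for (dir in c("gain", "loss")) {
    rr <- recurrent_regions(build_frequency_track(calls, dir, classes), 0.25)
    planted <- cfg$regions[cfg$regions$direction == dir, ]
    expect_equal(nrow(rr), nrow(planted))
    for (k in seq_len(nrow(planted))) {
      m <- rr[rr$chrom == planted$chrom[k], ]
      expect_equal(nrow(m), 1)
      # at zero noise the region is exactly the planted probe span
      pr <- g$acgh_probes[g$acgh_probes$chrom == planted$chrom[k] &
                            g$acgh_probes$start >= planted$start[k] &
                            g$acgh_probes$start < planted$end[k], ]
      expect_equal(m$start, min(pr$start))
      expect_equal(m$end, max(pr$end))
    }
  }
})
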