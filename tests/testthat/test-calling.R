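test_that("derivative-based noise estimate is accurate within 5%", {
  set.seed(31)
  p <- make_profile(rnorm(1e4, 0, 0.2))
  expect_lt(abs(estimate_noise(p)$sd - 0.2) / 0.2, 0.05)
  expect_lt(abs(estimate_noise(p, "sd")$sd - 0.2) / 0.2, 0.05)
  # piecewise-constant signal does not inflate the robust estimate
  sig <- rep(c(0, 1, 0, -1, 0), each = 2000)
  p2 <- make_profile(sig + rnorm(1e4, 0, 0.2))
  expect_lt(abs(estimate_noise(p2)$sd - 0.2) / 0.2, 0.05)
  expect_error(estimate_noise(make_profile(rnorm(5))), "10 probes")
  expect_error(estimate_noise(make_profile(rep(1, 100))), "positive")
})

test_that("interval score matches its closed form and symmetries", {
  p <- make_profile(rep(1, 9))
  ns <- noise_est(0.3)
  expect_equal(interval_score(p, "chr1", 0, 9000, ns), 9 / (0.3 * 3))
  expect_equal(interval_score(make_profile(rep(0, 9)), "chr1", 0, 9000, ns), 0)
  # sign flip leaves the score unchanged
  v <- rnorm(20)
  expect_equal(interval_score(make_profile(v), "chr1", 0, 2e4, ns),
               interval_score(make_profile(-v), "chr1", 0, 2e4, ns))
  # scale invariance: multiplying values and sigma by c > 0
  expect_equal(interval_score(make_profile(3 * v), "chr1", 0, 2e4, noise_est(0.9)),
               interval_score(make_profile(v), "chr1", 0, 2e4, ns))
  expect_error(interval_score(p, "chr1", 5e6, 6e6, ns), "no probe")
})

test_that("greedy peeling finds the enumeration-optimal interval first", {
  set.seed(32)
  for (rep in 1:20) {
    v <- rnorm(30) + rep(c(0, sample(c(-1, 1), 1) * runif(1, 0, 2), 0),
                         times = c(10, 10, 10))
    sigma <- 0.5
    got <- cnadose:::max_scoring_interval(v, sigma)
    want <- oracle_max_interval(v, sigma)
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
})

test_that("multi-scale search approximates the planted optimum on long profiles", {
  set.seed(33)
  v <- rnorm(12000, 0, 0.2)
  v[6001:6400] <- v[6001:6400] + 1
  got <- cnadose:::max_scoring_interval(v, 0.2)
  expect_gt(got$i, 5900); expect_lt(got$j, 6500)
  expect_gt(got$score, 0.9 * 1 * sqrt(400) / 0.2)
})

test_that("calls recover planted segments, are disjoint, and scores recompute", {
  # zero-noise single segment: exact span, direction from sign
  v <- rep(0, 200); v[76:125] <- 1
  p <- make_profile(v)
  calls <- call_aberrations(p, noise_est(0.1))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$direction, "gain")
  expect_equal(calls$start, p$start[76]); expect_equal(calls$end, p$end[125])
  down <- call_aberrations(make_profile(-v), noise_est(0.1))
  expect_equal(down$direction, "loss")
  expect_equal(down[, c("start", "end", "n_probes", "score")],
               calls[, c("start", "end", "n_probes", "score")])
  # noisy multi-segment profile: disjointness + stored score integrity
  set.seed(34)
  v2 <- rnorm(1500, 0, 0.2)
  v2[201:260] <- v2[201:260] + 1
  v2[901:1000] <- v2[901:1000] - 0.8
  p2 <- make_profile(v2)
  ns <- estimate_noise(p2)
  c2 <- call_aberrations(p2, ns)
  expect_gte(nrow(c2), 2)
  c2 <- c2[order(c2$start), ]
  if (nrow(c2) > 1) expect_true(all(c2$start[-1] >= c2$end[-nrow(c2)]))
  for (k in seq_len(nrow(c2))) {
    expect_equal(interval_score(p2, c2$chrom[k], c2$start[k], c2$end[k], ns),
                 c2$score[k], tolerance = 1e-9)
    expect_equal((c2$mean_log2[k] > 0), (c2$direction[k] == "gain"))
  }
})

test_that("planted segments are recovered with tight boundaries across seeds", {
  # a segment is detectable at threshold T only if its planted score
  # |log2| * sqrt(len) / sigma reaches T; at |log2| = 0.58, sigma = 0.2,
  # T = 12 that means len >= (12 * 0.2 / 0.58)^2 ~ 18 probes
  hits <- 0; total <- 0
  for (seed in 1:50) {
    set.seed(seed + 100)
    n <- 600
    v <- rnorm(n, 0, 0.2)
    i0 <- sample(50:400, 1); len <- sample(20:40, 1)
    sign <- sample(c(-1, 1), 1)
    v[i0:(i0 + len - 1)] <- v[i0:(i0 + len - 1)] + sign * 0.58
    p <- make_profile(v)
    calls <- apply_filters(call_aberrations(p, estimate_noise(p)))
    total <- total + 1
    ok <- FALSE
    for (k in seq_len(nrow(calls))) {
      ia <- match(calls$start[k], p$start); ib <- match(calls$end[k], p$end)
      if (abs(ia - i0) <= 2 && abs(ib - (i0 + len - 1)) <= 2) ok <- TRUE
    }
    hits <- hits + ok
  }
  expect_gte(hits / total, 0.95)
})

test_that("aberration filters drop small, weak and surplus calls", {
  base <- data.frame(sample = "S1", chrom = "chr1",
                     start = (0:1) * 1e5, end = (0:1) * 1e5 + 5e4,
                     direction = "gain", stringsAsFactors = FALSE)
  calls <- rbind(
    cbind(base[1, ], n_probes = 2L, mean_log2 = 1.0, score = 20),
    cbind(base[2, ], n_probes = 10L, mean_log2 = 0.20, score = 20))
  expect_equal(nrow(apply_filters(calls)), 0)
  # inclusive boundaries survive
  keep <- cbind(base[1, ], n_probes = 3L, mean_log2 = 0.27, score = 20)
  expect_equal(nrow(apply_filters(keep)), 1)
  # cap at max_regions keeps the highest scores per sample
  many <- data.frame(sample = "S1", chrom = "chr1",
                     start = (0:1004) * 1e5, end = (0:1004) * 1e5 + 5e4,
                     direction = "gain", n_probes = 5L, mean_log2 = 1,
                     score = 12 + (0:1004), stringsAsFactors = FALSE)
  res <- apply_filters(many)
  expect_equal(nrow(res), 1000)
  expect_equal(min(res$score), 12 + 5)
})
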