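# fixtures and independent oracles used across the suite

# build a small profile from a value vector (one probe per kb by default)
make_profile <- function(values, chrom = "chr1", spacing = 1000,
                         sample_id = "S1", platform = "acgh",
                         scale = "log2", outlier = FALSE, intensity = NULL,
                         start0 = 0) {
  n <- length(values)
  chrom <- rep_len(chrom, n)
  start <- unlist(lapply(split(seq_len(n), factor(chrom, unique(chrom))),
                         function(ii) start0 + (seq_along(ii) - 1) * spacing))
  d <- data.frame(probe = sprintf("P%04d", seq_len(n)), chrom = chrom,
                  start = start, end = start + 60,
                  value = values, outlier = rep_len(outlier, n),
                  stringsAsFactors = FALSE)
  if (!is.null(intensity)) d$intensity <- intensity
  array_profile(d, sample_id, platform, scale, sort = FALSE)
}

noise_est <- function(sd, sample_id = "S1") {
  structure(list(sample_id = sample_id, sd = sd), class = "noise_estimate")
}

# O(n^2) enumeration oracle for the maximal-scoring interval
oracle_max_interval <- function(values, sigma) {
  n <- length(values)
  best <- list(i = NA, j = NA, score = -Inf)
  for (i in seq_len(n)) for (j in i:n) {
    sc <- abs(sum(values[i:j])) / (sigma * sqrt(j - i + 1))
    if (sc > best$score + 1e-12) best <- list(i = i, j = j, score = sc)
  }
  best
}

# per-basepair brute-force recurrence oracle on a coarse integer grid
oracle_recurrent_bp <- function(calls, direction, n_total, min_fraction,
                                chrom, lo, hi, step = 1) {
  thr <- ceiling(min_fraction * n_total)
  pos <- seq(lo, hi - 1, by = step)
  cov <- vapply(pos, function(p) {
    length(unique(calls$sample[calls$direction == direction &
                                 calls$chrom == chrom &
                                 calls$start <= p & p < calls$end]))
  }, numeric(1))
  ok <- cov >= thr
  if (!any(ok)) return(data.frame(start = numeric(0), end = numeric(0)))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  keep <- r$values
  data.frame(start = pos[starts[keep]], end = pos[ends[keep]] + step)
}

# full-enumeration Mann-Whitney oracle (two-sided, no ties)
oracle_mw_exact <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  m <- na * length(b) / 2
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - na * (na + 1) / 2
  }
  u_obs <- u_of(seq_len(na))
  combs <- utils::combn(length(pooled), na)
  us <- apply(combs, 2, function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - na * (na + 1) / 2
  })
  list(U = u_obs, p = mean(abs(us - m) >= abs(u_obs - m) - 1e-9))
}

# small simulated world shared by several tests
tiny_world <- function(seed = 11, n_chrom = 4, chrom_len = 3e7,
                       n_acgh = 3000, n_expr = 1500, n_genes = 300, ...) {
  g <- simulate_genome(n_chrom, chrom_len, n_acgh, n_expr, n_genes,
                       seed = seed)
  cfg <- sim_config(regions = default_regions(g), seed = seed, ...)
  list(genome = g, config = cfg)
}
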