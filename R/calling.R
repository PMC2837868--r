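#' Estimate per-array noise from successive probe differences
#'
#' Derivative log-ratio spread: the sd of differences between adjacent
#' probes within chromosomes, divided by sqrt(2).  First differences
#' cancel the (piecewise-constant) copy-number signal except at the few
#' breakpoints, so the robust variant (`"mad"`, default) is essentially
#' unbiased for the probe-level noise sd even on aberrant genomes.
#'
#' @param profile an [array_profile()] with at least 10 probes.
#' @param method `"mad"` (median-absolute-deviation-scaled, robust) or
#'   `"sd"` (plain).
#' @return a `noise_estimate`: list with `sample_id` and `sd` (> 0).
#' @export
estimate_noise <- function(profile, method = c("mad", "sd")) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "array_profile"))
  if (nrow(profile) < 10) stop("need >= 10 probes to estimate noise")
  d <- unlist(lapply(split(profile$value, factor(profile$chrom,
                                                 levels = unique(profile$chrom))),
                     diff), use.names = FALSE)
  est <- switch(method, mad = mad(d), sd = sd(d)) / sqrt(2)
  if (!is.finite(est) || est <= 0)
    stop("noise estimate is not strictly positive (constant profile?)")
  structure(list(sample_id = profile_sample(profile), sd = est),
            class = "noise_estimate")
}

# exhaustive or multi-scale maximal-scoring interval for one chromosome's
# probe values; returns list(i, j, score) with 1-based probe indices
max_scoring_interval <- function(values, sigma, exact_limit = 5000L) {
  n <- length(values)
  if (n == 0) stop("empty probe vector")
  if (n <= exact_limit) return(.scan_exhaustive(values, sigma))
  # geometric multi-scale pass, then exact refinement around the candidate
  S <- c(0, cumsum(values))
  best <- list(i = 1L, j = 1L, score = abs(values[1]) / sigma)
  len <- 1L
  while (len <= n) {
    stride <- max(1L, len %/% 4L)
    starts <- seq.int(1L, n - len + 1L, by = stride)
    sc <- abs(S[starts + len] - S[starts]) / (sigma * sqrt(len))
    k <- which.max(sc)
    if (sc[k] > best$score)
      best <- list(i = starts[k], j = starts[k] + len - 1L, score = sc[k])
    len <- max(len + 1L, ceiling(len * 1.25))
  }
  # refine: exact scan on a window around the candidate
  w <- best$j - best$i + 1L
  lo <- max(1L, best$i - w)
  hi <- min(n, best$j + w)
  if (hi - lo + 1L <= exact_limit) {
    r <- .scan_exhaustive(values[lo:hi], sigma)
    list(i = lo + r$i - 1L, j = lo + r$j - 1L, score = r$score)
  } else {
    # window still too wide: pattern search over endpoints
    cur <- best
    step <- max(1L, w %/% 4L)
    while (step >= 1L) {
      improved <- TRUE
      while (improved) {
        improved <- FALSE
        for (di in c(-step, 0L, step)) for (dj in c(-step, 0L, step)) {
          i2 <- min(max(1L, cur$i + di), n)
          j2 <- max(min(n, cur$j + dj), i2)
          sc <- abs(S[j2 + 1L] - S[i2]) / (sigma * sqrt(j2 - i2 + 1L))
          if (sc > cur$score) {
            cur <- list(i = i2, j = j2, score = sc)
            improved <- TRUE
          }
        }
      }
      if (step == 1L) break
      step <- max(1L, step %/% 2L)
    }
    cur
  }
}

#' Interval score of a genomic interval
#'
#' The ADM-style interval statistic `|sum(r_i)| / (sigma * sqrt(k))` over
#' the `k` probes falling in `[start, end)`: the absolute probe sum in
#' noise-sd units.  It is symmetric in sign and invariant to rescaling
#' values and sigma by a common factor.
#'
#' @param profile an [array_profile()].
#' @param chrom,start,end the interval (0-based half-open; probes are
#'   assigned by their start coordinate).
#' @param noise a [estimate_noise()] result (or a list with an `sd`).
#' @return the nonnegative score.  An interval containing no probe is an
#'   error.
#' @export
interval_score <- function(profile, chrom, start, end, noise) {
  idx <- profile$chrom == chrom & profile$start >= start & profile$start < end
  if (!any(idx)) stop("interval contains no probe")
  r <- profile$value[idx]
  abs(sum(r)) / (noise$sd * sqrt(length(r)))
}

new_calls <- function(df) {
  if (is.null(df) || !nrow(df)) {
    df <- data.frame(sample = character(0), chrom = character(0),
                     start = numeric(0), end = numeric(0),
                     direction = character(0), n_probes = integer(0),
                     mean_log2 = numeric(0), score = numeric(0),
                     stringsAsFactors = FALSE)
  }
  ord <- order(df$sample, df$chrom, df$start)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("cna_calls", "data.frame"))
}

#' @export
print.cna_calls <- function(x, ...) {
  cat(sprintf("Copy-number aberration calls: %d interval(s), %d sample(s) (%d gain / %d loss)\n",
              nrow(x), length(unique(x$sample)),
              sum(x$direction == "gain"), sum(x$direction == "loss")))
  print(head(as.data.frame(x), 8L))
  if (nrow(x) > 8L) cat("...\n")
  invisible(x)
}

#' Call copy-number aberrations in one profile
#'
#' Greedy maximal-interval peeling with the interval score: per
#' chromosome, the highest-scoring interval is found; if it reaches the
#' threshold it is emitted, its probes are masked, and the search recurses
#' into the flanks, until no interval reaches the threshold.  Direction is
#' the sign of the interval mean.  Emitted calls are pairwise disjoint.
#'
#' The exhaustive O(n^2) scan is used on chromosomes up to 5000 probes; a
#' geometric multi-scale approximation with exact local refinement is
#' used above that.
#'
#' @param profile a normalized (and, if applicable, calibrated)
#'   [array_profile()].
#' @param noise a [estimate_noise()] result for the same array.
#' @param threshold minimum interval score for an emitted call
#'   (default 12.0).
#' @return a `cna_calls` data.frame: sample, chrom, start, end (half-open
#'   bp), direction, n_probes, mean_log2, score.
#' @export
call_aberrations <- function(profile, noise, threshold = 12.0) {
  stopifnot(inherits(profile, "array_profile"), threshold > 0)
  sigma <- noise$sd
  res <- list()
  for (cc in unique(profile$chrom)) {
    sub <- profile[profile$chrom == cc, , drop = FALSE]
    v <- sub$value
    # iterative peeling over active index ranges
    stack <- list(c(1L, length(v)))
    while (length(stack)) {
      rng <- stack[[1]]; stack <- stack[-1]
      if (rng[2] < rng[1]) next
      m <- max_scoring_interval(v[rng[1]:rng[2]], sigma)
      if (m$score >= threshold) {
        i <- rng[1] + m$i - 1L
        j <- rng[1] + m$j - 1L
        mu <- mean(v[i:j])
        res[[length(res) + 1L]] <- data.frame(
          sample = profile_sample(profile), chrom = cc,
          start = sub$start[i], end = sub$end[j],
          direction = if (mu > 0) "gain" else "loss",
          n_probes = j - i + 1L, mean_log2 = mu, score = m$score,
          stringsAsFactors = FALSE)
        stack <- c(stack, list(c(rng[1], i - 1L)), list(c(j + 1L, rng[2])))
      }
    }
  }
  new_calls(if (length(res)) do.call(rbind, res) else NULL)
}

#' Apply the aberration filters
#'
#' Per sample: drop calls with fewer than `min_probes` probes or with
#' `|mean log2 ratio| < min_abs_log2` (0.27 corresponds to a 1.2-fold
#' copy-number change); if more than `max_regions` calls survive, keep the
#' `max_regions` highest-scoring.
#'
#' @param calls a `cna_calls` data.frame.
#' @param min_probes minimum probes per region (default 3).
#' @param min_abs_log2 minimum absolute mean log2 ratio (default 0.27).
#' @param max_regions maximum aberrant regions per sample (default 1000).
#' @return the filtered `cna_calls`.
#' @export
apply_filters <- function(calls, min_probes = 3L, min_abs_log2 = 0.27,
                          max_regions = 1000L) {
  stopifnot(all(c("n_probes", "mean_log2", "score", "sample") %in% names(calls)))
  keep <- calls$n_probes >= min_probes & abs(calls$mean_log2) >= min_abs_log2
  out <- as.data.frame(calls)[keep, , drop = FALSE]
  if (nrow(out)) {
    kept <- unlist(lapply(split(seq_len(nrow(out)), out$sample), function(ii) {
      if (length(ii) <= max_regions) return(ii)
      ii[order(out$score[ii], decreasing = TRUE)[seq_len(max_regions)]]
    }), use.names = FALSE)
    out <- out[sort(kept), , drop = FALSE]
  }
  new_calls(out)
}
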