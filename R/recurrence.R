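#' Build a carrier-frequency track from per-sample calls
#'
#' Sweep-line aggregation: for one direction, at every genomic position
#' the track records how many distinct tissue samples and how many cell
#' lines carry a call covering that position.  The track is a step
#' function with breaks only at call start/end positions; spans with zero
#' carriers are omitted.
#'
#' @param calls a `cna_calls` data.frame pooled over samples (each
#'   sample's calls must be disjoint).
#' @param direction `"gain"` or `"loss"`.
#' @param sample_classes named character vector mapping sample id to
#'   `"tissue"` or `"cell_line"`; its names define the cohort, and its
#'   length the total sample count.
#' @return a `frequency_track` data.frame: chrom, start, end, n_tissue,
#'   n_cell; attributes `direction`, `n_tissue_total`, `n_cell_total`.
#' @export
build_frequency_track <- function(calls, direction = c("gain", "loss"),
                                  sample_classes) {
  direction <- match.arg(direction)
  stopifnot(all(sample_classes %in% c("tissue", "cell_line")),
            !is.null(names(sample_classes)))
  d <- as.data.frame(calls)[calls$direction == direction, , drop = FALSE]
  # same-sample overlap violates the caller's disjointness invariant
  if (nrow(d)) {
    for (key in unique(paste(d$sample, d$chrom))) {
      sub <- d[paste(d$sample, d$chrom) == key, , drop = FALSE]
      if (nrow(sub) > 1) {
        sub <- sub[order(sub$start), ]
        if (any(sub$start[-1] < sub$end[-nrow(sub)]))
          stop("overlapping calls within sample ", sub$sample[1],
               " on ", sub$chrom[1])
      }
    }
  }
  totals <- table(factor(sample_classes, levels = c("tissue", "cell_line")))
  spans <- list()
  for (cc in unique(d$chrom)) {
    sub <- d[d$chrom == cc, , drop = FALSE]
    bp <- sort(unique(c(sub$start, sub$end)))
    if (length(bp) < 2) next
    s0 <- bp[-length(bp)]; e0 <- bp[-1]
    cls <- sample_classes[sub$sample]
    nt <- nc <- integer(length(s0))
    for (k in seq_len(nrow(sub))) {
      cov <- s0 >= sub$start[k] & e0 <= sub$end[k]
      if (cls[k] == "tissue") nt[cov] <- nt[cov] + 1L else nc[cov] <- nc[cov] + 1L
    }
    keep <- (nt + nc) > 0
    if (any(keep))
      spans[[cc]] <- data.frame(chrom = cc, start = s0[keep], end = e0[keep],
                                n_tissue = nt[keep], n_cell = nc[keep],
                                stringsAsFactors = FALSE)
  }
  out <- if (length(spans)) do.call(rbind, spans) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               n_tissue = integer(0), n_cell = integer(0))
  rownames(out) <- NULL
  structure(out, direction = direction,
            n_tissue_total = as.integer(totals["tissue"]),
            n_cell_total = as.integer(totals["cell_line"]),
            class = c("frequency_track", "data.frame"))
}

#' Interval size in megabases
#'
#' @param start,end interval boundaries in bp, half-open, `start < end`.
#' @return `(end - start) / 1e6` rounded to two decimals (half away from
#'   zero).
#' @export
region_size_mb <- function(start, end) {
  if (any(start >= end)) stop("start must be < end")
  round_half_up((end - start) / 1e6, 2)
}

#' Detect recurrent regions in a frequency track
#'
#' A region is recurrent when it is carried by at least
#' `ceil(min_fraction * n samples)` samples.  The minimal common regions
#' are reported as the maximal contiguous runs meeting that threshold;
#' for each run the tissue and cell-line carrier counts are the maximum
#' simultaneous counts attained within the run, the frequency is
#' `round(100 * (tissue + cell-line carriers) / total)` to the nearest
#' whole percent, and the size is in Mb to two decimals.  The peak
#' sub-interval of maximal total carrier count is also reported.
#'
#' @param track a [build_frequency_track()] result.
#' @param min_fraction recurrence threshold as a fraction of the cohort
#'   (default 0.25).
#' @return a `recurrent_regions` data.frame: direction, chrom, start,
#'   end, n_tissue, n_cell, frequency (percent), size_mb, peak_start,
#'   peak_end, genes (empty until [annotate_genes()]).
#' @export
recurrent_regions <- function(track, min_fraction = 0.25) {
  n_total <- attr(track, "n_tissue_total") + attr(track, "n_cell_total")
  if (is.na(n_total) || n_total <= 0) stop("total sample count must be > 0")
  thr <- ceiling(min_fraction * n_total)
  res <- list()
  for (cc in unique(track$chrom)) {
    sub <- as.data.frame(track)[track$chrom == cc, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    tot <- sub$n_tissue + sub$n_cell
    ok <- tot >= thr
    if (!any(ok)) next
    # maximal contiguous runs: adjacent qualifying spans that abut
    sub <- sub[ok, , drop = FALSE]; tot <- tot[ok]
    run_id <- cumsum(c(1L, as.integer(sub$start[-1] != sub$end[-nrow(sub)])))
    for (g in unique(run_id)) {
      rr <- sub[run_id == g, , drop = FALSE]
      rt <- tot[run_id == g]
      pk <- which(rt == max(rt))
      # first maximal-count stretch of abutting spans
      pk1 <- pk[1]; pk2 <- pk1
      while (pk2 < nrow(rr) && (pk2 + 1L) %in% pk &&
             rr$start[pk2 + 1L] == rr$end[pk2]) pk2 <- pk2 + 1L
      nt <- max(rr$n_tissue); nc <- max(rr$n_cell)
      res[[length(res) + 1L]] <- data.frame(
        direction = attr(track, "direction"), chrom = cc,
        start = rr$start[1], end = rr$end[nrow(rr)],
        n_tissue = nt, n_cell = nc,
        frequency = round_half_up(100 * (nt + nc) / n_total),
        size_mb = region_size_mb(rr$start[1], rr$end[nrow(rr)]),
        peak_start = rr$start[pk1], peak_end = rr$end[pk2],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(direction = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0), n_tissue = integer(0),
               n_cell = integer(0), frequency = numeric(0),
               size_mb = numeric(0), peak_start = numeric(0),
               peak_end = numeric(0), stringsAsFactors = FALSE)
  out$genes <- I(rep(list(character(0)), nrow(out)))
  rownames(out) <- NULL
  structure(out, min_fraction = min_fraction, n_total = n_total,
            class = c("recurrent_regions", "data.frame"))
}

#' Annotate recurrent regions with member genes
#'
#' A gene is a member when its interval overlaps the region by at least
#' 1 bp (half-open coordinates: a gene abutting the region end is not a
#' member).
#'
#' @param regions a `recurrent_regions` data.frame.
#' @param gene_map data.frame with columns gene, chrom, start, end.
#' @return the regions with the `genes` list-column filled.
#' @export
annotate_genes <- function(regions, gene_map) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(gene_map)))
  genes <- lapply(seq_len(nrow(regions)), function(k) {
    hit <- gene_map$chrom == regions$chrom[k] &
      gene_map$start < regions$end[k] & regions$start[k] < gene_map$end
    gene_map$gene[hit]
  })
  regions$genes <- I(genes)
  regions
}

#' @export
print.recurrent_regions <- function(x, ...) {
  cat(sprintf("Recurrent copy-number regions (>= %d%% of %d samples): %d region(s)\n",
              round(100 * attr(x, "min_fraction")), attr(x, "n_total"), nrow(x)))
  if (nrow(x)) {
    show <- as.data.frame(x)[, c("direction", "chrom", "start", "end",
                                 "n_tissue", "n_cell", "frequency", "size_mb")]
    show$genes <- vapply(x$genes, function(g)
      paste(head(g, 4L), collapse = ","), character(1))
    print(show)
  }
  invisible(x)
}

#' @export
plot.frequency_track <- function(x, ...) {
  if (!nrow(x)) { graphics::plot.new(); return(invisible(x)) }
  chroms <- unique(x$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(cc) max(x$end[x$chrom == cc]),
                             numeric(1))))
  names(offs) <- c(chroms, "_end")
  tot <- x$n_tissue + x$n_cell
  graphics::plot(NA, xlim = c(0, max(offs)), ylim = c(0, max(tot)),
                 xlab = "genome position (bp, concatenated)",
                 ylab = "carrier count", ...)
  graphics::segments(x$start + offs[x$chrom], tot, x$end + offs[x$chrom], tot)
  graphics::abline(v = offs[-1], col = "grey80", lty = 3)
  invisible(x)
}
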