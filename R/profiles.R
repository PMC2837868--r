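#' Probe-level array profile
#'
#' One sample's ordered probe-level measurements: an array-CGH profile
#' (tumour/reference ratios, later log2) or a gene-expression profile
#' (log10 sample/reference ratios).  The object is a `data.frame` with
#' columns `probe`, `chrom`, `start`, `end`, `value`, `outlier` (and
#' optionally `intensity`, the mean log-intensity covariate used by loess
#' normalization), plus attributes `sample_id`, `platform` and `scale`.
#'
#' Coordinates are 0-based half-open.  Records are kept sorted by
#' `(chrom, start)`; probe ids must be unique.  The `scale` marker tracks
#' the value scale through the pipeline: `"raw"` (linear ratio), `"log2"`,
#' `"log10"` or `"normalized"`.
#'
#' @param records data.frame with the columns listed above.
#' @param sample_id sample identifier.
#' @param platform `"acgh"` or `"expression"`.
#' @param scale one of `"raw"`, `"log2"`, `"log10"`, `"normalized"`.
#' @param sort sort records by `(chrom, start)` if they are not already.
#' @return An `array_profile` object.
#' @export
array_profile <- function(records, sample_id, platform = c("acgh", "expression"),
                          scale = c("raw", "log2", "log10", "normalized"),
                          sort = TRUE) {
  platform <- match.arg(platform)
  scale <- match.arg(scale)
  need <- c("probe", "chrom", "start", "end", "value", "outlier")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("profile records lack columns: ", paste(miss, collapse = ", "))
  records$probe <- as.character(records$probe)
  records$chrom <- as.character(records$chrom)
  if (anyDuplicated(records$probe))
    stop("duplicate probe ids in profile '", sample_id, "'")
  if (any(records$start >= records$end))
    stop("probe with start >= end in profile '", sample_id, "'")
  if (sort) {
    ord <- order(records$chrom, records$start)
    records <- records[ord, , drop = FALSE]
  }
  rownames(records) <- NULL
  structure(records,
            sample_id = as.character(sample_id),
            platform = platform, scale = scale,
            class = c("array_profile", "data.frame"))
}

profile_scale <- function(x) attr(x, "scale")
profile_sample <- function(x) attr(x, "sample_id")
profile_platform <- function(x) attr(x, "platform")

# rebuild with same metadata after a row/value modification
reprofile <- function(x, records, scale = profile_scale(x), sort = FALSE) {
  array_profile(records, sample_id = profile_sample(x),
                platform = profile_platform(x), scale = scale, sort = sort)
}

#' @export
print.array_profile <- function(x, ...) {
  cat(sprintf("Array profile '%s' (%s, %s scale): %d probes on %d chromosome(s)\n",
              profile_sample(x), profile_platform(x), profile_scale(x),
              nrow(x), length(unique(x$chrom))))
  print(head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat("...\n")
  invisible(x)
}

#' Plot a profile's values along the genome
#'
#' @param x an [array_profile()].
#' @param calls optional `cna_calls` for the same sample; called intervals
#'   are shaded.
#' @param ... passed to [graphics::plot()].
#' @export
plot.array_profile <- function(x, calls = NULL, ...) {
  chroms <- unique(x$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(cc) max(x$end[x$chrom == cc]),
                             numeric(1))))
  names(offs) <- c(chroms, "_end")
  gx <- x$start + offs[x$chrom]
  graphics::plot(gx, x$value, pch = ".", cex = 2,
                 xlab = "genome position (bp, concatenated)",
                 ylab = sprintf("value (%s)", profile_scale(x)), ...)
  graphics::abline(v = offs[-1], col = "grey80", lty = 3)
  graphics::abline(h = 0, col = "grey60")
  if (!is.null(calls) && nrow(calls)) {
    for (k in seq_len(nrow(calls))) {
      x0 <- calls$start[k] + offs[calls$chrom[k]]
      x1 <- calls$end[k] + offs[calls$chrom[k]]
      col <- if (calls$direction[k] == "gain") "#d6604d55" else "#4393c355"
      graphics::rect(x0, graphics::par("usr")[3], x1, graphics::par("usr")[4],
                     col = col, border = NA)
    }
  }
  invisible(x)
}
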