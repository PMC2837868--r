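# Tab-separated readers/writers for the pipeline's table dialects.
# All files carry '#key=value' header lines so every artifact records the
# metadata (and, where relevant, parameters/seed) that produced it.

write_header <- function(con, meta) {
  for (nm in names(meta))
    writeLines(sprintf("#%s=%s", nm, as.character(meta[[nm]])), con)
}

read_header <- function(path) {
  lines <- readLines(path, n = 50L)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(x) paste(x[-1], collapse = "=")),
                  vapply(kv, `[[`, character(1), 1))
}

read_body <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read a probe-level profile table
#'
#' Tab-separated text with columns probe, chrom, start, end, value,
#' outlier (and intensity when present); sample id, platform and scale
#' marker are recorded in `#key=value` header lines.
#'
#' @param profile an [array_profile()].
#' @param path file path.
#' @return `write_profile()` returns the path invisibly; `read_profile()`
#'   returns the [array_profile()].
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w"); on.exit(close(con))
  write_header(con, list(sample = profile_sample(profile),
                         platform = profile_platform(profile),
                         scale = profile_scale(profile)))
  write.table(as.data.frame(profile), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @param strict reject (rather than sort with a warning) out-of-order
#'   probe tables.
#' @export
read_profile <- function(path, strict = FALSE) {
  hdr <- read_header(path)
  need <- c("sample", "platform", "scale")
  if (!all(need %in% names(hdr)))
    stop("profile file lacks header line(s): ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  d <- read_body(path)
  bad <- which(d$start >= d$end)
  if (length(bad))
    stop("start >= end at data line ", bad[1], " of ", path)
  ord <- order(d$chrom, d$start)
  if (!identical(ord, seq_len(nrow(d)))) {
    if (strict) stop("probe table not sorted by (chrom, start): ", path)
    warning("sorting out-of-order probe table: ", path)
  }
  array_profile(d, hdr$sample, hdr$platform, hdr$scale, sort = TRUE)
}

#' Write / read aberration calls
#'
#' BED-like tab-separated text (0-based half-open): chrom, start, end,
#' direction, score, n_probes, mean_log2, sample.
#'
#' @param calls a `cna_calls` data.frame.
#' @param path file path.
#' @param meta optional named list written as header lines.
#' @export
write_calls <- function(calls, path, meta = list()) {
  con <- file(path, "w"); on.exit(close(con))
  write_header(con, meta)
  cols <- c("chrom", "start", "end", "direction", "score", "n_probes",
            "mean_log2", "sample")
  write.table(as.data.frame(calls)[, cols], con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  d <- read_body(path)
  bad <- which(d$start >= d$end)
  if (length(bad)) stop("start >= end at data line ", bad[1], " of ", path)
  if (!all(d$direction %in% c("gain", "loss")))
    stop("unknown direction value in ", path)
  new_calls(d)
}

#' Write / read recurrent regions
#'
#' Tab-separated table mirroring the minimal-common-region report:
#' direction, chrom, start, end, n_tissue, n_cell, frequency, size_mb,
#' peak_start, peak_end, genes (comma-separated).
#'
#' @param regions a `recurrent_regions` data.frame.
#' @param path file path.
#' @param meta optional named list written as header lines.
#' @export
write_regions <- function(regions, path, meta = list()) {
  con <- file(path, "w"); on.exit(close(con))
  write_header(con, c(meta, list(
    min_fraction = attr(regions, "min_fraction"),
    n_total = attr(regions, "n_total"))))
  d <- as.data.frame(regions)
  d$genes <- vapply(regions$genes, paste, character(1), collapse = ",")
  write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_regions
#' @export
read_regions <- function(path) {
  hdr <- read_header(path)
  d <- read_body(path)
  bad <- which(d$start >= d$end)
  if (length(bad)) stop("start >= end at data line ", bad[1], " of ", path)
  genes <- strsplit(ifelse(is.na(d$genes), "", d$genes), ",", fixed = TRUE)
  d$genes <- I(lapply(genes, function(g) g[nzchar(g)]))
  structure(d,
            min_fraction = as.numeric(hdr$min_fraction),
            n_total = as.integer(hdr$n_total),
            class = c("recurrent_regions", "data.frame"))
}

#' Write intervals as BED
#'
#' 0-based half-open BED3+1: chrom, start, end, name.
#'
#' @param df data.frame with chrom, start, end columns.
#' @param path file path.
#' @param name_col column used as the BED name field.
#' @export
write_bed <- function(df, path, name_col = "direction") {
  nm <- if (name_col %in% names(df)) df[[name_col]] else "."
  write.table(data.frame(df$chrom, format(df$start, scientific = FALSE,
                                          trim = TRUE),
                         format(df$end, scientific = FALSE, trim = TRUE), nm),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write / read assay tables
#'
#' Long tab-separated tables: one row per Ct replicate (sample, gene,
#' replicate, ct_target, ct_control) or per TRAC well (sample, gene,
#' replicate, target_signal, control_signal).
#'
#' @param tab the table.
#' @param path file path.
#' @param meta optional named list written as header lines.
#' @export
write_assay_table <- function(tab, path, meta = list()) {
  con <- file(path, "w"); on.exit(close(con))
  write_header(con, meta)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assay_table
#' @param kind `"ct"` or `"trac"` (validates the expected columns).
#' @export
read_assay_table <- function(path, kind = c("ct", "trac")) {
  kind <- match.arg(kind)
  d <- read_body(path)
  need <- switch(kind,
                 ct = c("sample", "gene", "replicate", "ct_target", "ct_control"),
                 trac = c("sample", "gene", "replicate", "target_signal",
                          "control_signal"))
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(kind, " table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (kind == "ct") {
    bad <- which(!(d$ct_target > 0 & d$ct_target < 45 &
                     d$ct_control > 0 & d$ct_control < 45))
    if (length(bad)) stop("Ct out of (0, 45) at data line ", bad[1])
  }
  d
}

#' Write a generic results table
#'
#' @param tab data.frame (e.g. comparisons, candidates, assay results).
#' @param path file path.
#' @param meta optional named list written as header lines.
#' @export
write_results <- function(tab, path, meta = list()) {
  con <- file(path, "w"); on.exit(close(con))
  write_header(con, meta)
  d <- as.data.frame(tab)
  for (nm in names(d)) if (is.list(d[[nm]]))
    d[[nm]] <- vapply(d[[nm]], paste, character(1), collapse = ",")
  write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
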