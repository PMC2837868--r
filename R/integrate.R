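#' Per-gene median expression across samples
#'
#' Collapses probe-level log10 expression ratios to one value per (gene,
#' sample): the median over the gene's probes (midpoint convention for
#' even counts).  Genes with no surviving probe in any sample are absent
#' from the output, not zero.
#'
#' @param profiles list of expression [array_profile()]s (after quality
#'   filtering / normalization).
#' @param probe_gene_map data.frame with columns `probe`, `gene`
#'   (e.g. `genome$expr_probes`); probes mapping to no gene are ignored.
#' @return numeric matrix, genes x samples, `NA` where a gene has no
#'   retained probe in a sample.
#' @export
gene_median_expression <- function(profiles, probe_gene_map) {
  if (inherits(profiles, "array_profile")) profiles <- list(profiles)
  map <- probe_gene_map[!is.na(probe_gene_map$gene),
                        c("probe", "gene"), drop = FALSE]
  genes <- unique(map$gene)
  out <- matrix(NA_real_, nrow = length(genes), ncol = length(profiles),
                dimnames = list(genes,
                                vapply(profiles, profile_sample, character(1))))
  for (s in seq_along(profiles)) {
    p <- profiles[[s]]
    g <- map$gene[match(p$probe, map$probe)]
    keep <- !is.na(g)
    med <- tapply(p$value[keep], factor(g[keep], levels = genes), median)
    out[, s] <- as.numeric(med)
  }
  out[rowSums(!is.na(out)) > 0, , drop = FALSE]
}

#' Stratify cancer samples by copy-number status at a gene
#'
#' `g1`: cancer samples with a filtered call of the stated direction
#' overlapping the gene's interval.  `g0`: cancer samples with no call of
#' either direction over the gene.  Samples carrying only the
#' opposite-direction alteration belong to neither group.
#'
#' @param gene one-row data.frame (or list) with chrom, start, end.
#' @param calls filtered `cna_calls` over the cohort.
#' @param direction `"gain"` or `"loss"`.
#' @param samples character vector of cancer sample ids to stratify.
#' @return list with character vectors `g1` and `g0`.
#' @export
stratify_by_copy_number <- function(gene, calls, direction = c("gain", "loss"),
                                    samples) {
  direction <- match.arg(direction)
  ov <- calls$chrom == gene$chrom & calls$start < gene$end &
    gene$start < calls$end
  hit_dir <- unique(calls$sample[ov & calls$direction == direction])
  hit_any <- unique(calls$sample[ov])
  g1 <- intersect(samples, hit_dir)
  g0 <- setdiff(samples, hit_any)
  list(g1 = g1, g0 = g0)
}

#' Signed fold change between two groups
#'
#' Summarizes each group (median by default; mean for assay data), forms
#' the ratio of linear-scale summaries, and reports it signed: `m1/m0`
#' when the numerator summary is the larger, `-(m0/m1)` otherwise, so
#' `|FC| >= 1` and under-expression is negative.  When `log_base` is
#' given the inputs are log-scale values, the summaries are taken on the
#' log scale and exponentiated (so for medians the result is invariant to
#' the monotone log transform); otherwise inputs are linear and their
#' summaries must be strictly positive.
#'
#' @param x1,x0 numerator and denominator group values (nonempty).
#' @param summary `"median"` or `"mean"`.
#' @param log_base base of the log scale the values are on, or `NULL`
#'   for linear-scale values.
#' @return the signed fold change.
#' @export
signed_fold_change <- function(x1, x0, summary = c("median", "mean"),
                               log_base = NULL) {
  summary <- match.arg(summary)
  if (!length(x1) || !length(x0)) stop("empty group in fold-change computation")
  f <- switch(summary, median = median, mean = mean)
  if (is.null(log_base)) {
    m1 <- f(x1); m0 <- f(x0)
    if (!is.finite(m1) || !is.finite(m0) || m1 <= 0 || m0 <= 0)
      stop("non-positive linear group summary")
    r <- m1 / m0
  } else {
    r <- log_base^(f(x1) - f(x0))
  }
  if (r >= 1) r else -1 / r
}

#' Copy-number-associated expression comparisons
#'
#' For every gene (optionally restricted to those inside recurrent
#' regions) and each direction, stratifies the cancer samples into g1/g0
#' by the calls, computes the signed fold change of the g1 vs g0 median
#' log10 expression, and, when nonmalignant samples are present, the
#' cancer-vs-nonmalignant fold change.  Genes whose g1 or g0 set is empty
#' among the expression-profiled samples are skipped for that direction.
#'
#' @param expr gene x sample matrix from [gene_median_expression()].
#' @param gene_map data.frame gene, chrom, start, end.
#' @param calls filtered `cna_calls`.
#' @param cancer_samples,nonmalignant_samples sample ids (columns of
#'   `expr`).
#' @param regions optional `recurrent_regions`; when given, only genes
#'   overlapping a region of the matching direction are analyzed.
#' @param min_fc significance cut on `|FC g1 vs g0|` (default 2).
#' @param summary group summary passed to [signed_fold_change()].
#' @return a `gene_comparisons` data.frame: gene, chrom, start, end,
#'   direction, n_g1, n_g0, fc_g1_g0, fc_cancer_normal, significant.
#' @export
copy_number_comparisons <- function(expr, gene_map, calls, cancer_samples,
                                    nonmalignant_samples = character(0),
                                    regions = NULL, min_fc = 2,
                                    summary = "median") {
  cancer_samples <- intersect(cancer_samples, colnames(expr))
  nonmalignant_samples <- intersect(nonmalignant_samples, colnames(expr))
  res <- list()
  for (direction in c("gain", "loss")) {
    gm <- gene_map[gene_map$gene %in% rownames(expr), , drop = FALSE]
    if (!is.null(regions)) {
      rr <- regions[regions$direction == direction, , drop = FALSE]
      if (!nrow(rr)) next
      inreg <- vapply(seq_len(nrow(gm)), function(k) {
        any(rr$chrom == gm$chrom[k] & rr$start < gm$end[k] &
              gm$start[k] < rr$end)
      }, logical(1))
      gm <- gm[inreg, , drop = FALSE]
    }
    for (k in seq_len(nrow(gm))) {
      st <- stratify_by_copy_number(gm[k, ], calls, direction, cancer_samples)
      v1 <- expr[gm$gene[k], st$g1]; v1 <- v1[!is.na(v1)]
      v0 <- expr[gm$gene[k], st$g0]; v0 <- v0[!is.na(v0)]
      if (!length(v1) || !length(v0)) next
      fc <- signed_fold_change(v1, v0, summary = summary, log_base = 10)
      fc_cn <- NA_real_
      if (length(nonmalignant_samples)) {
        vc <- expr[gm$gene[k], cancer_samples]
        vn <- expr[gm$gene[k], nonmalignant_samples]
        fc_cn <- signed_fold_change(vc[!is.na(vc)], vn[!is.na(vn)],
                                    summary = summary, log_base = 10)
      }
      res[[length(res) + 1L]] <- data.frame(
        gene = gm$gene[k], chrom = gm$chrom[k],
        start = gm$start[k], end = gm$end[k], direction = direction,
        n_g1 = length(v1), n_g0 = length(v0),
        fc_g1_g0 = fc, fc_cancer_normal = fc_cn,
        significant = abs(fc) >= min_fc, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(gene = character(0), chrom = character(0), start = numeric(0),
               end = numeric(0), direction = character(0), n_g1 = integer(0),
               n_g0 = integer(0), fc_g1_g0 = numeric(0),
               fc_cancer_normal = numeric(0), significant = logical(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("gene_comparisons", "data.frame"))
}

#' Select dosage-candidate genes
#'
#' Keeps comparisons with `|FC g1 vs g0| >= min_fc` (inclusive: a 2.0-fold
#' change passes the default 2-fold cut) and partitions them into
#' overexpressed-in-gain and underexpressed-in-loss lists.  Summary
#' statistics (count, |FC| range and median) are attached as the
#' `summary` attribute.
#'
#' @param comparisons a `gene_comparisons` data.frame.
#' @param min_fc fold-change cut (default 2).
#' @return a `candidate_genes` data.frame (subset of the comparisons with
#'   a `list` column removed), gains first.
#' @export
select_candidates <- function(comparisons, min_fc = 2) {
  gained <- comparisons[comparisons$direction == "gain" &
                          comparisons$fc_g1_g0 >= min_fc, , drop = FALSE]
  lost <- comparisons[comparisons$direction == "loss" &
                        comparisons$fc_g1_g0 <= -min_fc, , drop = FALSE]
  out <- rbind(gained, lost)
  rownames(out) <- NULL
  afc <- abs(out$fc_g1_g0)
  structure(out,
            summary = list(n = nrow(out), n_gain = nrow(gained),
                           n_loss = nrow(lost),
                           fc_range = if (nrow(out)) range(afc) else c(NA, NA),
                           fc_median = if (nrow(out)) median(afc) else NA),
            class = c("candidate_genes", "data.frame"))
}

#' @export
print.candidate_genes <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("Candidate genes: %d (%d gained/overexpressed, %d lost/underexpressed)\n",
              s$n, s$n_gain, s$n_loss))
  if (s$n)
    cat(sprintf("|FC| range %.1f - %.1f, median %.1f\n",
                s$fc_range[1], s$fc_range[2], s$fc_median))
  print(head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}
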