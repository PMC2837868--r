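#' Relative expression by the delta-delta-Ct method
#'
#' `dCt = mean(target replicate Cts) - mean(control replicate Cts)`;
#' `ddCt = dCt - calibrator dCt`; relative expression `2^-ddCt`.  The
#' endogenous control (here an 18S-like rRNA assay) cancels loading
#' differences; the calibrator anchors the scale (conventionally the
#' nonmalignant group mean, see [qpcr_relative_expression()]).
#'
#' @param target_ct,control_ct numeric triplicate Ct values (no missing
#'   values).
#' @param calibrator_delta_ct the calibrator sample's (or group's) dCt.
#' @return relative expression, `2^-ddCt` (> 0).
#' @export
delta_delta_ct <- function(target_ct, control_ct, calibrator_delta_ct) {
  if (anyNA(target_ct) || anyNA(control_ct))
    stop("missing Ct replicate")
  if (!length(target_ct) || !length(control_ct))
    stop("missing Ct replicate")
  if (!is.finite(calibrator_delta_ct)) stop("calibrator dCt must be finite")
  dct <- mean(target_ct) - mean(control_ct)
  2^(-(dct - calibrator_delta_ct))
}

#' Per-sample relative expression for a triplicate Ct table
#'
#' Computes each (sample, gene) dCt from the triplicate means and
#' converts to `2^-ddCt` relative expression.  The calibrator dCt per
#' gene is the mean dCt of the nonmalignant samples (default), making
#' the values interpretable as fold change relative to normal tissue;
#' pass a named numeric vector to use custom calibrator dCts.
#'
#' @param ct long Ct table: sample, gene, replicate, ct_target,
#'   ct_control.
#' @param samples sample metadata with `sample` and `disease` columns.
#' @param calibrator `"nonmalignant"` or a named numeric vector of dCt
#'   per gene.
#' @return data.frame sample, gene, delta_ct, rel_expr.
#' @export
qpcr_relative_expression <- function(ct, samples, calibrator = "nonmalignant") {
  key <- interaction(ct$sample, ct$gene, drop = TRUE)
  dct <- tapply(ct$ct_target, key, mean) - tapply(ct$ct_control, key, mean)
  ids <- do.call(rbind, strsplit(names(dct), ".", fixed = TRUE))
  out <- data.frame(sample = ids[, 1], gene = ids[, 2],
                    delta_ct = as.numeric(dct), stringsAsFactors = FALSE)
  if (identical(calibrator, "nonmalignant")) {
    normal <- samples$sample[samples$disease == "nonmalignant"]
    cal <- tapply(out$delta_ct[out$sample %in% normal],
                  out$gene[out$sample %in% normal], mean)
  } else cal <- calibrator
  out$rel_expr <- 2^(-(out$delta_ct - as.numeric(cal[out$gene])))
  rownames(out) <- NULL
  out
}

#' Normalize TRAC signals to the hybridization control
#'
#' Per well, the target peak signal is divided by the spiked synthetic
#' hybridization-control signal (removing well-to-well, non-biological
#' variation); replicate wells of a sample are then averaged
#' (arithmetic mean of the ratios).
#'
#' @param records TRAC well table: sample, gene, replicate,
#'   target_signal, control_signal.
#' @return data.frame sample, gene, rel_intensity (mean over wells).
#' @export
trac_normalize <- function(records) {
  bad <- which(records$control_signal <= 0)
  if (length(bad))
    stop("zero or negative hybridization-control signal in well(s): ",
         paste(sprintf("%s/%s rep %s", records$sample[bad], records$gene[bad],
                       records$replicate[bad])[seq_len(min(5, length(bad)))],
               collapse = "; "))
  ratio <- records$target_signal / records$control_signal
  key <- interaction(records$sample, records$gene, drop = TRUE)
  m <- tapply(ratio, key, mean)
  ids <- do.call(rbind, strsplit(names(m), ".", fixed = TRUE))
  out <- data.frame(sample = ids[, 1], gene = ids[, 2],
                    rel_intensity = as.numeric(m), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test for two independent samples
#'
#' Rank-sum U with midrank ties.  The p-value is from the exact
#' permutation distribution when the pooled size is at most
#' `exact_limit` and there are no ties, and from the normal
#' approximation with tie correction and continuity correction
#' otherwise; two-sided.
#'
#' @param a,b the two groups (nonempty numeric vectors).
#' @param exact_limit pooled-size limit for the exact distribution.
#' @return list with `U` (for group `a`), `p`, and `method`.
#' @export
mann_whitney <- function(a, b, exact_limit = 16L) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && (length(a) + length(b)) <= exact_limit
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  p <- wt$p.value
  # fully tied data has zero rank variance; no evidence against the null
  if (is.nan(p)) p <- 1
  list(U = unname(wt$statistic), p = p,
       method = if (exact) "exact" else "normal approximation")
}

#' Compare assay values between two sample groups
#'
#' The group fold change is computed from arithmetic means on the
#' assay's natural linear scale, signed so that under-expression of the
#' first group is negative; the p-value is the two-sided Mann-Whitney
#' test; significance is declared at `p < alpha` (default 0.05).
#'
#' @param values named numeric vector of per-sample assay values
#'   (relative expression / relative intensity).
#' @param group_a,group_b sample ids of the two groups; an empty side is
#'   an error naming the side.
#' @param gene,grouping labels copied into the result row.
#' @param alpha significance level.
#' @return one-row data.frame: gene, grouping, n_a, n_b, U, p, fc,
#'   significant.
#' @export
group_comparison <- function(values, group_a, group_b, gene = NA_character_,
                             grouping = NA_character_, alpha = 0.05) {
  va <- values[intersect(names(values), group_a)]
  vb <- values[intersect(names(values), group_b)]
  if (!length(va)) stop("empty group side A (", grouping, ")")
  if (!length(vb)) stop("empty group side B (", grouping, ")")
  mw <- mann_whitney(as.numeric(va), as.numeric(vb))
  fc <- signed_fold_change(as.numeric(va), as.numeric(vb), summary = "mean")
  data.frame(gene = gene, grouping = grouping,
             n_a = length(va), n_b = length(vb),
             U = mw$U, p = mw$p, fc = fc,
             significant = mw$p < alpha, stringsAsFactors = FALSE)
}

#' Run the standard grouping comparisons for one assay table
#'
#' For every gene, compares: cancer vs nonmalignant; intestinal vs
#' diffuse; g1 vs g0 (restricted to cancer samples with copy-number
#' status); M0 vs M1; T1-2 vs T3-4; N0 vs N1-3.  Groupings with an empty
#' side (e.g. no copy-number data) are reported as `NA` rows rather than
#' errors when `strict = FALSE`.
#'
#' @param expr data.frame sample, gene, value column (named by
#'   `value_col`).
#' @param samples sample metadata (columns sample, disease, histology,
#'   m_stage, t_stage, n_stage).
#' @param carriers optional long truth/annotation table gene, sample,
#'   cn_available, carrier giving g1/g0 status.
#' @param value_col name of the value column in `expr`.
#' @param alpha significance level.
#' @param adjust apply Benjamini-Hochberg correction across genes within
#'   each grouping (off by default).
#' @param strict error (rather than skip) on empty group sides.
#' @return an `assay_results` data.frame, one row per gene x grouping.
#' @export
assay_group_tests <- function(expr, samples, carriers = NULL,
                              value_col = "rel_expr", alpha = 0.05,
                              adjust = FALSE, strict = FALSE) {
  res <- list()
  cancer <- samples$sample[samples$disease == "cancer"]
  normal <- samples$sample[samples$disease == "nonmalignant"]
  pick <- function(col, lvl) samples$sample[!is.na(samples[[col]]) &
                                              samples[[col]] == lvl]
  for (g in unique(expr$gene)) {
    v <- stats::setNames(expr[[value_col]][expr$gene == g],
                         expr$sample[expr$gene == g])
    grp <- list(
      "cancer_vs_nonmalignant" = list(cancer, normal),
      "intestinal_vs_diffuse" = list(pick("histology", "intestinal"),
                                     pick("histology", "diffuse")),
      "M0_vs_M1" = list(pick("m_stage", "M0"), pick("m_stage", "M1")),
      "T1-2_vs_T3-4" = list(pick("t_stage", "T1-2"), pick("t_stage", "T3-4")),
      "N0_vs_N1-3" = list(pick("n_stage", "N0"), pick("n_stage", "N1-3")))
    if (!is.null(carriers)) {
      cg <- carriers[carriers$gene == g & carriers$cn_available, ]
      g1 <- intersect(cancer, cg$sample[cg$carrier])
      g0 <- intersect(cancer, cg$sample[!cg$carrier])
      grp[["g1_vs_g0"]] <- list(g1, g0)
    }
    for (nm in names(grp)) {
      ga <- grp[[nm]][[1]]; gb <- grp[[nm]][[2]]
      if (length(intersect(names(v), ga)) < 2 ||
          length(intersect(names(v), gb)) < 2) {
        if (strict) stop("grouping ", nm, " has an empty/undersized side")
        next
      }
      res[[length(res) + 1L]] <-
        group_comparison(v, ga, gb, gene = g, grouping = nm, alpha = alpha)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (adjust && !is.null(out)) {
    for (nm in unique(out$grouping)) {
      ii <- out$grouping == nm
      out$p[ii] <- stats::p.adjust(out$p[ii], method = "BH")
      out$significant[ii] <- out$p[ii] < alpha
    }
  }
  structure(out, class = c("assay_results", "data.frame"))
}

#' Validate candidate genes against copy-number status
#'
#' A candidate is validated when its g1-vs-g0 comparison is significant
#' and the fold change has the direction the alteration predicts
#' (positive for gains, negative for losses).
#'
#' @param results an [assay_group_tests()] result containing `g1_vs_g0`
#'   rows.
#' @param panel gene panel with `gene` and `direction` columns.
#' @param alpha significance level.
#' @return list with the per-gene table (`genes`) and the validation
#'   `rate` in percent.
#' @export
validate_candidates <- function(results, panel, alpha = 0.05) {
  gg <- results[results$grouping == "g1_vs_g0", , drop = FALSE]
  gg <- gg[match(panel$gene, gg$gene), , drop = FALSE]
  expected <- ifelse(panel$direction == "gain", 1, -1)
  validated <- !is.na(gg$p) & gg$p < alpha & sign(gg$fc) == expected
  tab <- data.frame(gene = panel$gene, direction = panel$direction,
                    fc_g1_g0 = gg$fc, p = gg$p, validated = validated,
                    stringsAsFactors = FALSE)
  list(genes = tab, rate = 100 * mean(validated))
}

#' @export
print.assay_results <- function(x, ...) {
  cat(sprintf("Assay group comparisons: %d test(s), %d gene(s), %d significant at the stated level\n",
              nrow(x), length(unique(x$gene)), sum(x$significant)))
  print(head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}
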