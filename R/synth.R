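#' Simulate a genome model for array emulation
#'
#' Builds a toy genome — chromosome lengths, aCGH probe positions,
#' expression probe positions with a probe-to-gene map, and a
#' non-overlapping gene tiling — emulating (at reduced scale) a 244K CGH
#' oligoarray paired with a 44K whole-genome expression oligoarray.
#'
#' Probes are scattered uniformly per chromosome and sorted; positions are
#' unique so they are strictly increasing.  Genes are tiled into
#' equal-width slots so they never overlap; each gene receives at least
#' one expression probe (placed inside the gene), the remaining expression
#' probes are scattered uniformly and mapped to a gene when they fall
#' inside one.
#'
#' @param n_chromosomes number of chromosomes (all autosomal, named
#'   `"chr1"`, `"chr2"`, ...).
#' @param chrom_length chromosome length in bp (same for all).
#' @param n_acgh_probes,n_expr_probes total probe counts, split evenly
#'   across chromosomes.
#' @param n_genes total gene count, split evenly across chromosomes.
#'   Rejected when the non-overlapping tiling would leave slots narrower
#'   than 1 kb.
#' @param seed integer seed; the model is deterministic given the seed.
#' @return A `genome_model`: list with `chromosomes` (chrom, length),
#'   `acgh_probes`, `expr_probes` (with a `gene` column, `NA` for
#'   intergenic probes) and `genes` (gene, chrom, start, end).
#' @export
simulate_genome <- function(n_chromosomes = 8L, chrom_length = 1.2e8,
                            n_acgh_probes = 10000L, n_expr_probes = 1800L,
                            n_genes = 600L, seed) {
  stopifnot(n_chromosomes >= 1, chrom_length >= 1, n_acgh_probes >= 1,
            n_expr_probes >= 1, n_genes >= 1)
  if (missing(seed)) stop("seed is mandatory")
  if (n_expr_probes < n_genes)
    stop("need at least one expression probe per gene")
  set.seed(as.integer(seed))
  chroms <- paste0("chr", seq_len(n_chromosomes))
  split_counts <- function(n) diff(round(seq(0, n, length.out = n_chromosomes + 1)))
  n_acgh_k <- split_counts(n_acgh_probes)
  n_expr_k <- split_counts(n_expr_probes)
  n_gene_k <- split_counts(n_genes)
  if (any(n_acgh_k < 3))
    stop("fewer than 3 aCGH probes on a chromosome; increase n_acgh_probes")

  probe_len <- 60L
  genes <- acgh <- expr <- vector("list", n_chromosomes)
  for (c_i in seq_len(n_chromosomes)) {
    cc <- chroms[c_i]
    # gene tiling: one slot per gene, gene confined to its slot
    gk <- n_gene_k[c_i]
    if (gk > 0) {
      slot <- floor(chrom_length / gk)
      if (slot < 1000)
        stop("cannot tile ", gk, " non-overlapping genes on a ",
             chrom_length, " bp chromosome")
      slot_start <- (seq_len(gk) - 1) * slot
      gstart <- slot_start + floor(runif(gk, 0, 0.4) * slot)
      glen <- pmax(200L, floor(runif(gk, 0.3, 0.6) * slot))
      gend <- pmin(gstart + glen, slot_start + slot)
      genes[[c_i]] <- data.frame(
        gene = sprintf("G%s_%03d", sub("^chr", "", cc), seq_len(gk)),
        chrom = cc, start = gstart, end = gend, stringsAsFactors = FALSE)
    } else {
      genes[[c_i]] <- NULL
    }
    # aCGH probes: unique uniform positions
    ak <- n_acgh_k[c_i]
    apos <- sort(sample.int(chrom_length - probe_len, ak))
    acgh[[c_i]] <- data.frame(
      probe = sprintf("A_%s_%05d", cc, seq_len(ak)),
      chrom = cc, start = apos, end = apos + probe_len,
      stringsAsFactors = FALSE)
    # expression probes: one guaranteed per gene, remainder scattered
    ek <- n_expr_k[c_i]
    gtab <- genes[[c_i]]
    inpos <- if (!is.null(gtab))
      gtab$start + floor(runif(nrow(gtab)) * pmax(1, gtab$end - gtab$start - probe_len))
    else integer(0)
    extra <- ek - length(inpos)
    epos <- c(inpos,
              if (extra > 0) sample.int(chrom_length - probe_len, extra) else integer(0))
    epos <- sort(unique(epos))
    while (length(epos) < ek) {   # resolve rare collisions
      epos <- sort(unique(c(epos, sample.int(chrom_length - probe_len,
                                             ek - length(epos)))))
    }
    gene_of <- rep(NA_character_, length(epos))
    if (!is.null(gtab)) {
      idx <- findInterval(epos, gtab$start)
      ok <- idx >= 1 & idx <= nrow(gtab)
      hit <- ok & epos < gtab$end[pmax(idx, 1)]
      gene_of[hit] <- gtab$gene[idx[hit]]
    }
    expr[[c_i]] <- data.frame(
      probe = sprintf("E_%s_%05d", cc, seq_along(epos)),
      chrom = cc, start = epos, end = epos + probe_len,
      gene = gene_of, stringsAsFactors = FALSE)
  }
  structure(list(
    chromosomes = data.frame(chrom = chroms, length = chrom_length,
                             stringsAsFactors = FALSE),
    acgh_probes = do.call(rbind, acgh),
    expr_probes = do.call(rbind, expr),
    genes = do.call(rbind, genes)),
    class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("Genome model: %d chromosome(s), %d aCGH probes, %d expression probes, %d genes\n",
              nrow(x$chromosomes), nrow(x$acgh_probes), nrow(x$expr_probes),
              nrow(x$genes)))
  invisible(x)
}

#' Default planted-region table for a genome model
#'
#' Four recurrent copy-number regions (two single-copy gains at copy
#' number 3, two single-copy losses at copy number 1) on the first four
#' chromosomes, each spanning ~10% of its chromosome.  Gains carry a
#' 3-fold expression dosage effect, losses a 1/3-fold effect.
#'
#' @param genome a [simulate_genome()] model.
#' @param recurrence target carrier fraction among cancer samples.
#' @param dosage_fold linear expression fold change in carriers (gains;
#'   losses use its reciprocal).
#' @return data.frame with columns chrom, start, end, copy_number,
#'   direction, recurrence, dosage_fold.
#' @export
default_regions <- function(genome, recurrence = 0.4, dosage_fold = 3) {
  nch <- min(4L, nrow(genome$chromosomes))
  cc <- genome$chromosomes$chrom[seq_len(nch)]
  len <- genome$chromosomes$length[seq_len(nch)]
  dirs <- rep(c("gain", "loss"), length.out = nch)
  data.frame(chrom = cc,
             start = floor(0.35 * len), end = floor(0.45 * len),
             copy_number = ifelse(dirs == "gain", 3L, 1L),
             direction = dirs,
             recurrence = recurrence,
             dosage_fold = ifelse(dirs == "gain", dosage_fold, 1 / dosage_fold),
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic cohort: sample counts (13 tumour
#' tissues + 7 cancer cell lines profiled by aCGH, expression arrays for
#' 10 of them), noise levels, outlier rate, planted region specs, and the
#' validation-cohort assay parameters (46 cancer / 36 nonmalignant
#' qPCR-like samples with copy-number status for 37; 53 / 35 TRAC-like
#' samples with copy-number status for 43; 9 samples assayed in replicate
#' wells).
#'
#' @param regions planted region table (see [default_regions()]).
#' @param n_tissue,n_cell_lines,n_expression array-cohort sizes.
#' @param acgh_sd Gaussian noise sd of aCGH log2 ratios.
#' @param expr_sd Gaussian noise sd of expression log10 ratios.
#' @param outlier_rate fraction of probes flagged as outliers (their
#'   values get an extra 10x-sd Gaussian deviate).
#' @param purity multiplier on segment log2 ratios (1 = pure tumour).
#' @param expr_trend linear dye-bias coefficient per log-intensity unit
#'   (0 = no intensity-dependent trend).
#' @param ct_sd technical sd of a single Ct replicate.
#' @param bio_sd_log2 between-sample biological sd of log2 expression
#'   (qPCR cohort).
#' @param bio_sd_log10 between-sample biological sd of log10 expression
#'   (TRAC cohort).
#' @param trac_cv multiplicative coefficient of variation of TRAC signals.
#' @param qpcr_n_cancer,qpcr_n_normal,qpcr_n_cn qPCR cohort sizes and the
#'   number of cancer samples with copy-number status.
#' @param trac_n_cancer,trac_n_normal,trac_n_cn TRAC cohort analogues.
#' @param n_replicate_samples samples assayed in replicate TRAC wells.
#' @param seed integer seed (mandatory).
#' @return a `sim_config` list.
#' @export
sim_config <- function(regions, n_tissue = 13L, n_cell_lines = 7L,
                       n_expression = 10L,
                       acgh_sd = 0.2, expr_sd = 0.1, outlier_rate = 0.02,
                       purity = 1.0, expr_trend = 0,
                       ct_sd = 0.25, bio_sd_log2 = 0.5, bio_sd_log10 = 0.15,
                       trac_cv = 0.1,
                       qpcr_n_cancer = 46L, qpcr_n_normal = 36L, qpcr_n_cn = 37L,
                       trac_n_cancer = 53L, trac_n_normal = 35L, trac_n_cn = 43L,
                       n_replicate_samples = 9L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(acgh_sd >= 0, expr_sd >= 0, ct_sd >= 0, bio_sd_log2 >= 0,
            bio_sd_log10 >= 0, trac_cv >= 0,
            outlier_rate >= 0, outlier_rate <= 1,
            n_tissue >= 1, n_cell_lines >= 0,
            n_expression <= n_tissue + n_cell_lines,
            qpcr_n_cn <= qpcr_n_cancer, trac_n_cn <= trac_n_cancer)
  if (!missing(regions) && !is.null(regions)) {
    stopifnot(all(regions$recurrence >= 0), all(regions$recurrence <= 1),
              all(regions$direction %in% c("gain", "loss")),
              all(regions$start < regions$end),
              all((regions$direction == "gain") == (regions$copy_number > 2)))
  } else regions <- NULL
  structure(list(regions = regions, n_tissue = as.integer(n_tissue),
                 n_cell_lines = as.integer(n_cell_lines),
                 n_expression = as.integer(n_expression),
                 acgh_sd = acgh_sd, expr_sd = expr_sd,
                 outlier_rate = outlier_rate, purity = purity,
                 expr_trend = expr_trend, ct_sd = ct_sd,
                 bio_sd_log2 = bio_sd_log2, bio_sd_log10 = bio_sd_log10,
                 trac_cv = trac_cv,
                 qpcr_n_cancer = as.integer(qpcr_n_cancer),
                 qpcr_n_normal = as.integer(qpcr_n_normal),
                 qpcr_n_cn = as.integer(qpcr_n_cn),
                 trac_n_cancer = as.integer(trac_n_cancer),
                 trac_n_normal = as.integer(trac_n_normal),
                 trac_n_cn = as.integer(trac_n_cn),
                 n_replicate_samples = as.integer(n_replicate_samples),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a cohort of truth profiles
#'
#' Draws, for every planted region with target recurrence `f`, exactly
#' `round(f * n_cancer)` carrier samples at random, and assigns each gene
#' lying fully inside a carried region the region's dosage multiplier (1
#' elsewhere; a gene straddling a region boundary has ambiguous dosage
#' and is left neutral).  All array-cohort samples are cancer (tissues +
#' cell lines), mirroring a tumour-vs-pooled-reference design.
#'
#' @param genome a [simulate_genome()] model.
#' @param config a [sim_config()]; planted regions must lie within the
#'   genome and opposite-direction regions may not overlap in a sample.
#' @return list of `truth_profile` objects (sample id, class, disease,
#'   CNA segments, per-gene dosage multiplier, child seed).
#' @export
simulate_cohort <- function(genome, config) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "sim_config"))
  regions <- config$regions
  if (!is.null(regions)) {
    chr_len <- stats::setNames(genome$chromosomes$length, genome$chromosomes$chrom)
    if (!all(regions$chrom %in% names(chr_len)) ||
        any(regions$end > chr_len[regions$chrom]))
      stop("planted regions outside genome coordinates")
  }
  ids <- c(sprintf("T%02d", seq_len(config$n_tissue)),
           sprintf("CL%02d", seq_len(config$n_cell_lines)))
  classes <- c(rep("tissue", config$n_tissue),
               rep("cell_line", config$n_cell_lines))
  n_cancer <- length(ids)
  set.seed(config$seed)
  carriers <- vector("list", if (is.null(regions)) 0L else nrow(regions))
  if (!is.null(regions)) {
    for (r in seq_len(nrow(regions))) {
      k <- round(regions$recurrence[r] * n_cancer)
      carriers[[r]] <- if (k > 0) sample(ids, k) else character(0)
    }
  }
  profiles <- vector("list", n_cancer)
  names(profiles) <- ids
  for (i in seq_len(n_cancer)) {
    id <- ids[i]
    ridx <- if (length(carriers))
      which(vapply(carriers, function(cs) id %in% cs, logical(1))) else integer(0)
    segs <- if (length(ridx)) regions[ridx, , drop = FALSE] else
      regions[0, , drop = FALSE]
    if (!is.null(segs) && nrow(segs) > 1) {
      for (a in seq_len(nrow(segs) - 1)) for (b in seq((a + 1), nrow(segs))) {
        if (segs$chrom[a] == segs$chrom[b] &&
            segs$start[a] < segs$end[b] && segs$start[b] < segs$end[a]) {
          if (segs$direction[a] != segs$direction[b])
            stop("overlapping planted regions of opposite direction in sample ", id)
          stop("overlapping planted regions in sample ", id)
        }
      }
    }
    dosage <- stats::setNames(rep(1, nrow(genome$genes)), genome$genes$gene)
    if (!is.null(segs) && nrow(segs)) {
      for (r in seq_len(nrow(segs))) {
        hit <- genome$genes$chrom == segs$chrom[r] &
          genome$genes$start >= segs$start[r] & genome$genes$end <= segs$end[r]
        dosage[hit] <- dosage[hit] * segs$dosage_fold[r]
      }
    }
    profiles[[i]] <- structure(list(
      sample_id = id, class = classes[i], disease = "cancer",
      segments = if (is.null(segs)) data.frame() else
        segs[, c("chrom", "start", "end", "copy_number", "direction")],
      dosage = dosage,
      seed = derive_seed(config$seed, i)),
      class = "truth_profile")
  }
  profiles
}

#' Simulate an aCGH profile from planted truth
#'
#' Probe value on the log2 scale is `purity * log2(cn / 2)` plus Gaussian
#' noise; a fraction `outlier_rate` of probes is flagged and receives an
#' additional heavy-tailed (10x-sd Gaussian) deviate.  With
#' `scale = "raw"` (default) the values are exponentiated to linear
#' ratios, which is the form the preprocessing chain ingests; with
#' `scale = "log2"` they are returned as log2 ratios directly.
#'
#' @param truth a `truth_profile` from [simulate_cohort()].
#' @param genome the genome model the truth was simulated on.
#' @param config a [sim_config()].
#' @param scale `"raw"` or `"log2"`.
#' @return an [array_profile()].
#' @export
simulate_acgh <- function(truth, genome, config, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  probes <- genome$acgh_probes
  set.seed(derive_seed(truth$seed, 1L))
  cn <- rep(2, nrow(probes))
  segs <- truth$segments
  if (!is.null(segs) && nrow(segs)) {
    for (r in seq_len(nrow(segs))) {
      hit <- probes$chrom == segs$chrom[r] &
        probes$start >= segs$start[r] & probes$start < segs$end[r]
      cn[hit] <- segs$copy_number[r]
    }
  }
  v <- config$purity * log2(cn / 2) + rnorm(nrow(probes), 0, config$acgh_sd)
  flag <- rep(FALSE, nrow(probes))
  n_out <- round(config$outlier_rate * nrow(probes))
  if (n_out > 0) {
    idx <- sample.int(nrow(probes), n_out)
    flag[idx] <- TRUE
    v[idx] <- v[idx] + rnorm(n_out, 0, 10 * config$acgh_sd)
  }
  rec <- data.frame(probe = probes$probe, chrom = probes$chrom,
                    start = probes$start, end = probes$end,
                    value = if (scale == "raw") 2^v else v,
                    outlier = flag, stringsAsFactors = FALSE)
  array_profile(rec, truth$sample_id, "acgh", scale, sort = FALSE)
}

#' Simulate a reference (calibration) aCGH profile
#'
#' A copy-number-neutral profile from the same noise model, usable as the
#' calibration array in [calibrate()].
#'
#' @inheritParams simulate_acgh
#' @export
simulate_reference <- function(genome, config, scale = c("raw", "log2")) {
  truth <- structure(list(sample_id = "REF", class = "tissue",
                          disease = "nonmalignant",
                          segments = data.frame(), dosage = numeric(0),
                          seed = derive_seed(config$seed, 424243L)),
                     class = "truth_profile")
  simulate_acgh(truth, genome, config, scale = match.arg(scale))
}

#' Simulate an expression profile from planted truth
#'
#' Probe log10 ratio is `log10(dosage multiplier)` (baseline 1.0, so 0 for
#' genes without a planted effect and for all intergenic probes) plus an
#' optional intensity-dependent dye-bias trend plus Gaussian noise.  The
#' mean log-intensity covariate used by loess normalization is emitted in
#' the `intensity` column.
#'
#' @inheritParams simulate_acgh
#' @return an [array_profile()] with platform `"expression"`, scale
#'   `"log10"`.
#' @export
simulate_expression <- function(truth, genome, config) {
  probes <- genome$expr_probes
  set.seed(derive_seed(truth$seed, 2L))
  mult <- rep(1, nrow(probes))
  known <- !is.na(probes$gene) & probes$gene %in% names(truth$dosage)
  mult[known] <- truth$dosage[probes$gene[known]]
  A <- rnorm(nrow(probes), 10, 1)
  v <- log10(mult) + config$expr_trend * (A - 10) +
    rnorm(nrow(probes), 0, config$expr_sd)
  flag <- rep(FALSE, nrow(probes))
  n_out <- round(config$outlier_rate * nrow(probes))
  if (n_out > 0) {
    idx <- sample.int(nrow(probes), n_out)
    flag[idx] <- TRUE
    v[idx] <- v[idx] + rnorm(n_out, 0, 10 * config$expr_sd)
  }
  rec <- data.frame(probe = probes$probe, chrom = probes$chrom,
                    start = probes$start, end = probes$end,
                    value = v, outlier = flag,
                    intensity = A, stringsAsFactors = FALSE)
  array_profile(rec, truth$sample_id, "expression", "log10", sort = FALSE)
}

#' Default validation-assay gene panel
#'
#' Thirteen candidate genes split over the two assay platforms: 2 qPCR
#' genes and 11 TRAC genes.  Nine genes carry a true copy-number dosage
#' effect (`dosage_fold` != 1) and four do not; all are differentially
#' expressed between cancer and nonmalignant samples (`cancer_fold`).
#' Gene symbols follow the gastric-cancer candidate panel this layout
#' emulates.
#'
#' @param cancer_fold linear cancer-vs-normal fold change planted for all
#'   panel genes.
#' @param dosage_fold linear g1-vs-g0 fold change planted for
#'   dosage-associated genes.
#' @param carrier_fraction fraction of copy-number-informative cancer
#'   samples carrying the alteration.
#' @return data.frame with one row per gene.
#' @export
default_assay_panel <- function(cancer_fold = 3, dosage_fold = 3,
                                carrier_fraction = 0.4) {
  qpcr <- data.frame(gene = c("HHIPL2", "ALPK2"),
                     assay = "qpcr",
                     direction = c("gain", "loss"),
                     dosage = c(TRUE, TRUE),
                     stringsAsFactors = FALSE)
  trac <- data.frame(
    gene = c("ENAH", "OSMR", "CYP3A4", "ERBB2", "PERLD1", "PTPRA", "MMP9",
             "ASAP1", "CEACAM5", "LTB4R", "PNMT"),
    assay = "trac",
    direction = "gain",
    dosage = c(rep(TRUE, 7), rep(FALSE, 4)),
    stringsAsFactors = FALSE)
  panel <- rbind(qpcr, trac)
  panel$cancer_fold <- ifelse(panel$direction == "loss",
                              1 / cancer_fold, cancer_fold)
  panel$dosage_fold <- ifelse(panel$dosage,
                              ifelse(panel$direction == "gain",
                                     dosage_fold, 1 / dosage_fold), 1)
  panel$carrier_fraction <- carrier_fraction
  panel
}

make_assay_samples <- function(prefix, n_cancer, n_normal) {
  ids <- c(sprintf("%sC%02d", prefix, seq_len(n_cancer)),
           sprintf("%sN%02d", prefix, seq_len(n_normal)))
  disease <- c(rep("cancer", n_cancer), rep("nonmalignant", n_normal))
  histology <- m_stage <- t_stage <- n_stage <- rep(NA_character_, length(ids))
  ic <- disease == "cancer"
  histology[ic] <- sample(c("intestinal", "diffuse"), n_cancer, replace = TRUE)
  m_stage[ic] <- sample(c("M0", "M1"), n_cancer, TRUE, prob = c(0.7, 0.3))
  t_stage[ic] <- sample(c("T1-2", "T3-4"), n_cancer, TRUE, prob = c(0.4, 0.6))
  n_stage[ic] <- sample(c("N0", "N1-3"), n_cancer, TRUE, prob = c(0.4, 0.6))
  data.frame(sample = ids, disease = disease, histology = histology,
             m_stage = m_stage, t_stage = t_stage, n_stage = n_stage,
             stringsAsFactors = FALSE)
}

#' Simulate validation-cohort assay tables
#'
#' Generates triplicate Ct tables (target + endogenous 18S-like control)
#' for the qPCR panel genes and per-well TRAC peak-signal tables (target +
#' spiked hybridization-control channel) for the TRAC panel genes, over a
#' validation cohort that is disjoint from the array cohort.  The true
#' relative expression of a sample is
#' `cancer_fold^[cancer] * dosage_fold^[carrier]` times a lognormal
#' biological deviate; Ct values decrease by one cycle per doubling of
#' true expression; TRAC target and control signals share a per-well
#' scale factor that the control-ratio normalization removes.
#'
#' Copy-number (g1/g0) status is only assigned to the configured number
#' of cancer samples (`qpcr_n_cn`, `trac_n_cn`); carriers are drawn as
#' exactly `round(carrier_fraction * n_cn)` of them per gene.
#'
#' @param config a [sim_config()].
#' @param panel a gene panel as from [default_assay_panel()].
#' @param seed seed for this draw (defaults to `config$seed`).
#' @return list with `ct` (long triplicate Ct table), `trac` (per-well
#'   signal table), `qpcr_samples`/`trac_samples` (sample metadata), and
#'   `carriers` (long gene x sample truth: `cn_available`, `carrier`).
#' @export
simulate_assays <- function(config, panel = default_assay_panel(),
                            seed = config$seed) {
  stopifnot(inherits(config, "sim_config"),
            all(c("gene", "assay", "direction", "cancer_fold",
                  "dosage_fold", "carrier_fraction") %in% names(panel)))
  if (config$qpcr_n_cancer < 2 || config$qpcr_n_normal < 2 ||
      config$trac_n_cancer < 2 || config$trac_n_normal < 2)
    stop("validation cohort needs at least 2 samples per class")
  set.seed(derive_seed(seed, 77L))

  one_cohort <- function(prefix, n_cancer, n_normal, n_cn, genes) {
    samp <- make_assay_samples(prefix, n_cancer, n_normal)
    cancer_ids <- samp$sample[samp$disease == "cancer"]
    cn_ids <- sample(cancer_ids, n_cn)
    carr <- do.call(rbind, lapply(seq_len(nrow(genes)), function(g) {
      k <- round(genes$carrier_fraction[g] * n_cn)
      carrier_ids <- if (k > 0) sample(cn_ids, k) else character(0)
      data.frame(gene = genes$gene[g], sample = samp$sample,
                 cn_available = samp$sample %in% cn_ids,
                 carrier = samp$sample %in% carrier_ids,
                 stringsAsFactors = FALSE)
    }))
    list(samples = samp, carriers = carr)
  }

  qp_genes <- panel[panel$assay == "qpcr", , drop = FALSE]
  tr_genes <- panel[panel$assay == "trac", , drop = FALSE]
  qp <- one_cohort("Q", config$qpcr_n_cancer, config$qpcr_n_normal,
                   config$qpcr_n_cn, qp_genes)
  tr <- one_cohort("K", config$trac_n_cancer, config$trac_n_normal,
                   config$trac_n_cn, tr_genes)

  true_log <- function(samples, carriers, genes, sdlog, base) {
    out <- vector("list", nrow(genes))
    for (g in seq_len(nrow(genes))) {
      cg <- carriers[carriers$gene == genes$gene[g], ]
      cg <- cg[match(samples$sample, cg$sample), ]
      l <- log(genes$cancer_fold[g], base) * (samples$disease == "cancer") +
        log(genes$dosage_fold[g], base) * cg$carrier +
        rnorm(nrow(samples), 0, sdlog)
      out[[g]] <- data.frame(gene = genes$gene[g], sample = samples$sample,
                             logexpr = l, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }

  # qPCR: triplicate Cts, one cycle per doubling
  ct <- NULL
  if (nrow(qp_genes)) {
    tl <- true_log(qp$samples, qp$carriers, qp_genes,
                   config$bio_sd_log2, base = 2)
    base_t <- stats::setNames(runif(nrow(qp_genes), 22, 28), qp_genes$gene)
    rows <- tl[rep(seq_len(nrow(tl)), each = 3L), c("gene", "sample")]
    rows$replicate <- rep(1:3, nrow(tl))
    rows$ct_target <- base_t[rows$gene] -
      rep(tl$logexpr, each = 3L) + rnorm(nrow(rows), 0, config$ct_sd)
    rows$ct_control <- 12 + rnorm(nrow(rows), 0, config$ct_sd)
    rownames(rows) <- NULL
    ct <- rows
  }

  # TRAC: per-well target + hybridization-control signals
  trac <- NULL
  if (nrow(tr_genes)) {
    tl <- true_log(tr$samples, tr$carriers, tr_genes,
                   config$bio_sd_log10, base = 10)
    rep_ids <- head(tr$samples$sample[tr$samples$disease == "cancer"],
                    config$n_replicate_samples)
    wells <- tr$samples[, "sample", drop = FALSE]
    wells$n_well <- ifelse(wells$sample %in% rep_ids, 2L, 1L)
    out <- vector("list", nrow(tr_genes))
    for (g in seq_len(nrow(tr_genes))) {
      e <- 10^tl$logexpr[tl$gene == tr_genes$gene[g]]
      e <- rep(e, wells$n_well)
      sample_id <- rep(wells$sample, wells$n_well)
      repl <- unlist(lapply(wells$n_well, seq_len))
      w <- 2^rnorm(length(e), 0, 0.25)  # per-well scale, removed by control
      out[[g]] <- data.frame(
        gene = tr_genes$gene[g], sample = sample_id, replicate = repl,
        target_signal = 100 * e * w * (1 + rnorm(length(e), 0, config$trac_cv)),
        control_signal = 1000 * w * (1 + rnorm(length(e), 0, config$trac_cv)),
        stringsAsFactors = FALSE)
    }
    trac <- do.call(rbind, out)
    rownames(trac) <- NULL
  }

  list(ct = ct, trac = trac,
       qpcr_samples = qp$samples, trac_samples = tr$samples,
       carriers = rbind(qp$carriers, tr$carriers),
       panel = panel)
}
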