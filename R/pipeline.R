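#' Pipeline configuration
#'
#' All stage parameters in one list, defaulting to the analysis' stated
#' values: calling threshold 12.0; aberration filters (min 3 probes, min
#' |log2| 0.27, max 1000 regions); recurrence fraction 0.25; fold-change
#' cut 2.0; significance level 0.05.  Either a simulation block
#' (`genome` + `sim`) or input profile paths must be supplied.
#'
#' @param genome a [simulate_genome()] model (simulation mode).
#' @param sim a [sim_config()] (simulation mode).
#' @param inputs list with `acgh` (profile paths), optional `expression`
#'   (paths) and `classes` (named vector sample -> tissue/cell_line), for
#'   running on existing probe tables instead of simulating.
#' @param out_dir output directory for all artifacts.
#' @param threshold calling threshold on the interval score.
#' @param min_probes,min_abs_log2,max_regions aberration filters.
#' @param recurrence_fraction recurrence threshold.
#' @param fold_cut candidate fold-change cut.
#' @param alpha significance level for assay tests.
#' @param z,z_before_calibration,use_reference preprocessing switches
#'   (Z-normalize; Z before calibration-array subtraction; subtract a
#'   simulated calibration array).
#' @param loess_span loess span for expression normalization.
#' @param write_profiles also write every preprocessed profile table.
#' @param run_assays simulate and analyze the validation-cohort assays
#'   (simulation mode only).
#' @param seed run seed; defaults to the simulation seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(genome = NULL, sim = NULL, inputs = NULL,
                            out_dir = tempfile("cnadose_run_"),
                            threshold = 12.0, min_probes = 3L,
                            min_abs_log2 = 0.27, max_regions = 1000L,
                            recurrence_fraction = 0.25, fold_cut = 2.0,
                            alpha = 0.05, z = TRUE,
                            z_before_calibration = TRUE,
                            use_reference = FALSE, loess_span = 0.3,
                            write_profiles = TRUE, run_assays = TRUE,
                            seed = NULL) {
  if (is.null(sim) && is.null(inputs))
    stop("either a simulation block (genome + sim) or inputs must be given")
  if (!is.null(sim) && is.null(genome))
    stop("simulation mode needs a genome model")
  if (is.null(sim)) {
    missing_paths <- inputs$acgh[!file.exists(inputs$acgh)]
    if (length(missing_paths))
      stop("missing input path(s): ", paste(missing_paths, collapse = ", "))
  }
  if (is.null(seed)) seed <- if (!is.null(sim)) sim$seed else 1L
  structure(list(genome = genome, sim = sim, inputs = inputs,
                 out_dir = out_dir, threshold = threshold,
                 min_probes = min_probes, min_abs_log2 = min_abs_log2,
                 max_regions = max_regions,
                 recurrence_fraction = recurrence_fraction,
                 fold_cut = fold_cut, alpha = alpha, z = z,
                 z_before_calibration = z_before_calibration,
                 use_reference = use_reference, loess_span = loess_span,
                 write_profiles = write_profiles, run_assays = run_assays,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# noise estimate with graceful degenerate handling: robust -> plain ->
# small positive floor (zero-noise synthetic profiles)
noise_or_floor <- function(profile, floor = 1e-3) {
  est <- tryCatch(estimate_noise(profile, "mad"),
                  error = function(e) NULL)
  if (is.null(est))
    est <- tryCatch(estimate_noise(profile, "sd"), error = function(e) NULL)
  if (is.null(est))
    est <- structure(list(sample_id = profile_sample(profile), sd = floor),
                     class = "noise_estimate")
  est$sd <- max(est$sd, floor)
  est
}

#' Run the integrated copy-number / expression pipeline
#'
#' Executes simulate (optional) -> preprocess -> call -> filter ->
#' recurrence -> integrate -> assays, writing every intermediate table
#' under `config$out_dir`, and returns a run report whose counts equal
#' the rows of the emitted tables.  Rerunning with the same configuration
#' and seed reproduces the outputs bit-identically.
#'
#' @param config a [pipeline_config()].
#' @return a `cna_run` report: parameters, per-stage counts, output file
#'   digests, and the in-memory stage results in `$results`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(seed = config$seed, threshold = config$threshold,
               min_probes = config$min_probes,
               min_abs_log2 = config$min_abs_log2,
               max_regions = config$max_regions,
               recurrence_fraction = config$recurrence_fraction,
               fold_cut = config$fold_cut, alpha = config$alpha)
  paths <- character(0)
  emit <- function(writer, obj, name, ...) {
    p <- file.path(config$out_dir, name)
    writer(obj, p, ...)
    paths[[length(paths) + 1L]] <<- p
    p
  }

  # --- stage 1: obtain raw profiles -------------------------------------
  if (!is.null(config$sim)) {
    genome <- config$genome
    cohort <- simulate_cohort(genome, config$sim)
    acgh_raw <- lapply(cohort, simulate_acgh, genome = genome,
                       config = config$sim)
    set.seed(derive_seed(config$seed, 5L))
    expr_ids <- sample(names(cohort), config$sim$n_expression)
    expr_raw <- lapply(cohort[expr_ids], simulate_expression,
                       genome = genome, config = config$sim)
    classes <- vapply(cohort, `[[`, character(1), "class")
    reference <- if (config$use_reference)
      simulate_reference(genome, config$sim) else NULL
    gene_map <- genome$genes
    probe_gene_map <- genome$expr_probes
  } else {
    acgh_raw <- lapply(config$inputs$acgh, read_profile)
    names(acgh_raw) <- vapply(acgh_raw, profile_sample, character(1))
    expr_raw <- if (!is.null(config$inputs$expression))
      lapply(config$inputs$expression, read_profile) else list()
    names(expr_raw) <- vapply(expr_raw, profile_sample, character(1))
    classes <- config$inputs$classes
    reference <- NULL
    gene_map <- config$inputs$gene_map
    probe_gene_map <- config$inputs$probe_gene_map
    cohort <- NULL
  }

  # --- stage 2: preprocess ----------------------------------------------
  acgh <- lapply(acgh_raw, function(p) {
    if (profile_scale(p) == "raw")
      preprocess_acgh(p, reference = reference, z = config$z,
                      z_before_calibration = config$z_before_calibration)
    else if (config$z) z_normalize(filter_outliers(p))
    else filter_outliers(p)
  })
  expr <- if (length(expr_raw))
    loess_normalize(lapply(expr_raw, filter_outliers),
                    span = config$loess_span) else list()
  if (config$write_profiles) {
    pdir <- file.path(config$out_dir, "profiles")
    dir.create(pdir, showWarnings = FALSE)
    for (p in c(acgh, expr)) {
      pp <- file.path(pdir, paste0(profile_sample(p), "_",
                                   profile_platform(p), ".tsv"))
      write_profile(p, pp)
      paths[[length(paths) + 1L]] <- pp
    }
  }

  # --- stage 3/4: call + filter -----------------------------------------
  calls <- new_calls(do.call(rbind, lapply(acgh, function(p) {
    as.data.frame(call_aberrations(p, noise_or_floor(p),
                                   threshold = config$threshold))
  })))
  filtered <- apply_filters(calls, config$min_probes, config$min_abs_log2,
                            config$max_regions)
  emit(write_calls, calls, "calls.tsv", meta = meta)
  emit(write_calls, filtered, "calls_filtered.tsv", meta = meta)

  # --- stage 5: recurrence ----------------------------------------------
  regions <- do.call(rbind, lapply(c("gain", "loss"), function(dir) {
    tr <- build_frequency_track(filtered, dir, classes)
    as.data.frame(annotate_genes(
      recurrent_regions(tr, config$recurrence_fraction), gene_map))
  }))
  n_total <- length(classes)
  regions <- structure(regions,
                       min_fraction = config$recurrence_fraction,
                       n_total = n_total,
                       class = c("recurrent_regions", "data.frame"))
  emit(write_regions, regions, "regions.tsv", meta = meta)

  # --- stage 6: integrate -----------------------------------------------
  comparisons <- candidates <- NULL
  if (length(expr)) {
    expr_mat <- gene_median_expression(expr, probe_gene_map)
    cancer_samples <- names(classes)
    comparisons <- copy_number_comparisons(
      expr_mat, gene_map, filtered, cancer_samples,
      regions = regions, min_fc = config$fold_cut)
    candidates <- select_candidates(comparisons, min_fc = config$fold_cut)
    emit(write_results, comparisons, "comparisons.tsv", meta = meta)
    emit(write_results, candidates, "candidates.tsv", meta = meta)
  }

  # --- stage 7: assays ---------------------------------------------------
  assay <- qpcr_res <- trac_res <- validation <- NULL
  if (!is.null(config$sim) && isTRUE(config$run_assays)) {
    assay <- simulate_assays(config$sim)
    emit(write_assay_table, assay$ct, "ct.tsv", meta = meta)
    emit(write_assay_table, assay$trac, "trac.tsv", meta = meta)
    rel <- qpcr_relative_expression(assay$ct, assay$qpcr_samples)
    qpcr_res <- assay_group_tests(rel, assay$qpcr_samples, assay$carriers,
                                  value_col = "rel_expr",
                                  alpha = config$alpha)
    tn <- trac_normalize(assay$trac)
    trac_res <- assay_group_tests(tn, assay$trac_samples, assay$carriers,
                                  value_col = "rel_intensity",
                                  alpha = config$alpha)
    both <- rbind(qpcr_res, trac_res)
    validation <- validate_candidates(both, assay$panel, alpha = config$alpha)
    emit(write_results, qpcr_res, "qpcr_results.tsv", meta = meta)
    emit(write_results, trac_res, "trac_results.tsv", meta = meta)
    emit(write_results, validation$genes, "validation.tsv", meta = meta)
  }

  paths <- unlist(paths)
  counts <- list(
    samples = length(acgh),
    expression_arrays = length(expr),
    calls = nrow(calls), filtered_calls = nrow(filtered),
    recurrent_regions = nrow(regions),
    comparisons = if (is.null(comparisons)) 0L else nrow(comparisons),
    candidates = if (is.null(candidates)) 0L else nrow(candidates),
    assay_tests = (if (is.null(qpcr_res)) 0L else nrow(qpcr_res)) +
      (if (is.null(trac_res)) 0L else nrow(trac_res)),
    validated = if (is.null(validation)) 0L else
      sum(validation$genes$validated))
  structure(list(params = meta, counts = counts,
                 digests = tools::md5sum(paths),
                 out_dir = config$out_dir, seed = config$seed,
                 results = list(calls = calls, filtered = filtered,
                                regions = regions,
                                comparisons = comparisons,
                                candidates = candidates,
                                qpcr = qpcr_res, trac = trac_res,
                                validation = validation,
                                cohort = cohort)),
            class = "cna_run")
}

#' @export
print.cna_run <- function(x, ...) {
  cat("Integrated copy-number / expression run (seed", x$seed, ")\n")
  cat("Output:", x$out_dir, "\n")
  for (nm in names(x$counts)) cat(sprintf("  %-18s %s\n", nm, x$counts[[nm]]))
  if (!is.null(x$results$validation))
    cat(sprintf("  validation rate    %.1f%%\n", x$results$validation$rate))
  invisible(x)
}
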