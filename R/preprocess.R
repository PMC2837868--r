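#' Remove probes flagged as outliers
#'
#' Quality filtering: probes carrying an outlier flag (as emitted by the
#' scanner feature-extraction step, or by the simulator) are dropped
#' before any downstream analysis.  Probe order is preserved.
#'
#' @param profile an [array_profile()] with outlier flags.
#' @return the profile without flagged probes.  Errors if removal leaves
#'   any chromosome with fewer than 3 probes (the downstream minimum
#'   region size).
#' @export
filter_outliers <- function(profile) {
  stopifnot(inherits(profile, "array_profile"))
  keep <- !profile$outlier
  out <- as.data.frame(profile)[keep, , drop = FALSE]
  left <- table(factor(out$chrom, levels = unique(profile$chrom)))
  if (any(left < 3))
    stop("outlier removal leaves chromosome(s) with < 3 probes: ",
         paste(names(left)[left < 3], collapse = ", "))
  reprofile(profile, out)
}

#' Convert linear ratios to log2 ratios
#'
#' A log2 ratio of 0.27 corresponds to a 1.2-fold copy-number change
#' (2^0.27 ~ 1.2), which is the unit the aberration filters are stated in.
#'
#' @param profile an [array_profile()] on the raw (linear ratio) scale.
#' @return the profile with `value <- log2(value)` and scale `"log2"`.
#'   Non-positive ratios are an error naming the offending probe.
#' @export
to_log2 <- function(profile) {
  stopifnot(inherits(profile, "array_profile"))
  if (profile_scale(profile) != "raw")
    stop("to_log2() expects a raw-ratio profile, got scale '",
         profile_scale(profile), "'")
  bad <- which(!is.finite(profile$value) | profile$value <= 0)
  if (length(bad))
    stop("non-positive ratio at probe(s): ",
         paste(profile$probe[head(bad, 5L)], collapse = ", "))
  out <- as.data.frame(profile)
  out$value <- log2(out$value)
  reprofile(profile, out, scale = "log2")
}

#' Z-normalize a log-ratio profile
#'
#' Centers and scales values to mean 0 and standard deviation 1.  The
#' mean and sd are estimated over autosomal probes only (gender
#' differences make sex-chromosome probes biased estimators of the array
#' centre); sex-chromosome probes are transformed with the autosomal
#' parameters.  The sd is the sample convention (divisor `n - 1`), so
#' e.g. values (1, 2, 3) standardize to (-1, 0, 1).
#'
#' @param profile an [array_profile()] with at least 2 finite values.
#' @return the standardized profile, scale `"normalized"`.  Errors on
#'   zero-variance input.
#' @export
z_normalize <- function(profile) {
  stopifnot(inherits(profile, "array_profile"))
  auto <- !is_sex_chrom(profile$chrom)
  v <- profile$value[auto & is.finite(profile$value)]
  if (length(v) < 2) stop("need >= 2 finite autosomal probes")
  m <- mean(v)
  s <- sd(v)                     # sample convention (n - 1)
  if (s == 0) stop("zero-variance profile cannot be Z-normalized")
  out <- as.data.frame(profile)
  out$value <- (out$value - m) / s
  reprofile(profile, out, scale = "normalized")
}

#' Calibrate a profile against a reference array
#'
#' Probe-wise subtraction of a calibration array (e.g. a male-vs-female
#' reference hybridization): `value <- value - reference value` for
#' autosomal probes.  Chromosomes X and Y are excluded from the
#' calibration (their reference log ratios reflect the gender difference,
#' not array bias) and pass through uncorrected.  Probes flagged as
#' outliers on the reference array are dropped from both profiles.
#'
#' @param profile an [array_profile()].
#' @param reference an [array_profile()] on the same scale covering (at
#'   least) the profile's probe set.
#' @return the calibrated profile, scale `"normalized"`.
#' @export
calibrate <- function(profile, reference) {
  stopifnot(inherits(profile, "array_profile"),
            inherits(reference, "array_profile"))
  ref_bad <- reference$probe[reference$outlier]
  keep <- !(profile$probe %in% ref_bad)
  out <- as.data.frame(profile)[keep, , drop = FALSE]
  ref <- as.data.frame(reference)[!reference$outlier, , drop = FALSE]
  idx <- match(out$probe, ref$probe)
  if (anyNA(idx))
    stop("probes missing from reference array: ",
         paste(head(out$probe[is.na(idx)], 5L), collapse = ", "))
  auto <- !is_sex_chrom(out$chrom)
  out$value[auto] <- out$value[auto] - ref$value[idx][auto]
  reprofile(profile, out, scale = "normalized")
}

#' Loess-normalize expression profiles
#'
#' Removes the intensity-dependent dye-bias trend from each array: a
#' locally weighted regression of the log ratio on the mean log intensity
#' (the `intensity` column) is fitted and subtracted, then the profile is
#' median-centred so the post-normalization median log ratio is 0.  With
#' a (near-)constant intensity covariate the fit degenerates and plain
#' median-centring is applied.
#'
#' @param profiles a single [array_profile()] or a list of them, each
#'   carrying an `intensity` column.
#' @param span loess span (fraction of probes in the local window).
#' @param iterations robustifying iterations of the loess fit.
#' @return profiles of the same shape, scale `"normalized"`.
#' @export
loess_normalize <- function(profiles, span = 0.3, iterations = 1L) {
  one <- function(profile) {
    stopifnot(inherits(profile, "array_profile"))
    if (!"intensity" %in% names(profile))
      stop("profile '", profile_sample(profile),
           "' has no intensity covariate for loess normalization")
    n <- nrow(profile)
    if (n < 10) stop("too few probes (", n, ") for the smoothing window")
    out <- as.data.frame(profile)
    if (sd(out$intensity) < .Machine$double.eps^0.5) {
      out$value <- out$value - median(out$value)
    } else {
      fit <- limma::loessFit(y = out$value, x = out$intensity,
                             span = span, iterations = iterations)
      out$value <- out$value - fit$fitted
      out$value <- out$value - median(out$value)
    }
    reprofile(profile, out, scale = "normalized")
  }
  if (inherits(profiles, "array_profile")) one(profiles) else lapply(profiles, one)
}

#' Run the full aCGH preprocessing chain
#'
#' Outlier filtering, log2 conversion, Z-normalization and (optionally)
#' calibration-array subtraction, in that order.  The Z step and the
#' order of Z vs calibration are configurable.
#'
#' @param profile raw-ratio aCGH [array_profile()].
#' @param reference optional calibration array (raw scale; preprocessed
#'   identically before subtraction).
#' @param z apply Z-normalization.
#' @param z_before_calibration if `FALSE`, calibrate first, then
#'   Z-normalize.
#' @return preprocessed profile.
#' @export
preprocess_acgh <- function(profile, reference = NULL, z = TRUE,
                            z_before_calibration = TRUE) {
  p <- to_log2(filter_outliers(profile))
  r <- if (!is.null(reference)) to_log2(filter_outliers(reference)) else NULL
  if (z && z_before_calibration) {
    p <- z_normalize(p)
    if (!is.null(r)) r <- z_normalize(r)
  }
  if (!is.null(r)) p <- calibrate(p, r)
  if (z && !z_before_calibration) p <- z_normalize(p)
  p
}
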