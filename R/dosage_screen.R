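# Intensity-based dosage screen: sex-balance filtering, female-median
# normalization, reference-band fitting and per-sample dosage calls.

#' Flag samples with unbalanced sex chromosomes
#'
#' Computes, per sample, the median log2 ratio of its intensities to the
#' sex-matched reference median, separately over X-flank and Y-flank
#' markers; all PAR-associated markers (regions `PAR1` and `EPAR_INTERVAL`)
#' are excluded. A sample passes when both medians lie within
#' `+/- threshold`, which removes sex-chromosome aneuploidies (e.g. 47,XXY)
#' before dosage classification.
#'
#' @param intensities data frame with columns `sample_id`, `sex` and one
#'   column per marker (as produced by [simulate_cohort()]).
#' @param markers marker metadata data frame (`marker_id`, `chrom`, `pos`,
#'   `region`).
#' @param threshold maximum absolute median log2 ratio (default 0.35).
#' @return Logical vector of balance passes, named by sample id.
#' @export
sex_balance_filter <- function(intensities, markers, threshold = 0.35) {
  flank <- markers$marker_id[markers$region %in% c("X_FLANK", "Y_FLANK")]
  if (!length(flank)) {
    stop("no non-PAR X/Y markers available for the sex-balance filter")
  }
  sex <- intensities$sex
  eps <- .Machine$double.eps
  med_log2 <- function(region) {
    ids <- markers$marker_id[markers$region == region]
    if (!length(ids)) return(rep(0, nrow(intensities)))
    m <- as.matrix(intensities[, ids, drop = FALSE])
    lr <- matrix(NA_real_, nrow(m), ncol(m))
    for (s in unique(sex)) {
      rows <- sex == s
      ref <- apply(m[rows, , drop = FALSE], 2, median, na.rm = TRUE)
      lr[rows, ] <- log2(pmax(m[rows, , drop = FALSE], eps) /
                           rep(pmax(ref, eps), each = sum(rows)))
    }
    apply(lr, 1, median, na.rm = TRUE)
  }
  pass <- abs(med_log2("X_FLANK")) <= threshold & abs(med_log2("Y_FLANK")) <= threshold
  setNames(pass, intensities$sample_id)
}

#' Normalize informative-marker intensities against female medians
#'
#' Per marker, the deviation of each sample from the female median of that
#' marker is computed; the normalized value of a sample is the median of
#' these deviations over the informative markers (median of deviation from
#' the median in females). On this scale female two-copy samples centre at
#' 0 and each copy lost shifts the value down by one copy-signal unit.
#'
#' @inheritParams sex_balance_filter
#' @param informative marker ids to use; defaults to all markers tagged
#'   `EPAR_INTERVAL`.
#' @return Numeric vector of normalized values, named by sample id.
#' @export
normalize_intensities <- function(intensities, markers,
                                  informative = markers$marker_id[markers$region == "EPAR_INTERVAL"]) {
  if (!length(informative)) stop("informative marker set is empty")
  if (!any(intensities$sex == "F")) {
    stop("no females in the cohort: female reference medians are undefined")
  }
  m <- as.matrix(intensities[, informative, drop = FALSE])
  fmed <- apply(m[intensities$sex == "F", , drop = FALSE], 2, median, na.rm = TRUE)
  bad <- !is.finite(fmed)
  if (any(bad)) {
    warning(sprintf("excluding %d marker(s) with undefined female median: %s",
                    sum(bad), paste(informative[bad], collapse = ", ")))
    m <- m[, !bad, drop = FALSE]
    fmed <- fmed[!bad]
    if (!ncol(m)) stop("all informative markers have undefined female medians")
  }
  dev <- sweep(m, 2, fmed)
  setNames(apply(dev, 1, median, na.rm = TRUE), intensities$sample_id)
}

#' Fit haploid / diploid / deletion reference bands
#'
#' Reference samples are chosen in a single deterministic pass: each sample
#' is assigned to the nearest dosage centre (copy-number 0, 1 or 2 levels
#' anchored at the male and female medians), and the samples nearest the
#' normal centre of their sex (one-copy males, two-copy females) define the
#' reference sets. The haploid and diploid bands are their central 95%
#' intervals; by default these are nearest-rank percentile intervals
#' (lower = ceiling(0.025 n)-th, upper = ceiling(0.975 n)-th order
#' statistic), with a Gaussian `mean +/- 1.96 sd` alternative. The deletion
#' band defaults to the haploid band shifted one copy-step further down,
#' i.e. centred on the zero-copy dosage level; it can be overridden.
#'
#' Band ordering `deletion < haploid < diploid` (strictly separated bands;
#' zero-width bands are permitted for noiseless data) is enforced, otherwise
#' the fit is refused.
#'
#' @param normalized named numeric vector from [normalize_intensities()].
#' @param sex character vector (`"M"`/`"F"`) aligned with `normalized`.
#' @param ci_method `"percentile"` (nearest-rank, default) or `"gaussian"`.
#' @param deletion_band optional numeric length-2 override for the deletion
#'   band.
#' @param min_reference minimum reference samples required per fitted band
#'   (default 40).
#' @return An object of class `reference_bands`: list with `haploid_band`,
#'   `diploid_band`, `deletion_band` (each `c(lower, upper)`) and
#'   `provenance` (reference counts).
#' @export
build_reference_bands <- function(normalized, sex,
                                  ci_method = c("percentile", "gaussian"),
                                  deletion_band = NULL, min_reference = 40) {
  ci_method <- match.arg(ci_method)
  stopifnot(length(normalized) == length(sex))
  f_c <- median(normalized[sex == "F"], na.rm = TRUE)
  m_c <- median(normalized[sex == "M"], na.rm = TRUE)
  step <- m_c - f_c  # one copy lost (negative on the normalized scale)
  centres <- c(f_c, f_c + step, f_c + 2 * step)  # 2, 1, 0 copies

  nearest <- function(x) apply(abs(outer(x, centres, "-")), 1, which.min)
  males <- normalized[sex == "M"]
  females <- normalized[sex == "F"]
  ref_m <- males[nearest(males) == 2L]    # one-copy males
  ref_f <- females[nearest(females) == 1L]  # two-copy females
  if (length(ref_m) < min_reference || length(ref_f) < min_reference) {
    stop(sprintf("need >= %d reference samples per band (got %d males, %d females)",
                 min_reference, length(ref_m), length(ref_f)))
  }
  central95 <- function(x) {
    if (ci_method == "gaussian") {
      mean(x) + c(-1.96, 1.96) * sd(x)
    } else {
      s <- sort(x)
      n <- length(s)
      c(s[ceiling(0.025 * n)], s[ceiling(0.975 * n)])
    }
  }
  hap <- central95(ref_m)
  dip <- central95(ref_f)
  del <- if (is.null(deletion_band)) hap + step else sort(deletion_band)

  bands <- list(haploid_band = hap, diploid_band = dip, deletion_band = del,
                provenance = c(n_reference_males = length(ref_m),
                               n_reference_females = length(ref_f)))
  class(bands) <- "reference_bands"
  if (!(del[2] < hap[1] && hap[1] <= hap[2] && hap[2] < dip[1] && dip[1] <= dip[2])) {
    stop(sprintf(paste0("fitted bands are not ordered deletion < haploid < diploid: ",
                        "deletion [%.4g, %.4g], haploid [%.4g, %.4g], diploid [%.4g, %.4g]"),
                 del[1], del[2], hap[1], hap[2], dip[1], dip[2]))
  }
  bands
}

#' @export
print.reference_bands <- function(x, ...) {
  cat("Reference dosage bands (normalized intensity)\n")
  cat(sprintf("  deletion (0 copies): [%.4f, %.4f]\n", x$deletion_band[1], x$deletion_band[2]))
  cat(sprintf("  haploid  (1 copy)  : [%.4f, %.4f]\n", x$haploid_band[1], x$haploid_band[2]))
  cat(sprintf("  diploid  (2 copies): [%.4f, %.4f]\n", x$diploid_band[1], x$diploid_band[2]))
  cat(sprintf("  fitted from %d reference males, %d reference females\n",
              x$provenance["n_reference_males"], x$provenance["n_reference_females"]))
  invisible(x)
}

#' Classify samples into dosage call classes
#'
#' Males: haploid band -> `REF`, diploid band -> `EPAR` (putative carrier of
#' the PAR1 extension), deletion band -> `DEL_HEMI`, otherwise
#' `UNCLASSIFIED`. Females: diploid band -> `REF`, haploid band ->
#' `HET_DEL`, deletion band -> `HOM_DEL`, otherwise `UNCLASSIFIED`.
#' Samples failing the sex-balance filter are `EXCLUDED_IMBALANCE`
#' regardless of intensity. Every sample receives exactly one call.
#'
#' @param normalized named numeric vector from [normalize_intensities()].
#' @param bands a [build_reference_bands()] fit.
#' @param sex character vector aligned with `normalized`.
#' @param balance_pass logical vector from [sex_balance_filter()], aligned
#'   with `normalized`; `NULL` treats all samples as passing.
#' @return Data frame with columns `sample_id`, `sex`, `normalized_value`,
#'   `balance_pass`, `call`.
#' @export
classify_samples <- function(normalized, bands, sex, balance_pass = NULL) {
  stopifnot(inherits(bands, "reference_bands"))
  if (is.null(balance_pass)) balance_pass <- rep(TRUE, length(normalized))
  stopifnot(length(sex) == length(normalized), length(balance_pass) == length(normalized))
  inband <- function(x, b) !is.na(x) & x >= b[1] & x <= b[2]
  male <- sex == "M"
  call <- rep("UNCLASSIFIED", length(normalized))
  call[male & inband(normalized, bands$haploid_band)] <- "REF"
  call[male & inband(normalized, bands$diploid_band)] <- "EPAR"
  call[male & inband(normalized, bands$deletion_band)] <- "DEL_HEMI"
  call[!male & inband(normalized, bands$diploid_band)] <- "REF"
  call[!male & inband(normalized, bands$haploid_band)] <- "HET_DEL"
  call[!male & inband(normalized, bands$deletion_band)] <- "HOM_DEL"
  call[!balance_pass] <- "EXCLUDED_IMBALANCE"
  data.frame(sample_id = names(normalized), sex = sex,
             normalized_value = unname(normalized),
             balance_pass = unname(balance_pass),
             call = factor(call, levels = c("REF", "EPAR", "DEL_HEMI", "HET_DEL",
                                            "HOM_DEL", "UNCLASSIFIED",
                                            "EXCLUDED_IMBALANCE")),
             row.names = NULL)
}

#' Summarize call incidence per sex
#'
#' Counts and percentages of each call class per sex. The percentage
#' denominator is the number of non-excluded samples of the same sex
#' (samples removed by the balance filter do not enter the denominator).
#' Raw proportions are retained unrounded; rounding is presentation only.
#'
#' @param calls data frame from [classify_samples()].
#' @return Data frame with columns `sex`, `call`, `count`, `denominator`,
#'   `proportion`, `percent`.
#' @export
incidence_summary <- function(calls) {
  stopifnot(nrow(calls) > 0)
  out <- list()
  for (s in unique(calls$sex)) {
    sub <- calls[calls$sex == s, ]
    denom <- sum(sub$call != "EXCLUDED_IMBALANCE")
    tab <- table(sub$call)
    out[[s]] <- data.frame(sex = s, call = names(tab),
                           count = as.integer(tab), denominator = denom,
                           proportion = as.integer(tab) / denom,
                           percent = 100 * as.integer(tab) / denom)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Percentage of a count over a denominator
#'
#' Presentation helper used by [incidence_summary()]; exposed for ad hoc
#' incidence arithmetic (e.g. the share of carriers attributable to one
#' lineage).
#'
#' @param count,denominator non-negative numbers.
#' @param digits optional rounding for display; `NULL` returns the raw value.
#' @return `100 * count / denominator`, optionally rounded.
#' @export
pct_of <- function(count, denominator, digits = NULL) {
  stopifnot(denominator > 0)
  x <- 100 * count / denominator
  if (is.null(digits)) x else round(x, digits)
}
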