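make_cohort <- function(...) simulate_cohort(cohort_spec(...))

test_that("normalization is the median of deviations from female medians", {
  # hand example: female medians (1.0, 1.0, 2.0), sample (0.4, 0.6, 1.4)
  intens <- data.frame(
    sample_id = c("f1", "f2", "f3", "s"),
    sex = c("F", "F", "F", "M"),
    m1 = c(0.9, 1.0, 1.1, 0.4),
    m2 = c(1.0, 1.0, 1.0, 0.6),
    m3 = c(1.9, 2.0, 2.1, 1.4))
  markers <- data.frame(marker_id = c("m1", "m2", "m3"), chrom = "chrX",
                        pos = 1:3, region = "EPAR_INTERVAL")
  nv <- normalize_intensities(intens, markers)
  expect_equal(unname(nv["s"]), -0.6)
  # a sample equal to the female medians normalizes to zero
  expect_equal(unname(nv["f2"]), 0)
})

test_that("normalized values are invariant to per-marker global shifts", {
  co <- make_cohort(n_males = 300, n_females = 300, seed = 10)
  nv1 <- normalize_intensities(co$intensities, co$markers)
  shifted <- co$intensities
  shifted$inf_03 <- shifted$inf_03 + 5  # all samples, females included
  nv2 <- normalize_intensities(shifted, co$markers)
  expect_equal(nv1, nv2)
})

test_that("normalization requires females and flags undefined marker medians", {
  co <- make_cohort(n_males = 50, n_females = 50, seed = 2)
  males_only <- co$intensities[co$intensities$sex == "M", ]
  expect_error(normalize_intensities(males_only, co$markers), "female")
  nas <- co$intensities
  nas$inf_01[nas$sex == "F"] <- NA
  expect_warning(nv <- normalize_intensities(nas, co$markers), "undefined female median")
  expect_length(nv, nrow(co$intensities))
})

test_that("sex-balance filter catches an extra X and ignores PAR markers", {
  co <- make_cohort(n_males = 400, n_females = 400, noise_sd = 0,
                    aneuploidy_fraction = 0, seed = 3)
  pass <- sex_balance_filter(co$intensities, co$markers)
  expect_true(all(pass))  # all ratios exactly 0

  # male with X-flank intensities emulating an extra X (log2 ratio ~ +0.9)
  xx <- co$intensities
  xfl <- co$markers$marker_id[co$markers$region == "X_FLANK"]
  xx[1, xfl] <- xx[1, xfl] * 2^0.9
  pass2 <- sex_balance_filter(xx, co$markers, threshold = 0.35)
  expect_false(pass2[[1]])
  expect_true(all(pass2[-1]))

  # extreme values confined to PAR-tagged markers change nothing
  par_ids <- co$markers$marker_id[co$markers$region %in% c("PAR1", "EPAR_INTERVAL")]
  yy <- co$intensities
  yy[1, par_ids] <- 100
  expect_identical(sex_balance_filter(yy, co$markers), pass)

  no_flank <- co$markers[co$markers$region %in% c("PAR1", "EPAR_INTERVAL"), ]
  expect_error(sex_balance_filter(co$intensities[, c("sample_id", "sex", par_ids)],
                                  no_flank), "no non-PAR")
})

test_that("simulated aneuploid samples are excluded by the balance filter", {
  co <- make_cohort(n_males = 2000, n_females = 2000, aneuploidy_fraction = 0.05,
                    seed = 14)
  pass <- sex_balance_filter(co$intensities, co$markers)
  expect_true(all(!pass[co$truth$aneuploid]))
  expect_true(mean(pass[!co$truth$aneuploid]) > 0.99)
})

test_that("reference bands use nearest-rank order statistics", {
  # 41 distinct male values 1..41 -> central 95% band [2, 40]
  vals <- c(1:41, rnorm(60, 100, 0.1))  # females far away at their own centre
  sex <- rep(c("M", "F"), c(41, 60))
  b <- build_reference_bands(setNames(vals, paste0("s", seq_along(vals))), sex,
                             min_reference = 40)
  expect_equal(unname(b$haploid_band), c(2, 40))
  # degenerate diploid band from constant females
  vals2 <- c(1:41, rep(100, 60))
  b2 <- build_reference_bands(setNames(vals2, paste0("s", seq_along(vals2))), sex,
                              min_reference = 40)
  expect_equal(unname(b2$diploid_band), c(100, 100))
  expect_error(build_reference_bands(setNames(vals, paste0("s", seq_along(vals))),
                                     sex, min_reference = 100),
               "reference samples")
})

test_that("classification partitions samples and respects band semantics", {
  co <- make_cohort(n_males = 3000, n_females = 3000, freq_epar = 0.03,
                    freq_xdel_allele = 0.01, seed = 4)
  pass <- sex_balance_filter(co$intensities, co$markers)
  nv <- normalize_intensities(co$intensities, co$markers)
  bands <- build_reference_bands(nv, co$intensities$sex)
  calls <- classify_samples(nv, bands, co$intensities$sex, pass)

  # every sample receives exactly one call
  expect_equal(nrow(calls), nrow(co$intensities))
  expect_false(anyNA(calls$call))
  # EXCLUDED_IMBALANCE iff balance fails
  expect_identical(calls$call == "EXCLUDED_IMBALANCE", !unname(pass))
  # sex-specific classes
  expect_true(all(calls$sex[calls$call %in% c("EPAR", "DEL_HEMI")] == "M"))
  expect_true(all(calls$sex[calls$call %in% c("HET_DEL", "HOM_DEL")] == "F"))
  # synthetic carrier males fall inside the fitted diploid band
  carrier_vals <- nv[co$truth$class == "EPAR" & co$truth$sex == "M" & pass]
  inside <- carrier_vals >= bands$diploid_band[1] & carrier_vals <= bands$diploid_band[2]
  expect_gt(mean(inside), 0.9)
})

test_that("male calls are monotone in the normalized value", {
  co <- make_cohort(n_males = 2000, n_females = 2000, seed = 6)
  nv <- normalize_intensities(co$intensities, co$markers)
  bands <- build_reference_bands(nv, co$intensities$sex)
  grid <- seq(min(nv) - 1, max(nv) + 1, length.out = 500)
  calls <- classify_samples(setNames(grid, paste0("g", seq_along(grid))), bands,
                            rep("M", length(grid)))
  rank_of <- c(DEL_HEMI = 1, UNCLASSIFIED = NA, REF = 2, EPAR = 3)
  r <- rank_of[as.character(calls$call)]
  r <- r[!is.na(r)]
  expect_true(all(diff(r) >= 0))
})

test_that("the screen is exact on zero-noise cohorts", {
  co <- make_cohort(n_males = 1500, n_females = 1500, freq_epar = 0.05,
                    freq_xdel_allele = 0.02, noise_sd = 0,
                    aneuploidy_fraction = 0, seed = 7)
  nv <- normalize_intensities(co$intensities, co$markers)
  bands <- build_reference_bands(nv, co$intensities$sex)
  calls <- classify_samples(nv, bands, co$intensities$sex)
  expect_identical(as.character(calls$call), co$truth$class)
})

test_that("incidence percentages use non-excluded same-sex denominators", {
  calls <- data.frame(
    sample_id = sprintf("s%d", 1:10),
    sex = rep(c("M", "F"), each = 5),
    normalized_value = 0, balance_pass = rep(c(TRUE, FALSE), c(9, 1)),
    call = factor(c("REF", "REF", "EPAR", "DEL_HEMI", "REF",
                    "REF", "HET_DEL", "REF", "REF", "EXCLUDED_IMBALANCE"),
                  levels = levels(classify_samples(c(s = 0),
                    build_reference_bands(setNames(c(rnorm(50, -1, .01), rnorm(50, 0, .01)),
                                                   paste0("x", 1:100)),
                                          rep(c("M", "F"), each = 50)),
                    "M")$call)))
  inc <- incidence_summary(calls)
  epar <- inc[inc$sex == "M" & inc$call == "EPAR", ]
  expect_equal(epar$count, 1L)
  expect_equal(epar$denominator, 5L)
  expect_equal(epar$percent, 20)
  het <- inc[inc$sex == "F" & inc$call == "HET_DEL", ]
  expect_equal(het$denominator, 4L)  # the excluded female does not count
  expect_equal(het$percent, 25)
  # zero carriers -> 0%
  expect_equal(inc[inc$sex == "F" & inc$call == "EPAR", "percent"], 0)
})
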