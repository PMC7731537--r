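test_that("a noise-free cohort is inverted exactly by the analysis chain", {
  cfg <- cohort_config(n_volunteer = 0, n_mgus = 0, n_mm = 3,
                       additive_sigma = 0, multiplicative_cv = 0,
                       enrichment_measurement_cv = 0, seed = 101)
  cohort <- generate_cohort(cfg)
  rec <- recover_cohort(cohort)
  expect_equal(rec$f_hat, rec$f_true, tolerance = 1e-6)
})

test_that("cohort generation is fully determined by the seed", {
  cfg <- cohort_config(n_volunteer = 1, n_mgus = 2, n_mm = 2, seed = 55)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(cohort_config(n_volunteer = 1, n_mgus = 2,
                                      n_mm = 2, seed = 56))
  expect_false(identical(a$intensities$intensity,
                         c2$intensities$intensity))
  expect_error(cohort_config(n_mm = 2), "seed")
})

test_that("cohort tables are mutually consistent and within configured ranges", {
  cfg <- cohort_config(seed = 77)
  cohort <- generate_cohort(cfg)
  expect_setequal(unique(cohort$metadata$group),
                  c("volunteer", "MGUS", "MM"))
  expect_equal(nrow(cohort$metadata), 2 * (7 + 11 + 12))
  expect_true(all(cohort$intensities$sample_id %in%
                    cohort$metadata$sample_id))
  expect_true(all(cohort$truth$f_true > 0 & cohort$truth$f_true < 1))
  vol <- cohort$plasma_enrichment$subject_id %in%
    cohort$metadata$subject_id[cohort$metadata$group == "volunteer"]
  expect_true(all(cohort$plasma_enrichment$enrichment[vol] > 0.02 &
                    cohort$plasma_enrichment$enrichment[vol] < 0.12))
  expect_true(all(cohort$concentrations$concentration > 0))
  expect_true(all(cohort$intensities$intensity >= 0))
})

test_that("configured group structure appears in the generated cohort", {
  cfg <- cohort_config(seed = 1)
  cohort <- generate_cohort(cfg)
  rec <- recover_cohort(cohort)
  mm <- rec[rec$group == "MM", ]
  mgus <- rec[rec$group == "MGUS", ]
  pat_mm <- merge(mm[mm$fraction == "CD138+",
                     c("subject_id", "metabolite", "f_hat")],
                  mm[mm$fraction == "CD138-",
                     c("subject_id", "metabolite", "f_hat")],
                  by = c("subject_id", "metabolite"),
                  suffixes = c("_pos", "_neg"))
  # MM: all five metabolites labeled higher in CD138+ on average
  sig_mm <- vapply(split(pat_mm, pat_mm$metabolite), function(d)
    paired_group_test(d$f_hat_pos, d$f_hat_neg)$p, numeric(1))
  expect_gte(sum(sig_mm < 0.05), 4)
  # MGUS: aspartate carries the configured effect, others are near-null
  pat_mg <- merge(mgus[mgus$fraction == "CD138+",
                       c("subject_id", "metabolite", "f_hat")],
                  mgus[mgus$fraction == "CD138-",
                       c("subject_id", "metabolite", "f_hat")],
                  by = c("subject_id", "metabolite"),
                  suffixes = c("_pos", "_neg"))
  sig_mg <- vapply(split(pat_mg, pat_mg$metabolite), function(d)
    paired_group_test(d$f_hat_pos, d$f_hat_neg)$p, numeric(1))
  expect_lt(sig_mg[["aspartate"]], 0.05)
  expect_lte(sum(sig_mg[setdiff(names(sig_mg), "aspartate")] < 0.05), 1)
  ratio_null <- pat_mg[pat_mg$metabolite != "aspartate", ]
  gm <- exp(mean(log(ratio_null$f_hat_pos / ratio_null$f_hat_neg)))
  expect_gt(gm, 0.8); expect_lt(gm, 1.25)
})

test_that("concentrations rise with marrow plasma-cell percentage as configured", {
  cfg <- cohort_config(seed = 19)
  cohort <- generate_cohort(cfg)
  gc <- cohort$concentrations
  gc <- gc[gc$platform == "GC-MS" & gc$group %in% c("MGUS", "MM"), ]
  glu <- gc[gc$analyte == "glutamate", ]
  cc <- correlate(glu$bmpc_percent, glu$concentration)
  expect_gt(cc$slope, 0)
  expect_gt(cc$r, 0.5)
  gln <- gc[gc$analyte == "glutamine", ]
  expect_lt(correlate(gln$bmpc_percent, gln$concentration)$slope, 0)
  # MM group sits at higher tumor burden, hence higher glutamate
  expect_gt(median(glu$concentration[glu$group == "MM"]),
            median(glu$concentration[glu$group == "MGUS"]))
})

test_that("infusion timecourse rises to plateau within the rise time", {
  tc <- generate_enrichment_timecourse(0.05, n_timepoints = 13,
                                       jitter_cv = 0)
  after <- tc$enrichment[tc$time_min >= 15]
  expect_true(all(after == 0.05))
  expect_equal(tc$enrichment[1], 0)
  expect_error(generate_enrichment_timecourse(0.05, n_timepoints = 1),
               "at least 2")
  set.seed(61)
  plateaus <- runif(20, 0.04, 0.10)
  for (p in plateaus) {
    tc <- generate_enrichment_timecourse(p, jitter_cv = 0.02)
    expect_true(all(tc$enrichment[tc$time_min >= 15] > 0.03 &
                      tc$enrichment[tc$time_min >= 15] < 0.12))
  }
})
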