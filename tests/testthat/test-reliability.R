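test_that("repetition mean and SD use the sample (n-1) convention", {
  r <- rep_mean_sd(c(140, 140, 140, 140, 140))
  expect_equal(c(r$mean, r$sd), c(140, 0))
  r <- rep_mean_sd(c(138, 139, 140, 141, 142))
  expect_equal(r$mean, 140)
  expect_equal(r$sd, sqrt(10 / 4), tolerance = 1e-12)  # 1.5811...
  expect_error(rep_mean_sd(140), "2 repetitions")
})

test_that("repeatability table averages within-repetition SDs over cells", {
  sheet <- expand.grid(subject = 1:2, rater = 1:2, rep = 1:5)
  sheet$angle_id <- "cervical_flexion"
  sheet$measured_rom_deg <- 60
  tab <- repeatability_table(sheet, catalog = CATALOG)
  expect_equal(tab$mean_sd_measurements, 0)
  # two cells with per-cell SDs 2 and 4 average to 3
  s2 <- data.frame(subject = rep(1:2, each = 3), rater = 1,
                   angle_id = "cervical_flexion", rep = rep(1:3, 2),
                   measured_rom_deg = c(58, 60, 62, 56, 60, 64))
  tab2 <- repeatability_table(s2, catalog = CATALOG)
  expect_equal(tab2$mean_sd_measurements, 3)
  # sides pool into one examination-angle family
  s3 <- rbind(
    data.frame(subject = 1, rater = 1, angle_id = "knee_flexion_L",
               rep = 1:2, measured_rom_deg = c(140, 142)),
    data.frame(subject = 1, rater = 1, angle_id = "knee_flexion_R",
               rep = 1:2, measured_rom_deg = c(139, 145)))
  tab3 <- repeatability_table(s3, catalog = CATALOG)
  expect_identical(nrow(tab3), 1L)
  expect_equal(tab3$mean_sd_measurements,
               mean(c(stats::sd(c(140, 142)), stats::sd(c(139, 145)))))
})

test_that("ICC(3,k) matches an independent two-way ANOVA oracle", {
  set.seed(11)
  for (i in 1:100) {
    m <- matrix(stats::rnorm(60, 100, 10), 20, 3) +
      matrix(stats::rnorm(20, 0, 5), 20, 3)  # add subject effects
    expect_equal(suppressWarnings(icc_3k(m)$icc_3k), icc_3k_oracle(m),
                 tolerance = 1e-10)
  }
})

test_that("ICC(3,k) limiting and degenerate cases", {
  # identical rater columns with subject variance: perfect reliability
  m <- matrix(rep(c(10, 20, 30, 40), 3), 4, 3)
  expect_equal(icc_3k(m)$icc_3k, 1)
  # adding a constant to one rater changes nothing (consistency ICC)
  m2 <- m; m2[, 2] <- m2[, 2] + 7
  expect_equal(icc_3k(m2)$icc_3k, 1)
  # permuting subjects changes nothing
  set.seed(12)
  m3 <- matrix(stats::rnorm(30, 50, 8), 10, 3)
  expect_equal(icc_3k(m3)$icc_3k, icc_3k(m3[sample(10), ])$icc_3k,
               tolerance = 1e-12)
  # no subject variance: undefined, flagged not thrown
  flat <- matrix(5, 4, 3)
  r <- icc_3k(flat)
  expect_true(r$undefined)
  expect_true(is.nan(r$icc_3k))
  # negative estimates (interaction noise swamps subject variance) come
  # back raw with a warning
  neg <- rbind(c(10, 20), c(12, 9), c(11, 14))
  expect_warning(rn <- icc_3k(neg), "negative")
  expect_lt(rn$icc_3k, 0)
})

test_that("Bland-Altman statistics follow the direct formulas", {
  m <- cbind(a = c(10, 20, 30), b = c(10, 20, 30))
  r <- bland_altman(m, c("a", "b"))
  expect_equal(c(r$mdiff, r$loa_low, r$loa_high), c(0, 0, 0))
  # constant offset: exact MDiff, zero-width LOA, strict 5-degree rule
  m2 <- cbind(a = c(10, 20, 30), b = c(15, 25, 35))
  r2 <- bland_altman(m2, c("a", "b"))
  expect_equal(r2$mdiff, -5)
  expect_equal(r2$sd_diff, 0)
  expect_false(r2$mdiff_acceptable)   # |−5| < 5 is false
  # differences -2, 0, 2: SD 2, LOA at +/- 3.92
  m3 <- cbind(a = c(8, 20, 32), b = c(10, 20, 30))
  r3 <- bland_altman(m3, c("a", "b"))
  expect_equal(c(r3$mdiff, r3$sd_diff), c(0, 2))
  expect_equal(c(r3$loa_low, r3$loa_high), c(-3.92, 3.92))
  # antisymmetry
  r4 <- bland_altman(m3, c("b", "a"))
  expect_equal(r4$mdiff, -r3$mdiff)
  expect_equal(r4$loa_low, -r3$loa_high)
  expect_error(bland_altman(m3, c("a", "z")), "not present")
})

test_that("agreement panel enumerates comparisons in the published order", {
  sheet <- expand.grid(subject = 1:5, rater = 1:3, rep = 1:2)
  sheet$angle_id <- "wrist_flexion_L"
  set.seed(13)
  sheet$measured_rom_deg <- 70 + stats::rnorm(nrow(sheet), 0, 5)
  ex <- sheet; names(ex)[names(ex) == "measured_rom_deg"] <- "rating_deg"
  mt <- rating_table(sheet, "wrist_flexion_L")
  et <- rating_table(ex, "wrist_flexion_L")
  panel <- agreement_panel(mt, et)
  expect_length(panel, 9L)  # 3 + C(3,2) + C(3,2)
  expect_identical(vapply(panel, `[[`, "", "comparison"),
                   rep(c("examiner_vs_measurement", "measurement_pair",
                         "examiner_pair"), each = 3))
  # examiner sheet equal to measurements: first-row mdiffs are all zero
  expect_true(all(abs(vapply(panel[1:3], `[[`, 0, "mdiff")) < 1e-12))
  # k = 2 gives 2 + 1 + 1 comparisons
  s2 <- sheet[sheet$rater <= 2, ]; e2 <- ex[ex$rater <= 2, ]
  panel2 <- agreement_panel(rating_table(s2, "wrist_flexion_L"),
                            rating_table(e2, "wrist_flexion_L"))
  expect_length(panel2, 4L)
})

test_that("rating tables drop incomplete subjects and count them", {
  sheet <- expand.grid(subject = 1:5, rater = 1:3, rep = 1:2)
  sheet$angle_id <- "hip_flexion_L"
  sheet$measured_rom_deg <- 120
  sheet <- sheet[!(sheet$subject == 4 & sheet$rater == 2), ]
  tab <- rating_table(sheet, "hip_flexion_L")
  expect_identical(nrow(tab$values), 4L)
  expect_identical(tab$n_dropped, 1L)
  expect_false(4 %in% tab$subject_ids)
})

test_that("validity flags compare cohort means to both references", {
  f <- validity_flags(c(cervical_rotation_L = 75), CATALOG)
  expect_identical(f$flag_ref1, "below")   # range 80..80
  expect_identical(f$flag_ref2, "above")   # minimum expectation 70
  f2 <- validity_flags(c(elbow_supination_L = 47), CATALOG)
  expect_identical(unname(unlist(f2[c("flag_ref1", "flag_ref2")])),
                   c("below", "below"))
  # boundary is inclusive
  f3 <- validity_flags(c(cervical_rotation_L = 70), CATALOG)
  expect_identical(f3$flag_ref2, "within")
  f4 <- validity_flags(c(hip_lateral_rotation_L = 38), CATALOG)
  expect_identical(f4$flag_ref1, "within")  # range 35..40
})
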