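test_that("accumulation curve honours its boundary and limit conditions", {
  profs <- default_food_profiles()
  for (p in profs) {
    expect_equal(accumulation_curve(p, 0), p$c0, label = p$food)
  }
  # day-30 means equal the study's reported peaks
  expect_equal(round(accumulation_curve(profs$chili, 30), 2), 869.82)
  expect_equal(round(accumulation_curve(profs$corn, 30), 2), 308.24)
  expect_equal(round(accumulation_curve(profs$tofu, 30), 2), 265.70)
  expect_equal(round(accumulation_curve(profs$pork, 30), 2), 141.59)
  expect_error(accumulation_curve(profs$corn, -1), "non-negative")
})

test_that("dip-free curves increase monotonically and speed up with rate", {
  p <- food_profile("x", c0 = 5, c_peak = 100, rate = 0.1,
                    rba_range = c(0.02, 0.1))
  grid <- seq(0, 30, by = 0.5)
  expect_true(all(diff(accumulation_curve(p, grid)) > 0))
  p2 <- food_profile("x", c0 = 5, c_peak = 100, rate = 0.2,
                     rba_range = c(0.02, 0.1))
  expect_true(all(accumulation_curve(p2, grid[-1]) >
                    accumulation_curve(p, grid[-1])))
  # the chili-like dip lowers the curve only inside its window
  pd <- food_profile("x", c0 = 5, c_peak = 100, rate = 0.2,
                     rba_range = c(0.02, 0.1),
                     dip = list(start_day = 20, depth = 0.1))
  expect_equal(accumulation_curve(pd, c(0, 10, 19, 26, 30)),
               accumulation_curve(p2, c(0, 10, 19, 26, 30)))
  expect_lt(accumulation_curve(pd, 22.5), accumulation_curve(p2, 22.5))
})

test_that("concentration table has the study shape and honours noise", {
  design <- study_design()
  tab <- generate_concentration_table(design, seed = 7)
  expect_equal(nrow(tab), 4 * 7 * 3)  # 84 records as in the study
  expect_identical(tab, generate_concentration_table(design, seed = 7))

  quiet <- study_design(noise_cv = 0)
  tq <- generate_concentration_table(quiet, seed = 1)
  for (p in quiet$foods) {
    sub <- tq[tq$food == p$food, ]
    expect_equal(sub$concentration,
                 accumulation_curve(p, sub$roast_day), tolerance = 1e-12)
  }

  # oversampled replicates recover the curve by the law of large numbers
  big <- study_design(foods = default_food_profiles()["corn"],
                      days = c(0, 15, 30), replicates = 1000)
  tb <- generate_concentration_table(big, seed = 3)
  means <- tapply(tb$concentration, tb$roast_day, mean)
  curve <- accumulation_curve(default_food_profiles()$corn, c(0, 15, 30))
  expect_lt(max(abs(means - curve) / curve), 0.01)
})

test_that("intake survey draws are seeded and recover their ground truth", {
  spec <- list(chili = list(family = "gumbel_max",
                            params = c(location = 0.025, scale = 0.01)))
  s <- generate_intake_survey(spec, 2000, seed = 6, group = "children")
  expect_equal(nrow(s), 2000)
  fit <- fit_mle(s$intake_kg_per_day, "gumbel_max")
  rel <- abs(fit$params - spec$chili$params) / spec$chili$params
  expect_lt(max(rel), 0.05)

  clamped <- generate_intake_survey(spec, 500, seed = 6,
                                    clamp = list(chili = c(0.002, 0.08)))
  expect_true(all(clamped$intake_kg_per_day >= 0.002 &
                    clamped$intake_kg_per_day <= 0.08))
  empty <- generate_intake_survey(spec, 0, seed = 1)
  expect_equal(nrow(empty), 0L)
})

test_that("inverted transport assays reproduce their RBA targets exactly", {
  prof <- default_food_profiles()$chili
  conc <- data.frame(food = "chili", roast_day = 0, replicate = 1:3,
                     concentration = c(8.56, 8.56, 8.56))
  assays <- generate_transport_assays(
    prof, conc, target_rba_by_day = c("0" = 0.0218))
  got <- vapply(seq_len(nrow(assays)), function(i) {
    as.numeric(relative_bioavailability(assays[i, ]))
  }, numeric(1))
  expect_equal(got, rep(0.0218, 3), tolerance = 1e-9)

  # target 0 means no depletion
  z <- generate_transport_assays(prof, conc, target_rba_by_day = c("0" = 0))
  expect_equal(z$c_av, z$c_iv)

  # infeasible explicit c_iv is rejected with the required floor
  expect_error(
    generate_transport_assays(prof, conc, target_rba_by_day = c("0" = 0.5),
                              c_iv = 0.1),
    "c_iv >=")

  # noisy assays scatter around the target: group mean within 3 SE at n = 50
  conc50 <- data.frame(food = "chili", roast_day = 0, replicate = 1:50,
                       concentration = rep(100, 50))
  noisy <- generate_transport_assays(prof, conc50,
                                     target_rba_by_day = c("0" = 0.05),
                                     seed = 9, noise_sd = 0.02)
  rbas <- vapply(seq_len(nrow(noisy)), function(i) {
    as.numeric(relative_bioavailability(noisy[i, ]))
  }, numeric(1))
  se <- sd(rbas) / sqrt(length(rbas))
  expect_lt(abs(mean(rbas) - 0.05), 3 * se)
})

test_that("study bundles are byte-identical under one seed", {
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  design <- study_design(survey_n = 50)
  b1 <- study_bundle(31, d1, design)
  b2 <- study_bundle(31, d2, design)
  for (nm in names(b1$paths)) {
    expect_identical(readLines(b1$paths[[nm]]), readLines(b2$paths[[nm]]),
                     label = nm)
  }
  b3 <- study_bundle(32, file.path(tempdir(), "bundle_c"), design)
  expect_false(identical(readLines(b1$paths$foods),
                         readLines(b3$paths$foods)))
})

test_that("pipeline on a noise-free bundle recovers the manifest truth", {
  dir <- file.path(tempdir(), "bundle_exact")
  design <- study_design(noise_cv = 0, survey_n = 0)
  b <- study_bundle(5, dir, design)
  bio <- summarize_bioavailability(read_assays_csv(b$paths$assays),
                                   read_foods_csv(b$paths$foods))
  for (i in seq_len(nrow(bio))) {
    target <- b$truth$rba_targets[[bio$food[i]]][[as.character(bio$roast_day[i])]]
    expect_equal(bio$rba[i], target, tolerance = 1e-9,
                 label = sprintf("%s day %d", bio$food[i], bio$roast_day[i]))
  }
})
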