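test_that("average daily dose matches hand arithmetic and cancels EF/AT", {
  p <- population_parameters("children", "corn")
  expect_equal(average_daily_dose(308.24, p), 308.24 * 0.010 / 25.9,
               tolerance = 1e-12)
  expect_equal(average_daily_dose(0, p), 0)
  # with EF = 365 and AT = ED*365 the dose reduces to C*IR/BW for any ED
  for (ed in c(1, 9, 37.5, 100)) {
    q <- exposure_parameters(ir = 0.02, bw = 60, ed = ed)
    expect_equal(average_daily_dose(50, q), 50 * 0.02 / 60, tolerance = 1e-12)
  }
})

test_that("hazard quotient is ADD/RfD with the at-risk flag at 1", {
  expect_equal(as.numeric(hazard_quotient(0.06, 0.06)), 1)
  expect_true(attr(hazard_quotient(0.06, 0.06), "at_risk"))
  expect_false(attr(hazard_quotient(0.059, 0.06), "at_risk"))
  expect_error(hazard_quotient(0.1, 0), "rfd")
})

test_that("peak-stage point HQs reproduce the self-consistent study values", {
  expect_equal(round(as.numeric(point_hq(308.24, population_parameters("children", "corn"))), 2),
               1.98)
  expect_equal(round(as.numeric(point_hq(141.59, population_parameters("adults", "pork"))), 2),
               2.78)
})

test_that("HQ is linear in concentration and intake separately", {
  p <- population_parameters("adults", "chili")
  h1 <- as.numeric(point_hq(100, p))
  expect_equal(as.numeric(point_hq(200, p)), 2 * h1, tolerance = 1e-12)
  p2 <- exposure_parameters(ir = 2 * p$ir, bw = p$bw, ed = p$ed, ef = p$ef,
                            at = p$at, rfd = p$rfd)
  expect_equal(as.numeric(point_hq(100, p2)), 2 * h1, tolerance = 1e-12)
})

test_that("hazard index sums HQs and rejects mixed groups/stages", {
  expect_equal(as.numeric(hazard_index(c(0.5, 0.25, 0.125, 0.125))), 1)
  expect_equal(as.numeric(hazard_index(0.7)), 0.7)
  df <- data.frame(hq = c(1, 2), group = c("children", "adults"),
                   roast_day = c(0, 0))
  expect_error(hazard_index(df), "single group")
  # fresh-food children HI from initial concentrations and median intakes
  fresh <- c(corn = 1.72, chili = 8.56, pork = 6.47, tofu = 6.19)
  hqs <- vapply(names(fresh), function(f) {
    as.numeric(point_hq(fresh[[f]], population_parameters("children", f)))
  }, numeric(1))
  expect_equal(round(as.numeric(hazard_index(hqs)), 2), 0.35)
})

test_that("contribution shares normalise, obey symmetry and the day-30 value", {
  expect_equal(unname(contribution_shares(c(1, 1, 1, 1))),
               rep(0.25, 4))
  expect_equal(unname(contribution_shares(c(a = 0, b = 3))), c(0, 1))
  expect_error(contribution_shares(c(0, 0)), "zero")
  # absorbed day-30 doses weighted by adult median intakes: chili share 0.73
  absorbed <- c(chili = 97.97, corn = 21.71, pork = 12.87, tofu = 30.97)
  ir <- c(chili = 0.056, corn = 0.021, pork = 0.067, tofu = 0.023)
  sh <- contribution_shares(absorbed * ir)
  expect_equal(sum(sh), 1, tolerance = 1e-12)
  expect_equal(round(sh[["chili"]], 2), 0.73)
})

test_that("ir_max reproduces printed intake limits for fresh and peak stages", {
  groups <- list(children = c(corn = 1.72, chili = 8.56, pork = 6.47, tofu = 6.19),
                 adults   = c(corn = 1.72, chili = 8.56, pork = 6.47, tofu = 6.19))
  # fresh-food limits (kg/d, 2 d.p.); corn values reflect exact arithmetic
  fresh_expect <- list(children = c(corn = 0.90, chili = 0.18, pork = 0.24, tofu = 0.25),
                       adults   = c(corn = 1.98, chili = 0.40, pork = 0.53, tofu = 0.55))
  peak <- c(corn = 308.24, chili = 869.82, pork = 141.59, tofu = 265.70)
  peak_expect <- list(children = c(corn = 0.005, chili = 0.002, pork = 0.011, tofu = 0.006),
                      adults   = c(corn = 0.011, chili = 0.004, pork = 0.024, tofu = 0.013))
  for (g in names(groups)) {
    for (f in names(groups[[g]])) {
      p <- population_parameters(g, f)
      expect_equal(round(ir_max(groups[[g]][[f]], p), 2),
                   fresh_expect[[g]][[f]],
                   label = sprintf("fresh %s %s", g, f))
      expect_equal(round(ir_max(peak[[f]], p), 3), peak_expect[[g]][[f]],
                   label = sprintf("peak %s %s", g, f))
    }
  }
})

test_that("ir_max inversion identity and RBA scaling hold", {
  p <- population_parameters("adults", "chili")
  for (target in c(0.5, 1, 2)) {
    ir <- ir_max(300, p, hq_target = target)
    p_ir <- exposure_parameters(ir = ir, bw = p$bw, ed = p$ed, ef = p$ef,
                                at = p$at, rfd = p$rfd)
    expect_equal(as.numeric(point_hq(300, p_ir)), target, tolerance = 1e-12)
  }
  base <- ir_max(300, p)
  for (r in c(0.02, 0.1, 0.5, 1)) {
    expect_equal(ir_max(300, p, rba = r), base / r, tolerance = 1e-12)
  }
  expect_equal(ir_max(300, p, rba = 1), base)
  expect_error(ir_max(300, p, rba = 0), "rba")
  expect_error(ir_max(0, p), "c")
})
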