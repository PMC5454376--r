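test_that("CSP follows the averaged weighted form and is symmetric", {
  expect_equal(compute_csp(8.0, 120, 8.0, 120), 0)
  # dH = 0.10, dN = 0.50, weight 0.2, averaging: sqrt((0.01+0.01)/2) = 0.1
  expect_equal(compute_csp(8.1, 120.5, 8.0, 120.0), 0.1)
  expect_equal(compute_csp(8.1, 120.5, 8.0, 120.0, averaging = FALSE),
               0.1 * sqrt(2))
  withr::with_seed(1, {
    for (i in 1:25) {
      a <- c(rnorm(1, 8, 0.5), rnorm(1, 119, 4))
      b <- c(rnorm(1, 8, 0.5), rnorm(1, 119, 4))
      expect_equal(compute_csp(a[1], a[2], b[1], b[2]),
                   compute_csp(b[1], b[2], a[1], a[2]))
    }
  })
  expect_true(is.na(compute_csp(NA, 120, 8.0, 120)))
})

test_that("intensity normalization fixes the reference at 1 and is scale invariant", {
  st <- grid_shift_table(10)
  st$residue_number[10] <- 354
  pl <- as_peaklist(st, intensity = c(6.0e6, rep(1e6, 8), 2.0e6))
  norm <- normalize_intensities(pl)
  expect_equal(norm$intensity[1], 3.0)
  expect_equal(norm$intensity[10], 1.0)
  scaled <- pl; scaled$intensity <- scaled$intensity * 17.3
  expect_equal(normalize_intensities(scaled)$intensity, norm$intensity)
  missing_ref <- pl[1:9, ]
  expect_error(normalize_intensities(missing_ref), "354")
})

test_that("intensity ratios floor at exactly 100 below 1% of free", {
  expect_identical(compute_iratio(1.0, 0.005), 100)
  expect_equal(compute_iratio(1.0, 1.0), 1.0)
  expect_equal(compute_iratio(1.0, 0.25), 4.0)
  expect_identical(compute_iratio(1.0, 0), 100)
  expect_identical(compute_iratio(1.0, NA, lost = TRUE), 100)
  expect_true(is.na(compute_iratio(NA, 0.5)))
  expect_true(is.na(compute_iratio(1.0, NA, lost = FALSE)))
})

test_that("median-multiple classes follow the 3/5/10 rule on the linear scale", {
  cls <- classify(c(1, 1, 1, 1, 35))
  expect_equal(as.character(cls), c(rep("below", 4), "strong"))
  expect_equal(attr(cls, "median"), 1)
  expect_equal(as.character(classify(rep(2.5, 6))), rep("below", 6))
  # floored ratio of 100 against median 3 exceeds 10 M
  cls2 <- classify(c(3, 3, 3, 100))
  expect_equal(as.character(cls2)[4], "strong")
  # boundary reading: thresholds are strict, so 3M is below, 5M weak, 10M medium
  cls3 <- classify(c(1, 1, 1, 1, 3, 5, 10))
  expect_equal(as.character(cls3), c(rep("below", 4), "below", "weak",
                                     "medium"))
  expect_equal(as.character(classify(c(NA, 1, 9)))[1], "no_data")
  expect_warning(classify(c(0, 0, 0)), "median")
})

test_that("classification is monotone in the metric", {
  withr::with_seed(7, {
    vals <- rlnorm(40, 0, 1)
    cls <- classify(vals)
    for (i in seq(5, 40, by = 7)) {
      bumped <- vals
      bumped[i] <- bumped[i] * 1.5
      cls2 <- classify(bumped)
      expect_gte(as.integer(cls2[i]), as.integer(cls[i]))
    }
  })
})

test_that("composite class takes the larger, treating no_data as absence", {
  lv <- function(x) factor(x, levels = c("no_data", "below", "weak",
                                         "medium", "strong"), ordered = TRUE)
  expect_equal(as.character(composite_class(lv("weak"), lv("strong"))), "strong")
  expect_equal(as.character(composite_class(lv("no_data"), lv("medium"))), "medium")
  expect_equal(as.character(composite_class(lv("no_data"), lv("no_data"))), "no_data")
  expect_equal(as.character(composite_class(lv(c("weak", "strong")),
                                            lv(c("below", "no_data")))),
               c("weak", "strong"))
})

test_that("profile correlation matches an independent sum-formula oracle", {
  make_rec <- function(ir) {
    r <- data.frame(residue_number = seq_along(ir), residue_type = "A",
                    atom_group = "backbone-amide", csp = NA_real_,
                    i_free_norm = 1, i_bound_norm = 1 / ir, i_ratio = ir,
                    lost = FALSE)
    class(r) <- c("perturbation_records", "data.frame")
    r
  }
  withr::with_seed(3, {
    ir <- rlnorm(60, log(3), 0.5)
    a <- make_rec(ir)
    expect_equal(correlate_profiles(a, a)$r, 1.0)
    b <- make_rec(1 / ir)   # log10 ratios exactly negated
    expect_equal(correlate_profiles(a, b)$r, -1.0)
    ir2 <- ir * rlnorm(60, 0, 0.3)
    c2 <- make_rec(ir2)
    got <- correlate_profiles(a, c2)
    expect_equal(got$r, oracle_pearson(log10(ir), log10(ir2)),
                 tolerance = 1e-12)
    expect_equal(got$n, 60)
  })
  expect_error(correlate_profiles(make_rec(c(1, 2)), make_rec(c(1, 2))),
               "fewer than 3")
})

test_that("intensity-decrease summary reports the median attenuation", {
  rec <- data.frame(i_free_norm = rep(1, 5), i_bound_norm = rep(1, 5),
                    i_ratio = rep(1, 5))
  expect_equal(summarize_intensity_decrease(rec)$percent_decrease, 0)
  rec$i_bound_norm <- 1 / 3; rec$i_ratio <- 3
  s <- summarize_intensity_decrease(rec)
  expect_equal(s$percent_decrease, 100 * (1 - 1 / 3))
  expect_equal(s$median_iratio, 3)
  rec$i_bound_norm <- 0.85; rec$i_ratio <- 1 / 0.85
  expect_equal(summarize_intensity_decrease(rec)$percent_decrease, 15)
})

test_that("raw intensity scale cancels end to end", {
  st <- gen_shift_table(60, seed = 9)
  pair <- gen_peaklist_pair(st, default_profile("givct"), seed = 10)
  rec1 <- classify_records(perturbation_records(pair$free, pair$bound))
  f2 <- pair$free; f2$intensity <- f2$intensity * 3.7e6
  b2 <- pair$bound; b2$intensity <- b2$intensity * 0.021
  rec2 <- classify_records(perturbation_records(f2, b2))
  expect_equal(rec2$i_ratio, rec1$i_ratio)
  expect_identical(as.character(rec2$composite_class),
                   as.character(rec1$composite_class))
})

test_that("records treat residues missing from the bound list as broadened", {
  st <- grid_shift_table(12)
  st$residue_number[12] <- 354
  free <- as_peaklist(st, intensity = c(rep(2, 11), 1))
  bound <- as_peaklist(st[-3, ], intensity = c(rep(1, 10), 1))
  rec <- perturbation_records(free, bound)
  r3 <- rec[rec$residue_number == st$residue_number[3], ]
  expect_true(r3$lost)
  expect_identical(r3$i_ratio, 100)
  expect_true(is.na(r3$csp))
  expect_equal(rec$i_ratio[rec$residue_number == st$residue_number[1]], 2)
})

test_that("shifted fraction is reported per threshold", {
  fr <- shifted_fraction(c(rep(1, 8), 4, 100))
  expect_equal(unname(fr[">3M"]), 0.2)
  expect_equal(unname(fr[">10M"]), 0.1)
})
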