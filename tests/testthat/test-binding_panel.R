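conc8 <- c(0, 0.125, 0.25, 0.5, 1, 2, 4, 8)
hyper <- function(conc, kd, rmin = 20, rmax = 180) {
  rmin + (rmax - rmin) * conc / (kd + conc)
}

test_that("one-site fits recover exact parameters from noiseless curves", {
  f <- fit_kd(conc8, hyper(conc8, 1.0))
  expect_equal(f$kd, 1.0, tolerance = 1e-6)
  expect_equal(f$response_min, 20, tolerance = 1e-4)
  expect_equal(f$response_max, 180, tolerance = 1e-4)
  expect_true(f$reliable)
})

test_that("a weak binder sampled far from its plateau is flagged non-saturating", {
  f <- fit_kd(conc8, hyper(conc8, 50))
  expect_equal(f$kd, 50, tolerance = 1e-4)
  expect_false(f$saturating)
  expect_true(fit_kd(conc8, hyper(conc8, 0.3))$saturating)
})

test_that("Kd is invariant to affine rescaling of the responses", {
  withr::with_seed(11, {
    y <- hyper(conc8, 0.7) * exp(rnorm(8, 0, 0.02))
    f1 <- fit_kd(conc8, y)
    f2 <- fit_kd(conc8, 3.1 * y + 40)
    expect_equal(f2$kd, f1$kd, tolerance = 1e-6)
  })
})

test_that("curve preconditions are enforced", {
  expect_error(fit_kd(c(0, 1, 2, 4), hyper(c(0, 1, 2, 4), 1)), "at least 5")
  expect_error(fit_kd(c(0, 1, 1, 2, 4), rep(1, 5)), "unique")
})

test_that("WT-plateau normalization rescales to 100 and refits shared plateaus", {
  curves <- rbind(
    data.frame(variant = "WT", conc_uM = conc8,
               response = hyper(conc8, 0.2)),
    data.frame(variant = "M1", conc_uM = conc8,
               response = hyper(conc8, 0.5)),
    data.frame(variant = "M2", conc_uM = conc8,
               response = hyper(conc8, 30)))
  r <- normalize_to_wt_max(curves)
  wt <- r$fits[r$fits$variant == "WT", ]
  expect_equal(wt$response_max, 100, tolerance = 1e-4)
  expect_equal(max(abs(r$curves$response[r$curves$variant == "WT"] -
                         curves$response[curves$variant == "WT"] / 1.8)), 0,
               tolerance = 1e-3)
  m2 <- r$fits[r$fits$variant == "M2", ]
  expect_true(m2$shared_plateau)
  expect_equal(m2$response_max, 100)
  expect_equal(m2$kd, 30, tolerance = 0.05)
  # a saturating mutant agrees between free and shared-plateau fits
  m1_free <- fit_kd(conc8, r$curves$response[r$curves$variant == "M1"])
  m1_shared <- fit_kd(conc8, r$curves$response[r$curves$variant == "M1"],
                      fix_rmax = 100)
  expect_equal(m1_free$kd, m1_shared$kd, tolerance = 0.01)
  expect_error(normalize_to_wt_max(curves[curves$variant != "WT", ]), "WT")
  weak_wt <- curves
  weak_wt$response[weak_wt$variant == "WT"] <- hyper(conc8, 60)
  expect_error(normalize_to_wt_max(weak_wt), "saturation")
})

test_that("Kd matrices use strict 2-fold boundaries with neutral edges", {
  fits <- data.frame(variant = c("WT", "M1", "M2", "M3", "M4"),
                     ligand = "GIV",
                     kd = c(1, 2.0, 2.01, 0.5, 0.49),
                     reliable = TRUE)
  mat <- build_kd_matrix(fits)
  expect_equal(mat$log2_ratio[mat$variant == "WT"], 0)
  expect_equal(mat$fold_class,
               c("neutral", "neutral", "impaired", "neutral", "enhanced"))
  fits$reliable[3] <- FALSE
  mat2 <- build_kd_matrix(fits)
  expect_true(is.na(mat2$fold_class[3]))
  expect_equal(nrow(attr(mat2, "excluded")), 1)
  expect_error(build_kd_matrix(fits[fits$variant != "WT", ]), "wild type")
})

test_that("cross-ligand effect correlation excludes WT and needs 3 mutants", {
  fits <- rbind(
    data.frame(variant = c("WT", "M1", "M2", "M3"), ligand = "GIV",
               kd = c(1, 2, 4, 0.5), reliable = TRUE),
    data.frame(variant = c("WT", "M1", "M2", "M3"), ligand = "DAPLE",
               kd = c(2, 4, 8, 1), reliable = TRUE))
  mat <- build_kd_matrix(fits)
  r <- correlate_mutant_effects(mat, "GIV", "DAPLE")
  expect_equal(r$r, 1.0)
  expect_equal(r$n, 3)
  expect_error(correlate_mutant_effects(mat[mat$variant %in% c("WT", "M1", "M2"), ],
                                        "GIV", "DAPLE"), "fewer than 3")
})

test_that("activation and inhibition follow the percent-of-basal conventions", {
  a <- compute_activation(c(100, 250, 100), c(100, 100, 0))
  expect_equal(a$activation_delta[1], 0)
  expect_equal(a$percent_basal[2], 250)
  expect_equal(a$activation_delta[2], 150)
  expect_true(a$nd[3])
  expect_true(is.na(a$activation_delta[3]))
  cls <- classify_inhibition(c(150, 0.4 * 150, 90, 75, 110, NA), 150)
  expect_equal(cls$inhibition_percent[2], 60)
  # 50% inhibition is the top of the moderate band; strong is strictly above
  expect_equal(cls$inhibition_class,
               c("none", "strong", "moderate", "moderate", "none", "ND"))
  expect_error(classify_inhibition(50, 0), "positive")
})

test_that("noiseless synthetic panels are recovered exactly and rho is preserved", {
  truth <- gen_panel_truth(n_mutants = 8, rho = 0.9, seed = 31)
  fp <- gen_fp_panel(truth, noise_cv = 0, seed = 32)
  for (lg in truth$ligands) {
    g <- fp[fp$ligand == lg, ]
    for (v in unique(g$variant)) {
      gv <- g[g$variant == v, ]
      f <- fit_kd(gv$conc_uM, gv$response)
      expect_equal(f$kd, unname(truth$kd[v, lg]), tolerance = 1e-5)
    }
  }
  # with zero noise the recovered correlation equals the truth sample
  # correlation of the injected effects
  fits <- do.call(rbind, lapply(split(fp, fp$ligand), function(g) {
    do.call(rbind, lapply(split(g, g$variant), function(gv) {
      data.frame(variant = gv$variant[1], ligand = gv$ligand[1],
                 kd = fit_kd(gv$conc_uM, gv$response)$kd)
    }))
  }))
  mat <- build_kd_matrix(fits)
  r <- correlate_mutant_effects(mat, "GIV", "DAPLE")
  eff <- log2(sweep(truth$kd[-1, ], 2, truth$kd["WT", ], "/"))
  expect_equal(r$r, cor(eff[, 1], eff[, 2]), tolerance = 1e-4)
})
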