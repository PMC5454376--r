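test_that("shift tables are deterministic, complete and reference-isolated", {
  a <- gen_shift_table(250, seed = 7)
  b <- gen_shift_table(250, seed = 7)
  expect_identical(a, b)
  expect_equal(sum(a$atom_group == "backbone-amide"), 250)
  expect_equal(sum(a$atom_group == "trp-indole"), 3)
  expect_true(all(c(131, 211, 258, 354) %in% a$residue_number))
  ref <- which(a$residue_number == 354 & a$atom_group == "backbone-amide")
  d <- scaled_dist(a$w_H[-ref] - a$w_H[ref], a$w_N[-ref] - a$w_N[ref])
  expect_gte(min(d), 0.1)
  expect_gt(min_scaled_spacing(a), 0)
  expect_true(all(a$w_H[a$atom_group == "backbone-amide"] >= 6.5 &
                    a$w_H[a$atom_group == "backbone-amide"] <= 10.5))
})

test_that("a null profile produces identical free and bound lists", {
  st <- gen_shift_table(40, seed = 3)
  prof <- default_profile("givct")
  prof$binding_site <- integer()
  prof$attenuation_median <- 1; prof$attenuation_sigma <- 0
  prof$sigma_H <- 0; prof$sigma_N <- 0; prof$intensity_cv <- 0
  prof$offset_H <- 0; prof$offset_N <- 0
  prof$broadened_out <- integer()
  pair <- gen_peaklist_pair(st, prof, seed = 4)
  expect_equal(pair$free$w_H, pair$bound$w_H)
  expect_equal(pair$free$intensity, pair$bound$intensity)
  rec <- perturbation_records(pair$free, pair$bound)
  expect_true(all(rec$csp == 0))
  expect_true(all(rec$i_ratio == 1))
})

test_that("broadened-out residues are absent from the bound list and floored", {
  st <- gen_shift_table(120, seed = 13)
  pair <- gen_peaklist_pair(st, default_profile("givct"), seed = 14)
  expect_false(any(pair$bound$residue_number %in% c(211, 258)))
  rec <- perturbation_records(pair$free, pair$bound)
  floored <- rec[rec$residue_number %in% c(211, 258), ]
  expect_true(all(floored$i_ratio == 100))
  expect_true(all(floored$lost))
})

test_that("an explicit binding site must exist in the shift table", {
  st <- gen_shift_table(40, seed = 3)
  prof <- default_profile("givct")
  prof$binding_site <- c(st$residue_number[1], 9999)
  expect_error(gen_peaklist_pair(st, prof, seed = 1), "9999")
})

test_that("generators are pure functions of parameters and seed", {
  st <- gen_shift_table(60, seed = 5)
  p <- default_profile("givpept")
  a <- gen_peaklist_pair(st, p, seed = 8)
  b <- gen_peaklist_pair(st, p, seed = 8)
  expect_identical(a$free$w_H, b$free$w_H)
  expect_identical(a$truth$site, b$truth$site)
  t1 <- gen_titration(st, p, seed = 9)
  t2 <- gen_titration(st, p, seed = 9)
  expect_identical(t1$peaklists[[4]]$w_N, t2$peaklists[[4]]$w_N)
})

test_that("truth records score the pipeline without reading generator internals", {
  st <- gen_shift_table(100, seed = 23)
  pair <- gen_peaklist_pair(st, default_profile("givct"), seed = 24)
  tr <- pair$truth
  rec <- perturbation_records(pair$free, pair$bound)
  i <- match(paste0(rec$residue_number, "/", rec$atom_group), tr$delta$key)
  ok <- !rec$lost
  # measured CSP approximates injected magnitude within position noise
  expect_lt(median(abs(rec$csp[ok] - tr$delta$csp[i][ok])), 0.03)
  # measured I_ratio tracks injected attenuation
  expect_lt(median(abs(log(rec$i_ratio[ok]) - log(tr$delta$attenuation[i][ok]))),
            0.25)
})

test_that("the one-site equilibrium matches a numeric root finder", {
  expect_equal(fbound_one_site(32, 32, 10),
               oracle_fbound(32, 32, 10), tolerance = 1e-10)
  expect_equal(fbound_one_site(32, 6.4, 1.5),
               oracle_fbound(32, 6.4, 1.5), tolerance = 1e-10)
  expect_equal(fbound_one_site(32, 32, 1e9), 0, tolerance = 1e-6)
  # saturation is monotone in the molar ratio
  fb <- fbound_one_site(32, 32 * c(0, 0.2, 0.5, 1, 2, 5), 10)
  expect_true(all(diff(fb) > 0))
  expect_equal(fb[1], 0)
})

test_that("titrations move site peaks monotonically toward the bound position", {
  st <- grid_shift_table(20, spacing = 0.6)
  st$residue_number[20] <- 354
  prof <- default_profile("givct")
  prof$binding_site <- st$residue_number[c(3, 7)]
  prof$sigma_H <- 0; prof$sigma_N <- 0; prof$intensity_cv <- 0
  prof$broadened_out <- integer()
  ts <- gen_titration(st, prof, kd_uM = 10, seed = 33)
  tr <- attr(ts, "truth")
  for (rn in prof$binding_site) {
    k <- which(st$residue_number == rn)
    pos <- vapply(ts$peaklists, function(pl) pl$w_H[pl$residue_number == rn], 0)
    dlt <- tr$delta$delta_H[tr$delta$key == paste0(rn, "/backbone-amide")]
    expect_equal(pos, st$w_H[k] + prof$offset_H + tr$f_bound * dlt,
                 tolerance = 1e-10)
    steps <- diff(pos)
    expect_true(all(steps > 0) || all(steps < 0) || dlt == 0)
  }
})

test_that("activity panels propagate dead-basal variants as ND", {
  truth <- gen_panel_truth(n_mutants = 4, basal_dead = "M02", seed = 41)
  act <- gen_activity_panel(truth, seed = 42)
  w <- act[act$ligand == truth$ligands[1], ]
  basal <- w$activity[w$condition == "basal"]
  gef <- w$activity[w$condition == "gef"]
  a <- compute_activation(gef, basal)
  expect_true(a$nd[w$variant[w$condition == "basal"] == "M02"])
  expect_false(any(a$nd[w$variant[w$condition == "basal"] == "WT"]))
})

test_that("the synthetic structure is readable and maps classes per residue", {
  pdb_path <- withr::local_tempfile(fileext = ".pdb")
  gen_synthetic_pdb(pdb_path, n_residues = 60)
  pdb <- bio3d::read.pdb(pdb_path)
  expect_equal(nrow(pdb$atom), 60)
  expect_equal(unique(pdb$atom$elety), "CA")
})
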