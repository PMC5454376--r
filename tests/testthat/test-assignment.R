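test_that("offset estimation is exact on clean displacements", {
  st <- gen_shift_table(80, seed = 21)
  same <- as_peaklist(st)
  est0 <- estimate_offset(same, st)
  expect_equal(est0$delta_H, 0)
  expect_equal(est0$delta_N, 0)
  disp <- st; disp$w_H <- disp$w_H + 0.09; disp$w_N <- disp$w_N - 1.1
  est <- estimate_offset(as_peaklist(disp), st)
  expect_equal(est$delta_H, 0.09)
  expect_equal(est$delta_N, -1.1)
  expect_true(est$reliable)
  expect_gte(est$n_matched, 20)
})

test_that("noisy offset recovery agrees with a brute-force matching oracle", {
  st <- grid_shift_table(7)
  withr::with_seed(31, {
    exp_pl <- st
    exp_pl$w_H <- exp_pl$w_H + 0.09 + rnorm(7, 0, 0.01)
    exp_pl$w_N <- exp_pl$w_N - 1.1 + rnorm(7, 0, 0.05)
    pl <- as_peaklist(exp_pl, assigned = FALSE)
    est <- estimate_offset(pl, st, n_min = 5)
    # oracle: optimal bipartite matching (after removing the coarse
    # median shift), then medians of its residuals
    d <- sqrt(outer(pl$w_H - median(pl$w_H), st$w_H - median(st$w_H), "-")^2 +
                (0.2 * outer(pl$w_N - median(pl$w_N),
                             st$w_N - median(st$w_N), "-"))^2)
    m <- oracle_matching(d, gate = 0.5)$pairs
    expect_equal(est$delta_H,
                 median(pl$w_H[m$row] - st$w_H[m$col]), tolerance = 1e-9)
    expect_equal(est$delta_N,
                 median(pl$w_N[m$row] - st$w_N[m$col]), tolerance = 1e-9)
  })
})

test_that("offset estimation is exactly translation equivariant", {
  st <- gen_shift_table(60, seed = 41)
  withr::with_seed(42, {
    pl <- as_peaklist(st, assigned = FALSE)
    pl$w_H <- pl$w_H + rnorm(nrow(pl), 0, 0.01)
    pl$w_N <- pl$w_N + rnorm(nrow(pl), 0, 0.05)
    base <- estimate_offset(pl, st)
    for (shift in list(c(0.09, -1.1), c(-0.3, 2.0), c(1.5, -6))) {
      moved <- pl
      moved$w_H <- moved$w_H + shift[1]
      moved$w_N <- moved$w_N + shift[2]
      est <- estimate_offset(moved, st)
      expect_equal(est$delta_H, base$delta_H + shift[1])
      expect_equal(est$delta_N, base$delta_N + shift[2])
    }
  })
})

test_that("assignment transfer is complete on well-separated peaks and local", {
  st <- grid_shift_table(25)
  pl <- withr::with_seed(5, {
    p <- as_peaklist(st, assigned = FALSE)
    p$w_H <- p$w_H + rnorm(25, 0, 0.005)
    p$w_N <- p$w_N + rnorm(25, 0, 0.02)
    p
  })
  asn <- transfer_assignments(pl, st, zero_offset())
  expect_equal(attr(asn, "n_transferred"), 25)
  expect_equal(sort(asn$residue_number), st$residue_number)
  # removing one peak only affects its own reference
  asn2 <- transfer_assignments(pl[-7, ], st, zero_offset())
  um <- attr(asn2, "unmatched_reference")
  expect_equal(nrow(um), 1)
  expect_equal(um$reason, "no_candidate")
  expect_equal(attr(asn2, "n_transferred"), 24)
})

test_that("transfer refuses exact ties instead of breaking them", {
  st <- grid_shift_table(4)
  # two references exactly equidistant from one peak
  st$w_H[1] <- 7.4; st$w_N[1] <- 107
  st$w_H[2] <- 7.44; st$w_N[2] <- 107
  pl <- as_peaklist(data.frame(residue_number = 99, residue_type = "A",
                               atom_group = "backbone-amide",
                               w_H = 7.42, w_N = 107,
                               stringsAsFactors = FALSE), assigned = FALSE)
  asn <- transfer_assignments(pl, st[1:2, ], zero_offset())
  expect_equal(attr(asn, "n_transferred"), 0)
  um <- attr(asn, "unmatched_reference")
  expect_setequal(um$reason, "ambiguous")
})

test_that("transfer is independent of experimental row order", {
  st <- gen_shift_table(50, seed = 51)
  pl <- withr::with_seed(52, {
    p <- as_peaklist(st, assigned = FALSE)
    p$w_H <- p$w_H + rnorm(nrow(p), 0, 0.005)
    p$w_N <- p$w_N + rnorm(nrow(p), 0, 0.02)
    p
  })
  asn1 <- transfer_assignments(pl, st, zero_offset())
  perm <- withr::with_seed(53, sample(nrow(pl)))
  asn2 <- transfer_assignments(pl[perm, ], st, zero_offset())
  k1 <- paste(asn1$residue_number, asn1$w_H)
  k2 <- paste(asn2$residue_number, asn2$w_H)
  expect_setequal(k1, k2)
})

test_that("greedy transfer equals the exhaustive assignment oracle when separated", {
  withr::with_seed(61, {
    for (case in 1:20) {
      n <- sample(3:7, 1)
      st <- grid_shift_table(n, spacing = 0.3)
      pl <- as_peaklist(st, assigned = FALSE)
      pl$w_H <- pl$w_H + rnorm(n, 0, 0.01)
      pl$w_N <- pl$w_N + rnorm(n, 0, 0.03)
      asn <- transfer_assignments(pl, st, zero_offset(), r_accept = 0.05)
      d <- sqrt(outer(pl$w_H, st$w_H, "-")^2 +
                  (0.2 * outer(pl$w_N, st$w_N, "-"))^2)
      opt <- oracle_matching(d, gate = 0.05)
      got <- data.frame(row = which(!is.na(asn$residue_number)),
                        col = match(asn$residue_number[!is.na(asn$residue_number)],
                                    st$residue_number))
      got <- got[order(got$row), ]
      expect_equal(nrow(got), nrow(opt$pairs))
      expect_equal(got$col, opt$pairs$col)
    }
  })
})

test_that("stationary peaks track with zero displacement and no losses", {
  st <- grid_shift_table(16)
  st$residue_number[16] <- 354
  pls <- lapply(1:4, function(i) as_peaklist(st, intensity = 1))
  ts <- titration_series(c(0, 0.5, 1, 5), pls)
  trj <- track_titration(ts, pls[[1]])
  expect_false(any(trj$lost))
  ep <- trajectory_endpoints(trj)
  expect_equal(ep$w_H, st$w_H[order(st$residue_number)])
  expect_true(all(is.na(ep$lost_at)))
  expect_lte(length(unique(paste(trj$residue_number, trj$atom_group))),
             nrow(pls[[1]]))
})

test_that("fast-exchange titrations recover the injected end-point shift change", {
  st <- grid_shift_table(30, spacing = 0.5)
  st$residue_number[30] <- 354
  st$residue_type[30] <- "Y"
  prof <- default_profile("givct")
  prof$binding_site <- st$residue_number[c(2, 5, 9)]
  prof$sigma_H <- 0.002; prof$sigma_N <- 0.01
  ts <- gen_titration(st, prof, kd_uM = 10, protein_uM = 32, seed = 71)
  truth <- attr(ts, "truth")
  asn <- transfer_assignments(strip_assignments(ts$peaklists[[1]]), st,
                              zero_offset(),
                              r_accept = 0.4)
  trj <- track_titration(ts, asn, gate = 0.3)
  ep <- trajectory_endpoints(trj)
  f_top <- truth$f_bound[length(truth$f_bound)]
  for (rn in prof$binding_site) {
    i <- which(ep$residue_number == rn)
    j <- which(truth$delta$key == paste0(rn, "/backbone-amide"))
    k <- which(st$residue_number == rn)
    obs_dH <- ep$w_H[i] - (st$w_H[k] + prof$offset_H)
    obs_dN <- ep$w_N[i] - (st$w_N[k] + prof$offset_N)
    expect_equal(obs_dH, f_top * truth$delta$delta_H[j], tolerance = 0.05)
    expect_equal(obs_dN, f_top * truth$delta$delta_N[j], tolerance = 0.1)
  }
})

test_that("stepwise tracking equals the per-step optimal assignment when separated", {
  withr::with_seed(81, {
    for (case in 1:15) {
      n <- sample(3:6, 1)
      st <- grid_shift_table(n, spacing = 0.4)
      move_H <- rnorm(n, 0, 0.01); move_N <- rnorm(n, 0, 0.05)
      pls <- lapply(0:3, function(s) {
        m <- st
        m$w_H <- m$w_H + s * move_H / 3
        m$w_N <- m$w_N + s * move_N / 3
        as_peaklist(m, intensity = 1)
      })
      ts <- titration_series(c(0, 1, 2, 5), pls)
      trj <- track_titration(ts, pls[[1]])
      ep <- trajectory_endpoints(trj)
      # oracle: optimal assignment at each step links each peak to itself
      expect_false(any(trj$lost))
      expect_equal(ep$w_H[order(ep$residue_number)],
                   (st$w_H + move_H)[order(st$residue_number)])
    }
  })
})

test_that("a peak that disappears mid-series is lost and never reacquired", {
  st <- grid_shift_table(9)
  pls <- lapply(1:4, function(i) {
    keep <- if (i >= 3) -2 else seq_len(9)
    as_peaklist(st[keep, ], intensity = 1)
  })
  ts <- titration_series(c(0, 1, 2, 5), pls)
  trj <- track_titration(ts, pls[[1]])
  lost_at <- attr(trj, "lost_at")
  key <- paste0(st$residue_number[2], "/backbone-amide")
  expect_equal(unname(lost_at[key]), 2)
  rows <- trj[trj$residue_number == st$residue_number[2], ]
  expect_true(all(rows$lost[rows$ratio >= 2]))
  expect_true(all(is.na(rows$w_H[rows$ratio >= 2])))
})

test_that("round-trip checking passes clean tracks and flags a swapped endpoint", {
  st <- grid_shift_table(12)
  pls <- lapply(1:3, function(i) as_peaklist(st, intensity = 1))
  ts <- titration_series(c(0, 1, 5), pls)
  asn <- pls[[1]]
  trj <- track_titration(ts, asn)
  top <- trj[trj$ratio == 5 & !trj$lost, ]
  ep <- peaklist(data.frame(label = format_assignment(top$residue_type,
                                                      top$residue_number,
                                                      top$atom_group),
                            residue_number = top$residue_number,
                            residue_type = top$residue_type,
                            atom_group = top$atom_group,
                            w_N = top$w_N, w_H = top$w_H,
                            intensity = top$intensity))
  expect_length(check_tracking_roundtrip(ts, ep, asn), 0)
  # swap two endpoint labels: both must fail the backward check
  sw <- ep
  sw$residue_number[1:2] <- sw$residue_number[2:1]
  bad <- check_tracking_roundtrip(ts, sw, asn)
  expect_setequal(bad, paste0(sw$residue_number[1:2], "/backbone-amide"))
})
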