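# Synthetic data with known ground truth for every pipeline stage. All
# generators are pure functions of (parameters, seed): the global RNG state
# is saved and restored around each call.

#' Shipped region annotation for Galpha-i3
#'
#' G-boxes, switches and secondary-structure elements of Galpha-i3 in
#' UniProt P08754 numbering, used by the default synthetic profiles and the
#' end-to-end demo.
#' @return a `region_annotation` data frame.
#' @export
gai3_regions <- function() {
  read_region_annotation(system.file("extdata", "gai3_regions.tsv",
                                     package = "gbamap", mustWork = TRUE))
}

#' Load a shipped perturbation profile
#'
#' Profiles parameterize [gen_peaklist_pair()]: binding-site segments,
#' CSP magnitude distribution, global lognormal intensity attenuation,
#' signals broadened beyond detection, referencing offsets and noise
#' levels. Two are shipped: `"givct"` (GBA-containing C-terminal
#' construct: median 3-fold attenuation, W211/W258 lost) and `"givpept"`
#' (short GBA peptide: median intensity decrease 15%, same binding site).
#'
#' @param name profile name, or a path to a YAML file of profiles.
#' @return named list of profile parameters.
#' @export
default_profile <- function(name = c("givct", "givpept")) {
  path <- system.file("extdata", "profiles.yaml", package = "gbamap",
                      mustWork = TRUE)
  profiles <- yaml::read_yaml(path)
  if (file.exists(name[1])) {
    profiles <- yaml::read_yaml(name[1])
    name <- names(profiles)[1]
  } else {
    name <- match.arg(name)
  }
  p <- profiles[[name]]
  p$name <- name
  stopifnot(p$shifted_fraction_target < 1)
  if (p$reference_residue %in% p$broadened_out) {
    stop("reference residue may not be broadened out")
  }
  p
}

.amino_acids <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                  "N", "P", "Q", "R", "S", "T", "V", "Y")

.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Generate a plausible amide shift table
#'
#' Draws backbone amide shifts (1H ~ N(8.3, 0.5^2) truncated to
#' [6.5, 10.5] ppm; 15N ~ N(119, 4^2) truncated to [103, 135] ppm) for
#' `n_residues` residues sampled from a protein of `protein_length`
#' residues, always including the reference tyrosine (354) and the three
#' tryptophans (131, 211, 258), whose side-chain indoles are added as
#' three extra entries. The reference tyrosine is redrawn until its signal
#' is isolated (no neighbour within 0.1 scaled ppm), the property that
#' makes it usable as an intensity standard.
#'
#' @param n_residues number of backbone entries (>= 30).
#' @param seed RNG seed.
#' @param protein_length chain length (default 354, Galpha-i3).
#' @return a `shift_table` with `n_residues` backbone + 3 indole rows.
#' @export
gen_shift_table <- function(n_residues = 250, seed, protein_length = 354) {
  stopifnot(n_residues >= 30, n_residues <= protein_length)
  withr::local_seed(seed)
  trp <- c(131, 211, 258); tyr_ref <- protein_length
  forced <- c(trp, tyr_ref)
  pool <- setdiff(seq_len(protein_length), forced)
  resno <- sort(c(forced, sample(pool, n_residues - length(forced))))
  type <- sample(.amino_acids, n_residues, replace = TRUE)
  type[resno %in% trp] <- "W"
  type[resno == tyr_ref] <- "Y"
  bb <- data.frame(residue_number = resno, residue_type = type,
                   atom_group = "backbone-amide",
                   w_H = .rtrunc_norm(n_residues, 8.3, 0.5, 6.5, 10.5),
                   w_N = .rtrunc_norm(n_residues, 119, 4, 103, 135),
                   stringsAsFactors = FALSE)
  # the intensity reference must be an isolated signal
  ref <- which(bb$residue_number == tyr_ref)
  repeat {
    d <- scaled_dist(bb$w_H[-ref] - bb$w_H[ref], bb$w_N[-ref] - bb$w_N[ref])
    if (min(d) >= 0.1) break
    bb$w_H[ref] <- .rtrunc_norm(1, 8.3, 0.5, 6.5, 10.5)
    bb$w_N[ref] <- .rtrunc_norm(1, 119, 4, 103, 135)
  }
  ind <- data.frame(residue_number = trp, residue_type = "W",
                    atom_group = "trp-indole",
                    w_H = .rtrunc_norm(3, 10.1, 0.15, 9.6, 10.6),
                    w_N = .rtrunc_norm(3, 129.4, 0.8, 127, 132),
                    stringsAsFactors = FALSE)
  out <- rbind(bb, ind)
  out <- out[order(out$residue_number, out$atom_group), ]
  rownames(out) <- NULL
  class(out) <- c("shift_table", "data.frame")
  out
}

#' Minimum pairwise scaled distance of a shift table
#'
#' Diagnostic used to build well-separated fixtures for the exact-matching
#' oracle tests.
#' @param shifts a `shift_table` or [peaklist()].
#' @param n_weight nitrogen weight.
#' @export
min_scaled_spacing <- function(shifts, n_weight = 0.2) {
  d2 <- .dist_matrix(shifts$w_H, shifts$w_N, shifts$w_H, shifts$w_N, n_weight)
  diag(d2) <- Inf
  sqrt(min(d2))
}

# Realize the concrete binding site of a profile against a shift table:
# all core-segment residues present in the table, plus a seeded sample of
# peripheral-segment residues topping the site up to
# round(shifted_fraction_target * n_backbone). Consumes RNG draws.
realize_site <- function(profile, shifts, regions = gai3_regions()) {
  if (!is.null(profile$binding_site)) {
    site <- as.integer(profile$binding_site)
    bb <- shifts$residue_number[shifts$atom_group == "backbone-amide"]
    if (!all(site %in% bb)) {
      stop("binding-site residue(s) absent from the shift table: ",
           paste(setdiff(site, bb), collapse = ", "))
    }
    return(sort(site))
  }
  seg_res <- function(names) {
    sel <- regions[regions$name %in% names, ]
    unique(unlist(mapply(seq, sel$start, sel$end, SIMPLIFY = FALSE)))
  }
  bb <- shifts$residue_number[shifts$atom_group == "backbone-amide"]
  core <- intersect(seg_res(profile$core_site_segments), bb)
  peri <- setdiff(intersect(seg_res(profile$peripheral_site_segments), bb), core)
  target <- round(profile$shifted_fraction_target * length(bb))
  extra <- max(0, min(length(peri), target - length(core)))
  site <- sort(c(core, if (extra > 0) sample(peri, extra)))
  setdiff(site, profile$reference_residue)
}

#' Generate a free/bound peak-list pair with ground truth
#'
#' The free list is the shift table displaced by the profile's referencing
#' offsets plus Gaussian position noise, with lognormal intensities around
#' 1 (the reference residue fixed at exactly 1). The bound list adds the
#' binding-site chemical-shift changes (CSP magnitudes lognormal around
#' `csp_median_ppm`, random direction in the scaled plane), divides
#' intensities by per-peak lognormal attenuation factors with median
#' `attenuation_median`, and removes the `broadened_out` residues
#' entirely. Both lists carry their true assignments; use
#' [strip_assignments()] to feed them to the assignment-transfer stage.
#'
#' @param shifts a `shift_table` (see [gen_shift_table()]).
#' @param profile a profile list (see [default_profile()]); an explicit
#'   `binding_site` residue vector overrides the segment-based site and
#'   must be present in the shift table.
#' @param seed RNG seed.
#' @param n_weight nitrogen weight used to draw the 15N component of site
#'   shift changes.
#' @return list with `free` and `bound` [peaklist()]s and `truth`
#'   (realized site, per-residue injected shift changes and CSPs,
#'   attenuation factors, offsets, broadened-out set, reference residue).
#' @export
gen_peaklist_pair <- function(shifts, profile, seed, n_weight = 0.2) {
  withr::local_seed(seed)
  site <- realize_site(profile, shifts)
  n <- nrow(shifts)
  key <- residue_key(shifts)
  ref_row <- which(shifts$residue_number == profile$reference_residue &
                     shifts$atom_group == "backbone-amide")
  if (length(ref_row) != 1) stop("reference residue absent from shift table")

  # injected site shift changes: magnitude m gives CSP exactly m under the
  # averaged formula; direction uniform in the scaled (dH, 0.2*dN) plane
  in_site <- shifts$residue_number %in% site
  m <- theta <- numeric(n)
  m[in_site] <- stats::rlnorm(sum(in_site), log(profile$csp_median_ppm),
                              profile$csp_sdlog)
  theta[in_site] <- stats::runif(sum(in_site), 0, 2 * pi)
  dH <- m * sqrt(2) * cos(theta)
  dN <- m * sqrt(2) * sin(theta) / n_weight

  i_true <- stats::rlnorm(n, 0, profile$intensity_sdlog)
  i_true[ref_row] <- 1
  atten <- stats::rlnorm(n, log(profile$attenuation_median),
                         profile$attenuation_sigma)
  atten[ref_row] <- 1
  noise_f <- exp(stats::rnorm(n, 0, profile$intensity_cv))
  noise_b <- exp(stats::rnorm(n, 0, profile$intensity_cv))
  noise_f[ref_row] <- noise_b[ref_row] <- 1

  base <- data.frame(label = format_assignment(shifts$residue_type,
                                               shifts$residue_number,
                                               shifts$atom_group),
                     residue_number = shifts$residue_number,
                     residue_type = shifts$residue_type,
                     atom_group = shifts$atom_group,
                     stringsAsFactors = FALSE)
  free <- cbind(base, data.frame(
    w_N = shifts$w_N + profile$offset_N + stats::rnorm(n, 0, profile$sigma_N),
    w_H = shifts$w_H + profile$offset_H + stats::rnorm(n, 0, profile$sigma_H),
    intensity = i_true * noise_f))
  bound <- cbind(base, data.frame(
    w_N = shifts$w_N + profile$offset_N + dN + stats::rnorm(n, 0, profile$sigma_N),
    w_H = shifts$w_H + profile$offset_H + dH + stats::rnorm(n, 0, profile$sigma_H),
    intensity = i_true / atten * noise_b))
  lost <- bound$residue_number %in% profile$broadened_out
  truth <- list(site = site,
                delta = data.frame(key = key, residue_number = shifts$residue_number,
                                   atom_group = shifts$atom_group,
                                   delta_H = dH, delta_N = dN, csp = m,
                                   attenuation = atten,
                                   stringsAsFactors = FALSE),
                offsets = c(H = profile$offset_H, N = profile$offset_N),
                broadened_out = profile$broadened_out,
                reference_residue = profile$reference_residue,
                profile = profile$name)
  list(free = peaklist(free, spectrum_id = paste0(profile$name, "_free"),
                       condition = "free"),
       bound = peaklist(bound[!lost, , drop = FALSE],
                        spectrum_id = paste0(profile$name, "_bound"),
                        condition = paste0("bound:", profile$name)),
       truth = truth)
}

#' Fraction bound from the exact one-site equilibrium
#'
#' Solves the one-site binding equilibrium with ligand depletion: the
#' complex concentration is the smaller root of the binding quadratic, and
#' the fraction of protein bound is complex / total protein.
#'
#' @param protein_uM,ligand_uM total concentrations, uM.
#' @param kd_uM dissociation constant, uM.
#' @return fraction of protein in complex, in [0, 1).
#' @export
fbound_one_site <- function(protein_uM, ligand_uM, kd_uM) {
  s <- protein_uM + ligand_uM + kd_uM
  cpx <- (s - sqrt(s^2 - 4 * protein_uM * ligand_uM)) / 2
  cpx / protein_uM
}

#' Generate a fast-exchange titration series with ground truth
#'
#' At each ligand:protein molar ratio, the fraction bound comes from the
#' exact one-site equilibrium; observed positions are
#' `delta_free + f_bound * delta_shift` (fast exchange: one population-
#' weighted peak) and intensities interpolate between the free intensity
#' and the attenuated bound intensity. Residues broadened out in the
#' profile fade with `1 - f_bound` and are dropped once below the
#' detection fraction.
#'
#' @param shifts a `shift_table`.
#' @param profile a profile list (see [default_profile()]).
#' @param kd_uM true dissociation constant, uM.
#' @param protein_uM protein concentration, uM (default 32).
#' @param ratios molar ratios, starting at 0.
#' @param seed RNG seed.
#' @param n_weight nitrogen weight for the injected shift directions.
#' @param detect_frac intensity fraction of the free signal below which a
#'   broadened peak is no longer detected.
#' @return a `titration_series`; attribute `truth` carries the injected
#'   shift changes, Kd and per-ratio bound fractions.
#' @export
gen_titration <- function(shifts, profile, kd_uM = 10, protein_uM = 32,
                          ratios = c(0, 0.2, 0.5, 1, 2, 5), seed,
                          n_weight = 0.2, detect_frac = 0.1) {
  stopifnot(ratios[1] == 0, all(diff(ratios) > 0))
  withr::local_seed(seed)
  site <- realize_site(profile, shifts)
  n <- nrow(shifts)
  in_site <- shifts$residue_number %in% site
  m <- theta <- numeric(n)
  m[in_site] <- stats::rlnorm(sum(in_site), log(profile$csp_median_ppm),
                              profile$csp_sdlog)
  theta[in_site] <- stats::runif(sum(in_site), 0, 2 * pi)
  dH <- m * sqrt(2) * cos(theta)
  dN <- m * sqrt(2) * sin(theta) / n_weight
  ref_row <- which(shifts$residue_number == profile$reference_residue &
                     shifts$atom_group == "backbone-amide")
  if (length(ref_row) != 1) stop("reference residue absent from shift table")
  i_true <- stats::rlnorm(n, 0, profile$intensity_sdlog)
  i_true[ref_row] <- 1
  atten <- stats::rlnorm(n, log(profile$attenuation_median),
                         profile$attenuation_sigma)
  atten[ref_row] <- 1
  broad <- shifts$residue_number %in% profile$broadened_out
  base <- data.frame(label = format_assignment(shifts$residue_type,
                                               shifts$residue_number,
                                               shifts$atom_group),
                     residue_number = shifts$residue_number,
                     residue_type = shifts$residue_type,
                     atom_group = shifts$atom_group,
                     stringsAsFactors = FALSE)
  fb <- fbound_one_site(protein_uM, ratios * protein_uM, kd_uM)
  lists <- lapply(seq_along(ratios), function(s) {
    f <- fb[s]
    ib <- ifelse(broad, 0, i_true / atten)
    inten <- (i_true * (1 - f) + ib * f) *
      exp(stats::rnorm(n, 0, profile$intensity_cv))
    inten[ref_row] <- 1
    df <- cbind(base, data.frame(
      w_N = shifts$w_N + profile$offset_N + f * dN +
        stats::rnorm(n, 0, profile$sigma_N),
      w_H = shifts$w_H + profile$offset_H + f * dH +
        stats::rnorm(n, 0, profile$sigma_H),
      intensity = inten))
    keep <- inten >= detect_frac * i_true
    peaklist(df[keep, , drop = FALSE],
             spectrum_id = sprintf("%s_ratio_%g", profile$name, ratios[s]),
             condition = sprintf("molar ratio 1:%g", ratios[s]))
  })
  out <- titration_series(ratios, lists)
  attr(out, "truth") <- list(site = site, kd_uM = kd_uM,
                             protein_uM = protein_uM, f_bound = fb,
                             delta = data.frame(key = residue_key(shifts),
                                                delta_H = dH, delta_N = dN,
                                                csp = m,
                                                stringsAsFactors = FALSE))
  out
}

#' Generate ground truth for a mutant binding/activity panel
#'
#' Mutant log2 Kd effects are drawn from a bivariate normal across two
#' ligands with correlation `rho`; true Kds are the wild-type Kds scaled
#' by 2^effect. Activation deltas shrink with the first ligand's binding
#' impairment (a mutant that cannot bind the GEF is not activated by it).
#'
#' @param n_mutants number of mutants.
#' @param rho cross-ligand correlation of log2 effects.
#' @param sd_log2 standard deviation of log2 effects.
#' @param wt_kd named vector of wild-type Kds per ligand, uM.
#' @param delta_wt wild-type activation delta, percentage points over
#'   basal.
#' @param basal_dead optional mutant names whose basal activity is 0 (ND).
#' @param seed RNG seed.
#' @return a `panel_truth` list: `variants`, `ligands`, `kd` (matrix
#'   variant x ligand), `rho`, `activation_delta`, `basal`.
#' @export
gen_panel_truth <- function(n_mutants = 12, rho = 0.97, sd_log2 = 2,
                            wt_kd = c(GIV = 0.2, DAPLE = 0.3),
                            delta_wt = 150, basal_dead = character(), seed) {
  stopifnot(length(wt_kd) == 2, abs(rho) <= 1)
  withr::local_seed(seed)
  mut <- sprintf("M%02d", seq_len(n_mutants))
  z1 <- stats::rnorm(n_mutants)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n_mutants)
  eff <- cbind(z1, z2) * sd_log2
  kd <- rbind(WT = wt_kd,
              sweep(2^eff, 2, wt_kd, "*"))
  rownames(kd) <- c("WT", mut)
  colnames(kd) <- names(wt_kd)
  delta <- c(WT = delta_wt,
             stats::setNames(delta_wt * 2^(-pmax(eff[, 1], 0)), mut))
  basal <- stats::setNames(rep(100, n_mutants + 1), c("WT", mut))
  basal[basal_dead] <- 0
  structure(list(variants = c("WT", mut), ligands = names(wt_kd), kd = kd,
                 rho = rho, activation_delta = delta, basal = basal),
            class = "panel_truth")
}

#' Generate fluorescence-polarization binding curves from panel truth
#'
#' Hyperbolic responses `rmin + (rmax - rmin) * c / (Kd + c)` at the given
#' concentrations, with multiplicative lognormal noise.
#'
#' @param truth a `panel_truth` (see [gen_panel_truth()]).
#' @param concentrations titrant concentrations, uM (default 8 points in
#'   0-8 uM, the assay range).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param rmin,rmax true baseline and plateau polarization, arbitrary
#'   units.
#' @param seed RNG seed.
#' @return long-format data frame: `variant`, `ligand`, `conc_uM`,
#'   `response`.
#' @export
gen_fp_panel <- function(truth, concentrations = c(0, 0.125, 0.25, 0.5, 1, 2, 4, 8),
                         noise_cv = 0.02, rmin = 20, rmax = 180, seed) {
  withr::local_seed(seed)
  rows <- list()
  for (lg in truth$ligands) {
    for (v in truth$variants) {
      kd <- truth$kd[v, lg]
      r <- rmin + (rmax - rmin) * concentrations / (kd + concentrations)
      r <- r * exp(stats::rnorm(length(r), 0, noise_cv))
      rows[[length(rows) + 1]] <- data.frame(variant = v, ligand = lg,
                                             conc_uM = concentrations,
                                             response = r,
                                             stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a GEF-activity table from panel truth
#'
#' Basal and +GEF activities per variant and ligand with multiplicative
#' noise; variants with zero basal activity stay at zero (they will be
#' reported ND downstream).
#'
#' @param truth a `panel_truth`.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed RNG seed.
#' @return long-format data frame: `variant`, `ligand`, `condition`
#'   (`"basal"` or `"gef"`), `activity`.
#' @export
gen_activity_panel <- function(truth, noise_cv = 0.05, seed) {
  withr::local_seed(seed)
  rows <- list()
  for (lg in truth$ligands) {
    for (v in truth$variants) {
      b <- truth$basal[v]
      d <- truth$activation_delta[v]
      nb <- b * exp(stats::rnorm(1, 0, noise_cv))
      ng <- b * (1 + d / 100) * exp(stats::rnorm(1, 0, noise_cv))
      rows[[length(rows) + 1]] <- data.frame(
        variant = v, ligand = lg, condition = c("basal", "gef"),
        activity = c(nb, ng), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a synthetic C-alpha-only PDB model
#'
#' A generic helical C-alpha trace of the requested length, used as a
#' stand-in structure for demonstrating per-residue B-factor class mapping.
#' It is synthetic and carries no real coordinates.
#'
#' @param path output PDB path.
#' @param n_residues chain length (default 354).
#' @param chain chain identifier.
#' @return the path, invisibly.
#' @export
gen_synthetic_pdb <- function(path, n_residues = 354, chain = "A") {
  i <- seq_len(n_residues)
  t <- i * 100 * pi / 180
  n <- n_residues
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(rbind(2.3 * cos(t), 2.3 * sin(t), 1.5 * i)),
                   resno = i, resid = rep("ALA", n), chain = rep(chain, n),
                   elety = rep("CA", n), o = rep(1, n), b = rep(0, n))
  invisible(path)
}
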