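#' Fit a one-site binding hyperbola to a fluorescence-polarization curve
#'
#' Model: `R([G]) = R_min + (R_max - R_min) * [G] / (Kd + [G])`, the free
#' ≈ total approximation (the fluorescent probe is far below the titrant
#' concentrations). Least squares via Levenberg-Marquardt with multi-start
#' from Kd in {0.1, 1, 10} x median concentration; the best converged start
#' (lowest residual sum of squares) wins. A fit is `saturating` when the
#' fitted fractional occupancy at the top concentration,
#' `top / (Kd + top)`, reaches `sat_threshold` (default 0.9) — i.e. the
#' fitted response at the top concentration reaches 90% of the plateau
#' amplitude.
#'
#' @param concentrations titrant concentrations, uM, >= 5 unique points.
#' @param responses polarization readings, same length.
#' @param fix_rmin,fix_rmax optionally pin a baseline/plateau (used for the
#'   shared-plateau refit of non-saturating mutants).
#' @param kd_bounds box for Kd, uM; a fit ending on a bound is flagged
#'   unreliable.
#' @param sat_threshold fractional occupancy defining saturation.
#' @return a `kd_fit`: list with `kd`, `response_min`, `response_max`,
#'   `saturating`, `reliable`, `sse`.
#' @export
fit_kd <- function(concentrations, responses, fix_rmin = NULL,
                   fix_rmax = NULL, kd_bounds = c(1e-4, 1e4),
                   sat_threshold = 0.9) {
  stopifnot(length(concentrations) == length(responses))
  if (anyDuplicated(concentrations)) stop("concentrations must be unique")
  if (length(concentrations) < 5) stop("need at least 5 concentration points")
  if (is.unsorted(concentrations)) stop("concentrations must be ascending")
  if (any(concentrations < 0)) stop("negative concentration")
  df <- data.frame(x = concentrations, y = responses)
  starts <- c(0.1, 1, 10) * stats::median(concentrations[concentrations > 0])
  r_lo <- min(responses); r_hi <- max(responses)
  fits <- list()
  for (k0 in starts) {
    fml <- if (!is.null(fix_rmin) && !is.null(fix_rmax)) {
      stats::as.formula(sprintf("y ~ %g + (%g - %g) * x / (kd + x)",
                                fix_rmin, fix_rmax, fix_rmin))
    } else if (!is.null(fix_rmax)) {
      stats::as.formula(sprintf("y ~ rmin + (%g - rmin) * x / (kd + x)", fix_rmax))
    } else if (!is.null(fix_rmin)) {
      stats::as.formula(sprintf("y ~ %g + (rmax - %g) * x / (kd + x)",
                                fix_rmin, fix_rmin))
    } else {
      y ~ rmin + (rmax - rmin) * x / (kd + x)
    }
    start <- list(kd = k0)
    lower <- c(kd = kd_bounds[1]); upper <- c(kd = kd_bounds[2])
    if (is.null(fix_rmin)) {
      start$rmin <- r_lo; lower <- c(lower, rmin = -Inf); upper <- c(upper, rmin = Inf)
    }
    if (is.null(fix_rmax)) {
      start$rmax <- r_hi; lower <- c(lower, rmax = -Inf); upper <- c(upper, rmax = Inf)
    }
    f <- try(minpack.lm::nlsLM(fml, data = df, start = start,
                               lower = lower[names(start)],
                               upper = upper[names(start)],
                               control = minpack.lm::nls.lm.control(maxiter = 200)),
             silent = TRUE)
    if (!inherits(f, "try-error")) fits[[length(fits) + 1]] <- f
  }
  if (length(fits) == 0) {
    stop("one-site fit failed to converge from all starts (Kd starts: ",
         paste(signif(starts, 3), collapse = ", "), " uM)")
  }
  sse <- vapply(fits, stats::deviance, 0)
  best <- fits[[which.min(sse)]]
  cf <- stats::coef(best)
  kd <- unname(cf["kd"])
  rmin <- if (is.null(fix_rmin)) unname(cf["rmin"]) else fix_rmin
  rmax <- if (is.null(fix_rmax)) unname(cf["rmax"]) else fix_rmax
  top <- max(concentrations)
  at_bound <- kd <= kd_bounds[1] * 1.001 || kd >= kd_bounds[2] * 0.999
  structure(list(kd = kd, response_min = rmin, response_max = rmax,
                 saturating = top / (kd + top) >= sat_threshold,
                 reliable = !at_bound, sse = min(sse)),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("Kd = %.4g uM (Rmin %.4g, Rmax %.4g)%s%s\n", x$kd,
              x$response_min, x$response_max,
              if (x$saturating) "" else ", non-saturating",
              if (x$reliable) "" else ", UNRELIABLE"))
  invisible(x)
}

#' Normalize a ligand's curves to the wild-type plateau and fit all variants
#'
#' All responses for one ligand are rescaled so that the fitted wild-type
#' plateau equals 100% binding. Saturating variants are then fitted freely;
#' variants not reaching saturation within the sampled range are refitted
#' with the plateau fixed at the shared 100% value, as their own plateau is
#' not identified by the data.
#'
#' @param curves long-format data frame with columns `variant`,
#'   `conc_uM`, `response` (one ligand).
#' @param wt_variant wild-type identifier (default `"WT"`).
#' @param ... passed to [fit_kd()].
#' @return list with `curves` (normalized responses) and `fits` (data
#'   frame: `variant`, `kd`, `response_min`, `response_max`, `saturating`,
#'   `shared_plateau`, `reliable`).
#' @export
normalize_to_wt_max <- function(curves, wt_variant = "WT", ...) {
  need <- c("variant", "conc_uM", "response")
  stopifnot(all(need %in% names(curves)))
  if (!wt_variant %in% curves$variant) {
    stop("wild-type variant '", wt_variant, "' missing from curves")
  }
  wt <- curves[curves$variant == wt_variant, ]
  wt_fit <- fit_kd(wt$conc_uM, wt$response, ...)
  if (!wt_fit$saturating) {
    stop("wild-type curve does not reach saturation; normalization undefined")
  }
  scale <- 100 / wt_fit$response_max
  curves$response <- curves$response * scale
  fits <- lapply(split(curves, curves$variant), function(g) {
    f <- fit_kd(g$conc_uM, g$response, ...)
    shared <- FALSE
    if (!f$saturating) {
      f <- fit_kd(g$conc_uM, g$response, fix_rmax = 100, ...)
      shared <- TRUE
    }
    data.frame(variant = g$variant[1], kd = f$kd,
               response_min = f$response_min, response_max = f$response_max,
               saturating = f$saturating, shared_plateau = shared,
               reliable = f$reliable, stringsAsFactors = FALSE)
  })
  fits <- do.call(rbind, fits)
  rownames(fits) <- NULL
  list(curves = curves, fits = fits)
}

#' Build a variant x ligand Kd matrix with fold-change classes
#'
#' Computes per-cell log2(Kd_variant / Kd_WT) and the fold-change class of
#' the binding effect: `impaired` when the Kd ratio exceeds 2, `enhanced`
#' when below 0.5, `neutral` otherwise — boundaries (exactly 2 or 0.5) are
#' neutral. Unreliable fits are excluded (NA ratio/class) and reported.
#'
#' @param fits data frame with `variant`, `ligand`, `kd` and optionally
#'   `reliable`.
#' @param wt_variant wild-type identifier.
#' @param fold_bounds c(impaired_above, enhanced_below) Kd ratios.
#' @return a `kd_matrix` data frame: `variant`, `ligand`, `kd`,
#'   `log2_ratio`, `fold_class`; attribute `excluded` lists unreliable
#'   cells.
#' @export
build_kd_matrix <- function(fits, wt_variant = "WT",
                            fold_bounds = c(2, 0.5)) {
  need <- c("variant", "ligand", "kd")
  stopifnot(all(need %in% names(fits)))
  if (!"reliable" %in% names(fits)) fits$reliable <- TRUE
  out <- fits[c("variant", "ligand", "kd")]
  out$log2_ratio <- NA_real_
  out$fold_class <- NA_character_
  for (lg in unique(out$ligand)) {
    sel <- out$ligand == lg
    wt <- which(sel & out$variant == wt_variant & fits$reliable)
    if (length(wt) != 1) {
      stop("wild type '", wt_variant, "' missing (or unreliable) for ligand ", lg)
    }
    ratio <- out$kd[sel] / out$kd[wt]
    out$log2_ratio[sel] <- log2(ratio)
    out$fold_class[sel] <- ifelse(ratio > fold_bounds[1], "impaired",
                                  ifelse(ratio < fold_bounds[2], "enhanced",
                                         "neutral"))
  }
  drop <- !fits$reliable
  out$log2_ratio[drop] <- NA_real_
  out$fold_class[drop] <- NA_character_
  attr(out, "excluded") <- fits[drop, c("variant", "ligand")]
  class(out) <- c("kd_matrix", "data.frame")
  out
}

#' Correlate mutant binding effects across two ligands
#'
#' Pearson correlation of log2 Kd ratios over the mutants (wild type
#' excluded — it is identically 0 in both columns) shared between the two
#' ligands, skipping excluded cells.
#'
#' @param mat a `kd_matrix`.
#' @param ligand_a,ligand_b ligand identifiers.
#' @param wt_variant wild-type identifier.
#' @return list with `r` and `n` (mutants used).
#' @export
correlate_mutant_effects <- function(mat, ligand_a, ligand_b,
                                     wt_variant = "WT") {
  a <- mat[mat$ligand == ligand_a & mat$variant != wt_variant, ]
  b <- mat[mat$ligand == ligand_b & mat$variant != wt_variant, ]
  i <- match(a$variant, b$variant)
  x <- a$log2_ratio
  y <- b$log2_ratio[i]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("fewer than 3 mutants shared between the two ligands")
  list(r = stats::cor(x[ok], y[ok]), n = sum(ok))
}

#' GEF-mediated activation relative to basal activity
#'
#' Expresses activity in the presence of a GEF as per cent of the basal
#' activity of the same protein, and the activation as the increment over
#' basal in percentage points:
#' `activation_delta = 100 * (with - without) / without`. A variant with
#' non-positive basal activity is not determined (ND).
#'
#' @param with_gef,without activities (e.g. GTPase counts) with and
#'   without the GEF; vectorized.
#' @return data frame with `percent_basal`, `activation_delta`, `nd`.
#' @export
compute_activation <- function(with_gef, without) {
  nd <- is.na(without) | without <= 0
  pb <- ifelse(nd, NA_real_, 100 * with_gef / without)
  data.frame(percent_basal = pb,
             activation_delta = pb - 100,
             nd = nd)
}

#' Classify inhibition of GEF-mediated activation
#'
#' Inhibition is defined on activation deltas (the GEF-induced increment
#' over basal), not raw activities:
#' `inhibition = 100 * (1 - delta_mut / delta_wt)`; `moderate` when in
#' [30, 50], `strong` when > 50, `none` below 30. A missing mutant delta
#' (ND) yields class `"ND"`.
#'
#' @param delta_mut,delta_wt activation deltas (percentage points over
#'   basal); `delta_wt` must be positive.
#' @param bounds inhibition percentages delimiting moderate and strong.
#' @return data frame with `inhibition_percent` and `inhibition_class`.
#' @export
classify_inhibition <- function(delta_mut, delta_wt, bounds = c(30, 50)) {
  stopifnot(length(delta_wt) == 1)
  if (is.na(delta_wt) || delta_wt <= 0) {
    stop("wild-type activation delta must be positive")
  }
  inh <- 100 * (1 - delta_mut / delta_wt)
  cls <- ifelse(is.na(inh), "ND",
                ifelse(inh > bounds[2], "strong",
                       ifelse(inh >= bounds[1], "moderate", "none")))
  data.frame(inhibition_percent = inh, inhibition_class = cls,
             stringsAsFactors = FALSE)
}
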