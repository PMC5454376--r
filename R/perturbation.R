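#' Chemical shift perturbation
#'
#' Weighted combined change of the amide 1H and 15N shifts between two
#' states: `CSP = sqrt((dH^2 + (n_weight * dN)^2) / k)` with `k = 2` when
#' `averaging` is on (the default) and `k = 1` otherwise. The convention
#' (nitrogen weight and averaging divisor) rescales all CSPs uniformly, so
#' median-multiple classes are essentially insensitive to it; both knobs
#' are exposed. Symmetric in the two states; `NA` in any input gives `NA`
#' (missing, never zero).
#'
#' @param free_H,free_N,bound_H,bound_N shifts in ppm (vectorized).
#' @param n_weight nitrogen weight (default 0.2).
#' @param averaging divide the squared sum by 2 before the root.
#' @return CSP in ppm, >= 0 or NA.
#' @export
compute_csp <- function(free_H, free_N, bound_H, bound_N,
                        n_weight = 0.2, averaging = TRUE) {
  k <- if (averaging) 2 else 1
  sqrt(((free_H - bound_H)^2 + (n_weight * (free_N - bound_N))^2) / k)
}

#' Normalize peak intensities to a reference signal
#'
#' Divides every intensity by that of a reference residue's backbone amide
#' (default Y354, a narrow isolated signal unaffected by binding), making
#' intensities comparable across spectra; the reference becomes exactly 1.
#'
#' @param pl an assigned [peaklist()].
#' @param reference_residue residue number of the reference signal.
#' @return the peak list with normalized intensities; attribute
#'   `reference_intensity` holds the raw divisor.
#' @export
normalize_intensities <- function(pl, reference_residue = 354) {
  stopifnot(inherits(pl, "peaklist"))
  i <- which(pl$residue_number == reference_residue &
               pl$atom_group == "backbone-amide")
  if (length(i) != 1 || is.na(pl$intensity[i]) || pl$intensity[i] <= 0) {
    stop("reference residue ", reference_residue,
         " missing or without positive intensity in '",
         attr(pl, "spectrum_id"),
         "'; pick another reference via reference_residue=")
  }
  ref <- pl$intensity[i]
  pl$intensity <- pl$intensity / ref
  attr(pl, "reference_intensity") <- ref
  pl
}

#' Free/bound intensity ratio with the 1% detection floor
#'
#' `I_ratio = I_free / I_bound` on normalized intensities. When the bound
#' intensity is below 1% of the free intensity — including measured zeros
#' and peaks broadened beyond detection (`NA` bound with `lost = TRUE`,
#' treated as 0) — the ratio is set to exactly 100, i.e. the bound
#' intensity is treated as 1% of free. Missing free intensity gives `NA`.
#'
#' @param free_norm,bound_norm normalized intensities (vectorized).
#' @param lost logical: bound peak broadened beyond detection (its `NA`
#'   bound intensity counts as zero rather than missing).
#' @param floor_frac detection floor as a fraction of `free_norm`.
#' @return I_ratio, dimensionless in (0, 100].
#' @export
compute_iratio <- function(free_norm, bound_norm, lost = FALSE,
                           floor_frac = 0.01) {
  n <- max(length(free_norm), length(bound_norm))
  free_norm <- rep_len(free_norm, n)
  bound_norm <- rep_len(bound_norm, n)
  lost <- rep_len(lost, n)
  b <- ifelse(lost & is.na(bound_norm), 0, bound_norm)
  out <- ifelse(b < floor_frac * free_norm, 1 / floor_frac, free_norm / b)
  out[is.na(free_norm) | (is.na(b) & !lost)] <- NA_real_
  out
}

#' Build per-residue perturbation records from assigned free/bound lists
#'
#' Normalizes both lists to the reference residue, joins them on residue
#' identity, and computes the CSP and the floored intensity ratio per
#' residue. Residues assigned in the free form but absent from the bound
#' list are treated as broadened beyond detection: their I_ratio is the
#' floor value (100), their CSP is missing.
#'
#' @param free,bound assigned [peaklist()]s.
#' @param reference_residue residue used by [normalize_intensities()].
#' @param n_weight,averaging CSP convention, see [compute_csp()].
#' @param floor_frac detection floor, see [compute_iratio()].
#' @return a `perturbation_records` data frame: `residue_number`,
#'   `residue_type`, `atom_group`, `csp`, `i_free_norm`, `i_bound_norm`,
#'   `i_ratio`, `lost`.
#' @export
perturbation_records <- function(free, bound, reference_residue = 354,
                                 n_weight = 0.2, averaging = TRUE,
                                 floor_frac = 0.01) {
  free <- normalize_intensities(free, reference_residue)
  bound <- normalize_intensities(bound, reference_residue)
  fa <- free[!is.na(free$residue_number), , drop = FALSE]
  ba <- bound[!is.na(bound$residue_number), , drop = FALSE]
  idx <- match(residue_key(fa), residue_key(ba))
  lost <- is.na(idx)
  rec <- data.frame(
    residue_number = fa$residue_number,
    residue_type = fa$residue_type,
    atom_group = fa$atom_group,
    csp = compute_csp(fa$w_H, fa$w_N, ba$w_H[idx], ba$w_N[idx],
                      n_weight, averaging),
    i_free_norm = fa$intensity,
    i_bound_norm = ba$intensity[idx],
    lost = lost,
    stringsAsFactors = FALSE
  )
  rec$i_ratio <- compute_iratio(rec$i_free_norm, rec$i_bound_norm,
                                lost = lost, floor_frac = floor_frac)
  rec <- rec[order(rec$residue_number, rec$atom_group),
             c("residue_number", "residue_type", "atom_group", "csp",
               "i_free_norm", "i_bound_norm", "i_ratio", "lost")]
  rownames(rec) <- NULL
  class(rec) <- c("perturbation_records", "data.frame")
  rec
}

#' Median-multiple significance classes
#'
#' Classifies a per-residue metric (CSP in ppm, or the dimensionless
#' I_ratio) against multiples of its own median M over residues with data:
#' strong when metric > 10 M, medium when 5 M < metric <= 10 M, weak when
#' 3 M < metric <= 5 M, below otherwise; residues without data are
#' `no_data`. Applied on the linear metric scale. An all-zero metric
#' (M = 0) yields all `below` with a warning unless an explicit `epsilon`
#' replaces M.
#'
#' @param values numeric metric per residue; NA means no data.
#' @param thresholds increasing median multiples (default 3, 5, 10).
#' @param epsilon optional replacement for M when the median is zero.
#' @return ordered factor with levels no_data < below < weak < medium <
#'   strong; attribute `median` holds M.
#' @export
classify <- function(values, thresholds = c(3, 5, 10), epsilon = NULL) {
  stopifnot(length(thresholds) == 3, all(diff(thresholds) > 0))
  if (all(is.na(values))) stop("no residue with data to classify")
  M <- stats::median(values, na.rm = TRUE)
  if (M == 0) {
    if (!is.null(epsilon)) {
      M <- epsilon
    } else {
      warning("median of the metric is 0; all residues with data classified 'below'")
    }
  }
  lev <- rep("no_data", length(values))
  has <- !is.na(values)
  lev[has] <- "below"
  if (M > 0) {
    lev[has & values > thresholds[1] * M] <- "weak"
    lev[has & values > thresholds[2] * M] <- "medium"
    lev[has & values > thresholds[3] * M] <- "strong"
  }
  out <- factor(lev, levels = .class_levels, ordered = TRUE)
  attr(out, "median") <- M
  out
}

#' Composite perturbation class
#'
#' For residues with both a CSP and an I_ratio class the larger of the two
#' is taken; if one is `no_data` the other is returned; both `no_data`
#' gives `no_data`. (Since `no_data` is the lowest level, this is simply
#' the elementwise maximum.)
#'
#' @param csp_class,iratio_class ordered factors from [classify()].
#' @return ordered factor of composite classes.
#' @export
composite_class <- function(csp_class, iratio_class) {
  stopifnot(is.ordered(csp_class), is.ordered(iratio_class))
  out <- ifelse(as.integer(csp_class) >= as.integer(iratio_class),
                as.integer(csp_class), as.integer(iratio_class))
  factor(.class_levels[out], levels = .class_levels, ordered = TRUE)
}

#' Classify perturbation records
#'
#' Adds `csp_class`, `iratio_class` and `composite_class` columns using the
#' median-multiple rule on each metric.
#'
#' @param records a `perturbation_records` data frame.
#' @param thresholds median multiples, see [classify()].
#' @return the records with class columns; attribute `medians` holds the
#'   CSP and I_ratio medians used.
#' @export
classify_records <- function(records, thresholds = c(3, 5, 10)) {
  records$csp_class <- classify(records$csp, thresholds)
  records$iratio_class <- classify(records$i_ratio, thresholds)
  records$composite_class <- composite_class(records$csp_class,
                                             records$iratio_class)
  attr(records, "medians") <- c(csp = attr(records$csp_class, "median"),
                                i_ratio = attr(records$iratio_class, "median"))
  records
}

#' Correlate perturbation profiles between two conditions
#'
#' Pearson correlation of a per-residue metric over the residues with data
#' in both profiles. The default metric is log10(I_ratio), whose detection
#' floor otherwise creates a bounded heavy tail on the linear scale.
#'
#' @param a,b `perturbation_records` for the two conditions.
#' @param metric `"log_iratio"` or `"csp"`.
#' @return list with `r` (Pearson), `n` (residues used), `metric`.
#' @export
correlate_profiles <- function(a, b, metric = c("log_iratio", "csp")) {
  metric <- match.arg(metric)
  col <- if (metric == "csp") "csp" else "i_ratio"
  ia <- match(residue_key(a), residue_key(b))
  xa <- a[[col]]
  xb <- b[[col]][ia]
  ok <- !is.na(xa) & !is.na(xb)
  if (sum(ok) < 3) stop("fewer than 3 residues with data in both profiles")
  x <- xa[ok]; y <- xb[ok]
  if (metric == "log_iratio") { x <- log10(x); y <- log10(y) }
  list(r = stats::cor(x, y), n = sum(ok), metric = metric)
}

#' Overall intensity decrease on binding
#'
#' Reports `100 * (1 - median(i_bound_norm / i_free_norm))` over residues
#' with both normalized intensities, together with the median I_ratio (the
#' median fold attenuation) and the number of residues used.
#'
#' @param records a `perturbation_records` data frame.
#' @return list with `percent_decrease`, `median_iratio`, `n`.
#' @export
summarize_intensity_decrease <- function(records) {
  ok <- !is.na(records$i_free_norm) & !is.na(records$i_bound_norm)
  if (!any(ok)) stop("no residue with both intensities")
  ratio <- records$i_bound_norm[ok] / records$i_free_norm[ok]
  list(percent_decrease = 100 * (1 - stats::median(ratio)),
       median_iratio = stats::median(records$i_ratio, na.rm = TRUE),
       n = sum(ok))
}

#' Fraction of residues above each significance threshold
#'
#' The criterion behind "significantly shifted" is reported per threshold
#' rather than asserted: for each median multiple, the fraction of residues
#' with data whose metric exceeds it.
#'
#' @param values numeric metric per residue; NA means no data.
#' @param thresholds median multiples.
#' @return named vector of fractions (of residues with data).
#' @export
shifted_fraction <- function(values, thresholds = c(3, 5, 10)) {
  has <- !is.na(values)
  if (!any(has)) stop("no residue with data")
  M <- stats::median(values[has])
  out <- vapply(thresholds, function(t) mean(values[has] > t * M), 0)
  names(out) <- paste0(">", thresholds, "M")
  out
}
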