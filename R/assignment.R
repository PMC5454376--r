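#' Scaled 1H/15N distance
#'
#' Distance in a combined shift space where the 15N axis is compressed by a
#' weight `s` (default 0.2) to account for the wider nitrogen dispersion:
#' `d = sqrt(dH^2 + (s * dN)^2)`. The same metric is used for assignment
#' matching, titration tracking and the CSP (up to the averaging divisor).
#'
#' @param dH,dN shift differences in ppm (vectorized).
#' @param n_weight nitrogen scale factor.
#' @return scaled distances in 1H-equivalent ppm.
#' @export
scaled_dist <- function(dH, dN, n_weight = 0.2) {
  sqrt(dH^2 + (n_weight * dN)^2)
}

# cross distance matrix between two position sets in scaled space
.dist_matrix <- function(H1, N1, H2, N2, n_weight) {
  outer(H1, H2, "-")^2 + (n_weight * outer(N1, N2, "-"))^2
}

#' Estimate systematic referencing offsets
#'
#' Experimental spectra are often referenced with a constant offset relative
#' to published shifts. The offset (experimental minus reference) is
#' estimated iteratively: peaks and reference entries are matched by mutual
#' nearest neighbours in scaled shift space under the current offset, the
#' offsets are updated to the medians of the matched residuals, and the loop
#' stops when both change by less than `tol` (default 0.001 ppm) or after
#' `max_iter` iterations. Medians make the estimate robust to the minority
#' of binding-site peaks that genuinely move. The iteration is initialized
#' from the difference of the marginal medians of the two point sets, which
#' makes the estimator exactly translation-equivariant.
#'
#' @param experimental a [peaklist()].
#' @param reference a `shift_table`.
#' @param n_weight nitrogen weight of the matching metric.
#' @param gate matching gate in scaled ppm; candidate pairs farther apart
#'   are never matched.
#' @param n_min minimum number of mutual matches for the estimate to be
#'   flagged reliable.
#' @param tol convergence tolerance on both offsets, ppm.
#' @param max_iter iteration cap.
#' @return an `offset_estimate`: list with `delta_H`, `delta_N` (ppm),
#'   `n_matched`, `mad_H`, `mad_N` (median absolute deviations of matched
#'   residuals), `reliable`, `n_iter`.
#' @export
estimate_offset <- function(experimental, reference, n_weight = 0.2,
                            gate = 0.5, n_min = 20, tol = 1e-3,
                            max_iter = 20) {
  stopifnot(inherits(experimental, "peaklist"))
  eH <- experimental$w_H; eN <- experimental$w_N
  rH <- reference$w_H; rN <- reference$w_N
  if (length(eH) < 2 || length(rH) < 2) stop("too few peaks or reference entries")
  est <- c(H = stats::median(eH) - stats::median(rH),
           N = stats::median(eN) - stats::median(rN))
  n_iter <- 0L
  pairs <- NULL
  for (it in seq_len(max_iter)) {
    n_iter <- it
    d2 <- .dist_matrix(eH - est["H"], eN - est["N"], rH, rN, n_weight)
    nn_e <- apply(d2, 1, which.min)          # best reference for each peak
    nn_r <- apply(d2, 2, which.min)          # best peak for each reference
    i <- seq_along(eH)
    mutual <- nn_r[nn_e] == i
    dmin <- sqrt(d2[cbind(i, nn_e)])
    ok <- mutual & dmin <= gate
    pairs <- cbind(peak = i[ok], ref = nn_e[ok])
    if (nrow(pairs) == 0) break
    new <- c(H = stats::median(eH[pairs[, 1]] - rH[pairs[, 2]]),
             N = stats::median(eN[pairs[, 1]] - rN[pairs[, 2]]))
    done <- all(abs(new - est) < tol)
    est <- new
    if (done) break
  }
  resH <- eH[pairs[, 1]] - rH[pairs[, 2]] - est["H"]
  resN <- eN[pairs[, 1]] - rN[pairs[, 2]] - est["N"]
  n_matched <- nrow(pairs)
  structure(list(delta_H = unname(est["H"]), delta_N = unname(est["N"]),
                 n_matched = n_matched,
                 mad_H = if (n_matched) stats::mad(resH) else NA_real_,
                 mad_N = if (n_matched) stats::mad(resN) else NA_real_,
                 reliable = n_matched >= n_min, n_iter = n_iter),
            class = "offset_estimate")
}

#' @export
print.offset_estimate <- function(x, ...) {
  cat(sprintf("offset estimate: dH = %+.4f ppm, dN = %+.4f ppm (n = %d%s)\n",
              x$delta_H, x$delta_N, x$n_matched,
              if (x$reliable) "" else ", UNRELIABLE"))
  invisible(x)
}

#' Zero offsets (for forcing no correction)
#' @export
zero_offset <- function() {
  structure(list(delta_H = 0, delta_N = 0, n_matched = 0L,
                 mad_H = NA_real_, mad_N = NA_real_,
                 reliable = FALSE, n_iter = 0L),
            class = "offset_estimate")
}

#' Transfer published assignments onto an experimental peak list
#'
#' After offset correction, each reference entry is matched to experimental
#' peaks within an acceptance radius `r_accept` (scaled ppm); matches are
#' committed greedily by ascending distance, one-to-one. A match is only
#' committed when it beats every competing candidate (another reference
#' for the same peak, or another peak for the same reference) by at least
#' `ambiguity_margin`: two nearby references whose peaks both fall inside
#' the acceptance radius can otherwise be silently swapped by position
#' noise, so ambiguous parties are refused and reported as unmatched
#' instead. With the margin at 0 this reduces to refusing exact ties
#' (within `tie_tol`).
#'
#' @param experimental a [peaklist()] (existing labels are ignored).
#' @param reference a `shift_table`.
#' @param offsets an `offset_estimate` (see [estimate_offset()]), or
#'   [zero_offset()].
#' @param n_weight nitrogen weight of the matching metric.
#' @param r_accept acceptance radius, scaled ppm.
#' @param ambiguity_margin scaled ppm by which the best candidate must beat
#'   any competitor; default 0.02, about the peak-position noise between
#'   two spectra.
#' @param tie_tol distance difference below which two candidates count as
#'   exactly tied, ppm; the effective refusal window is
#'   `max(tie_tol, ambiguity_margin)`.
#' @return the experimental [peaklist()] with labels filled in for matched
#'   peaks; attributes `unmatched_reference` (data frame of reference
#'   entries without a match, with a `reason` of `"no_candidate"` or
#'   `"tie"`) and `n_transferred`.
#' @export
transfer_assignments <- function(experimental, reference, offsets,
                                 n_weight = 0.2, r_accept = 0.05,
                                 ambiguity_margin = 0.02, tie_tol = 1e-9) {
  stopifnot(inherits(experimental, "peaklist"))
  out <- strip_assignments(experimental)
  rH <- reference$w_H + offsets$delta_H
  rN <- reference$w_N + offsets$delta_N
  d2 <- .dist_matrix(experimental$w_H, experimental$w_N, rH, rN, n_weight)
  d <- sqrt(d2)
  cand <- which(d <= r_accept, arr.ind = TRUE)
  reason <- rep(NA_character_, nrow(reference))
  if (nrow(cand) > 0) {
    cd <- d[cand]
    ord <- order(cd, cand[, 2], cand[, 1])   # stable, order-independent
    cand <- cand[ord, , drop = FALSE]
    cd <- cd[ord]
    peak_used <- rep(FALSE, nrow(experimental))
    ref_used <- rep(FALSE, nrow(reference))
    k <- 1L
    while (k <= nrow(cand)) {
      p <- cand[k, 1]; r <- cand[k, 2]
      if (peak_used[p] || ref_used[r]) { k <- k + 1L; next }
      # competitors within the refusal window sharing this peak or reference
      margin <- max(tie_tol, ambiguity_margin)
      tie <- which(abs(cd - cd[k]) <= margin &
                     (cand[, 1] == p | cand[, 2] == r) &
                     !(cand[, 1] == p & cand[, 2] == r))
      tie <- tie[!peak_used[cand[tie, 1]] & !ref_used[cand[tie, 2]]]
      if (length(tie) > 0) {
        refs <- unique(c(r, cand[tie, 2]))
        peaks <- unique(c(p, cand[tie, 1]))
        ref_used[refs] <- TRUE
        peak_used[peaks] <- TRUE
        reason[refs] <- "ambiguous"
        k <- k + 1L
        next
      }
      out$label[p] <- format_assignment(reference$residue_type[r],
                                        reference$residue_number[r],
                                        reference$atom_group[r])
      out$residue_number[p] <- reference$residue_number[r]
      out$residue_type[p] <- reference$residue_type[r]
      out$atom_group[p] <- reference$atom_group[r]
      peak_used[p] <- TRUE
      ref_used[r] <- TRUE
      k <- k + 1L
    }
  }
  matched <- !is.na(out$residue_number)
  got <- paste0(out$residue_number[matched], "/", out$atom_group[matched])
  all_ref <- paste0(reference$residue_number, "/", reference$atom_group)
  miss <- !(all_ref %in% got)
  reason[miss & is.na(reason)] <- "no_candidate"
  um <- cbind(as.data.frame(reference)[miss, , drop = FALSE],
              reason = reason[miss])
  rownames(um) <- NULL
  attr(out, "unmatched_reference") <- um
  attr(out, "n_transferred") <- sum(matched)
  out
}

#' Use an assigned peak list as a reference shift table
#'
#' The assigned peaks of a list become reference entries at their observed
#' positions. Used to assign a bound-form spectrum on a nearest-neighbour
#' basis from the assigned free form (whose positions already carry the
#' experimental referencing, so no offset correction is needed).
#'
#' @param pl an assigned [peaklist()].
#' @return a `shift_table`.
#' @export
as_shift_table <- function(pl) {
  stopifnot(inherits(pl, "peaklist"))
  out <- as.data.frame(pl)[!is.na(pl$residue_number),
                           c("residue_number", "residue_type", "atom_group",
                             "w_H", "w_N")]
  if (nrow(out) == 0) stop("no assigned peaks")
  rownames(out) <- NULL
  class(out) <- c("shift_table", "data.frame")
  out
}

#' Assign a bound-form list by nearest neighbour from the free form
#'
#' Bound-state signals are matched one-to-one, greedily by ascending scaled
#' distance, to the positions of the assigned free-form peaks, within a
#' gate wide enough for typical binding-induced shift changes (default
#' 0.3 scaled ppm, several times the expected median CSP). Free-form
#' residues with no bound peak in the gate are reported unmatched; the
#' perturbation stage treats them as broadened beyond detection.
#'
#' @param assigned_free the assigned free-form [peaklist()].
#' @param bound the bound-form [peaklist()] (labels ignored).
#' @param n_weight nitrogen weight of the matching metric.
#' @param gate acceptance radius, scaled ppm.
#' @return the bound [peaklist()] with labels filled in (see
#'   [transfer_assignments()] for the reporting attributes).
#' @export
assign_bound_form <- function(assigned_free, bound, n_weight = 0.2,
                              gate = 0.3) {
  transfer_assignments(bound, as_shift_table(assigned_free), zero_offset(),
                       n_weight = n_weight, r_accept = gate)
}

#' Flag overlapped peaks
#'
#' Signals whose free-form positions lie closer than a resolution limit
#' cannot be matched or tracked reliably: any later assignment between
#' them is an arbitrary choice that can silently swap identities. Such
#' residues are treated as having no reliable measurement (the analysis
#' reports them as no-data) rather than risking a wrong value.
#'
#' @param pl a [peaklist()].
#' @param limit overlap limit in scaled ppm (default 0.03, about three
#'   times the combined peak-position noise of a typical pair of spectra).
#' @param n_weight nitrogen weight of the metric.
#' @return logical vector: `TRUE` for peaks with a neighbour within the
#'   limit.
#' @export
flag_overlaps <- function(pl, limit = 0.03, n_weight = 0.2) {
  d2 <- .dist_matrix(pl$w_H, pl$w_N, pl$w_H, pl$w_N, n_weight)
  diag(d2) <- Inf
  apply(d2, 1, min) <= limit^2
}

#' Track assigned peaks through a ligand titration
#'
#' Links each assigned free-form peak through the titration by stepwise
#' greedy nearest-neighbour matching: at each molar ratio the live
#' trajectories claim peaks of that spectrum in ascending cost order,
#' one-to-one, within a gating radius. The cost combines the scaled shift
#' distance with an intensity-continuity penalty,
#' `d + intensity_weight * |log(I_candidate / I_previous)|`: positions
#' alone cannot distinguish two trajectories crossing a coincidentally
#' overlapping peak, but intensities change slowly along a titration while
#' unrelated signals differ in height, so the penalty breaks such
#' ambiguities toward the intensity-consistent candidate. A trajectory
#' with no peak inside the gate is marked lost at that ratio (downstream
#' this means broadened beyond detection) and is never re-acquired. When
#' two trajectories contend for the same peak, the cheaper wins only if it
#' beats the contender by more than `ambiguity_margin`; contests within
#' the margin — which position noise could flip either way — are refused
#' for that step: the contested peak is claimed by nobody and the refused
#' trajectories coast, keeping their previous position (flagged
#' ambiguous, with no observation at that ratio) and competing again at
#' the next step once the crossing signals have separated. A trajectory
#' still unmatched at the last ratio has no usable bound-state
#' observation: it means "no reliable measurement", not "broadened" —
#' only a loss without any candidate in the gate should be read as
#' disappearance.
#'
#' @param series a `titration_series` (see [titration_series()]).
#' @param assigned_free the assigned [peaklist()] of the free form (ratio 0).
#' @param n_weight nitrogen weight of the matching metric.
#' @param gate per-step gating radius, scaled ppm (applied to the position
#'   distance only).
#' @param intensity_weight scaled ppm of cost per natural-log-fold of
#'   intensity change between consecutive points; 0 disables the penalty,
#'   and missing intensities contribute none.
#' @param ambiguity_margin cost difference (scaled ppm) below which a
#'   contest between trajectories for one peak, or between two peaks for
#'   one trajectory, is refused instead of decided; 0 disables refusal.
#' @param include_unassigned also follow the unassigned free-form peaks —
#'   and any peak that appears unclaimed at an intermediate ratio — as
#'   anonymous trajectories (default). They are omitted from the result
#'   but keep claiming their own signals at every step, so that a moving
#'   assigned peak cannot silently adopt a stray stationary signal whose
#'   owner is simply not tracked.
#' @return a `trajectories` data frame in long form: `residue_number`,
#'   `residue_type`, `atom_group`, `ratio`, `w_H`, `w_N`, `intensity`,
#'   `lost`, `ambiguous`; attribute `lost_at` (named vector, NA when never
#'   lost). A row with `lost = FALSE` but missing position is a coasting
#'   step (ambiguous contest, no observation). Use
#'   [trajectory_endpoints()] for bound-state end points.
#' @export
track_titration <- function(series, assigned_free, n_weight = 0.2,
                            gate = 0.08, intensity_weight = 0.03,
                            ambiguity_margin = 0.015,
                            include_unassigned = TRUE) {
  stopifnot(inherits(series, "titration_series"))
  ratios <- series$molar_ratios
  assigned <- !is.na(assigned_free$residue_number)
  if (!any(assigned)) stop("no assigned peaks in the free-form list")
  traj <- if (include_unassigned) assigned_free
    else assigned_free[assigned, , drop = FALSE]
  named <- !is.na(traj$residue_number)
  key <- ifelse(named, residue_key(traj), paste0(".anon", seq_len(nrow(traj))))
  curH <- traj$w_H; curN <- traj$w_N; curI <- traj$intensity
  alive <- rep(TRUE, nrow(traj))
  lost_at <- stats::setNames(rep(NA_real_, nrow(traj)), key)
  rows <- data.frame(residue_number = traj$residue_number,
                     residue_type = traj$residue_type,
                     atom_group = traj$atom_group,
                     ratio = ratios[1], w_H = traj$w_H, w_N = traj$w_N,
                     intensity = traj$intensity, lost = FALSE,
                     ambiguous = FALSE, stringsAsFactors = FALSE)
  out <- list(rows)
  for (s in seq_along(ratios)[-1]) {
    pl <- series$peaklists[[s]]
    n_tr <- length(curH)
    newH <- rep(NA_real_, n_tr); newN <- rep(NA_real_, n_tr)
    newI <- rep(NA_real_, n_tr)
    step_amb <- rep(FALSE, n_tr)
    peak_used <- rep(FALSE, nrow(pl))
    if (nrow(pl) > 0 && any(alive)) {
      ti <- which(alive)
      d <- sqrt(.dist_matrix(curH[ti], curN[ti], pl$w_H, pl$w_N, n_weight))
      cost <- d
      if (intensity_weight > 0) {
        ilog <- abs(outer(log(curI[ti]), log(pl$intensity), "-"))
        ilog[is.na(ilog)] <- 0
        cost <- cost + intensity_weight * ilog
      }
      cand <- which(d <= gate, arr.ind = TRUE)
      had_candidate <- rep(FALSE, length(ti))
      if (nrow(cand) > 0) {
        had_candidate[unique(cand[, 1])] <- TRUE
        ord <- order(cost[cand], cand[, 2], cand[, 1])
        cand <- cand[ord, , drop = FALSE]
        traj_done <- rep(FALSE, length(ti))
        forbidden <- rep(FALSE, nrow(cand))
        ccost <- cost[cand]
        for (k in seq_len(nrow(cand))) {
          a <- cand[k, 1]; p <- cand[k, 2]
          if (traj_done[a] || peak_used[p] || forbidden[k]) next
          rivals <- which(abs(ccost - ccost[k]) <= ambiguity_margin &
                            (cand[, 1] == a | cand[, 2] == p) &
                            !forbidden &
                            !(cand[, 1] == a & cand[, 2] == p))
          rivals <- rivals[!traj_done[cand[rivals, 1]] &
                             !peak_used[cand[rivals, 2]]]
          if (length(rivals) > 0) {
            # the contested peak (or peak pair) is unsafe to adopt; the
            # trajectories stay free to match their other candidates
            forbidden[c(k, rivals)] <- TRUE
            if (any(cand[rivals, 2] == p & cand[rivals, 1] != a)) {
              peak_used[p] <- TRUE
            }
            next
          }
          j <- ti[a]
          newH[j] <- pl$w_H[p]; newN[j] <- pl$w_N[p]; newI[j] <- pl$intensity[p]
          traj_done[a] <- TRUE; peak_used[p] <- TRUE
        }
        # ambiguity: had candidates but all were claimed or contested —
        # such trajectories coast (keep position) instead of being lost
        step_amb[ti[had_candidate & !traj_done]] <- TRUE
      }
    }
    coasting <- alive & is.na(newH) & step_amb
    newly_lost <- alive & is.na(newH) & !step_amb
    lost_at[newly_lost] <- ratios[s]
    alive <- alive & !newly_lost
    matched <- alive & !coasting
    curH[matched] <- newH[matched]; curN[matched] <- newN[matched]
    curI[matched] <- newI[matched]
    nt0 <- seq_len(nrow(traj))
    out[[s]] <- data.frame(residue_number = traj$residue_number,
                           residue_type = traj$residue_type,
                           atom_group = traj$atom_group,
                           ratio = ratios[s],
                           w_H = newH[nt0], w_N = newN[nt0],
                           intensity = newI[nt0],
                           lost = !alive[nt0],
                           ambiguous = step_amb[nt0],
                           stringsAsFactors = FALSE)
    if (include_unassigned && any(!peak_used)) {
      # unclaimed signals spawn anonymous claimants for the next step
      fresh <- which(!peak_used)
      curH <- c(curH, pl$w_H[fresh]); curN <- c(curN, pl$w_N[fresh])
      curI <- c(curI, pl$intensity[fresh])
      alive <- c(alive, rep(TRUE, length(fresh)))
      lost_at <- c(lost_at, rep(NA_real_, length(fresh)))
    }
  }
  res <- do.call(rbind, out)
  res <- res[!is.na(res$residue_number), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "lost_at") <- lost_at[seq_len(nrow(traj))][named]
  class(res) <- c("trajectories", "data.frame")
  res
}

#' Forward-backward consistency check for tracked trajectories
#'
#' Re-tracks each trajectory from its bound-state endpoint backwards
#' through the titration and compares where it lands with the residue's
#' assigned free-form position. A trajectory that silently adopted a
#' neighbouring signal on the way out will follow that signal's history
#' on the way back and return to the wrong free-form position; one that
#' tracked its own signal returns to within measurement noise. Endpoint
#' assignments that fail to return within `tol`, or that cannot be
#' resolved on the way back, are reported as unreliable.
#'
#' @param series the `titration_series` used for the forward pass.
#' @param endpoints an assigned [peaklist()] of bound-state endpoints
#'   (peaks of the last spectrum labelled by the forward pass).
#' @param assigned_free the assigned free-form [peaklist()].
#' @param tol maximum scaled distance between the back-tracked position
#'   and the free-form position (default 0.03, about twice the
#'   peak-position noise between two spectra).
#' @param ... passed to [track_titration()] (gate, weights, margin).
#' @return character vector of residue keys
#'   (`"<residue>/<atom group>"`) whose round trip failed.
#' @export
check_tracking_roundtrip <- function(series, endpoints, assigned_free,
                                     tol = 0.03, ...) {
  nlists <- length(series$peaklists)
  rev_series <- titration_series(seq(0, nlists - 1),
                                 rev(series$peaklists))
  back <- track_titration(rev_series, endpoints, ...)
  last <- back[back$ratio == nlists - 1, , drop = FALSE]
  fa <- assigned_free[!is.na(assigned_free$residue_number), , drop = FALSE]
  i <- match(residue_key(last), residue_key(fa))
  dH <- last$w_H - fa$w_H[i]
  dN <- last$w_N - fa$w_N[i]
  bad <- is.na(dH) | scaled_dist(dH, dN) > tol
  residue_key(last)[bad]
}

#' Construct a titration series
#'
#' @param molar_ratios strictly increasing ligand:protein molar ratios; the
#'   first must be 0 (the free form).
#' @param peaklists one [peaklist()] per ratio.
#' @export
titration_series <- function(molar_ratios, peaklists) {
  stopifnot(length(molar_ratios) == length(peaklists),
            all(diff(molar_ratios) > 0))
  if (molar_ratios[1] != 0) stop("first molar ratio must be 0 (free form)")
  if (!all(vapply(peaklists, inherits, TRUE, "peaklist"))) {
    stop("peaklists must all be peaklist objects")
  }
  structure(list(molar_ratios = molar_ratios, peaklists = peaklists),
            class = "titration_series")
}

#' Final bound-state position of each trajectory
#'
#' @param trj a `trajectories` object from [track_titration()].
#' @return data frame with one row per trajectory: last tracked position
#'   and intensity, the ratio at which it was last seen, and `lost_at`.
#' @export
trajectory_endpoints <- function(trj) {
  stopifnot(inherits(trj, "trajectories"))
  lost_at <- attr(trj, "lost_at")
  sp <- split(seq_len(nrow(trj)), residue_key(trj))
  out <- do.call(rbind, lapply(sp, function(idx) {
    g <- trj[idx, ]
    g <- g[order(g$ratio), ]
    seen <- g[!is.na(g$w_H), ]
    last <- seen[nrow(seen), ]
    data.frame(residue_number = last$residue_number,
               residue_type = last$residue_type,
               atom_group = last$atom_group,
               w_H = last$w_H, w_N = last$w_N,
               intensity = last$intensity,
               last_ratio = last$ratio,
               lost_at = unname(lost_at[residue_key(last)]),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$residue_number, out$atom_group), ]
  rownames(out) <- NULL
  out
}
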