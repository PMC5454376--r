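#' Build a validated run configuration
#'
#' Collects every tunable of the pipeline in one object. Inputs are either
#' file paths (`free_list`, `bound_list`, `shift_table`) or, when these are
#' `NULL`, synthetic data generated from `profile`/`n_residues`/`seed`.
#'
#' @param out_dir output directory (created if needed).
#' @param seed seed for every stochastic stage.
#' @param profile synthetic profile name (see [default_profile()]).
#' @param n_residues synthetic shift-table size.
#' @param free_list,bound_list,shift_table optional input paths.
#' @param annotation region annotation path; `NULL` uses the shipped
#'   Galpha-i3 table.
#' @param pdb structure path; `"synthetic"` (default) writes a synthetic
#'   C-alpha model; `NULL` skips the structure stage.
#' @param chain,numbering_offset structure mapping options.
#' @param reference_residue intensity-normalization reference.
#' @param n_weight,averaging CSP convention.
#' @param thresholds median multiples for significance classes.
#' @param r_accept,gate assignment-transfer radii (scaled ppm).
#' @param bound_gate nearest-neighbour gate for bound-form assignment from
#'   the free form (scaled ppm; wide enough for typical CSPs). Used in
#'   file-input mode, where only a free/bound pair is available.
#' @param track_gate per-step gate for titration tracking (scaled ppm).
#' @param overlap_limit free-form peaks closer than this (scaled ppm) are
#'   excluded as unresolvable overlaps (reported no-data), since matching
#'   between them can silently swap identities.
#' @param kd_uM,protein_uM,ratios synthetic titration conditions: the
#'   bound form is assigned by tracking peaks stepwise along a simulated
#'   titration, the assignment strategy a single free/bound pair cannot
#'   support when shift changes exceed the peak spacing.
#' @param binding_panel also run the synthetic mutant FP/activity panel.
#' @param fold_bounds,inhibition_bounds panel class boundaries.
#' @return a `run_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1, profile = "givct",
                            n_residues = 250, free_list = NULL,
                            bound_list = NULL, shift_table = NULL,
                            annotation = NULL, pdb = "synthetic",
                            chain = "A", numbering_offset = 0,
                            reference_residue = 354, n_weight = 0.2,
                            averaging = TRUE, thresholds = c(3, 5, 10),
                            r_accept = 0.05, gate = 0.5, bound_gate = 0.3,
                            track_gate = 0.08, overlap_limit = 0.03,
                            kd_uM = 10, protein_uM = 32,
                            ratios = c(0, 0.2, 0.5, 1, 2, 5),
                            binding_panel = FALSE,
                            fold_bounds = c(2, 0.5),
                            inhibition_bounds = c(30, 50)) {
  cfg <- as.list(environment())
  stopifnot(length(cfg$thresholds) == 3, all(diff(cfg$thresholds) > 0),
            all(cfg$fold_bounds > 0), all(cfg$inhibition_bounds > 0),
            diff(cfg$inhibition_bounds) > 0)
  for (p in c("free_list", "bound_list", "shift_table", "annotation")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop("input path for ", p, " does not exist: ", cfg[[p]])
    }
  }
  file_inputs <- !vapply(cfg[c("free_list", "bound_list", "shift_table")],
                         is.null, TRUE)
  if (any(file_inputs) && !all(file_inputs)) {
    stop("free_list, bound_list and shift_table must be given together")
  }
  cfg$synthetic <- !any(file_inputs)
  class(cfg) <- "run_config"
  cfg
}

#' Run the perturbation-mapping pipeline end to end
#'
#' Stages: (synthetic generation or input reading) -> referencing-offset
#' estimation -> assignment transfer onto free and bound lists -> CSP /
#' intensity-ratio perturbation records -> median-multiple classification
#' -> region summary -> structure mapping -> optional synthetic mutant
#' binding/activity panel. All tables, an annotated PDB, a provenance
#' record (config echo, package version, seed — no timestamp, so repeated
#' runs are byte-identical) and a plain-text log are written to
#' `config$out_dir`. Any stage error aborts the run, removes partial
#' outputs and names the failing stage.
#'
#' @param config a `run_config` from [pipeline_config()].
#' @return invisibly, a list with the main in-memory results (`offsets`,
#'   `records`, `regions`, `files`, and panel results when enabled).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  emit <- function(name) { p <- file.path(config$out_dir, name); written <<- c(written, p); p }
  stage <- "setup"
  res <- tryCatch({
    series <- NULL
    if (config$synthetic) {
      stage <- "simulate"
      profile <- default_profile(config$profile)
      profile$reference_residue <- config$reference_residue
      shifts <- gen_shift_table(config$n_residues, seed = config$seed)
      series <- gen_titration(shifts, profile, kd_uM = config$kd_uM,
                              protein_uM = config$protein_uM,
                              ratios = config$ratios,
                              seed = config$seed + 1,
                              n_weight = config$n_weight)
      free_raw <- strip_assignments(series$peaklists[[1]])
      note("simulate: profile '%s', %d residues, titration 1:%s, seed %d",
           profile$name, config$n_residues,
           paste(config$ratios[-1], collapse = "/1:"), config$seed)
    } else {
      stage <- "read-inputs"
      shifts <- read_shift_table(config$shift_table)
      free_raw <- read_peaklist(config$free_list)
      bound_raw <- read_peaklist(config$bound_list)
      note("inputs: %d reference entries, %d free peaks, %d bound peaks",
           nrow(shifts), nrow(free_raw), nrow(bound_raw))
    }
    annotation <- if (is.null(config$annotation)) gai3_regions()
      else read_region_annotation(config$annotation)

    stage <- "estimate-offset"
    offsets <- estimate_offset(free_raw, shifts, n_weight = config$n_weight,
                               gate = config$gate)
    note("offsets: dH = %+.4f, dN = %+.4f ppm (n = %d matched)",
         offsets$delta_H, offsets$delta_N, offsets$n_matched)
    jsonlite::write_json(
      list(delta_H = offsets$delta_H, delta_N = offsets$delta_N,
           n_matched = offsets$n_matched, mad_H = offsets$mad_H,
           mad_N = offsets$mad_N, reliable = offsets$reliable),
      emit("offsets.json"), auto_unbox = TRUE, digits = NA)

    stage <- "transfer"
    free_asn <- transfer_assignments(free_raw, shifts, offsets,
                                     n_weight = config$n_weight,
                                     r_accept = config$r_accept)
    note("transfer: %d / %d reference entries assigned on the free list",
         attr(free_asn, "n_transferred"), nrow(shifts))
    # overlapped free-form signals are tracked (so they keep claiming their
    # own peaks) but excluded from the per-residue analysis afterwards:
    # matching between coincident peaks can swap identities silently
    ov <- flag_overlaps(free_asn, limit = config$overlap_limit,
                        n_weight = config$n_weight)
    overlapped <- residue_key(free_asn)[ov & !is.na(free_asn$residue_number)]
    if (length(overlapped) > 0) {
      note("overlap filter: %d assigned signal(s) within %.3f scaled ppm of a neighbour reported as no reliable measurement",
           length(overlapped), config$overlap_limit)
    }
    if (!is.null(series)) {
      # bound-form assignment by stepwise tracking along the titration:
      # peaks lost on the way are treated as broadened beyond detection
      stage <- "titrate"
      trj <- track_titration(series, free_asn, n_weight = config$n_weight,
                             gate = config$track_gate)
      utils::write.csv(as.data.frame(trj), emit("trajectories.csv"),
                       row.names = FALSE, quote = FALSE)
      # trajectories without a matched observation at the top ratio (still
      # coasting through an ambiguous contest) are unreliable, not
      # broadened: report them as no-data rather than flooring their ratio
      top <- max(series$molar_ratios)
      at_top <- trj[trj$ratio == top, , drop = FALSE]
      amb <- residue_key(at_top[!at_top$lost & is.na(at_top$w_H), , drop = FALSE])
      if (length(amb) > 0) {
        note("tracking: %d trajectory(ies) unresolved at the final ratio reported as no reliable measurement",
             length(amb))
        overlapped <- union(overlapped, amb)
      }
      fin <- at_top[!at_top$lost & !is.na(at_top$w_H), , drop = FALSE]
      bound_asn <- peaklist(
        data.frame(label = format_assignment(fin$residue_type,
                                             fin$residue_number,
                                             fin$atom_group),
                   residue_number = fin$residue_number,
                   residue_type = fin$residue_type,
                   atom_group = fin$atom_group,
                   w_N = fin$w_N, w_H = fin$w_H,
                   intensity = fin$intensity,
                   stringsAsFactors = FALSE),
        spectrum_id = "tracked_bound",
        condition = sprintf("molar ratio 1:%g", top))
      note("titrate: %d of %d trajectories tracked to ratio 1:%g",
           nrow(fin), attr(free_asn, "n_transferred"), top)
      bad_rt <- check_tracking_roundtrip(series, bound_asn, free_asn,
                                         n_weight = config$n_weight,
                                         gate = config$track_gate)
      if (length(bad_rt) > 0) {
        note("round-trip check: %d endpoint(s) failed backward tracking reported as no reliable measurement",
             length(bad_rt))
        overlapped <- union(overlapped, bad_rt)
      }
    } else {
      bound_asn <- assign_bound_form(free_asn, bound_raw,
                                     n_weight = config$n_weight,
                                     gate = config$bound_gate)
      note("bound assignment: %d peaks matched by nearest neighbour",
           attr(bound_asn, "n_transferred"))
    }
    write_peaklist(free_asn, emit("assigned_free.list"))
    write_peaklist(bound_asn, emit("assigned_bound.list"))

    stage <- "perturbation"
    records <- perturbation_records(free_asn, bound_asn,
                                    reference_residue = config$reference_residue,
                                    n_weight = config$n_weight,
                                    averaging = config$averaging)
    records <- records[!residue_key(records) %in% overlapped, , drop = FALSE]
    records <- classify_records(records, thresholds = config$thresholds)
    med <- attr(records, "medians")
    note("perturbation: %d records; median CSP %.4f ppm, median I_ratio %.3f",
         nrow(records), med["csp"], med["i_ratio"])
    write_perturbation_table(records, emit("perturbation.csv"))

    stage <- "region-summary"
    regions <- summarize_regions(records, annotation)
    utils::write.csv(regions, emit("region_summary.csv"), row.names = FALSE,
                     quote = FALSE)
    for (i in seq_len(nrow(regions))) {
      note("region %-14s %-12s", regions$name[i], regions$status[i])
    }

    stage <- "structure-map"
    structure_files <- NULL
    if (!is.null(config$pdb)) {
      pdb_path <- config$pdb
      if (identical(pdb_path, "synthetic")) {
        pdb_path <- emit("synthetic_model.pdb")
        gen_synthetic_pdb(pdb_path, chain = config$chain)
      }
      map_to_structure(records, pdb_path, emit("structure_map.pdb"),
                       out_csv = emit("structure_map.csv"),
                       offset = config$numbering_offset, chain = config$chain)
      note("structure: classes written to B-factors of %s", basename(pdb_path))
    }

    panel <- NULL
    if (isTRUE(config$binding_panel)) {
      stage <- "binding-panel"
      truth <- gen_panel_truth(seed = config$seed + 2)
      fp <- gen_fp_panel(truth, seed = config$seed + 3)
      fits <- do.call(rbind, lapply(split(fp, fp$ligand), function(g) {
        r <- normalize_to_wt_max(g[c("variant", "conc_uM", "response")])
        cbind(r$fits, ligand = g$ligand[1])
      }))
      mat <- build_kd_matrix(fits, fold_bounds = config$fold_bounds)
      write_kd_table(mat, emit("kd_matrix.csv"))
      cr <- correlate_mutant_effects(mat, truth$ligands[1], truth$ligands[2])
      note("panel: cross-ligand Pearson r = %.3f over %d mutants (true rho %.2f)",
           cr$r, cr$n, truth$rho)
      act <- gen_activity_panel(truth, seed = config$seed + 4)
      act_w <- stats::reshape(act, idvar = c("variant", "ligand"),
                              timevar = "condition", direction = "wide")
      names(act_w) <- sub("^activity\\.", "", names(act_w))
      a <- compute_activation(act_w$gef, act_w$basal)
      wt_delta <- a$activation_delta[act_w$variant == "WT"][1]
      inh <- classify_inhibition(a$activation_delta, wt_delta,
                                 bounds = config$inhibition_bounds)
      activity <- cbind(act_w, a, inh)
      utils::write.csv(activity, emit("activity.csv"), row.names = FALSE,
                       quote = FALSE)
      panel <- list(truth = truth, kd_matrix = mat, correlation = cr,
                    activity = activity)
    }

    stage <- "provenance"
    cfg_echo <- unclass(config)
    jsonlite::write_json(
      list(package = "gbamap",
           version = as.character(utils::packageVersion("gbamap")),
           config = cfg_echo, seed = config$seed),
      emit("provenance.json"), auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(log_lines, emit("run.log"))
    list(offsets = offsets, records = records, regions = regions,
         panel = panel, files = written,
         truth = if (config$synthetic) attr(series, "truth") else NULL)
  }, error = function(e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
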