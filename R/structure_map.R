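# Numeric codes written to the B-factor column: viewer-agnostic, bit-exact.
.class_codes <- c(no_data = -1, below = 0, weak = 1, medium = 2, strong = 3)

#' Project perturbation classes onto a PDB structure
#'
#' Writes a copy of the structure with the temperature-factor (B-factor)
#' column of every atom replaced by a numeric code for the residue's
#' composite class: no_data = -1, below = 0, weak = 1, medium = 2,
#' strong = 3. Residues of the structure never observed by NMR get -1.
#' Record residue numbers are translated to structure numbering by an
#' explicit offset (`pdb_resno = residue_number + offset`).
#'
#' @param records classified `perturbation_records`
#'   (see [classify_records()]).
#' @param pdb_path input PDB file.
#' @param out_pdb output PDB path.
#' @param out_csv optional CSV path for the per-residue table.
#' @param offset sequence-numbering offset (UniProt to PDB).
#' @param chain chain identifier; `NULL` uses all chains.
#' @param class_column records column to project (default
#'   `"composite_class"`).
#' @return invisibly, a data frame with `residue_number` (record scheme),
#'   `pdb_resno`, `class`, `code`; attribute `unresolved` lists record
#'   residues absent from the structure.
#' @export
map_to_structure <- function(records, pdb_path, out_pdb, out_csv = NULL,
                             offset = 0, chain = NULL,
                             class_column = "composite_class") {
  if (!class_column %in% names(records)) {
    stop("records have no '", class_column, "' column; run classify_records() first")
  }
  pdb <- bio3d::read.pdb(pdb_path)
  atom <- pdb$atom
  in_chain <- if (is.null(chain)) rep(TRUE, nrow(atom)) else atom$chain == chain
  # one class per record residue (backbone entry wins over indole)
  rec <- records[order(records$residue_number,
                       records$atom_group != "backbone-amide"), ]
  rec <- rec[!duplicated(rec$residue_number), ]
  code <- .class_codes[as.character(rec[[class_column]])]
  pdb_resno <- rec$residue_number + offset
  b <- rep(.class_codes[["no_data"]], nrow(atom))
  resolved <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    sel <- in_chain & atom$resno == pdb_resno[i]
    resolved[i] <- any(sel)
    b[sel] <- code[i]
  }
  # empty records degrade to an all no-data structure; non-empty records
  # that resolve nothing indicate a wrong offset or chain
  if (nrow(rec) > 0 && !any(resolved)) {
    stop("no record residue resolved in the structure (check offset/chain)")
  }
  pdb$atom$b <- b
  bio3d::write.pdb(pdb, file = out_pdb)
  out <- data.frame(residue_number = rec$residue_number,
                    pdb_resno = pdb_resno,
                    class = as.character(rec[[class_column]]),
                    code = unname(code),
                    in_structure = resolved,
                    stringsAsFactors = FALSE)
  attr(out, "unresolved") <- rec$residue_number[!resolved]
  if (!is.null(out_csv)) {
    utils::write.csv(out, out_csv, row.names = FALSE, quote = FALSE)
  }
  invisible(out)
}

#' Summarize perturbation classes over annotated regions
#'
#' For each annotated segment (G-box, switch, helix, ...), counts residues
#' per class, the fraction of the segment with NMR data, and the top class
#' present. A segment is `"perturbed"` when every residue with data exceeds
#' `below`, `"unperturbed"` when none does, `"mixed"` otherwise and
#' `"no-data"` when no residue has data. With an empty annotation a single
#' whole-chain summary row is returned.
#'
#' @param records classified `perturbation_records`.
#' @param annotation a `region_annotation`
#'   (see [read_region_annotation()]).
#' @param class_column records column to summarize.
#' @return a data frame with one row per segment: identity, per-class
#'   counts (`n_no_data` ... `n_strong`), `n_data`, `fraction_with_data`,
#'   `top_class`, `status`.
#' @export
summarize_regions <- function(records, annotation,
                              class_column = "composite_class") {
  if (!class_column %in% names(records)) {
    stop("records have no '", class_column, "' column; run classify_records() first")
  }
  rec <- records[order(records$residue_number,
                       records$atom_group != "backbone-amide"), ]
  rec <- rec[!duplicated(rec$residue_number), ]
  cls <- rec[[class_column]]
  if (nrow(annotation) == 0) {
    annotation <- data.frame(name = "whole-chain",
                             start = min(rec$residue_number),
                             end = max(rec$residue_number),
                             category = "domain", stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(annotation)), function(i) {
    seg <- annotation[i, ]
    len <- seg$end - seg$start + 1L
    in_seg <- rec$residue_number >= seg$start & rec$residue_number <= seg$end
    seg_cls <- as.character(cls[in_seg])
    # residues of the segment never observed count as no_data
    n_missing <- len - sum(in_seg)
    counts <- table(factor(seg_cls, levels = .class_levels))
    counts["no_data"] <- counts["no_data"] + n_missing
    if (sum(in_seg) == 0) {
      warning("segment '", seg$name, "' is fully outside the record range")
    }
    n_data <- sum(counts[c("below", "weak", "medium", "strong")])
    n_above <- sum(counts[c("weak", "medium", "strong")])
    top <- if (n_data > 0) .class_levels[max(which(counts > 0))] else "no_data"
    status <- if (n_data == 0) "no-data"
      else if (n_above == 0) "unperturbed"
      else if (n_above == n_data) "perturbed"
      else "mixed"
    data.frame(name = seg$name, category = seg$category,
               start = seg$start, end = seg$end, length = len,
               n_no_data = as.integer(counts["no_data"]),
               n_below = as.integer(counts["below"]),
               n_weak = as.integer(counts["weak"]),
               n_medium = as.integer(counts["medium"]),
               n_strong = as.integer(counts["strong"]),
               n_data = as.integer(n_data),
               fraction_with_data = n_data / len,
               top_class = top, status = status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
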