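# Vocabulary shared across the package
.atom_groups <- c("backbone-amide", "trp-indole")
.region_categories <- c("G-box", "switch", "helix", "strand", "loop", "domain")
.class_levels <- c("no_data", "below", "weak", "medium", "strong")

#' Construct a peak list
#'
#' A peak list is a data frame with one row per 2D amide signal and columns
#' `label` (assignment string or `NA` for unassigned), `residue_number`,
#' `residue_type` (one-letter code), `atom_group` (`"backbone-amide"` or
#' `"trp-indole"`), `w_N` and `w_H` (chemical shifts, ppm) and `intensity`
#' (signal height, arbitrary units; `NA` when not measured — distinct from
#' an observed zero). Spectrum identity and condition travel as attributes.
#'
#' @param peaks data frame with at least `w_N`, `w_H`; optional `label`,
#'   `residue_number`, `residue_type`, `atom_group`, `intensity`.
#' @param spectrum_id character scalar identifying the spectrum.
#' @param condition free-text condition metadata (ligand, molar ratio).
#' @return object of class `peaklist`.
#' @export
peaklist <- function(peaks, spectrum_id = "", condition = "") {
  stopifnot(is.data.frame(peaks), all(c("w_N", "w_H") %in% names(peaks)))
  n <- nrow(peaks)
  out <- data.frame(
    label = if ("label" %in% names(peaks)) as.character(peaks$label) else rep(NA_character_, n),
    residue_number = if ("residue_number" %in% names(peaks)) as.integer(peaks$residue_number) else rep(NA_integer_, n),
    residue_type = if ("residue_type" %in% names(peaks)) as.character(peaks$residue_type) else rep(NA_character_, n),
    atom_group = if ("atom_group" %in% names(peaks)) as.character(peaks$atom_group) else rep(NA_character_, n),
    w_N = as.numeric(peaks$w_N),
    w_H = as.numeric(peaks$w_H),
    intensity = if ("intensity" %in% names(peaks)) as.numeric(peaks$intensity) else rep(NA_real_, n),
    stringsAsFactors = FALSE
  )
  lab <- out$label[!is.na(out$label)]
  if (anyDuplicated(lab)) {
    stop("duplicate assigned labels in peak list: ",
         paste(unique(lab[duplicated(lab)]), collapse = ", "))
  }
  bad <- !is.na(out$w_H) &
    (out$w_H < 4 | out$w_H > 13 | out$w_N < 95 | out$w_N > 140)
  if (any(bad)) {
    warning(sum(bad), " peak(s) outside the usual amide/indole shift window ",
            "(1H 4-13, 15N 95-140 ppm)")
  }
  structure(out, spectrum_id = spectrum_id, condition = condition,
            class = c("peaklist", "data.frame"))
}

# Parse a Sparky-style assignment label into residue fields.
# Recognized: "Y354N-H" / "Y354N-HN" (backbone), "W211NE1-HE1" (indole),
# "?-?" (unassigned). Anything else is kept as a bare label.
parse_assignment <- function(label) {
  n <- length(label)
  out <- data.frame(residue_number = rep(NA_integer_, n),
                    residue_type = rep(NA_character_, n),
                    atom_group = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  bb <- regmatches(label, regexec("^([A-Z])([0-9]+)N-HN?$", label))
  ind <- regmatches(label, regexec("^([A-Z])([0-9]+)NE1-HE1$", label))
  for (i in seq_len(n)) {
    if (length(bb[[i]]) == 3) {
      out$residue_type[i] <- bb[[i]][2]
      out$residue_number[i] <- as.integer(bb[[i]][3])
      out$atom_group[i] <- "backbone-amide"
    } else if (length(ind[[i]]) == 3) {
      out$residue_type[i] <- ind[[i]][2]
      out$residue_number[i] <- as.integer(ind[[i]][3])
      out$atom_group[i] <- "trp-indole"
    }
  }
  out
}

format_assignment <- function(residue_type, residue_number, atom_group) {
  ifelse(is.na(residue_number), "?-?",
         ifelse(atom_group == "trp-indole",
                sprintf("%s%dNE1-HE1", residue_type, residue_number),
                sprintf("%s%dN-H", residue_type, residue_number)))
}

#' Read a Sparky-style peak list
#'
#' Whitespace-separated columns: Assignment, w1 (15N ppm), w2 (1H ppm) and an
#' optional Height. An optional header line is skipped. Unassigned rows carry
#' the sentinel `?-?`; a missing height is blank or `-`.
#'
#' @param path file path.
#' @param dialect only `"sparky"` is supported.
#' @param spectrum_id,condition metadata attached to the returned list;
#'   `spectrum_id` defaults to the file name.
#' @return a [peaklist()].
#' @export
read_peaklist <- function(path, dialect = "sparky",
                          spectrum_id = basename(path), condition = "") {
  dialect <- match.arg(dialect, "sparky")
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(peaklist(data.frame(w_N = numeric(), w_H = numeric()),
                    spectrum_id, condition))
  }
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  # header: second token not parseable as a number
  if (length(toks) && suppressWarnings(is.na(as.numeric(toks[[1]][2])))) {
    toks <- toks[-1]
    lineno <- lineno[-1]
  }
  n <- length(toks)
  label <- character(n); w_N <- w_H <- inten <- numeric(n)
  for (i in seq_len(n)) {
    tk <- toks[[i]]
    if (length(tk) < 3) stop("line ", lineno[i], ": expected at least 3 fields")
    label[i] <- tk[1]
    v <- suppressWarnings(as.numeric(tk[2:3]))
    if (anyNA(v)) stop("line ", lineno[i], ": malformed numeric field")
    w_N[i] <- v[1]; w_H[i] <- v[2]
    if (length(tk) >= 4 && tk[4] != "-") {
      h <- suppressWarnings(as.numeric(tk[4]))
      if (is.na(h)) stop("line ", lineno[i], ": malformed numeric field")
      inten[i] <- h
    } else inten[i] <- NA_real_
  }
  label[label == "?-?"] <- NA_character_
  parsed <- parse_assignment(ifelse(is.na(label), "", label))
  peaklist(data.frame(label = label, parsed, w_N = w_N, w_H = w_H,
                      intensity = inten, stringsAsFactors = FALSE),
           spectrum_id, condition)
}

#' Write a Sparky-style peak list
#'
#' Shifts and heights are written with full double precision so that
#' read-write-read round trips are bit-exact.
#'
#' @param pl a [peaklist()].
#' @param path output path.
#' @export
write_peaklist <- function(pl, path) {
  stopifnot(inherits(pl, "peaklist"))
  lab <- ifelse(is.na(pl$label), "?-?", pl$label)
  num <- function(x) ifelse(is.na(x), "-", sprintf("%.17g", x))
  rows <- sprintf("%-16s %s %s %s", lab, num(pl$w_N), num(pl$w_H), num(pl$intensity))
  writeLines(c("Assignment w1 w2 Height", rows), path)
  invisible(path)
}

#' Read a simplified BMRB-style chemical shift table
#'
#' Tab-separated columns `residue_number`, `residue_type`, `atom`,
#' `shift_ppm` with atoms `N`/`H` (backbone amide) or `NE1`/`HE1`
#' (tryptophan indole). The two atoms of a pair are merged into one entry;
#' residues with only one atom of a pair are skipped with a warning.
#'
#' @param path file path.
#' @return a `shift_table` data frame with columns `residue_number`,
#'   `residue_type`, `atom_group`, `w_H`, `w_N`.
#' @export
read_shift_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue_number", "residue_type", "atom", "shift_ppm")
  if (!all(need %in% names(df))) {
    stop("shift table must have columns: ", paste(need, collapse = ", "))
  }
  if (!is.numeric(df$shift_ppm)) stop("non-numeric shift_ppm values")
  df$atom_group <- ifelse(df$atom %in% c("N", "H"), "backbone-amide",
                          ifelse(df$atom %in% c("NE1", "HE1"), "trp-indole", NA))
  if (anyNA(df$atom_group)) {
    stop("unknown atom(s): ", paste(unique(df$atom[is.na(df$atom_group)]), collapse = ", "))
  }
  key <- paste(df$residue_number, df$atom_group)
  out <- do.call(rbind, lapply(split(df, key), function(g) {
    hy <- g$shift_ppm[g$atom %in% c("H", "HE1")]
    ni <- g$shift_ppm[g$atom %in% c("N", "NE1")]
    if (length(hy) != 1 || length(ni) != 1) return(NULL)
    data.frame(residue_number = g$residue_number[1],
               residue_type = g$residue_type[1],
               atom_group = g$atom_group[1],
               w_H = hy, w_N = ni, stringsAsFactors = FALSE)
  }))
  n_in <- length(unique(key))
  if (is.null(out)) stop("no complete H/N pairs in shift table")
  if (nrow(out) < n_in) {
    warning(n_in - nrow(out), " residue(s) with an incomplete H/N pair skipped")
  }
  out <- out[order(out$residue_number, out$atom_group), ]
  rownames(out) <- NULL
  if (anyDuplicated(paste(out$residue_number, out$atom_group))) {
    stop("duplicate entries in shift table")
  }
  class(out) <- c("shift_table", "data.frame")
  out
}

#' Write a shift table in the simplified BMRB-style TSV dialect
#' @param st a `shift_table`.
#' @param path output path.
#' @export
write_shift_table <- function(st, path) {
  stopifnot(inherits(st, "shift_table"))
  long <- do.call(rbind, lapply(seq_len(nrow(st)), function(i) {
    at <- if (st$atom_group[i] == "trp-indole") c("NE1", "HE1") else c("N", "H")
    data.frame(residue_number = st$residue_number[i],
               residue_type = st$residue_type[i],
               atom = at, shift_ppm = c(st$w_N[i], st$w_H[i]),
               stringsAsFactors = FALSE)
  }))
  long$shift_ppm <- sprintf("%.17g", long$shift_ppm)
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a region annotation table
#'
#' Comma- or tab-separated columns `name`, `start`, `end`, `category` with
#' category one of G-box, switch, helix, strand, loop, domain. Segments
#' may overlap; `start <= end` and names must be unique. Residue numbers are
#' in the same scheme as the shift table (UniProt numbering by default).
#'
#' @param path file path (`.csv` or `.tsv`; separator auto-detected).
#' @return a `region_annotation` data frame.
#' @export
read_region_annotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    df <- data.frame(name = character(), start = integer(), end = integer(),
                     category = character(), stringsAsFactors = FALSE)
    class(df) <- c("region_annotation", "data.frame")
    return(df)
  }
  need <- c("name", "start", "end", "category")
  if (!all(need %in% names(df))) {
    stop("region annotation must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[need]
  bad <- !(df$category %in% .region_categories)
  if (any(bad)) {
    stop("unknown region category '", df$category[bad][1],
         "'; allowed: ", paste(.region_categories, collapse = ", "))
  }
  if (any(df$start > df$end)) stop("region with start > end")
  if (anyDuplicated(df$name)) stop("duplicate region names")
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  class(df) <- c("region_annotation", "data.frame")
  df
}

#' Write / read per-residue perturbation tables
#'
#' CSV with one row per residue: residue identity, CSP (ppm), normalized
#' free/bound intensities, I_ratio and the three class labels. Floats are
#' written with full precision; re-reading reproduces the values.
#'
#' @param records a `perturbation_records` data frame (see
#'   [perturbation_records()]).
#' @param path output path.
#' @export
write_perturbation_table <- function(records, path) {
  df <- as.data.frame(records)
  for (cl in c("csp_class", "iratio_class", "composite_class")) {
    if (cl %in% names(df)) df[[cl]] <- as.character(df[[cl]])
  }
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      df[[nm]] <- ifelse(is.na(df[[nm]]), NA, sprintf("%.17g", df[[nm]]))
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_perturbation_table
#' @export
read_perturbation_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  for (cl in c("csp_class", "iratio_class", "composite_class")) {
    if (cl %in% names(df)) df[[cl]] <- factor(df[[cl]], levels = .class_levels, ordered = TRUE)
  }
  class(df) <- c("perturbation_records", "data.frame")
  df
}

#' Write a Kd matrix as CSV
#' @param mat a `kd_matrix` (see [build_kd_matrix()]).
#' @param path output path.
#' @export
write_kd_table <- function(mat, path) {
  df <- as.data.frame(mat)
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      df[[nm]] <- ifelse(is.na(df[[nm]]), NA, sprintf("%.17g", df[[nm]]))
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Drop assignment information from a peak list
#'
#' Returns the same positions and intensities with all labels cleared, as an
#' instrument would export them before assignment transfer.
#' @param pl a [peaklist()].
#' @export
strip_assignments <- function(pl) {
  pl$label <- NA_character_
  pl$residue_number <- NA_integer_
  pl$residue_type <- NA_character_
  pl$atom_group <- NA_character_
  pl
}

# residue key used for joins: number + atom group
residue_key <- function(df) paste0(df$residue_number, "/", df$atom_group)
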