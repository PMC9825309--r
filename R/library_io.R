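# Precursor library input: Prosit-style CSV, MaxQuant-style evidence/msms
# tables, NIST .msp decoy libraries, and the built-in synthetic generator.
#
# A library is a tibble with one row per precursor (precursor_id,
# stripped_sequence, modified_sequence, charge, precursor_mz, rt_coord,
# rt_basis, base_abundance, source) and a `fragments` list-column of tibbles
# (series, index, charge, mz, rel_intensity).

.new_library <- function(df) {
  tibble::new_tibble(df, class = "dia_library")
}

.fragment_tbl <- function(series, index, charge, mz, rel_intensity) {
  m <- max(rel_intensity)
  tibble::tibble(series = series, index = as.integer(index),
                 charge = as.integer(charge), mz = mz,
                 rel_intensity = if (m > 0) rel_intensity / m else rel_intensity)
}

.require_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0("missing required column(s) in ", what, ": ",
                 paste(missing, collapse = ", ")))
  }
}

#' Default Prosit CSV column mapping
#'
#' Maps the generic Prosit spectral-library export header onto the internal
#' field names. Override individual entries through the `column_map` argument
#' of [read_prosit_library()] if a dialect differs.
#'
#' @return Named character vector `internal_name = csv_column`.
#' @export
prosit_column_map <- function() {
  c(modified_sequence = "ModifiedPeptide",
    stripped_sequence = "StrippedPeptide",
    charge            = "PrecursorCharge",
    precursor_mz      = "PrecursorMz",
    irt               = "iRT",
    fragment_mz       = "FragmentMz",
    fragment_type     = "FragmentType",
    fragment_number   = "FragmentNumber",
    fragment_charge   = "FragmentCharge",
    rel_intensity     = "RelativeIntensity")
}

#' Read a Prosit-style spectral library
#'
#' Reads a long-format CSV (one row per fragment) as exported by Prosit-style
#' spectral-library predictors, grouping rows by (modified sequence, charge)
#' into one precursor each. Fragment intensities are normalized to base peak
#' = 1 within each precursor. Retention coordinates are iRT scores. Gzip input
#' is handled transparently.
#'
#' @param path CSV file (optionally gzip-compressed).
#' @param column_map Named character vector mapping internal names to CSV
#'   column names; see [prosit_column_map()].
#' @param base_abundance Base abundance assigned to every precursor (Prosit
#'   libraries carry no abundance; default 1e5).
#' @return A precursor library tibble.
#' @export
read_prosit_library <- function(path, column_map = prosit_column_map(),
                                base_abundance = 1e5) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!nrow(df)) abort(paste0("empty spectral library: ", path))
  .require_columns(df, unname(column_map), paste0("Prosit library ", path))
  df <- df |>
    dplyr::rename(!!!rlang::set_names(unname(column_map), names(column_map)))
  grouped <- df |>
    dplyr::group_by(.data$modified_sequence, .data$charge) |>
    dplyr::summarise(
      stripped_sequence = .data$stripped_sequence[1],
      mz_spread_ppm = 1e6 * diff(range(.data$precursor_mz)) / .data$precursor_mz[1],
      precursor_mz = .data$precursor_mz[1],
      rt_coord = .data$irt[1],
      fragments = list(.fragment_tbl(.data$fragment_type, .data$fragment_number,
                                     .data$fragment_charge, .data$fragment_mz,
                                     .data$rel_intensity)),
      .groups = "drop"
    )
  bad <- grouped$mz_spread_ppm > 10
  if (any(bad)) {
    abort(sprintf(
      "conflicting precursor m/z (> 10 ppm spread) for %d precursor(s), e.g. %s/%d",
      sum(bad), grouped$modified_sequence[which(bad)[1]],
      grouped$charge[which(bad)[1]]))
  }
  .new_library(tibble::tibble(
    precursor_id = paste0(grouped$modified_sequence, "/", grouped$charge),
    stripped_sequence = grouped$stripped_sequence,
    modified_sequence = grouped$modified_sequence,
    charge = as.integer(grouped$charge),
    precursor_mz = grouped$precursor_mz,
    rt_coord = grouped$rt_coord,
    rt_basis = "irt",
    base_abundance = base_abundance,
    source = "prosit",
    fragments = grouped$fragments
  ))
}

#' Default MaxQuant column mapping
#'
#' Column names consumed from MaxQuant-style `evidence.txt` and `msms.txt`
#' tables. MaxQuant txt schemas drift across versions, so the mapping is
#' user-overridable.
#'
#' @return Named character vector `internal_name = tsv_column`.
#' @export
maxquant_column_map <- function() {
  c(sequence       = "Sequence",
    modifications  = "Modifications",
    charge         = "Charge",
    mz             = "m/z",
    retention_time = "Retention time",
    intensity      = "Intensity",
    msms_id        = "Best MS/MS",
    msms_key       = "id",
    msms_masses    = "Masses",
    msms_intensities = "Intensities")
}

#' Read a MaxQuant-style evidence table
#'
#' Reads an evidence-like TSV (one row per precursor observation) plus an
#' msms-like TSV carrying semicolon-separated fragment mass and intensity
#' lists, joining fragments onto evidence rows. Retention coordinates are the
#' observed retention times (minutes); base abundances are the reported
#' intensities, with missing intensities imputed as the library median. Rows
#' with modifications other than unmodified/carbamidomethyl-Cys are dropped
#' with a warning, as are rows without fragment data.
#'
#' @param evidence_path Evidence TSV (optionally gzipped), or a directory
#'   containing `evidence.txt` and `msms.txt`.
#' @param msms_path msms TSV; defaults to `msms.txt` next to the evidence file.
#' @param column_map See [maxquant_column_map()].
#' @return A precursor library tibble.
#' @export
read_maxquant_evidence <- function(evidence_path, msms_path = NULL,
                                   column_map = maxquant_column_map()) {
  if (dir.exists(evidence_path)) {
    msms_path <- file.path(evidence_path, "msms.txt")
    evidence_path <- file.path(evidence_path, "evidence.txt")
  }
  if (is.null(msms_path)) {
    msms_path <- file.path(dirname(evidence_path), "msms.txt")
  }
  ev <- readr::read_tsv(evidence_path, show_col_types = FALSE, progress = FALSE)
  ms <- readr::read_tsv(msms_path, show_col_types = FALSE, progress = FALSE)
  ev_cols <- column_map[c("sequence", "modifications", "charge", "mz",
                          "retention_time", "intensity", "msms_id")]
  ms_cols <- column_map[c("msms_key", "msms_masses", "msms_intensities")]
  .require_columns(ev, unname(ev_cols), paste0("evidence table ", evidence_path))
  .require_columns(ms, unname(ms_cols), paste0("msms table ", msms_path))

  allowed_mods <- c("Unmodified", "Carbamidomethyl (C)")
  mods <- ev[[ev_cols[["modifications"]]]]
  bad_mod <- !is.na(mods) & !mods %in% allowed_mods
  if (any(bad_mod)) {
    warn(sprintf("dropped %d evidence row(s) with unsupported modifications (only carbamidomethyl-Cys is simulated)",
                 sum(bad_mod)))
    ev <- ev[!bad_mod, , drop = FALSE]
  }
  if (!nrow(ev)) abort("no usable evidence rows after modification filtering")

  msms_lookup <- setNames(seq_len(nrow(ms)), as.character(ms[[ms_cols[["msms_key"]]]]))
  idx <- msms_lookup[as.character(ev[[ev_cols[["msms_id"]]]])]
  no_frag <- is.na(idx)
  if (any(no_frag)) {
    warn(sprintf("dropped %d evidence row(s) without matching fragment data",
                 sum(no_frag)))
    ev <- ev[!no_frag, , drop = FALSE]
    idx <- idx[!no_frag]
  }
  if (!nrow(ev)) abort("no evidence rows with fragment data")

  parse_list <- function(x) as.numeric(strsplit(x, ";", fixed = TRUE)[[1]])
  fragments <- purrr::map(idx, function(i) {
    mzs <- parse_list(ms[[ms_cols[["msms_masses"]]]][i])
    ints <- parse_list(ms[[ms_cols[["msms_intensities"]]]][i])
    .fragment_tbl(series = rep("other", length(mzs)),
                  index = seq_along(mzs), charge = 1L,
                  mz = mzs, rel_intensity = ints)
  })
  abundance <- ev[[ev_cols[["intensity"]]]]
  if (anyNA(abundance)) {
    abundance[is.na(abundance)] <- median(abundance, na.rm = TRUE)
  }
  seqs <- ev[[ev_cols[["sequence"]]]]
  has_cam <- !is.na(mods <- ev[[ev_cols[["modifications"]]]]) &
    mods == "Carbamidomethyl (C)"
  modified <- ifelse(has_cam, gsub("C", "C[Carbamidomethyl]", seqs, fixed = TRUE),
                     seqs)
  charge <- as.integer(ev[[ev_cols[["charge"]]]])
  .new_library(tibble::tibble(
    precursor_id = paste0(modified, "/", charge),
    stripped_sequence = seqs,
    modified_sequence = modified,
    charge = charge,
    precursor_mz = ev[[ev_cols[["mz"]]]],
    rt_coord = ev[[ev_cols[["retention_time"]]]],
    rt_basis = "rt_min",
    base_abundance = abundance,
    source = "maxquant",
    fragments = fragments
  ))
}

#' Read a NIST .msp spectral library of decoy species
#'
#' Parses the NIST text format (`Name:`, `PrecursorMZ:` or `MW:` + `Charge:`,
#' `Num Peaks:`, then whitespace-separated peak lines). Peak intensities are
#' normalized to base peak = 1 per entry. Decoys mimic chemical contaminants
#' and background ions: they carry no sequence and are assigned retention
#' times at simulation time by [place_decoys()].
#'
#' @param path .msp file (optionally gzipped).
#' @return A tibble with columns `name`, `precursor_mz` and a `fragments`
#'   list-column; zero rows for an empty file (decoys are optional).
#' @export
read_msp <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- trimws(lines)
  starts <- grep("^Name:", lines, ignore.case = TRUE)
  if (!length(starts)) {
    return(tibble::tibble(name = character(), precursor_mz = numeric(),
                          fragments = list()))
  }
  ends <- c(starts[-1] - 1L, length(lines))
  entries <- purrr::map2(starts, ends, function(s, e) {
    block <- lines[s:e]
    name <- sub("^Name:\\s*", "", block[1], ignore.case = TRUE)
    get_field <- function(key) {
      hit <- grep(paste0("^", key, ":"), block, ignore.case = TRUE, value = TRUE)
      if (!length(hit)) return(NA_character_)
      trimws(sub("^[^:]+:\\s*", "", hit[1]))
    }
    pmz <- suppressWarnings(as.numeric(get_field("PrecursorMZ")))
    if (is.na(pmz)) {
      mw <- suppressWarnings(as.numeric(get_field("MW")))
      z <- suppressWarnings(as.integer(get_field("Charge")))
      if (is.na(mw) || is.na(z)) {
        abort(paste0("msp entry '", name,
                     "' has neither PrecursorMZ nor MW + Charge"))
      }
      pmz <- ion_mz(mw, z)
    }
    n_declared <- suppressWarnings(as.integer(get_field("Num Peaks")))
    peak_start <- grep("^Num Peaks:", block, ignore.case = TRUE)[1] + 1L
    peak_lines <- block[peak_start:length(block)]
    peak_lines <- peak_lines[nzchar(peak_lines)]
    vals <- purrr::map(peak_lines, function(l) {
      as.numeric(strsplit(l, "[[:space:];]+")[[1]][1:2])
    })
    mzs <- purrr::map_dbl(vals, 1)
    ints <- purrr::map_dbl(vals, 2)
    if (!is.na(n_declared) && length(mzs) != n_declared) {
      abort(sprintf("msp entry '%s' declares %d peaks but lists %d",
                    name, n_declared, length(mzs)))
    }
    tibble::tibble(
      name = name, precursor_mz = pmz,
      fragments = list(.fragment_tbl(rep("other", length(mzs)),
                                     seq_along(mzs), 1L, mzs, ints))
    )
  })
  dplyr::bind_rows(entries)
}

#' Generate a synthetic precursor library
#'
#' Builds a reproducible library of tryptic-like peptides from scratch so no
#' external spectral library is ever needed: random sequences of length 7-20
#' ending in K/R, charges 2-3, precursor m/z computed from the elemental
#' composition, iRT scores uniform over `irt_range`, lognormal base abundances
#' and b/y fragment ladders (charge 1) with random relative intensities.
#'
#' @param n_precursors Number of precursors (>= 1).
#' @param seed Integer seed; the same seed always yields the same library.
#' @param irt_range iRT range the precursors span (default 0-100).
#' @param length_range Peptide length range (default 7-20).
#' @param abundance_meanlog,abundance_sdlog Lognormal parameters of the base
#'   abundance distribution (defaults: median 1e5, sdlog 1 — about one decade
#'   of spread, typical of the dynamic range retained after identification
#'   filtering).
#' @param n_fragments Number of most-intense b/y fragments kept per precursor
#'   (default 10).
#' @return A precursor library tibble (`source = "synthetic"`).
#' @export
#' @examples
#' lib <- generate_synthetic_library(5, seed = 1)
#' lib$stripped_sequence
generate_synthetic_library <- function(n_precursors, seed = 1L,
                                       irt_range = c(0, 100),
                                       length_range = c(7L, 20L),
                                       abundance_meanlog = log(1e5),
                                       abundance_sdlog = 1,
                                       n_fragments = 10L) {
  stopifnot(n_precursors >= 1)
  set.seed(seed)
  # residue pool without C (keeps fixtures modification-free) and without K/R
  # inside the peptide (tryptic peptides have no internal cleavage sites)
  pool <- setdiff(names(RESIDUE_COMPOSITIONS), c("C", "K", "R"))
  residue_mass <- vapply(RESIDUE_COMPOSITIONS, monoisotopic_mass, numeric(1))
  water <- monoisotopic_mass(WATER_COMPOSITION)
  rows <- purrr::map(seq_len(n_precursors), function(i) {
    len <- sample(length_range[1]:length_range[2], 1L)
    residues <- c(sample(pool, len - 1L, replace = TRUE),
                  sample(c("K", "R"), 1L))
    seq <- paste(residues, collapse = "")
    charge <- sample(2:3, 1L)
    pmz <- ion_mz(monoisotopic_mass(peptide_composition(seq)), charge)
    irt <- runif(1, irt_range[1], irt_range[2])
    abundance <- rlnorm(1, abundance_meanlog, abundance_sdlog)
    # b/y ladders from cumulative residue masses (singly protonated)
    rm <- unname(residue_mass[residues])
    idx <- seq_len(len - 1L)
    b_mz <- cumsum(rm)[idx] + PROTON_MASS
    y_mz <- cumsum(rev(rm))[idx] + water + PROTON_MASS
    ri <- runif(2L * (len - 1L), 0.02, 1)
    keep <- order(ri, decreasing = TRUE)[seq_len(min(n_fragments, 2L * (len - 1L)))]
    keep <- keep[order(c(b_mz, y_mz)[keep])]
    frag <- tibble::new_tibble(list(
      series = rep(c("b", "y"), each = len - 1L)[keep],
      index = rep(idx, 2L)[keep],
      charge = rep(1L, length(keep)),
      mz = c(b_mz, y_mz)[keep],
      rel_intensity = ri[keep] / max(ri[keep])
    ), nrow = length(keep))
    list(seq = seq, charge = charge, pmz = pmz, irt = irt,
         abundance = abundance, frag = frag)
  })
  seqs <- vapply(rows, `[[`, character(1), "seq")
  charges <- vapply(rows, `[[`, integer(1), "charge")
  lib <- tibble::tibble(
    precursor_id = paste0(seqs, "/", charges),
    stripped_sequence = seqs, modified_sequence = seqs,
    charge = charges,
    precursor_mz = vapply(rows, `[[`, numeric(1), "pmz"),
    rt_coord = vapply(rows, `[[`, numeric(1), "irt"),
    rt_basis = "irt",
    base_abundance = vapply(rows, `[[`, numeric(1), "abundance"),
    source = "synthetic",
    fragments = lapply(rows, `[[`, "frag")
  )
  # distinct ids: duplicated random sequences are re-suffixed is not possible
  # for real peptides, so just drop duplicates (rare at these lengths)
  lib <- lib[!duplicated(lib$precursor_id), , drop = FALSE]
  .new_library(lib)
}

#' Serialize a library to a Prosit-style CSV
#'
#' Writes the long one-row-per-fragment CSV that [read_prosit_library()]
#' consumes, so generated fixtures can exercise the reader round-trip.
#'
#' @param library A precursor library tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_prosit_library <- function(library, path) {
  cmap <- prosit_column_map()
  long <- library |>
    dplyr::select("modified_sequence", "stripped_sequence", "charge",
                  "precursor_mz", "rt_coord", "fragments") |>
    tidyr::unnest("fragments", names_sep = "_")
  out <- tibble::tibble(
    !!cmap[["modified_sequence"]] := long$modified_sequence,
    !!cmap[["stripped_sequence"]] := long$stripped_sequence,
    !!cmap[["charge"]] := long$charge,
    !!cmap[["precursor_mz"]] := long$precursor_mz,
    !!cmap[["irt"]] := long$rt_coord,
    !!cmap[["fragment_mz"]] := long$fragments_mz,
    !!cmap[["fragment_type"]] := long$fragments_series,
    !!cmap[["fragment_number"]] := long$fragments_index,
    !!cmap[["fragment_charge"]] := long$fragments_charge,
    !!cmap[["rel_intensity"]] := long$fragments_rel_intensity
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
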