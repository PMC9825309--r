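# The four-artifact output contract: mzML per sample, ground-truth TSV,
# replay file and parameter yaml; plus readers for all of them.

#' Write a simulated run to indexed mzML
#'
#' Emits a standards-compliant indexed mzML 1.1 file through the
#' ProteoWizard backend (via mzR): ms level, scan start time, centroid or
#' profile spectrum-type terms, MS2 precursor isolation-window target and
#' lower/upper offsets, zlib-compressed binary arrays.
#'
#' @param run A `dia_run` from [simulate_run()].
#' @param path Output file path (directory must exist).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  if (is.unsorted(run$start_time)) {
    abort("spectra must be sorted by scan start time")
  }
  if (!dir.exists(dirname(path))) {
    abort(paste0("output directory does not exist: ", dirname(path)))
  }
  instrument <- attr(run, "instrument")
  centroided <- is.null(instrument) || instrument$profile_shape == "centroid"
  n <- nrow(run)
  ms2 <- run$ms_level == 2L
  target <- ifelse(ms2, run$target_mz, NA_real_)
  peaks_count <- lengths(run$mz)
  low <- vapply(run$mz, function(m) if (length(m)) min(m) else 0, numeric(1))
  high <- vapply(run$mz, function(m) if (length(m)) max(m) else 0, numeric(1))
  bp_idx <- vapply(run$intensity, function(i) {
    if (length(i)) which.max(i) else NA_integer_
  }, integer(1))
  bp_mz <- ifelse(is.na(bp_idx), 0,
                  purrr::map2_dbl(run$mz, bp_idx, function(m, j) {
                    if (is.na(j)) 0 else m[j]
                  }))
  bp_int <- ifelse(is.na(bp_idx), 0,
                   purrr::map2_dbl(run$intensity, bp_idx, function(i, j) {
                     if (is.na(j)) 0 else i[j]
                   }))
  scal <- function(x) rep(x, length.out = n)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = as.integer(run$ms_level), polarity = scal(1L),
    peaksCount = as.integer(peaks_count),
    totIonCurrent = as.numeric(run$tic), retentionTime = run$start_time,
    basePeakMZ = as.numeric(bp_mz), basePeakIntensity = as.numeric(bp_int),
    collisionEnergy = as.numeric(ifelse(ms2, 27, 0)), ionisationEnergy = scal(0),
    lowMZ = low, highMZ = high,
    precursorScanNum = scal(0L),
    precursorMZ = as.numeric(ifelse(ms2, target, 0)),
    precursorCharge = scal(0L), precursorIntensity = scal(0),
    mergedScan = scal(0L), mergedResultScanNum = scal(0L),
    mergedResultStartScanNum = scal(0L), mergedResultEndScanNum = scal(0L),
    injectionTime = scal(0), filterString = scal(NA_character_),
    spectrumId = sprintf("scan=%d", seq_len(n)),
    centroided = scal(centroided), ionMobilityDriftTime = scal(NA_real_),
    isolationWindowTargetMZ = as.numeric(target),
    isolationWindowLowerOffset = as.numeric(ifelse(ms2, target - run$mz_lower,
                                                   NA_real_)),
    isolationWindowUpperOffset = as.numeric(ifelse(ms2, run$mz_upper - target,
                                                   NA_real_)),
    scanWindowLowerLimit = scal(if (is.null(instrument)) 0
                                else instrument$scan_range[1]),
    scanWindowUpperLimit = scal(if (is.null(instrument)) 0
                                else instrument$scan_range[2]),
    stringsAsFactors = FALSE
  )
  pks <- purrr::map2(run$mz, run$intensity, function(m, i) {
    if (!length(m)) {
      matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("mz", "intensity")))
    } else {
      cbind(mz = m, intensity = i)
    }
  })
  mzR::writeMSData(pks, file = path, header = hdr, outformat = "mzml",
                   rtime_seconds = TRUE)
  invisible(path)
}

#' Read an mzML file into a run tibble
#'
#' Reads spectra through mzR (ProteoWizard backend) into the same tibble
#' layout [simulate_run()] produces, with isolation windows reconstructed
#' from target m/z and offsets.
#'
#' @param path mzML file.
#' @return A `dia_run`-shaped tibble.
#' @export
read_mzml <- function(path) {
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  n <- nrow(hdr)
  pk <- if (n) mzR::peaks(handle) else list()
  if (n == 1L && is.matrix(pk)) pk <- list(pk)
  tibble::new_tibble(tibble::tibble(
    scan_index = seq_len(n),
    start_time = hdr$retentionTime,
    ms_level = hdr$msLevel,
    mz_lower = hdr$isolationWindowTargetMZ - hdr$isolationWindowLowerOffset,
    mz_upper = hdr$isolationWindowTargetMZ + hdr$isolationWindowUpperOffset,
    target_mz = hdr$isolationWindowTargetMZ,
    duration_s = NA_real_,
    mz = purrr::map(pk, function(p) unname(p[, 1])),
    intensity = purrr::map(pk, function(p) unname(p[, 2])),
    tic = hdr$totIonCurrent
  ), class = "dia_run")
}

# accession helpers for the xml2-based reader
.cv_value <- function(node, accession, ns) {
  p <- xml2::xml_find_first(
    node, sprintf(".//d1:cvParam[@accession='%s']", accession), ns)
  if (inherits(p, "xml_missing")) return(NA_character_)
  xml2::xml_attr(p, "value")
}

.cv_present <- function(node, accession, ns) {
  !inherits(xml2::xml_find_first(
    node, sprintf(".//d1:cvParam[@accession='%s']", accession), ns),
    "xml_missing")
}

#' Independent XML-level mzML reader
#'
#' Parses an mzML file with libxml2 (via xml2) and decodes the base64,
#' zlib-compressed binary arrays directly — a code path fully independent of
#' the ProteoWizard backend used to write and to read via [read_mzml()].
#' Intended for format-compliance checking: it insists on the required
#' controlled-vocabulary terms (ms level, m/z and intensity arrays, their
#' encoding) and checks the declared spectrum count.
#'
#' @param path mzML file.
#' @return A tibble: `scan_index`, `ms_level`, `start_time` (seconds),
#'   `mz_lower`, `mz_upper` (NA for MS1), `mz`, `intensity` list-columns.
#' @export
read_mzml_xml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  if (!grepl("mzML$", xml2::xml_name(xml2::xml_root(doc)))) {
    abort("not an mzML document")
  }
  empty <- tibble::tibble(scan_index = integer(), ms_level = integer(),
                          start_time = numeric(), mz_lower = numeric(),
                          mz_upper = numeric(), mz = list(),
                          intensity = list())
  slist <- xml2::xml_find_first(doc, "//d1:spectrumList", ns)
  # spectrumList is optional in the schema; writers omit it for empty runs
  if (inherits(slist, "xml_missing")) return(empty)
  declared <- as.integer(xml2::xml_attr(slist, "count"))
  spectra <- xml2::xml_find_all(slist, "./d1:spectrum", ns)
  if (length(spectra) != declared) {
    abort(sprintf("spectrumList declares %d spectra but contains %d",
                  declared, length(spectra)))
  }
  decode_array <- function(bda, ns) {
    is64 <- .cv_present(bda, "MS:1000523", ns)
    is32 <- .cv_present(bda, "MS:1000521", ns)
    if (!is64 && !is32) abort("binary array without a float-size CV term")
    zlib <- .cv_present(bda, "MS:1000574", ns)
    b64 <- xml2::xml_text(xml2::xml_find_first(bda, "./d1:binary", ns))
    raw <- jsonlite::base64_dec(b64)
    if (length(raw) == 0) return(numeric(0))
    if (zlib) raw <- memDecompress(raw, type = "gzip")
    readBin(raw, "double", n = length(raw) %/% (if (is64) 8L else 4L),
            size = if (is64) 8L else 4L, endian = "little")
  }
  rows <- purrr::imap(spectra, function(sp, i) {
    lev <- as.integer(.cv_value(sp, "MS:1000511", ns))
    if (is.na(lev)) abort(sprintf("spectrum %d lacks the ms-level CV term", i))
    scan <- xml2::xml_find_first(sp, ".//d1:scan", ns)
    rt_node <- xml2::xml_find_first(
      scan, "./d1:cvParam[@accession='MS:1000016']", ns)
    rt <- as.numeric(xml2::xml_attr(rt_node, "value"))
    if (identical(xml2::xml_attr(rt_node, "unitName"), "minute")) {
      rt <- rt * 60
    }
    iso <- xml2::xml_find_first(sp, ".//d1:isolationWindow", ns)
    lo <- up <- NA_real_
    if (!inherits(iso, "xml_missing")) {
      tgt <- as.numeric(.cv_value(iso, "MS:1000827", ns))
      lo <- tgt - as.numeric(.cv_value(iso, "MS:1000828", ns))
      up <- tgt + as.numeric(.cv_value(iso, "MS:1000829", ns))
    }
    bdas <- xml2::xml_find_all(sp, ".//d1:binaryDataArray", ns)
    mz <- intensity <- numeric(0)
    for (bda in bdas) {
      if (.cv_present(bda, "MS:1000514", ns)) {
        mz <- decode_array(bda, ns)
      } else if (.cv_present(bda, "MS:1000515", ns)) {
        intensity <- decode_array(bda, ns)
      }
    }
    if (length(mz) != length(intensity)) {
      abort(sprintf("spectrum %d: m/z and intensity array lengths differ", i))
    }
    tibble::tibble(scan_index = i, ms_level = lev, start_time = rt,
                   mz_lower = lo, mz_upper = up,
                   mz = list(mz), intensity = list(intensity))
  })
  if (!length(rows)) empty else dplyr::bind_rows(rows)
}

#' Write the ground-truth table
#'
#' One row per simulated species (precursors and decoys), ordered by apex
#' retention time then m/z, with per-sample abundance columns
#' (`abundance_group{g}_rep{r}`; absent cells are written as empty fields,
#' not zero) and per-group true log2 fold changes.
#'
#' @param truth Ground-truth tibble from [simulate_experiment()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  readr::write_tsv(truth, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a ground-truth table
#'
#' @param path TSV written by [write_ground_truth()]; empty abundance fields
#'   become `NA` (absent).
#' @return The ground-truth tibble.
#' @export
read_ground_truth <- function(path) {
  readr::read_tsv(path, na = "", show_col_types = FALSE, progress = FALSE)
}

#' Write the resolved parameter yaml
#'
#' Human-readable record of every configuration key, including defaulted
#' ones.
#'
#' @param config A [dia_config()].
#' @param path Output yaml path.
#' @return `path`, invisibly.
#' @export
write_parameter_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write a replay file
#'
#' Records everything needed to repeat a simulation exactly: the resolved
#' configuration (including the seed), the library source and its content
#' fingerprint, and the package version.
#'
#' @param sim A `dia_experiment`.
#' @param path Output yaml path.
#' @return `path`, invisibly.
#' @export
write_replay <- function(sim, path) {
  bundle <- list(
    diasimr_version = as.character(utils::packageVersion("diasimr")),
    library_fingerprint = sim$library_fingerprint,
    config = unclass(sim$config)
  )
  yaml::write_yaml(bundle, path)
  invisible(path)
}

#' Replay a recorded simulation
#'
#' Re-runs the simulation described by a replay file. The input library is
#' re-obtained from its recorded source (regenerated for the synthetic
#' source, re-read for file sources) and its content fingerprint must match
#' the recorded one; outputs are then identical to the original simulation.
#'
#' @param path Replay yaml from [write_replay()].
#' @param output_dir If non-`NULL`, the replayed outputs are written there via
#'   [write_simulation()].
#' @return The replayed `dia_experiment`, invisibly if written to disk.
#' @export
replay <- function(path, output_dir = NULL) {
  bundle <- yaml::read_yaml(path)
  cfg <- do.call(dia_config, bundle$config)
  library <- .config_library(cfg)
  fp <- .library_fingerprint(library)
  if (!identical(fp, bundle$library_fingerprint)) {
    abort(sprintf("library fingerprint mismatch: replay file records %s but the re-obtained library hashes to %s",
                  bundle$library_fingerprint, fp))
  }
  sim <- simulate_experiment(library, cfg)
  if (!is.null(output_dir)) {
    write_simulation(sim, output_dir)
    return(invisible(sim))
  }
  sim
}

#' Write all simulation outputs
#'
#' Emits the full output contract into a directory: one mzML per sample,
#' `ground_truth.tsv`, `replay.yaml` and `parameters.yaml`.
#'
#' @param sim A `dia_experiment`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (smp in names(sim$runs)) {
    p <- file.path(dir, paste0(smp, ".mzML"))
    write_mzml(sim$runs[[smp]], p)
    paths[smp] <- p
  }
  paths["ground_truth"] <- write_ground_truth(sim$truth,
                                              file.path(dir, "ground_truth.tsv"))
  paths["replay"] <- write_replay(sim, file.path(dir, "replay.yaml"))
  paths["parameters"] <- write_parameter_yaml(sim$config,
                                              file.path(dir, "parameters.yaml"))
  invisible(paths)
}
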