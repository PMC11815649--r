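#' @importFrom readr read_tsv write_tsv
NULL

# Atomic write contract: write to a temp file in the target directory, then
# rename over the destination.
.atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) abort(paste0("Could not move temp file onto ", path))
  invisible(path)
}

.psm_required_cols <- c("scan", "peptide", "charge", "precursor_mz", "protein")

#' Read a PSM table
#'
#' Reads the tab-separated peptide-spectrum-match table that pairs with a
#' spectrum file. Required columns: `scan`, `peptide`, `charge`,
#' `precursor_mz`, `protein`; any further columns (search scores such as
#' `xcorr`, `delta_cn`, `ppm_dev`, identifiers, ...) are preserved.
#'
#' @param path Path to a TSV file.
#' @return A validated tibble.
#' @export
read_psm_table <- function(path) {
  tab <- read_tsv(path, show_col_types = FALSE)
  missing <- setdiff(.psm_required_cols, names(tab))
  if (length(missing) > 0) {
    abort(paste0("PSM table is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(tab$charge < 1)) abort("PSM table contains charge < 1.")
  tab
}

#' Write a PSM table (atomically)
#'
#' @param psms PSM tibble.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  .atomic_write(path, function(tmp) write_tsv(psms, tmp))
}

#' Write / read a quantification table
#'
#' The quantified-peptide output of [quantify_psms()] (psm id, peptide,
#' protein, per-channel abundances, total S/N, residual, quantified flag) as
#' TSV. Writes are atomic.
#'
#' @param quant Quantification tibble.
#' @param path TSV path.
#' @return `write_quant_table()`: the path, invisibly; `read_quant_table()`:
#'   a tibble.
#' @export
write_quant_table <- function(quant, path) {
  .atomic_write(path, function(tmp) write_tsv(quant, tmp))
}

#' @rdname write_quant_table
#' @export
read_quant_table <- function(path) {
  read_tsv(path, show_col_types = FALSE)
}

#' Read centroided MS2 spectra from mzML
#'
#' Exposes scans as a tibble with one row per quantifiable MS2 scan:
#' `scan` (0-based index over MS2 scans), `native_id`, `precursor_mz`,
#' `precursor_charge` and a `peaks` list column (tibbles with `mz`,
#' `intensity`, `noise`). mzML does not carry the per-peak FT noise array,
#' so `noise` is filled with `noise_floor`. Profile-mode spectra are
#' rejected; MS2 scans without precursor metadata are skipped with a
#' warning.
#'
#' @param path mzML file.
#' @param noise_floor Per-peak noise estimate assigned on read (default 1).
#' @return Scan tibble compatible with [quantify_psms()].
#' @export
read_spectra <- function(path, noise_floor = 1) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("Package 'mzR' is required for mzML reading.")
  }
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms), add = TRUE)
  hdr <- mzR::header(ms)
  if (nrow(hdr) == 0) {
    warn("Empty spectrum file.")
    return(tibble(scan = integer(), native_id = character(),
                  precursor_mz = numeric(), precursor_charge = integer(),
                  peaks = list()))
  }
  if (any(!hdr$centroided, na.rm = TRUE)) {
    abort("Profile-mode spectra are not supported; centroid the data first.")
  }
  ms2 <- which(hdr$msLevel == 2)
  keep <- ms2[!is.na(hdr$precursorMZ[ms2]) & hdr$precursorMZ[ms2] > 0]
  if (length(keep) < length(ms2)) {
    warn(sprintf("%d MS2 scan(s) without precursor metadata skipped.",
                 length(ms2) - length(keep)))
  }
  rows <- purrr::map(seq_along(keep), function(i) {
    sc <- keep[i]
    pk <- mzR::peaks(ms, sc)
    tibble(
      scan = i - 1L,  # 0-based internal indexing; native ids preserved
      native_id = as.character(hdr$spectrumId[sc]),
      precursor_mz = hdr$precursorMZ[sc],
      precursor_charge = as.integer(hdr$precursorCharge[sc]),
      peaks = list(tibble(mz = pk[, 1], intensity = pk[, 2],
                          noise = noise_floor))
    )
  })
  bind_rows(rows)
}

#' Write spectra to mzML
#'
#' Writes the scan tibble of the simulator to centroided mzML via mzR. The
#' per-peak `noise` column is not representable in plain mzML and is
#' dropped; keep the truth ledger (or a constant noise floor) alongside.
#' Writes are atomic.
#'
#' @param spectra Scan tibble (`scan`, `precursor_mz`, `precursor_charge`,
#'   `peaks`).
#' @param path Output path (.mzML).
#' @return The path, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("Package 'mzR' is required for mzML writing.")
  }
  n <- nrow(spectra)
  pks <- purrr::map(seq_len(n), function(i) {
    p <- spectra$peaks[[i]]
    cbind(mz = p$mz, intensity = p$intensity)
  })
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 2L,
    polarity = 1L,
    peaksCount = vapply(pks, nrow, integer(1)),
    totIonCurrent = vapply(pks, function(x) sum(x[, 2]), numeric(1)),
    retentionTime = seq_len(n) * 1.0,
    basePeakMZ = vapply(pks, function(x) if (nrow(x)) x[which.max(x[, 2]), 1] else 0, numeric(1)),
    basePeakIntensity = vapply(pks, function(x) if (nrow(x)) max(x[, 2]) else 0, numeric(1)),
    collisionEnergy = 32, ionisationEnergy = 0,
    lowMZ = vapply(pks, function(x) if (nrow(x)) min(x[, 1]) else 0, numeric(1)),
    highMZ = vapply(pks, function(x) if (nrow(x)) max(x[, 1]) else 0, numeric(1)),
    precursorScanNum = 0L,
    precursorMZ = spectra$precursor_mz,
    precursorCharge = as.integer(spectra$precursor_charge),
    precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 100, filterString = "ftms",
    spectrumId = paste0("scan=", spectra$scan),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = spectra$precursor_mz,
    isolationWindowLowerOffset = 0.35, isolationWindowUpperOffset = 0.35,
    scanWindowLowerLimit = 100, scanWindowUpperLimit = 2000
  )
  .atomic_write(path, function(tmp) {
    mzR::writeMSData(object = pks, file = tmp, header = hdr, outformat = "mzml")
  })
}

#' Write a truth ledger
#'
#' Serializes the simulator's per-scan truth (without the list column of
#' noiseless peak tables) to TSV, atomically.
#'
#' @param truth Truth tibble from [simulate_interference_sample()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_truth_ledger <- function(truth, path) {
  flat <- truth |> select(-dplyr::any_of("noiseless_peaks"))
  .atomic_write(path, function(tmp) write_tsv(flat, tmp))
}

#' Read a YAML configuration file
#'
#' Named values from the file override matching formals of [sim_config()].
#'
#' @param path YAML file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- intersect(names(vals), names(formals(sim_config)))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    warn(paste0("Ignoring unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(sim_config, vals[known])
}
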