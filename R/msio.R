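#' Construct an in-memory LC-MS run
#'
#' A run holds one sample's centroided spectra ordered by retention time.
#' Spectra arriving unsorted are reordered and scan indices reassigned, so
#' downstream code can rely on a strictly increasing RT axis. Scan indices
#' are 0-based (`0 .. n-1`).
#'
#' @param sample_id character scalar identifying the sample.
#' @param rt numeric vector of retention times in seconds, one per spectrum.
#' @param spectra list of spectra, each a list with numeric `mz` (strictly
#'   ascending) and `intensity` (non-negative, same length).
#' @param metadata optional named list (polarity, instrument, ...).
#' @return An object of class `ms_run`.
#' @export
ms_run <- function(sample_id, rt, spectra, metadata = list()) {
  if (!is.character(sample_id) || length(sample_id) != 1L)
    stop_user("'sample_id' must be a single string")
  if (length(rt) != length(spectra))
    stop_user("'rt' and 'spectra' lengths differ")
  o <- order(rt)
  rt <- rt[o]
  spectra <- spectra[o]
  if (length(rt) > 1L && any(diff(rt) <= 0))
    stop_user("retention times must be strictly increasing (duplicate rt?)")
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    if (length(s$mz) != length(s$intensity))
      stop_user("spectrum ", i, ": mz and intensity lengths differ")
    if (length(s$mz) > 1L && any(diff(s$mz) <= 0)) {
      oo <- order(s$mz)
      s$mz <- s$mz[oo]
      s$intensity <- s$intensity[oo]
      spectra[[i]] <- s
    }
    if (length(s$mz) && any(s$mz <= 0))
      stop_user("spectrum ", i, ": non-positive m/z value")
  }
  structure(list(sample_id = sample_id, rt = as.numeric(rt),
                 spectra = spectra, metadata = metadata),
            class = "ms_run")
}

#' @export
print.ms_run <- function(x, ...) {
  np <- sum(vapply(x$spectra, function(s) length(s$mz), 0L))
  cat("<ms_run> sample '", x$sample_id, "': ", length(x$rt),
      " spectra, ", np, " points, rt ",
      if (length(x$rt)) paste0(round(min(x$rt), 1), "-", round(max(x$rt), 1))
      else "-", " s\n", sep = "")
  invisible(x)
}

#' @export
length.ms_run <- function(x) length(x$rt)

sniff_ms_format <- function(path) {
  head_txt <- paste(readLines(path, n = 20L, warn = FALSE), collapse = " ")
  if (grepl("<mzML", head_txt, fixed = TRUE)) return("mzML")
  if (grepl("<mzXML", head_txt, fixed = TRUE)) return("mzXML")
  NA_character_
}

#' Read a centroided mzML or mzXML file
#'
#' Parsing is delegated to \pkg{mzR}; both dialects are treated identically
#' and retention times are normalized to seconds. Only MS1 spectra are kept
#' (MS2, if present, is ignored). Profile-mode data are rejected rather than
#' centroided: centroiding is out of scope for this package.
#'
#' @param path path to an mzML or mzXML file.
#' @param format one of `"auto"`, `"mzML"`, `"mzXML"`. With `"auto"` the
#'   format is sniffed from the root element.
#' @param sample_id sample identifier; defaults to the file name without
#'   extension.
#' @return An [ms_run] object with spectra sorted by retention time.
#' @export
read_run <- function(path, format = c("auto", "mzML", "mzXML"),
                     sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_user("file not found: ", path)
  sniffed <- tryCatch(sniff_ms_format(path), error = function(e) NA_character_)
  if (format == "auto") {
    if (is.na(sniffed))
      stop_user("not a recognizable mzML/mzXML file: ", path)
    format <- sniffed
  } else if (!is.na(sniffed) && sniffed != format) {
    stop_user("file ", path, " looks like ", sniffed, ", not ", format)
  }
  fh <- tryCatch(mzR::openMSfile(path),
                 error = function(e) stop_user("cannot parse ", format,
                                               " file: ", path))
  on.exit(mzR::close(fh), add = TRUE)
  hd <- mzR::header(fh)
  if (nrow(hd) == 0L) stop_user("file contains no spectra: ", path)
  if (any(!is.na(hd$centroided) & !hd$centroided))
    stop_user("profile-mode spectra in ", path,
              "; centroided data required")
  keep <- which(hd$msLevel == 1L)
  if (!length(keep)) stop_user("file contains no MS1 spectra: ", path)
  pk <- mzR::peaks(fh, keep)
  if (is.matrix(pk)) pk <- list(pk)
  spectra <- lapply(pk, function(m)
    list(mz = as.numeric(m[, 1]), intensity = as.numeric(m[, 2])))
  if (is.null(sample_id))
    sample_id <- sub("\\.(mzML|mzXML|mzml|mzxml)$", "", basename(path))
  ms_run(sample_id, hd$retentionTime[keep], spectra,
         metadata = list(source = path, format = format))
}

b64_doubles <- function(x, endian = "little") {
  gsub("\n", "", jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                               size = 8L, endian = endian)),
       fixed = TRUE)
}

mzml_spectrum_xml <- function(i, rt, mz, intensity) {
  n <- length(mz)
  b1 <- b64_doubles(mz)
  b2 <- b64_doubles(intensity)
  paste0(
    '<spectrum index="', i - 1L, '" id="scan=', i,
    '" defaultArrayLength="', n, '">',
    '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>',
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
    '<scanList count="1">',
    '<cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>',
    '<scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="',
    sprintf("%.6f", rt),
    '" unitCvRef="UO" unitAccession="UO:0000010" unitName="second"/></scan>',
    '</scanList><binaryDataArrayList count="2">',
    '<binaryDataArray encodedLength="', nchar(b1), '">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" ',
    'unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    '<binary>', b1, '</binary></binaryDataArray>',
    '<binaryDataArray encodedLength="', nchar(b2), '">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" ',
    'unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
    '<binary>', b2, '</binary></binaryDataArray>',
    '</binaryDataArrayList></spectrum>')
}

#' Write a run as mzML
#'
#' A minimal, deterministic mzML 1.1 writer (64-bit little-endian arrays, no
#' compression, no timestamps), sufficient to round-trip synthetic runs
#' through any standards-compliant reader including [read_run]. Byte-stable
#' output from identical input makes pipeline re-runs reproducible
#' file-for-file.
#'
#' @param run an [ms_run].
#' @param path output file path (conventionally `.mzML`).
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  stopifnot(inherits(run, "ms_run"))
  n <- length(run$rt)
  body <- vapply(seq_len(n), function(i)
    mzml_spectrum_xml(i, run$rt[i], run$spectra[[i]]$mz,
                      run$spectra[[i]]$intensity), character(1))
  doc <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0" id="',
    run$sample_id, '">\n',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" ',
    'URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="http://ontologies.berkeleybop.org/uo.obo"/>',
    '</cvList>\n<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
    '</fileContent></fileDescription>\n',
    '<run id="', run$sample_id, '">\n<spectrumList count="', n, '">\n',
    paste0(body, collapse = "\n"),
    '\n</spectrumList>\n</run>\n</mzML>\n')
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(doc, con, eos = NULL)
  invisible(path)
}

#' Flatten a run to a table of ion points
#'
#' @param run an [ms_run].
#' @param min_intensity drop points below this intensity (default 0 keeps
#'   everything). Raising the threshold never adds points.
#' @return data.frame with columns `scan_index` (0-based), `rt`, `mz`,
#'   `intensity`, ordered by `(scan_index, mz)`.
#' @export
to_points <- function(run, min_intensity = 0) {
  stopifnot(inherits(run, "ms_run"))
  counts <- vapply(run$spectra, function(s) length(s$mz), 0L)
  pts <- data.frame(
    scan_index = rep(seq_along(run$rt) - 1L, counts),
    rt = rep(run$rt, counts),
    mz = unlist(lapply(run$spectra, `[[`, "mz"), use.names = FALSE) %||% numeric(0),
    intensity = unlist(lapply(run$spectra, `[[`, "intensity"),
                       use.names = FALSE) %||% numeric(0))
  if (min_intensity > 0) pts <- pts[pts$intensity >= min_intensity, ]
  rownames(pts) <- NULL
  pts
}
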