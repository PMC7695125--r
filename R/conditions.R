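## Structured conditions. Every failure mode raised by the package carries a
## dedicated condition class (prefixed "trackserve_") so callers and the REST
## layer can dispatch on it rather than on message text.

tsError <- function(class, message, ...) {
  stop(structure(
    class = c(paste0("trackserve_", class), "trackserve_error",
              "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

resourceUnavailableError <- function(uri, detail = NULL) {
  msg <- paste0("resource unavailable: ", uri)
  if (!is.null(detail)) msg <- paste0(msg, " (", detail, ")")
  tsError("resource_unavailable", msg, uri = uri)
}

rangesUnsupportedError <- function(uri) {
  tsError("ranges_unsupported",
          paste0("server does not honor HTTP range requests: ", uri),
          uri = uri)
}

outOfRangeError <- function(uri, offset, length, total) {
  tsError("out_of_range",
          sprintf("read [%s, %s) exceeds size %s of %s",
                  format(offset, scientific = FALSE),
                  format(offset + length, scientific = FALSE),
                  format(total, scientific = FALSE), uri))
}

unrecognizedFormatError <- function(what) {
  tsError("unrecognized_format", paste0("unrecognized format: ", what))
}

corruptHeaderError <- function(detail) {
  tsError("corrupt_header", paste0("corrupt header: ", detail))
}

corruptIndexError <- function(detail) {
  tsError("corrupt_index", paste0("corrupt index: ", detail))
}

corruptBlockError <- function(detail) {
  tsError("corrupt_block", paste0("corrupt block: ", detail))
}

unknownChromosomeError <- function(chrom) {
  tsError("unknown_chromosome", paste0("unknown chromosome: ", chrom),
          chrom = chrom)
}

unknownMeasurementError <- function(id) {
  tsError("unknown_measurement", paste0("unknown measurement: ", id), id = id)
}

unknownGeneError <- function(gene) {
  tsError("unknown_gene", paste0("unknown gene: ", gene), gene = gene)
}

duplicateIdError <- function(id) {
  tsError("duplicate_id", paste0("duplicate measurement id: ", id), id = id)
}

configError <- function(detail) {
  tsError("config_error", paste0("configuration error: ", detail))
}

computeError <- function(specId, detail) {
  tsError("compute_error",
          sprintf("computed measurement '%s' failed: %s", specId, detail),
          spec_id = specId)
}

shapeError <- function(specId, detail) {
  tsError("shape_error",
          sprintf("computed measurement '%s': %s", specId, detail),
          spec_id = specId)
}

overlapWithinSourceError <- function(id) {
  tsError("overlap_within_source",
          paste0("source has internally overlapping records: ", id), id = id)
}

invalidOffsetError <- function(detail) {
  tsError("invalid_offset", paste0("invalid virtual offset: ", detail))
}

serializationError <- function(detail) {
  tsError("serialization_error", paste0("serialization failure: ", detail))
}

generationError <- function(detail) {
  tsError("generation_error", paste0("fixture generation failed: ", detail))
}
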