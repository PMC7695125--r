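## Spill parsed file objects to disk and restore them. The container is a
## versioned internal format: magic string, one version byte, then the
## serialized payload (parsed metadata + pinned cache blocks). Corrupt or
## version-mismatched streams fail fast with SerializationError. Restoring
## re-opens the resource; subsequent queries hit the restored pinned blocks
## and perform new backend reads only for data blocks.

TS_MAGIC <- charToRaw("TSRVOBJ")
TS_VERSION <- as.raw(1)

#' Serialize a parsed BBI file object to disk
#'
#' Writes the parsed header, zoom headers, chromosome table and every pinned
#' cache block for this file's URI, so that a restored object answers
#' metadata-backed queries without re-reading the header structures.
#'
#' @param x a [BBIFile-class].
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @seealso [restoreBBI()]
#' @export
storeBBI <- function(x, path) {
  st <- x@cache@state
  uri <- x@handle@state$uri
  prefix <- paste0(uri, "|")
  pinned_keys <- intersect(ls(st$pinned), ls(st$entries))
  pinned_keys <- pinned_keys[startsWith(pinned_keys, prefix)]
  payload <- list(
    uri = uri, header = x@header, zooms = x@zooms, chroms = x@chroms,
    columns = x@columns,
    pinned = mget(pinned_keys, envir = st$entries))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(TS_MAGIC, con)
  writeBin(TS_VERSION, con)
  writeBin(serialize(payload, NULL), con)
  invisible(path)
}

#' Restore a BBI file object from disk
#'
#' @param path file written by [storeBBI()].
#' @param cache a [BlockCache-class] to restore pinned blocks into.
#' @return a [BBIFile-class] answering queries byte-identically to the
#'   stored object.
#' @export
restoreBBI <- function(path, cache = blockCache()) {
  if (!file.exists(path)) serializationError(paste0("no such file: ", path))
  raw <- readBin(path, "raw", file.size(path))
  nh <- length(TS_MAGIC) + 1L
  if (length(raw) < nh ||
      !identical(raw[seq_along(TS_MAGIC)], TS_MAGIC))
    serializationError("bad magic string")
  if (raw[nh] != TS_VERSION)
    serializationError(sprintf("unsupported version %d", as.integer(raw[nh])))
  payload <- tryCatch(unserialize(raw[(nh + 1L):length(raw)]),
                      error = function(e)
                        serializationError(conditionMessage(e)))
  need <- c("uri", "header", "zooms", "chroms", "columns", "pinned")
  if (!is.list(payload) || !all(need %in% names(payload)))
    serializationError("payload missing fields")
  for (key in names(payload$pinned))
    cachePut(cache, key, payload$pinned[[key]], pin = TRUE)
  handle <- openResource(payload$uri)
  new("BBIFile", handle = handle, cache = cache, header = payload$header,
      zooms = payload$zooms, chroms = payload$chroms,
      columns = payload$columns)
}
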