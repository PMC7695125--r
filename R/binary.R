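## Little cursor abstraction over a raw vector for decoding binary file
## structures. Offsets larger than 2^31 - 1 do not fit an R integer, so all
## file offsets are carried as doubles (exact up to 2^53, far beyond any
## genomic file).

newCursor <- function(raw, endian = "little") {
  env <- new.env(parent = emptyenv())
  env$raw <- raw
  env$pos <- 0           # 0-based byte position
  env$endian <- endian
  env
}

cursorRemaining <- function(cur) length(cur$raw) - cur$pos

cursorTake <- function(cur, n) {
  if (cursorRemaining(cur) < n)
    corruptBlockError(sprintf("expected %d more bytes, have %d",
                              n, cursorRemaining(cur)))
  out <- cur$raw[(cur$pos + 1):(cur$pos + n)]
  cur$pos <- cur$pos + n
  out
}

readU8 <- function(cur) as.integer(cursorTake(cur, 1L))

readU16 <- function(cur) {
  readBin(cursorTake(cur, 2L), "integer", size = 2L, signed = FALSE,
          endian = cur$endian)
}

## unsigned 32-bit as double (readBin's 4-byte integers are signed)
readU32 <- function(cur) {
  v <- readBin(cursorTake(cur, 4L), "integer", size = 4L, endian = cur$endian)
  if (v < 0) v + 4294967296 else as.double(v)
}

readU64 <- function(cur) {
  a <- readU32(cur)
  b <- readU32(cur)
  if (cur$endian == "little") a + b * 4294967296 else a * 4294967296 + b
}

readF32 <- function(cur) {
  readBin(cursorTake(cur, 4L), "numeric", size = 4L, endian = cur$endian)
}

readF64 <- function(cur) {
  readBin(cursorTake(cur, 8L), "numeric", size = 8L, endian = cur$endian)
}

readFixedString <- function(cur, n) {
  bytes <- cursorTake(cur, n)
  nul <- which(bytes == as.raw(0))
  if (length(nul)) bytes <- bytes[seq_len(nul[1] - 1L)]
  rawToChar(bytes)
}

## null-terminated string starting at the cursor
readCString <- function(cur) {
  rest <- cur$raw[(cur$pos + 1):length(cur$raw)]
  nul <- which(rest == as.raw(0))
  if (!length(nul))
    corruptBlockError("unterminated string")
  out <- if (nul[1] == 1L) "" else rawToChar(rest[seq_len(nul[1] - 1L)])
  cur$pos <- cur$pos + nul[1]
  out
}

## vectorised helpers for decoding homogeneous arrays in one readBin call
rawToU32s <- function(raw, endian = "little") {
  v <- readBin(raw, "integer", n = length(raw) %/% 4L, size = 4L,
               endian = endian)
  ifelse(v < 0, v + 4294967296, as.double(v))
}

rawToF32s <- function(raw, endian = "little") {
  readBin(raw, "numeric", n = length(raw) %/% 4L, size = 4L, endian = endian)
}

## inflate one zlib/gzip-wrapped deflate stream
inflateBlock <- function(raw) {
  out <- tryCatch(memDecompress(raw, type = "gzip"),
                  error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(out) || !is.raw(out))
    corruptBlockError("not a valid deflate stream")
  out
}
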