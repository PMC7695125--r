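## Tabix-indexed tabular files: a BGZF-compressed, position-sorted
## tab-delimited table plus a .tbi index. The index maps a genomic region to
## the "virtual offsets" (compressed block offset * 2^16 + in-block offset)
## of candidate chunks via the standard 6-level binning scheme, refined by a
## linear index of 16 kb windows.

TBI_MAGIC <- charToRaw("TBI\1")
TBI_FLAG_ZERO_BASED <- 65536      # 0x10000: coordinates already 0-based half-open
LINEAR_SHIFT <- 14                # 16 kb linear-index windows

#' Pack / unpack Tabix virtual offsets
#'
#' A virtual offset addresses an uncompressed byte inside a BGZF stream as
#' \code{compressed_block_offset * 65536 + within_block_offset}.
#'
#' @param compressedOffset byte offset of a BGZF block in the file.
#' @param uncompressedOffset offset within the decompressed block (< 65536).
#' @return \code{packVirtualOffset}: the packed numeric offset;
#'   \code{unpackVirtualOffset}: list with \code{compressed_offset} and
#'   \code{uncompressed_offset}.
#' @examples
#' packVirtualOffset(100, 5)        # 6553605
#' unpackVirtualOffset(6553605)
#' @export
packVirtualOffset <- function(compressedOffset, uncompressedOffset) {
  if (uncompressedOffset < 0 || uncompressedOffset >= 65536)
    invalidOffsetError("within-block offset must be in [0, 65536)")
  if (compressedOffset < 0)
    invalidOffsetError("block offset must be non-negative")
  compressedOffset * 65536 + uncompressedOffset
}

#' @rdname packVirtualOffset
#' @param voffset a packed virtual offset.
#' @export
unpackVirtualOffset <- function(voffset) {
  if (voffset < 0) invalidOffsetError("negative virtual offset")
  list(compressed_offset = floor(voffset / 65536),
       uncompressed_offset = voffset %% 65536)
}

#' Bins overlapping a region in the Tabix binning scheme
#'
#' The standard scheme has 6 levels (bin id offsets 0, 1, 9, 73, 585, 4681;
#' smallest bins 16 kb, coordinates up to 2^29). Returns every bin whose
#' span overlaps \code{[start, end)}.
#'
#' @param start,end 0-based half-open region, \code{0 <= start < end <= 2^29}.
#' @return numeric vector of bin ids, ascending.
#' @export
regionToBins <- function(start, end) {
  stopifnot(start >= 0, start < end, end <= 2^29)
  e <- end - 1
  bins <- 0
  for (level in 1:5) {
    offset <- c(1, 9, 73, 585, 4681)[level]
    shift <- c(26, 23, 20, 17, 14)[level]
    bins <- c(bins, (offset + floor(start / 2^shift)):(offset + floor(e / 2^shift)))
  }
  bins
}

## ---- BGZF ----

## One BGZF member starting at `offset`: returns list(size, data) where size
## is the compressed member length and data the inflated payload.
bgzfMember <- function(handle, offset, cache = NULL) {
  head <- readRange(handle, offset, 18, cache = cache)
  if (head[1] != as.raw(0x1f) || head[2] != as.raw(0x8b) ||
      head[3] != as.raw(0x08) || !as.logical(as.integer(head[4]) %/% 4 %% 2))
    corruptBlockError("not a BGZF (gzip + extra field) member")
  xlen <- as.integer(head[11]) + 256L * as.integer(head[12])
  extra <- if (xlen <= 6) head[13:(12 + xlen)]
           else readRange(handle, offset + 12, xlen, cache = cache)
  ## scan subfields for the BC block-size field
  bsize <- NA_real_
  i <- 1L
  while (i + 3L <= length(extra)) {
    slen <- as.integer(extra[i + 2]) + 256L * as.integer(extra[i + 3])
    if (extra[i] == as.raw(66) && extra[i + 1] == as.raw(67) && slen == 2) {
      bsize <- as.integer(extra[i + 4]) + 256L * as.integer(extra[i + 5]) + 1
      break
    }
    i <- i + 4L + slen
  }
  if (is.na(bsize)) corruptBlockError("BGZF member lacks BC subfield")
  member <- readRange(handle, offset, bsize, cache = cache)
  list(size = bsize, data = inflateBlock(member))
}

#' Read an uncompressed byte range out of a BGZF stream
#'
#' Decompresses only the BGZF blocks the half-open virtual range
#' \code{[from, until)} touches and returns the concatenated bytes.
#'
#' @param handle a [ResourceHandle-class] over the BGZF file.
#' @param from,until packed virtual offsets (see [packVirtualOffset()]).
#' @param cache optional [BlockCache-class].
#' @return raw vector.
#' @export
bgzfReadVirtual <- function(handle, from, until, cache = NULL) {
  if (from >= until) invalidOffsetError("empty or inverted virtual range")
  v0 <- unpackVirtualOffset(from)
  v1 <- unpackVirtualOffset(until)
  total <- resourceSize(handle)
  out <- list()
  coff <- v0$compressed_offset
  first <- TRUE
  repeat {
    if (coff >= v1$compressed_offset && v1$uncompressed_offset == 0) break
    if (!is.na(total) && coff >= total) break
    m <- bgzfMember(handle, coff, cache)
    dat <- m$data
    lo <- if (first) v0$uncompressed_offset else 0
    hi <- if (coff == v1$compressed_offset) v1$uncompressed_offset
          else length(dat)
    if (hi > lo) out[[length(out) + 1L]] <- dat[(lo + 1):hi]
    first <- FALSE
    if (coff == v1$compressed_offset) break
    coff <- coff + m$size
  }
  if (!length(out)) raw() else do.call(c, out)
}

## decompress an entire BGZF stream held in memory (used for .tbi files)
bgzfDecompressAll <- function(raw) {
  out <- list()
  off <- 0
  while (off < length(raw)) {
    if (off + 18 > length(raw)) corruptIndexError("truncated BGZF stream")
    xlen <- as.integer(raw[off + 11]) + 256L * as.integer(raw[off + 12])
    extra <- raw[(off + 13):(off + 12 + xlen)]
    bsize <- NA_real_
    i <- 1L
    while (i + 3L <= length(extra)) {
      slen <- as.integer(extra[i + 2]) + 256L * as.integer(extra[i + 3])
      if (extra[i] == as.raw(66) && extra[i + 1] == as.raw(67) && slen == 2) {
        bsize <- as.integer(extra[i + 4]) + 256L * as.integer(extra[i + 5]) + 1
        break
      }
      i <- i + 4L + slen
    }
    if (is.na(bsize) || off + bsize > length(raw))
      corruptIndexError("truncated BGZF stream")
    out[[length(out) + 1L]] <- inflateBlock(raw[(off + 1):(off + bsize)])
    off <- off + bsize
  }
  do.call(c, out)
}

## ---- .tbi parsing ----

#' Parse a Tabix (.tbi) index
#'
#' The index stream (itself BGZF-compressed) is read in full, pinned in the
#' cache, and decoded: per-sequence bin tables (bin id to chunk list) and
#' linear indexes, plus the column/format metadata describing the indexed
#' table's dialect.
#'
#' @param handle a [ResourceHandle-class] over the .tbi file.
#' @param cache optional [BlockCache-class] (the whole index read is pinned).
#' @return a list: \code{n_sequences}, \code{format_flags}, \code{col_seq},
#'   \code{col_beg}, \code{col_end}, \code{meta_char}, \code{skip_lines},
#'   \code{names}, and per-sequence \code{bins} (named list of two-column
#'   chunk matrices) and \code{linear} (virtual-offset vector per 16 kb
#'   window).
#' @export
parseTabixIndex <- function(handle, cache = NULL) {
  total <- resourceSize(handle)
  raw <- readRange(handle, 0, total, cache = cache, pin = TRUE)
  txt <- tryCatch(bgzfDecompressAll(raw), trackserve_corrupt_block = function(e)
    unrecognizedFormatError("index is not BGZF-compressed"))
  if (length(txt) < 4 || !identical(txt[1:4], TBI_MAGIC))
    unrecognizedFormatError("bad .tbi magic")
  cur <- newCursor(txt, "little")
  cursorTake(cur, 4L)
  n_ref <- readBin(cursorTake(cur, 4L), "integer", size = 4L, endian = "little")
  meta <- list(n_sequences = n_ref)
  ints <- function() readBin(cursorTake(cur, 4L), "integer", size = 4L,
                             endian = "little")
  meta$format_flags <- ints()
  meta$col_seq <- ints(); meta$col_beg <- ints(); meta$col_end <- ints()
  meta$meta_char <- rawToChar(as.raw(ints()))
  meta$skip_lines <- ints()
  l_nm <- ints()
  name_raw <- cursorTake(cur, l_nm)
  nuls <- which(name_raw == as.raw(0))
  starts <- c(1L, utils::head(nuls, -1L) + 1L)
  meta$names <- vapply(seq_along(nuls), function(i) {
    if (starts[i] > nuls[i] - 1L) "" else
      rawToChar(name_raw[starts[i]:(nuls[i] - 1L)])
  }, character(1))
  meta$names <- meta$names[meta$names != ""]
  if (length(meta$names) != n_ref)
    corruptIndexError("sequence name count mismatch")
  meta$bins <- vector("list", n_ref)
  meta$linear <- vector("list", n_ref)
  for (r in seq_len(n_ref)) {
    n_bin <- ints()
    if (is.na(n_bin) || n_bin < 0) corruptIndexError("negative bin count")
    bins <- list()
    for (b in seq_len(n_bin)) {
      bin_id <- readU32(cur)
      n_chunk <- ints()
      chunks <- matrix(numeric(), ncol = 2,
                       dimnames = list(NULL, c("beg", "end")))
      if (n_chunk > 0) {
        chunks <- matrix(vapply(seq_len(2L * n_chunk), function(i) readU64(cur),
                                numeric(1)),
                         ncol = 2, byrow = TRUE,
                         dimnames = list(NULL, c("beg", "end")))
      }
      if (bin_id == 37450) next   # pseudo-bin: per-sequence summary, not chunks
      if (nrow(chunks) && any(chunks[, "beg"] >= chunks[, "end"]))
        corruptIndexError("chunk with empty virtual range")
      bins[[as.character(bin_id)]] <- chunks
    }
    n_intv <- ints()
    lin <- vapply(seq_len(max(0L, n_intv)), function(i) readU64(cur), numeric(1))
    meta$bins[[r]] <- bins
    meta$linear[[r]] <- lin
  }
  names(meta$bins) <- meta$names
  names(meta$linear) <- meta$names
  meta
}

## ---- track object + query ----

#' Tabix-indexed tabular track
#'
#' @slot handle [ResourceHandle-class] over the BGZF data file.
#' @slot index parsed .tbi index (see [parseTabixIndex()]).
#' @slot cache shared [BlockCache-class].
#' @slot columns declared names for the non-coordinate columns.
#' @export
setClass("TabixTrack",
  representation(handle = "ResourceHandle", index = "list",
                 cache = "BlockCache", columns = "character"))

#' Open a Tabix-indexed table
#'
#' @param uri path/URL of the BGZF-compressed data file.
#' @param indexUri path/URL of the .tbi index (default \code{uri + ".tbi"}).
#' @param cache a [BlockCache-class].
#' @param columns optional names for the value columns (those other than the
#'   sequence/begin/end columns declared by the index).
#' @return a [TabixTrack-class].
#' @export
openTabix <- function(uri, indexUri = paste0(uri, ".tbi"),
                      cache = blockCache(), columns = character()) {
  handle <- openResource(uri)
  ih <- openResource(indexUri)
  index <- parseTabixIndex(ih, cache)
  new("TabixTrack", handle = handle, index = index, cache = cache,
      columns = columns)
}

#' @export
setMethod("show", "TabixTrack", function(object) {
  cat(sprintf("TabixTrack: %s\n  sequences: %s\n", object@handle@state$uri,
              paste(object@index$names, collapse = ", ")))
})

#' Query a Tabix-indexed table by genomic range
#'
#' Candidate chunks are gathered from the bins overlapping the region and
#' pruned by the linear index's lower bound; only the BGZF blocks those
#' chunks touch are decompressed. Each matching line is parsed into a row
#' with coordinates normalized to 0-based half-open (per the index's format
#' flags) and the remaining columns as value columns (numeric when every
#' cell parses, else text).
#'
#' @param x a [TabixTrack-class].
#' @param chrom sequence name (must be in the index).
#' @param start,end 0-based half-open query range.
#' @return an [IntervalFrame-class].
#' @export
queryTabix <- function(x, chrom, start, end) {
  stopifnot(start >= 0, start < end)
  idx <- x@index
  r <- match(chrom, idx$names)
  if (is.na(r)) unknownChromosomeError(chrom)
  bins <- idx$bins[[r]]
  want <- as.character(regionToBins(start, end))
  chunks <- do.call(rbind, unname(bins[intersect(want, names(bins))]))
  if (is.null(chunks) || !nrow(chunks)) return(tabixEmpty(x))
  ## linear-index lower bound for the window containing `start`
  lin <- idx$linear[[r]]
  w <- floor(start / 2^LINEAR_SHIFT) + 1
  min_off <- if (length(lin) >= w) lin[w] else if (length(lin)) lin[length(lin)] else 0
  keep <- chunks[, "end"] > min_off
  chunks <- chunks[keep, , drop = FALSE]
  if (!nrow(chunks)) return(tabixEmpty(x))
  chunks[, "beg"] <- pmax(chunks[, "beg"], min_off)
  chunks <- chunks[order(chunks[, "beg"]), , drop = FALSE]
  ## merge overlapping/adjacent chunks so no block is decoded twice
  merged <- list(chunks[1, ])
  for (i in seq_len(nrow(chunks))[-1]) {
    last <- merged[[length(merged)]]
    if (chunks[i, "beg"] <= last["end"])
      merged[[length(merged)]]["end"] <- max(last["end"], chunks[i, "end"])
    else merged[[length(merged) + 1L]] <- chunks[i, ]
  }
  lines <- character()
  for (ck in merged) {
    bytes <- bgzfReadVirtual(x@handle, ck["beg"], ck["end"], x@cache)
    if (length(bytes))
      lines <- c(lines, strsplit(rawToChar(bytes), "\n", fixed = TRUE)[[1]])
  }
  parseTabixLines(x, lines, chrom, start, end)
}

tabixEmpty <- function(x) {
  emptyIntervalFrame(if (length(x@columns)) x@columns else character())
}

parseTabixLines <- function(x, lines, chrom, start, end) {
  idx <- x@index
  lines <- lines[nzchar(lines)]
  if (nchar(idx$meta_char))
    lines <- lines[!startsWith(lines, idx$meta_char)]
  if (!length(lines)) return(tabixEmpty(x))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- max(lengths(fields))
  mat <- vapply(fields, function(p) c(p, rep(NA_character_, nf - length(p))),
                character(nf))
  mat <- matrix(mat, nrow = nf)
  seqs <- mat[idx$col_seq, ]
  keep <- seqs == chrom
  mat <- mat[, keep, drop = FALSE]
  if (!ncol(mat)) return(tabixEmpty(x))
  beg <- as.numeric(mat[idx$col_beg, ])
  zero_based <- bitwAnd(idx$format_flags, TBI_FLAG_ZERO_BASED) != 0
  if (!zero_based) beg <- beg - 1            # 1-based inclusive -> 0-based
  if (idx$col_end > 0 && idx$col_end != idx$col_beg && idx$col_end <= nf) {
    ends <- as.numeric(mat[idx$col_end, ])   # end column is exclusive bound
  } else {
    ends <- beg + 1
  }
  ok <- !is.na(beg) & !is.na(ends) & beg < ends & beg < end & ends > start
  mat <- mat[, ok, drop = FALSE]
  beg <- beg[ok]; ends <- ends[ok]
  if (!length(beg)) return(tabixEmpty(x))
  value_cols <- setdiff(seq_len(nf), c(idx$col_seq, idx$col_beg,
                                       if (idx$col_end > 0) idx$col_end))
  vals <- lapply(value_cols, function(j) coerceColumn(mat[j, ]))
  nm <- if (length(x@columns) >= length(value_cols))
    x@columns[seq_along(value_cols)] else paste0("col", value_cols)
  values <- S4Vectors::DataFrame(vals)
  names(values) <- nm
  intervalFrame(rep(chrom, length(beg)), beg, ends, values)
}
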