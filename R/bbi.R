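## BBI container parsing: BigWig and BigBed share one layout — a 64-byte
## header, a list of 24-byte zoom headers, a chromosome B+ tree, an R-tree
## spatial index over data blocks, and (per zoom level) reduced data with its
## own R-tree. Every structure is read through readRange() so that fetch
## accounting can prove a query touches only header + tree path + overlapping
## blocks.

BIGWIG_MAGIC <- 0x888FFC26
BIGBED_MAGIC <- 0x8789F2EB
CHROM_TREE_MAGIC <- 0x78CA8C91
RTREE_MAGIC <- 0x2468ACE0

#' Parsed handle over a BigWig or BigBed file
#'
#' Created by [openBBI()]. Holds the resource handle, the parsed main
#' header, zoom-level headers and chromosome table, plus the shared block
#' cache. Header, zoom headers and chromosome tree reads are pinned in the
#' cache; data and index blocks are cached subject to eviction.
#'
#' @slot handle the underlying [ResourceHandle-class].
#' @slot cache the [BlockCache-class] used for all reads.
#' @slot header list: \code{kind} ("bigwig"/"bigbed"), \code{endian},
#'   \code{version}, \code{zoom_levels}, tree/data/index offsets,
#'   \code{field_count}, \code{defined_field_count},
#'   \code{uncompress_buf_size}.
#' @slot zooms data.frame with \code{reduction_level}, \code{data_offset},
#'   \code{index_offset}, one row per zoom level (coarsest last).
#' @slot chroms data.frame with \code{name}, \code{id}, \code{length}.
#' @slot columns character: names for BigBed rest-of-line fields.
#' @export
setClass("BBIFile",
  representation(handle = "ResourceHandle", cache = "BlockCache",
                 header = "list", zooms = "data.frame",
                 chroms = "data.frame", columns = "character"))

#' Open and parse a BigWig/BigBed file
#'
#' Reads and pins the main header, zoom headers and chromosome B+ tree.
#' Nothing else is read until a query arrives. Both byte orders are
#' supported; the format is detected solely from the magic number.
#'
#' @param uri local path or http(s) URL of a BigWig or BigBed file.
#' @param cache a [BlockCache-class] (a private one is created if omitted).
#' @param columns optional column names for BigBed rest-of-line fields;
#'   unnamed fields fall back to \code{col4, col5, ...}.
#' @return a [BBIFile-class].
#' @export
openBBI <- function(uri, cache = blockCache(), columns = character()) {
  handle <- openResource(uri)
  hd <- parseBBIHeader(handle, cache)
  chroms <- readChromTree(handle, hd$header, cache)
  new("BBIFile", handle = handle, cache = cache, header = hd$header,
      zooms = hd$zooms, chroms = chroms, columns = columns)
}

#' @describeIn openBBI parsed main header (list).
#' @param x a [BBIFile-class].
#' @export
bbiHeader <- function(x) x@header

#' @describeIn openBBI chromosome table (data.frame: name, id, length).
#' @export
bbiChroms <- function(x) x@chroms

#' @describeIn openBBI zoom-level table (data.frame: reduction_level,
#'   data_offset, index_offset).
#' @export
bbiZoomLevels <- function(x) x@zooms

#' @export
setMethod("show", "BBIFile", function(object) {
  cat(sprintf("BBIFile (%s, v%d): %s\n", object@header$kind,
              object@header$version, object@handle@state$uri))
  cat(sprintf("  %d chromosome(s), %d zoom level(s), %s blocks\n",
              nrow(object@chroms), nrow(object@zooms),
              if (object@header$uncompress_buf_size > 0) "compressed"
              else "uncompressed"))
})

## ---- header ----

parseBBIHeader <- function(handle, cache) {
  raw <- readRange(handle, 0, 64, cache = cache, pin = TRUE)
  endian <- NULL
  for (e in c("little", "big")) {
    cur <- newCursor(raw, e)
    magic <- readU32(cur)
    if (magic == BIGWIG_MAGIC || magic == BIGBED_MAGIC) {
      endian <- e
      kind <- if (magic == BIGWIG_MAGIC) "bigwig" else "bigbed"
      break
    }
  }
  if (is.null(endian)) unrecognizedFormatError("magic is neither BigWig nor BigBed")
  header <- list(
    kind = kind, endian = endian,
    version = readU16(cur), zoom_levels = readU16(cur),
    chrom_tree_offset = readU64(cur), full_data_offset = readU64(cur),
    full_index_offset = readU64(cur),
    field_count = readU16(cur), defined_field_count = readU16(cur),
    auto_sql_offset = readU64(cur), total_summary_offset = readU64(cur),
    uncompress_buf_size = readU32(cur))
  total <- resourceSize(handle)
  offs <- c(header$chrom_tree_offset, header$full_data_offset,
            header$full_index_offset)
  if (!is.na(total) && any(offs > total))
    corruptHeaderError("structure offsets beyond end of file")
  zooms <- data.frame(reduction_level = numeric(), data_offset = numeric(),
                      index_offset = numeric())
  if (header$zoom_levels > 0) {
    zraw <- readRange(handle, 64, 24 * header$zoom_levels,
                      cache = cache, pin = TRUE)
    zcur <- newCursor(zraw, endian)
    for (i in seq_len(header$zoom_levels)) {
      rl <- readU32(zcur); readU32(zcur)
      zooms[i, ] <- c(rl, readU64(zcur), readU64(zcur))
    }
    if (is.unsorted(zooms$reduction_level, strictly = TRUE))
      corruptHeaderError("zoom reduction levels must strictly increase")
  }
  list(header = header, zooms = zooms)
}

## ---- chromosome B+ tree ----

readChromTree <- function(handle, header, cache) {
  off <- header$chrom_tree_offset
  raw <- readRange(handle, off, 32, cache = cache, pin = TRUE)
  cur <- newCursor(raw, header$endian)
  if (readU32(cur) != CHROM_TREE_MAGIC)
    corruptIndexError("bad chromosome B+ tree magic")
  readU32(cur)                       # block size
  key_size <- readU32(cur)
  val_size <- readU32(cur)
  if (val_size != 8) corruptIndexError("chromosome tree value size != 8")
  out <- list(name = character(), id = numeric(), length = numeric())
  walk <- function(node_off) {
    nraw <- readRange(handle, node_off, 4, cache = cache, pin = TRUE)
    ncur <- newCursor(nraw, header$endian)
    is_leaf <- readU8(ncur); readU8(ncur)
    count <- readU16(ncur)
    item <- if (is_leaf) key_size + 8 else key_size + 8
    body <- readRange(handle, node_off + 4, count * item,
                      cache = cache, pin = TRUE)
    bcur <- newCursor(body, header$endian)
    for (i in seq_len(count)) {
      key <- readFixedString(bcur, key_size)
      if (is_leaf) {
        out$name <<- c(out$name, key)
        out$id <<- c(out$id, readU32(bcur))
        out$length <<- c(out$length, readU32(bcur))
      } else {
        walk(readU64(bcur))
      }
    }
  }
  walk(off + 32)
  df <- data.frame(name = out$name, id = out$id, length = out$length,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) corruptIndexError("duplicate chromosome ids")
  df[order(df$id), , drop = FALSE]
}

## ---- R-tree traversal ----

## Returns the leaf items (data blocks) overlapping [start, end) on chrom_id,
## in file order, reading only index nodes on overlapping root-to-leaf paths.
findBlocks <- function(handle, cache, endian, index_offset, chrom_id,
                       start, end) {
  raw <- readRange(handle, index_offset, 48, cache = cache)
  cur <- newCursor(raw, endian)
  if (readU32(cur) != RTREE_MAGIC) corruptIndexError("bad R-tree magic")
  blocks <- list()
  overlaps <- function(sc, sb, ec, eb) {
    (sc < chrom_id || (sc == chrom_id && sb < end)) &&
      (ec > chrom_id || (ec == chrom_id && eb > start))
  }
  visit <- function(node_off) {
    nraw <- readRange(handle, node_off, 4, cache = cache)
    ncur <- newCursor(nraw, endian)
    is_leaf <- readU8(ncur); readU8(ncur)
    count <- readU16(ncur)
    if (count == 0) return()
    item <- if (is_leaf) 32 else 24
    body <- readRange(handle, node_off + 4, count * item, cache = cache)
    bcur <- newCursor(body, endian)
    for (i in seq_len(count)) {
      sc <- readU32(bcur); sb <- readU32(bcur)
      ec <- readU32(bcur); eb <- readU32(bcur)
      if (is_leaf) {
        doff <- readU64(bcur); dsize <- readU64(bcur)
        if (overlaps(sc, sb, ec, eb))
          blocks[[length(blocks) + 1L]] <<- list(
            chrom_id_start = sc, base_start = sb, chrom_id_end = ec,
            base_end = eb, offset = doff, size = dsize)
      } else {
        coff <- readU64(bcur)
        if (overlaps(sc, sb, ec, eb)) visit(coff)
      }
    }
  }
  visit(index_offset + 48)
  blocks
}

## ---- block decoders ----

#' Decode one BigWig data section
#'
#' A section is a 24-byte header followed by items in one of three layouts:
#' bedGraph-style (type 1: start, end, value), variable step (type 2: start,
#' value, width = span) or fixed step (type 3: value only, positions derived
#' from the section start/step/span).
#'
#' @param raw decompressed section bytes.
#' @param chromMap data.frame from [bbiChroms()] mapping ids to names.
#' @param endian byte order of the file.
#' @return an [IntervalFrame-class] with a \code{value} column.
#' @export
decodeWigSection <- function(raw, chromMap, endian = "little") {
  cur <- newCursor(raw, endian)
  chrom_id <- readU32(cur)
  chrom_start <- readU32(cur); chrom_end <- readU32(cur)
  step <- readU32(cur); span <- readU32(cur)
  type <- readU8(cur); readU8(cur)
  count <- readU16(cur)
  chrom <- chromMap$name[match(chrom_id, chromMap$id)]
  if (is.na(chrom)) corruptBlockError(sprintf("unknown chrom id %d", chrom_id))
  item_size <- c(`1` = 12L, `2` = 8L, `3` = 4L)[as.character(type)]
  if (is.na(item_size))
    corruptBlockError(sprintf("unknown section type %d", type))
  if (cursorRemaining(cur) < count * item_size)
    corruptBlockError("item count exceeds section size")
  body <- cursorTake(cur, count * item_size)
  if (type == 1L) {
    words <- rawToU32s(body, endian)
    idx <- seq_len(count)
    starts <- words[(idx - 1L) * 3L + 1L]
    ends <- words[(idx - 1L) * 3L + 2L]
    vals <- rawToF32s(body, endian)[(idx - 1L) * 3L + 3L]
  } else if (type == 2L) {
    words <- rawToU32s(body, endian)
    idx <- seq_len(count)
    starts <- words[(idx - 1L) * 2L + 1L]
    ends <- starts + span
    vals <- rawToF32s(body, endian)[(idx - 1L) * 2L + 2L]
  } else {
    starts <- chrom_start + (seq_len(count) - 1L) * step
    ends <- starts + span
    vals <- rawToF32s(body, endian)
  }
  intervalFrame(chrom, starts, ends, S4Vectors::DataFrame(value = vals))
}

#' Decode one BigBed data block
#'
#' Items are (chromId, start, end) followed by a null-terminated
#' rest-of-line; the rest is split on tabs into named columns per the
#' measurement's declared schema (unnamed fields become \code{col4, col5,
#' ...} following BED column numbering).
#'
#' @inheritParams decodeWigSection
#' @param columns declared names for the rest-of-line fields.
#' @return an [IntervalFrame-class].
#' @export
decodeBedBlock <- function(raw, chromMap, columns = character(),
                           endian = "little") {
  cur <- newCursor(raw, endian)
  chrom_id <- numeric(); starts <- numeric(); ends <- numeric()
  rests <- character()
  while (cursorRemaining(cur) > 0) {
    if (cursorRemaining(cur) < 12)
      corruptBlockError("truncated BigBed item header")
    chrom_id <- c(chrom_id, readU32(cur))
    starts <- c(starts, readU32(cur))
    ends <- c(ends, readU32(cur))
    rests <- c(rests, readCString(cur))
  }
  chrom <- chromMap$name[match(chrom_id, chromMap$id)]
  if (anyNA(chrom)) corruptBlockError("unknown chrom id in BigBed block")
  values <- splitRestFields(rests, columns)
  intervalFrame(chrom, starts, ends, values)
}

splitRestFields <- function(rests, columns) {
  if (!length(rests)) return(S4Vectors::DataFrame(matrix(nrow = 0, ncol = 0)))
  parts <- strsplit(rests, "\t", fixed = TRUE)
  nf <- max(c(0L, lengths(parts)))
  if (nf == 0L)
    return(S4Vectors::DataFrame(matrix(nrow = length(rests), ncol = 0)))
  mat <- vapply(parts, function(p) c(p, rep(NA_character_, nf - length(p))),
                character(nf))
  mat <- matrix(mat, nrow = nf)
  nm <- if (length(columns) >= nf) columns[seq_len(nf)]
        else c(columns, paste0("col", (length(columns) + 4L):(nf + 3L)))
  cols <- lapply(seq_len(nf), function(j) coerceColumn(mat[j, ]))
  values <- S4Vectors::DataFrame(cols)
  names(values) <- nm
  values
}

## numbers when every non-missing cell parses as one, else text
coerceColumn <- function(x) {
  ok <- !is.na(x) & x != ""
  if (!any(ok)) return(x)
  num <- suppressWarnings(as.numeric(x[ok]))
  if (anyNA(num)) x else {
    out <- rep(NA_real_, length(x)); out[ok] <- num; out
  }
}

#' Decode a block of 32-byte zoom records
#'
#' Each record summarizes a fixed span: (chromId, start, end, validCount,
#' min, max, sum, sumSquares). The mean over a record is
#' \code{sum / validCount} where \code{validCount > 0}.
#'
#' @inheritParams decodeWigSection
#' @return data.frame with one row per record plus a \code{mean} column.
#' @export
decodeZoomBlock <- function(raw, endian = "little") {
  if (length(raw) %% 32 != 0)
    corruptBlockError(sprintf("zoom block length %d not a multiple of 32",
                              length(raw)))
  n <- length(raw) %/% 32
  cur <- newCursor(raw, endian)
  out <- data.frame(chrom_id = numeric(n), start = numeric(n),
                    end = numeric(n), valid_count = numeric(n),
                    min = numeric(n), max = numeric(n), sum = numeric(n),
                    sum_sq = numeric(n))
  for (i in seq_len(n)) {
    out$chrom_id[i] <- readU32(cur)
    out$start[i] <- readU32(cur)
    out$end[i] <- readU32(cur)
    out$valid_count[i] <- readU32(cur)
    out$min[i] <- readF32(cur)
    out$max[i] <- readF32(cur)
    out$sum[i] <- readF32(cur)
    out$sum_sq[i] <- readF32(cur)
  }
  out$mean <- ifelse(out$valid_count > 0, out$sum / out$valid_count, NA_real_)
  out
}

## ---- query ----

bbiChromId <- function(x, chrom) {
  i <- match(chrom, x@chroms$name)
  if (is.na(i)) unknownChromosomeError(chrom)
  x@chroms$id[i]
}

readBlock <- function(x, block) {
  raw <- readRange(x@handle, block$offset, block$size, cache = x@cache)
  if (x@header$uncompress_buf_size > 0) inflateBlock(raw) else raw
}

#' Query a BigWig/BigBed file for a genomic region
#'
#' Returns all records overlapping \code{[start, end)} in coordinate order,
#' with their original (unclipped) coordinates — clipping and weighting are
#' the summarizer's job. Only the R-tree nodes on overlapping root-to-leaf
#' paths and the overlapping data blocks are read. With \code{zoomIndex}
#' set, records come from that zoom level's own index and data, and the
#' \code{value} column carries each zoom record's mean.
#'
#' @param x a [BBIFile-class].
#' @param chrom chromosome name (must be present in the file).
#' @param start,end 0-based half-open query range.
#' @param zoomIndex 1-based row of [bbiZoomLevels()], or \code{NULL} for
#'   full-resolution records.
#' @return an [IntervalFrame-class]; for BigWig a \code{value} column, for
#'   BigBed the rest-of-line columns, for zoom queries columns \code{value}
#'   (mean), \code{valid_count}, \code{min}, \code{max}.
#' @export
queryBBI <- function(x, chrom, start, end, zoomIndex = NULL) {
  stopifnot(start >= 0, start < end)
  cid <- bbiChromId(x, chrom)
  if (!is.null(zoomIndex)) {
    if (zoomIndex < 1 || zoomIndex > nrow(x@zooms))
      corruptIndexError(sprintf("zoom index %d out of range", zoomIndex))
    index_off <- x@zooms$index_offset[zoomIndex]
  } else {
    index_off <- x@header$full_index_offset
  }
  emptyCols <- if (!is.null(zoomIndex)) c("value", "valid_count", "min", "max")
               else if (x@header$kind == "bigwig") "value" else x@columns
  blocks <- findBlocks(x@handle, x@cache, x@header$endian, index_off,
                       cid, start, end)
  if (!length(blocks)) return(emptyIntervalFrame(emptyCols))
  frames <- lapply(blocks, function(b) {
    raw <- readBlock(x, b)
    if (!is.null(zoomIndex)) {
      z <- decodeZoomBlock(raw, x@header$endian)
      z <- z[z$chrom_id == cid & z$start < end & z$end > start, , drop = FALSE]
      intervalFrame(rep(chrom, nrow(z)), z$start, z$end,
                    S4Vectors::DataFrame(value = z$mean,
                                         valid_count = z$valid_count,
                                         min = z$min, max = z$max))
    } else if (x@header$kind == "bigwig") {
      f <- decodeWigSection(raw, x@chroms, x@header$endian)
      frameOverlap(f, chrom, start, end)
    } else {
      f <- decodeBedBlock(raw, x@chroms, x@columns, x@header$endian)
      frameOverlap(f, chrom, start, end)
    }
  })
  out <- bindFrames(frames)
  if (!length(out)) return(emptyIntervalFrame(emptyCols))
  out
}

bindFrames <- function(frames) {
  frames <- frames[vapply(frames, length, integer(1)) > 0]
  if (!length(frames)) return(emptyIntervalFrame())
  chrom <- unlist(lapply(frames, frameChrom))
  start <- unlist(lapply(frames, frameStart))
  end <- unlist(lapply(frames, frameEnd))
  values <- do.call(rbind, lapply(frames, frameValues))
  f <- intervalFrame(chrom, start, end, values)
  ## drop duplicate records when a query revisits a block boundary
  dup <- duplicated(data.frame(f@chrom, f@start, f@end))
  if (any(dup)) f <- frameSlice(f, !dup)
  f
}
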