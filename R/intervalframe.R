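#' Ordered table of genomic intervals with value columns
#'
#' The universal result container: one row per interval in 0-based half-open
#' coordinates, sorted by (chrom, start, end), plus zero or more value
#' columns aligned to the rows. All parsers (BigWig, BigBed, Tabix) and the
#' transformation/binning engine produce and consume \code{IntervalFrame}s,
#' so the overlap algebra is single-sourced on one coordinate convention.
#'
#' @slot chrom character vector of chromosome names.
#' @slot start,end double vectors, 0-based half-open (\code{start < end}).
#' @slot values a [S4Vectors::DataFrame-class] of per-row columns.
#' @export
setClass("IntervalFrame",
  representation(chrom = "character", start = "numeric", end = "numeric",
                 values = "DataFrame"),
  validity = function(object) {
    n <- length(object@chrom)
    if (length(object@start) != n || length(object@end) != n)
      return("chrom, start and end must have equal length")
    if (nrow(object@values) != n)
      return("value columns must have one entry per row")
    if (n && any(object@start >= object@end))
      return("all intervals must satisfy start < end")
    if (n && any(object@start < 0))
      return("starts must be non-negative")
    if (n > 1) {
      ## contiguous chromosome runs, sorted within each
      r <- rle(object@chrom)
      if (any(duplicated(r$values)))
        return("rows of one chromosome must be contiguous")
      o <- order(match(object@chrom, r$values), object@start, object@end)
      if (is.unsorted(o))
        return("rows must be sorted by (chrom, start, end)")
    }
    TRUE
  })

#' Construct an IntervalFrame
#'
#' Rows are sorted by (chrom, start, end); chromosome order follows first
#' appearance in the input.
#'
#' @param chrom,start,end interval coordinates, 0-based half-open.
#' @param values data.frame or DataFrame of value columns (may be omitted).
#' @return an [IntervalFrame-class].
#' @examples
#' intervalFrame("chr1", c(0, 10), c(10, 20), data.frame(value = c(1, 2)))
#' @export
intervalFrame <- function(chrom = character(), start = numeric(),
                          end = numeric(), values = NULL) {
  n <- length(start)
  chrom <- rep_len(as.character(chrom), n)
  if (is.null(values)) values <- S4Vectors::DataFrame(matrix(nrow = n, ncol = 0))
  values <- as(values, "DataFrame")
  o <- order(match(chrom, unique(chrom)), start, end)
  new("IntervalFrame", chrom = chrom[o], start = as.double(start)[o],
      end = as.double(end)[o], values = values[o, , drop = FALSE])
}

#' @describeIn intervalFrame an empty frame with named (zero-row) columns.
#' @param colnames column names for an empty frame.
#' @export
emptyIntervalFrame <- function(colnames = character()) {
  v <- S4Vectors::DataFrame(matrix(numeric(), nrow = 0, ncol = length(colnames)))
  names(v) <- colnames
  new("IntervalFrame", chrom = character(), start = numeric(),
      end = numeric(), values = v)
}

#' @export
setMethod("length", "IntervalFrame", function(x) length(x@start))

#' Accessors for IntervalFrame rows and columns
#' @param x an [IntervalFrame-class].
#' @return \code{frameChrom}, \code{frameStart}, \code{frameEnd}: per-row
#'   vectors; \code{frameValues}: the DataFrame of value columns.
#' @export
frameChrom <- function(x) x@chrom
#' @rdname frameChrom
#' @export
frameStart <- function(x) x@start
#' @rdname frameChrom
#' @export
frameEnd <- function(x) x@end
#' @rdname frameChrom
#' @export
frameValues <- function(x) x@values

#' @export
setMethod("as.data.frame", "IntervalFrame", function(x, ...) {
  cbind(data.frame(chrom = x@chrom, start = x@start, end = x@end,
                   stringsAsFactors = FALSE),
        as.data.frame(x@values))
})

setAs("IntervalFrame", "GRanges", function(from) {
  gr <- GenomicRanges::GRanges(
    from@chrom, IRanges::IRanges(start = from@start + 1, end = from@end))
  S4Vectors::mcols(gr) <- from@values
  gr
})

#' @export
setMethod("show", "IntervalFrame", function(object) {
  cat(sprintf("IntervalFrame with %d rows and %d value column(s)\n",
              length(object), ncol(object@values)))
  if (length(object)) {
    df <- as.data.frame(object)
    print(utils::head(df, 8))
    if (nrow(df) > 8) cat("...\n")
  }
})

## row subset (internal + tests)
frameSlice <- function(x, i) {
  new("IntervalFrame", chrom = x@chrom[i], start = x@start[i],
      end = x@end[i], values = x@values[i, , drop = FALSE])
}

## overlap filter against [start, end) on one chromosome; unclipped rows
frameOverlap <- function(x, chrom, start, end) {
  keep <- x@chrom == chrom & x@start < end & x@end > start
  frameSlice(x, keep)
}
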